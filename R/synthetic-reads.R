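#' @importFrom Biostrings BStringSet
NULL

## Vectorized fragment sampling from one haplotype genome; returns a
## data.frame of fragment coordinates plus mate sequences.
.sampleFragments <- function(hap, n, read_len, ins_mean, ins_sd) {
  lens <- nchar(as.character(hap))
  chrom <- sample(names(hap), n, replace = TRUE, prob = lens / sum(lens))
  flen <- pmax(2L * read_len + 20L,
               as.integer(round(rnorm(n, ins_mean, ins_sd))))
  res <- vector("list", length(hap))
  for (ch in names(hap)) {
    idx <- which(chrom == ch)
    if (!length(idx)) next
    L <- lens[[match(ch, names(hap))]]
    fl <- pmin(flen[idx], L)
    st <- floor(runif(length(idx), 1, L - fl + 1))
    s <- as.character(hap[[ch]])
    r1 <- substring(s, st, st + read_len - 1L)
    r2 <- revComp(substring(s, st + fl - read_len, st + fl - 1L))
    res[[ch]] <- data.frame(chrom = ch, start = st, end = st + fl - 1L,
                            r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulate paired-end resequencing reads for the accession panel
#'
#' For every accession in the truth genotype matrix, builds its two
#' haplotype genomes as mosaics of genomes A and B dictated by the truth
#' genotypes (heterozygous loci contribute reads from both haplotypes at
#' ~50:50), samples fragments uniformly at the configured depth, applies
#' per-base substitution errors, and writes gzip-compressed paired FASTQ
#' files (mate suffixes \code{/1}, \code{/2}).
#'
#' @param genome_a,genome_b \code{DNAStringSet} assemblies from
#'   \code{\link{generateGenomePair}}.
#' @param truth \linkS4class{TruthSet} (genotype matrix drives the mosaics).
#' @param config the \linkS4class{SimulationConfig} used throughout.
#' @param out_dir directory for FASTQ output (created if needed).
#' @param accessions subset of accession ids (default: all rows of the
#'   genotype matrix).
#' @return list with \code{files}: data.frame
#'   (\code{accession,fq1,fq2,n_pairs}) and \code{truth}: the input truth
#'   with per-read provenance filled in.
#' @export
generateAccessionReads <- function(genome_a, genome_b, truth, config,
                                   out_dir, accessions = NULL) {
  if (config@shortReadDepth <= 0)
    stop("requested read depth must be > 0")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gts <- truthGenotypes(truth)
  if (is.null(accessions)) accessions <- rownames(gts)
  rl <- config@shortReadLength
  set.seed(deriveSeed(config@seed, "reads"))
  prov <- list()
  files <- list()
  for (acc in accessions) {
    gt <- gts[acc, ]
    hap_alleles <- list(ifelse(gt == "B", "B", "A"),
                        ifelse(gt == "A", "A", "B"))
    glen <- sum(nchar(as.character(genome_a)))
    n_pairs <- as.integer(round(config@shortReadDepth * glen / (2 * rl)))
    n_h1 <- rbinom(1L, n_pairs, 0.5)
    frag <- list()
    for (h in 1:2) {
      nh <- if (h == 1L) n_h1 else n_pairs - n_h1
      if (nh == 0L) next
      hap <- buildHaplotype(genome_a, truth, hap_alleles[[h]])
      fr <- .sampleFragments(hap, nh, rl, config@insertSizeMean,
                             config@insertSizeSd)
      fr$haplotype <- h
      frag[[h]] <- fr
    }
    frag <- do.call(rbind, frag)
    frag$read_id <- sprintf("%s_r%06d", acc, seq_len(nrow(frag)))
    if (config@errorRate > 0) {
      frag$r1 <- mutateBases(frag$r1, config@errorRate)
      frag$r2 <- mutateBases(frag$r2, config@errorRate)
    }
    fq1 <- file.path(out_dir, paste0(acc, "_1.fq.gz"))
    fq2 <- file.path(out_dir, paste0(acc, "_2.fq.gz"))
    qual <- BStringSet(rep(strrep("I", rl), nrow(frag)))
    s1 <- DNAStringSet(frag$r1)
    names(s1) <- paste0(frag$read_id, "/1")
    s2 <- DNAStringSet(frag$r2)
    names(s2) <- paste0(frag$read_id, "/2")
    writeXStringSet(s1, fq1, format = "fastq", compress = TRUE,
                    qualities = qual)
    writeXStringSet(s2, fq2, format = "fastq", compress = TRUE,
                    qualities = qual)
    prov[[acc]] <- data.frame(accession = acc, read_id = frag$read_id,
                              haplotype = frag$haplotype,
                              chrom = frag$chrom, start = frag$start,
                              end = frag$end, stringsAsFactors = FALSE)
    files[[acc]] <- data.frame(accession = acc, fq1 = fq1, fq2 = fq2,
                               n_pairs = nrow(frag),
                               stringsAsFactors = FALSE)
  }
  truth@provenance <- do.call(rbind, c(list(truth@provenance), prov))
  rownames(truth@provenance) <- NULL
  list(files = do.call(rbind, files), truth = truth)
}

#' Simulate single-molecule long reads from one genome
#'
#' Lengths are exponential with the configured mean (floored at 500 bp);
#' per-base substitution errors at the configured rate. A minimal stand-in
#' for long-read sequencing sufficient to exercise read-based call inputs.
#'
#' @param genome \code{DNAStringSet}.
#' @param config \linkS4class{SimulationConfig}.
#' @param path output FASTQ (gz) path.
#' @param depth fold coverage (default 5).
#' @return \code{path}, invisibly.
#' @export
generateLongReads <- function(genome, config, path, depth = 5) {
  set.seed(deriveSeed(config@seed, "reads") + 7L)
  glen <- sum(nchar(as.character(genome)))
  n <- max(1L, as.integer(round(depth * glen / config@longReadMeanLength)))
  lens <- pmax(500L, as.integer(rexp(n, 1 / config@longReadMeanLength)))
  chrom_lens <- nchar(as.character(genome))
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = chrom_lens / sum(chrom_lens))
  reads <- character(n)
  for (i in seq_len(n)) {
    L <- chrom_lens[[match(chrom[i], names(genome))]]
    len <- min(lens[i], L)
    st <- floor(runif(1, 1, L - len + 1))
    reads[i] <- substr(as.character(genome[[chrom[i]]]), st, st + len - 1L)
  }
  reads <- mutateBases(reads, config@errorRate)
  rs <- DNAStringSet(reads)
  names(rs) <- sprintf("long_%06d", seq_len(n))
  writeXStringSet(rs, path, format = "fastq", compress = TRUE,
                  qualities = BStringSet(strrep("I", nchar(reads))))
  invisible(path)
}

#' Emulate a long-read SV caller over the planted truth
#'
#' Produces the precise-breakpoint call set a read-based caller would
#' report: simple indels and substitutions pass through; repeat/tandem
#' copy-number changes are reported as their net simple indel left-aligned
#' to the repeat locus start. Optional breakpoint jitter emulates caller
#' imprecision.
#'
#' Throughout the package \code{sv_type} describes genome B relative to
#' genome A (an "insertion" is extra sequence in B) and \code{len_a},
#' \code{len_b} are the allele lengths on A and B, whichever genome the
#' record is anchored on.
#'
#' @param truth \linkS4class{TruthSet}.
#' @param anchor report coordinates on genome \code{"A"} or \code{"B"}.
#' @param jitter max absolute breakpoint offset (bp) added uniformly.
#' @param seed seed for the jitter draw.
#' @return An \code{SVSet} with \code{source = "reads"}, all precise.
#' @export
simulateReadCalls <- function(truth, anchor = "A", jitter = 0, seed = 1L) {
  svs <- truthSvs(truth)
  m <- mcols(svRanges(svs))
  if (anchor == "A") {
    chrom <- as.character(seqnames(svRanges(svs)))
    st <- start(svRanges(svs)); en <- end(svRanges(svs))
  } else {
    chrom <- m$mate_chrom
    st <- m$mate_start; en <- m$mate_end
  }
  ## mate coordinates (on the genome this set is NOT anchored on)
  o_chrom <- if (anchor == "A") m$mate_chrom else
    as.character(seqnames(svRanges(svs)))
  o_st <- if (anchor == "A") m$mate_start else start(svRanges(svs))
  o_en <- if (anchor == "A") m$mate_end else end(svRanges(svs))
  rows <- list()
  for (i in seq_along(st)) {
    ty <- m$sv_type[i]
    if (ty %in% c("insertion", "deletion", "substitution")) {
      rows[[i]] <- data.frame(chrom = chrom[i], start = st[i], end = en[i],
                              sv_type = ty, len_a = m$len_a[i],
                              len_b = m$len_b[i], mate_chrom = o_chrom[i],
                              mate_start = o_st[i], mate_end = o_en[i])
    } else {
      ## complex class: report the net simple indel, left-aligned to the
      ## repeat locus start on this anchor
      net <- m$len_b[i] - m$len_a[i]
      if (net > 0)            # extra copies in B
        rows[[i]] <- data.frame(chrom = chrom[i], start = st[i],
                                end = if (anchor == "A") st[i] else
                                  st[i] + net - 1L,
                                sv_type = "insertion",
                                len_a = 0L, len_b = net,
                                mate_chrom = o_chrom[i],
                                mate_start = o_st[i],
                                mate_end = if (anchor == "A")
                                  o_st[i] + net - 1L else o_en[i])
      else                    # copies lost in B
        rows[[i]] <- data.frame(chrom = chrom[i], start = st[i],
                                end = if (anchor == "A")
                                  st[i] - net - 1L else st[i],
                                sv_type = "deletion",
                                len_a = -net, len_b = 0L,
                                mate_chrom = o_chrom[i],
                                mate_start = o_st[i],
                                mate_end = if (anchor == "A") o_st[i] else
                                  o_st[i] - net - 1L)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), sv_type = character(),
                     len_a = integer(), len_b = integer())
  if (jitter > 0 && nrow(df)) {
    set.seed(seed)
    off <- sample(seq(-jitter, jitter), nrow(df), replace = TRUE)
    df$start <- pmax(1L, df$start + off)
    df$end <- pmax(df$start, df$end + off)
  }
  df$sv_id <- sprintf("rc_%05d", seq_len(nrow(df)))
  df$source <- rep("reads", nrow(df))
  df$precise <- rep(TRUE, nrow(df))
  svSetFromFrame(df, anchorGenome = anchor)
}
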
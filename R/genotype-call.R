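#' Decide one genotype from dual-reference breakpoint evidence
#'
#' Evidence is interpreted cross-wise: an accession carrying the genome-A
#' allele produces split reads on genome B (where its sequence differs
#' from the reference being mapped to) and clean coverage on genome A, and
#' vice versa. Allele support requires at least \code{min_split} split
#' reads at every breakpoint on the opposite genome or, failing that, the
#' read-depth rule for deleted sequence (< 50\% of the event interval
#' covered at 2x while > 50\% of a same-length flank is covered), applied
#' when the opposite genome carries at least \code{min_depth_len} bp of
#' sequence absent from this allele. Support for A only gives
#' \code{"A"}, B only \code{"B"}, both \code{"H"}, neither \code{"U"}.
#'
#' @param evidence_a,evidence_b named lists for the two genomes with
#'   elements \code{split_left}, \code{split_right},
#'   \code{depth_fraction_event}, \code{depth_fraction_flank_best},
#'   \code{depth_applicable}.
#' @param min_split minimum split reads per breakpoint (default 3).
#' @return list with \code{genotype} (\code{"A","B","H","U"}) and
#'   \code{basis} (\code{"split_read"}, \code{"depth"}, \code{"none"};
#'   split-read evidence reported when either allele used it).
#' @export
callGenotype <- function(evidence_a, evidence_b, min_split = 3L) {
  support <- function(ev) {
    split_ok <- ev$split_left >= min_split && ev$split_right >= min_split
    depth_ok <- isTRUE(ev$depth_applicable) &&
      ev$depth_fraction_event < 0.5 && ev$depth_fraction_flank_best > 0.5
    if (split_ok) list(yes = TRUE, how = "split_read")
    else if (depth_ok) list(yes = TRUE, how = "depth")
    else list(yes = FALSE, how = "none")
  }
  ## split reads on genome B evidence the A allele and vice versa
  sup_a <- support(evidence_b)
  sup_b <- support(evidence_a)
  genotype <- if (sup_a$yes && sup_b$yes) "H"
    else if (sup_a$yes) "A"
    else if (sup_b$yes) "B"
    else "U"
  basis <- if (genotype == "U") "none"
    else if ("split_read" %in% c(if (sup_a$yes) sup_a$how,
                                 if (sup_b$yes) sup_b$how)) "split_read"
    else "depth"
  list(genotype = genotype, basis = basis)
}

#' Genotype a reference SV set in one accession
#'
#' Loads the accession's alignments against both genomes (mismatch
#' fraction <= \code{max_mismatch_fraction}), indexes split-read junctions
#' and per-base coverage once, and calls every SV with
#' \code{\link{callGenotype}}.
#'
#' @param svs reference \code{SVSet} (anchored on genome A, mate
#'   coordinates on genome B required).
#' @param bam_a,bam_b indexed BAMs of this accession's reads aligned to
#'   genomes A and B.
#' @param accession_id label for the output rows.
#' @param min_split minimum split reads per breakpoint (default 3).
#' @param window breakpoint matching window in bp (default 10).
#' @param depth_threshold per-base depth defining coverage of a deleted
#'   region (default 2).
#' @param min_depth_len minimum deleted-sequence length for the depth rule
#'   (default 50 bp).
#' @param max_mismatch_fraction alignment mismatch filter (default 0.03).
#' @return data.frame: one row per SV with the genotype, basis and the
#'   split/depth evidence on both genomes.
#' @export
genotypeAccession <- function(svs, bam_a, bam_b, accession_id = "acc",
                              min_split = 3L, window = 10L,
                              depth_threshold = 2L, min_depth_len = 50L,
                              max_mismatch_fraction = 0.03) {
  df <- .svsetAsFrame(svs)
  if (anyNA(df$mate_chrom))
    stop("reference SVs must carry mate coordinates on both genomes")
  aln_a <- loadFilteredAlignments(bam_a, max_mismatch_fraction)
  aln_b <- loadFilteredAlignments(bam_b, max_mismatch_fraction)
  jx_a <- .junctionIndex(aln_a)
  jx_b <- .junctionIndex(aln_b)
  cov_a <- GenomicAlignments::coverage(aln_a)
  cov_b <- GenomicAlignments::coverage(aln_b)
  anchor <- anchorGenome(svs)
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    co_a <- .svCoordsOn(df[i, ], "A", anchor)
    co_b <- .svCoordsOn(df[i, ], "B", anchor)
    ev <- list()
    for (g in c("A", "B")) {
      co <- if (g == "A") co_a else co_b
      jx <- if (g == "A") jx_a else jx_b
      cov <- if (g == "A") cov_a else cov_b
      other_len <- if (g == "A") co_b$allele_len else co_a$allele_len
      sp <- countSplitReads(jx, co$chrom, co$lo, co$hi, co$allele_len,
                            window = window)
      ## depth rule: this genome holds >= min_depth_len bases that the
      ## other allele lacks entirely
      applicable <- co$allele_len >= min_depth_len &&
        (other_len == 0L ||
         (df$sv_type[i] == "substitution" && co$allele_len >= min_depth_len))
      dp <- c(depth_fraction_event = NA_real_,
              depth_fraction_flank_best = NA_real_)
      if (applicable)
        dp <- depthEvidenceForDeletion(cov, co$chrom, co$lo, co$hi,
                                       depth_threshold)
      ev[[g]] <- list(split_left = sp[["split_left"]],
                      split_right = sp[["split_right"]],
                      depth_fraction_event = dp[["depth_fraction_event"]],
                      depth_fraction_flank_best =
                        dp[["depth_fraction_flank_best"]],
                      depth_applicable = applicable)
    }
    call <- callGenotype(ev$A, ev$B, min_split = min_split)
    rows[[i]] <- data.frame(
      accession = accession_id, sv_id = df$sv_id[i],
      genotype = call$genotype, basis = call$basis,
      split_left_a = ev$A$split_left, split_right_a = ev$A$split_right,
      split_left_b = ev$B$split_left, split_right_b = ev$B$split_right,
      depth_event_a = ev$A$depth_fraction_event,
      depth_flank_a = ev$A$depth_fraction_flank_best,
      depth_event_b = ev$B$depth_fraction_event,
      depth_flank_b = ev$B$depth_fraction_flank_best,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build the accession x SV genotype matrix and genotyping rates
#'
#' @param calls data.frame of genotype calls (rows from
#'   \code{\link{genotypeAccession}}, possibly several accessions).
#' @return list with \code{matrix} (accessions x SVs over
#'   \code{A/B/H/U}), \code{accession_rate} (fraction of SVs determined
#'   per accession) and \code{sv_determined} (fraction of accessions
#'   determined per SV).
#' @export
genotypeMatrix <- function(calls) {
  if (anyDuplicated(calls[, c("accession", "sv_id")]))
    stop("duplicate (accession, SV) genotype call")
  accs <- unique(calls$accession)
  svs <- unique(calls$sv_id)
  m <- matrix("U", nrow = length(accs), ncol = length(svs),
              dimnames = list(accs, svs))
  m[cbind(match(calls$accession, accs), match(calls$sv_id, svs))] <-
    calls$genotype
  list(matrix = m,
       accession_rate = rowMeans(m != "U"),
       sv_determined = colMeans(m != "U"))
}

#' Write a genotype matrix as TSV (accession rows, SV columns, A/B/H/U)
#'
#' @param m genotype matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeMatrix <- function(m, path) {
  df <- data.frame(accession = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$accession
  storage.mode(m) <- "character"
  m
}
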
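#' Alignment backend for flank validation
#'
#' \code{blastnBackend} returns a function mapping a named
#' \code{DNAStringSet} of queries to a hit table with columns
#' \code{qseqid,sseqid,pident,length,qstart,qend,sstart,send,evalue},
#' by running \code{blastn} against the given subject genome. Any function
#' with this contract can stand in (tests use synthetic backends).
#'
#' @param genome subject genome: \code{DNAStringSet} or FASTA path.
#' @return A function of one argument (the query \code{DNAStringSet}).
#' @export
blastnBackend <- function(genome) {
  fa <- if (is.character(genome)) genome else
    writeFastaTo(genome, tempfile("subject_", fileext = ".fa"))
  function(queries) {
    qfa <- writeFastaTo(queries, tempfile("query_", fileext = ".fa"))
    out <- tempfile("blast_", fileext = ".tsv")
    runTool("blastn",
            c("-query", shQuote(qfa), "-subject", shQuote(fa),
              "-outfmt",
              shQuote("6 qseqid sseqid pident length qstart qend sstart send evalue"),
              "-max_target_seqs", "20"),
            stdout = out)
    if (!file.size(out))
      return(data.frame(qseqid = character(), sseqid = character(),
                        pident = numeric(), length = integer(),
                        qstart = integer(), qend = integer(),
                        sstart = integer(), send = integer(),
                        evalue = numeric()))
    read.delim(out, header = FALSE,
               col.names = c("qseqid", "sseqid", "pident", "length",
                             "qstart", "qend", "sstart", "send", "evalue"),
               stringsAsFactors = FALSE)
  }
}

## Reliable-hit rule: alignment length > 50 bp, identity > 90%, and
## e-value < 1e-10 when the backend reports one (backends without e-values
## satisfy the clause via the length/identity requirement on 5-kb flanks).
.reliableHits <- function(hits) {
  ok <- hits$length > 50 & hits$pident > 90
  if ("evalue" %in% names(hits) && !all(is.na(hits$evalue)))
    ok <- ok & hits$evalue < 1e-10
  hits[ok, , drop = FALSE]
}

#' Validate SVs by re-aligning their flanking sequences to the other genome
#'
#' For each SV the two \code{flank}-bp sequences flanking the event on the
#' anchor genome are aligned to the other genome. The SV passes when both
#' flanks have reliable hits (length > 50 bp, identity > 90\%, e-value
#' < 1e-10) in the expected region — same chromosome and strand, inner ends
#' facing, within 10x SV length + 20 kb of each other — and the observed
#' inter-hit gap matches the expected allele length: deviation < 20\% for
#' insertions (and other events with sequence on the other genome), gap or
#' overlap < 3 bp for deletions.
#'
#' @param svs an \code{SVSet} (anchored on genome A).
#' @param genome_a,genome_b the assemblies (\code{DNAStringSet}).
#' @param flank flank length in bp (default 5000; truncated at chromosome
#'   ends).
#' @param backend hit-table function as returned by
#'   \code{\link{blastnBackend}}; defaults to blastn against the other
#'   genome.
#' @param max_deviation insertion-size deviation threshold (default 0.20).
#' @param max_del_gap deletion gap/overlap tolerance in bp (default 3).
#' @return A data.frame (one row per SV): \code{sv_id}, \code{verdict}
#'   (\code{pass}, \code{fail_no_hit}, \code{fail_wrong_region},
#'   \code{fail_size}), \code{observed_gap}, \code{expected_gap},
#'   \code{deviation}, and the selected left/right hit coordinates with
#'   identity, aligned length and e-value.
#' @export
validateFlanks <- function(svs, genome_a, genome_b, flank = 5000L,
                           backend = NULL, max_deviation = 0.20,
                           max_del_gap = 3L) {
  empty <- data.frame(sv_id = character(), verdict = character(),
                      observed_gap = numeric(), expected_gap = numeric(),
                      deviation = numeric())
  if (!length(svs)) return(empty)
  anchor <- if (anchorGenome(svs) == "A") genome_a else genome_b
  if (is.null(backend))
    backend <- blastnBackend(if (anchorGenome(svs) == "A") genome_b else
      genome_a)
  gr <- svRanges(svs)
  m <- mcols(gr)
  chrom <- as.character(seqnames(gr))
  chrlen <- setNames(nchar(as.character(anchor)), names(anchor))
  qs <- list(); qlen <- list()
  for (i in seq_along(gr)) {
    s <- start(gr)[i]; e <- end(gr)[i]
    point <- m$sv_type[i] == "insertion" & m$len_a[i] == 0L
    l_hi <- if (point) s else s - 1L
    l_lo <- max(1L, l_hi - flank + 1L)
    r_lo <- e + 1L
    r_hi <- min(chrlen[[chrom[i]]], r_lo + flank - 1L)
    cs <- as.character(anchor[[chrom[i]]])
    qs[[paste0(m$sv_id[i], "|L")]] <- substr(cs, l_lo, l_hi)
    qs[[paste0(m$sv_id[i], "|R")]] <- substr(cs, r_lo, r_hi)
  }
  queries <- DNAStringSet(unlist(qs))
  qlen <- setNames(nchar(unlist(qs)), names(qs))
  hits <- backend(queries)
  hits <- .reliableHits(hits)
  if (nrow(hits)) {
    hits$strand <- ifelse(hits$send >= hits$sstart, "+", "-")
    hits$smin <- pmin(hits$sstart, hits$send)
    hits$smax <- pmax(hits$sstart, hits$send)
  }
  res <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    id <- m$sv_id[i]
    exp_gap <- m$len_b[i]
    lh <- hits[hits$qseqid == paste0(id, "|L"), , drop = FALSE]
    rh <- hits[hits$qseqid == paste0(id, "|R"), , drop = FALSE]
    row <- data.frame(sv_id = id, verdict = "fail_no_hit",
                      observed_gap = NA_real_, expected_gap = exp_gap,
                      deviation = NA_real_,
                      left_chrom = NA_character_, left_start = NA_integer_,
                      left_end = NA_integer_, left_identity = NA_real_,
                      left_length = NA_integer_, left_evalue = NA_real_,
                      right_chrom = NA_character_,
                      right_start = NA_integer_, right_end = NA_integer_,
                      right_identity = NA_real_,
                      right_length = NA_integer_,
                      right_evalue = NA_real_, stringsAsFactors = FALSE)
    if (nrow(lh) && nrow(rh)) {
      span_lim <- 10 * max(m$len_a[i], m$len_b[i], 1) + 20000
      best <- NULL
      for (a in seq_len(nrow(lh))) for (b in seq_len(nrow(rh))) {
        L <- lh[a, ]; R <- rh[b, ]
        if (L$sseqid != R$sseqid || L$strand != R$strand) next
        lq <- qlen[[paste0(id, "|L")]]
        rq <- qlen[[paste0(id, "|R")]]
        if (L$strand == "+") {
          inner_l <- L$smax + (lq - L$qend)       # extrapolate truncation
          inner_r <- R$smin - (R$qstart - 1L)
          obs <- inner_r - inner_l - 1L
        } else {
          inner_l <- L$smin - (lq - L$qend)
          inner_r <- R$smax + (R$qstart - 1L)
          obs <- inner_l - inner_r - 1L
        }
        if (abs(obs) > span_lim) next
        if (is.null(best) || abs(obs - exp_gap) < abs(best$obs - exp_gap))
          best <- list(L = L, R = R, obs = obs)
      }
      if (is.null(best)) {
        row$verdict <- "fail_wrong_region"
      } else {
        obs <- best$obs
        dev <- abs(obs - exp_gap) / max(exp_gap, 1)
        is_del <- m$sv_type[i] == "deletion" | exp_gap == 0
        pass <- if (is_del) abs(obs) < max_del_gap else dev < max_deviation
        row$verdict <- if (pass) "pass" else "fail_size"
        row$observed_gap <- obs
        row$deviation <- dev
        row[c("left_chrom", "left_start", "left_end", "left_identity",
              "left_length", "left_evalue")] <-
          list(best$L$sseqid, best$L$smin, best$L$smax, best$L$pident,
               best$L$length,
               if ("evalue" %in% names(best$L)) best$L$evalue else NA_real_)
        row[c("right_chrom", "right_start", "right_end", "right_identity",
              "right_length", "right_evalue")] <-
          list(best$R$sseqid, best$R$smin, best$R$smax, best$R$pident,
               best$R$length,
               if ("evalue" %in% names(best$R)) best$R$evalue else NA_real_)
      }
    }
    res[[i]] <- row
  }
  do.call(rbind, res)
}

#' @describeIn validateFlanks validate a single SV (first row of the batch
#'   result).
#' @param sv a single-variant \code{SVSet}.
#' @export
validateByFlanks <- function(sv, genome_a, genome_b, flank = 5000L,
                             backend = NULL, max_deviation = 0.20,
                             max_del_gap = 3L) {
  stopifnot(length(sv) == 1L)
  validateFlanks(sv, genome_a, genome_b, flank = flank, backend = backend,
                 max_deviation = max_deviation, max_del_gap = max_del_gap)
}
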
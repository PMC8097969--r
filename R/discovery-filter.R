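## Minimum distance (bp) from each range to any gap range on the same
## chromosome; Inf when none. Overlapping/spanning a gap gives 0.
.minDistToGaps <- function(chrom, lo, hi, gaps) {
  if (!length(gaps)) return(rep(Inf, length(chrom)))
  g_chr <- as.character(seqnames(gaps))
  g_lo <- start(gaps); g_hi <- end(gaps)
  vapply(seq_along(chrom), function(i) {
    j <- which(g_chr == chrom[i])
    if (!length(j)) return(Inf)
    d <- pmax(0L, pmax(g_lo[j] - hi[i], lo[i] - g_hi[j]) - 1L)
    min(d)
  }, numeric(1))
}

#' Remove SVs spanning or close to assembly gap regions
#'
#' Gap regions are runs of at least \code{min_n_run} consecutive N bases in
#' either genome. An SV is removed when its anchor interval, or its mate
#' interval on the other genome, spans a gap or lies closer than
#' \code{max_distance} bp to one.
#'
#' @param svs an \code{SVSet}.
#' @param genome_a,genome_b the two assemblies (\code{DNAStringSet}).
#' @param max_distance minimum allowed distance to a gap (bp, default 50:
#'   SVs at distance < 50 bp are dropped).
#' @param min_n_run minimum N-run length defining a gap (default 10).
#' @return The filtered \code{SVSet} (a subset of the input).
#' @export
filterNearGaps <- function(svs, genome_a, genome_b, max_distance = 50L,
                           min_n_run = 10L) {
  if (!length(svs)) return(svs)
  gaps_anchor <- nRunRanges(if (anchorGenome(svs) == "A") genome_a else
    genome_b, min_n_run)
  gaps_other <- nRunRanges(if (anchorGenome(svs) == "A") genome_b else
    genome_a, min_n_run)
  gr <- svRanges(svs)
  d_anchor <- .minDistToGaps(as.character(seqnames(gr)), start(gr),
                             end(gr), gaps_anchor)
  m <- mcols(gr)
  have_mate <- !is.na(m$mate_chrom)
  d_mate <- rep(Inf, length(svs))
  if (any(have_mate))
    d_mate[have_mate] <- .minDistToGaps(m$mate_chrom[have_mate],
                                        m$mate_start[have_mate],
                                        m$mate_end[have_mate], gaps_other)
  keep <- d_anchor >= max_distance & d_mate >= max_distance
  svs[which(keep)]
}
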
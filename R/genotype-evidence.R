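## Per-genome coordinates of one SV. On the genome whose allele has
## length <= 1 the event is a point junction (single breakpoint);
## otherwise the interval contributes two breakpoints (its two edges).
.svCoordsOn <- function(sv_row, genome_label, anchor_label) {
  if (genome_label == anchor_label)
    list(chrom = sv_row$chrom, lo = sv_row$start, hi = sv_row$end,
         allele_len = if (anchor_label == "A") sv_row$len_a else
           sv_row$len_b)
  else
    list(chrom = sv_row$mate_chrom, lo = sv_row$mate_start,
         hi = sv_row$mate_end,
         allele_len = if (anchor_label == "A") sv_row$len_b else
           sv_row$len_a)
}

## Extract clip-junction and indel-op reference coordinates from a set of
## alignments once; reused across all SVs of an accession.
## min_clip is deliberately permissive (the +-window match against an
## expected breakpoint supplies the specificity; aligner score extension
## can shave several bases off a junction clip).
.junctionIndex <- function(galn, min_clip = 5L, min_indel = 10L) {
  cig <- cigar(galn)
  chrom <- as.character(GenomicAlignments::seqnames(galn))
  st <- GenomicAlignments::start(galn)
  en <- GenomicAlignments::end(galn)
  ## clips may be soft (S, primary) or hard (H, the supplementary record
  ## of a split read) — both mark a junction
  lead <- suppressWarnings(as.integer(sub("^([0-9]+)[SH].*", "\\1", cig)))
  lead[!grepl("^[0-9]+[SH]", cig)] <- 0L
  trail <- suppressWarnings(as.integer(sub(".*[A-Z=]([0-9]+)[SH]$", "\\1",
                                           cig)))
  trail[!grepl("[SH]$", cig)] <- 0L
  jx <- list()
  sel <- which(lead >= min_clip)
  if (length(sel))
    jx[[length(jx) + 1L]] <- data.frame(chrom = chrom[sel], pos = st[sel])
  sel <- which(trail >= min_clip)
  if (length(sel))
    jx[[length(jx) + 1L]] <- data.frame(chrom = chrom[sel], pos = en[sel])
  ## reference-space locations of I/D ops of at least min_indel bases;
  ## both edges of a D run are junction evidence, an I op is a point
  has_indel <- grepl("[0-9]+[ID]", cig)
  if (any(has_indel)) {
    idx <- which(has_indel)
    rl_d <- cigarRangesAlongReferenceSpace(cig[idx], pos = st[idx],
                                           ops = "D")
    nd <- S4Vectors::elementNROWS(rl_d)
    if (sum(nd)) {
      dch <- rep(chrom[idx], nd)
      dr <- unlist(rl_d)
      keep <- IRanges::width(dr) >= min_indel
      if (any(keep))
        jx[[length(jx) + 1L]] <-
          data.frame(chrom = rep(dch[keep], 2L),
                     pos = c(IRanges::start(dr)[keep],
                             IRanges::end(dr)[keep]))
    }
    rl_i <- cigarRangesAlongReferenceSpace(cig[idx], pos = st[idx],
                                           ops = "I")
    ni <- S4Vectors::elementNROWS(rl_i)
    if (sum(ni)) {
      ## insertion op lengths live in query space; pull them from the
      ## cigar strings in op order
      lens <- as.integer(sub("I", "",
                             unlist(regmatches(cig[idx],
                                               gregexpr("[0-9]+I",
                                                        cig[idx])))))
      ich <- rep(chrom[idx], ni)
      ir <- unlist(rl_i)
      keep <- lens >= min_indel
      if (any(keep))
        jx[[length(jx) + 1L]] <-
          data.frame(chrom = ich[keep], pos = IRanges::start(ir)[keep])
    }
  }
  if (!length(jx))
    return(data.frame(chrom = character(), pos = integer()))
  do.call(rbind, jx)
}

#' Count split reads at the breakpoints of an SV
#'
#' A split read is one whose alignment breaks at the breakpoint: a
#' soft-clip junction, or an indel operation of at least 10 bp, within
#' \code{window} bp of the breakpoint. For point junctions (allele length
#' <= 1 on this genome) the single junction count is reported on both
#' sides.
#'
#' @param junctions junction index built internally from the accession's
#'   alignments (data.frame \code{chrom,pos}).
#' @param chrom,lo,hi SV coordinates on this genome (1-based closed).
#' @param allele_len allele length on this genome.
#' @param window matching window in bp (default 10).
#' @return integer vector \code{c(split_left, split_right)}.
#' @export
countSplitReads <- function(junctions, chrom, lo, hi, allele_len,
                            window = 10L) {
  j <- junctions[junctions$chrom == chrom, , drop = FALSE]
  if (!nrow(j)) return(c(split_left = 0L, split_right = 0L))
  if (allele_len <= 1L) {
    n <- sum(abs(j$pos - lo) <= window | abs(j$pos - (lo + 1L)) <= window)
    return(c(split_left = n, split_right = n))
  }
  left <- sum(abs(j$pos - lo) <= window | abs(j$pos - (lo - 1L)) <= window)
  right <- sum(abs(j$pos - hi) <= window |
               abs(j$pos - (hi + 1L)) <= window)
  c(split_left = left, split_right = right)
}

#' Read-depth evidence for a deleted region
#'
#' Computes the fraction of the event interval covered at or above
#' \code{depth_threshold} and, over the two adjacent flanks of the same
#' length (truncated at chromosome ends), the best covered fraction (at
#' >= 1x). Low event coverage with well-covered flanks supports the allele
#' lacking this sequence.
#'
#' @param cov coverage \code{RleList} of the accession's filtered
#'   alignments on this genome.
#' @param chrom,lo,hi deleted interval on this genome.
#' @param depth_threshold per-base depth defining "covered" in the event
#'   (default 2).
#' @return numeric vector
#'   \code{c(depth_fraction_event, depth_fraction_flank_best)}.
#' @export
depthEvidenceForDeletion <- function(cov, chrom, lo, hi,
                                     depth_threshold = 2L) {
  if (!chrom %in% names(cov))
    return(c(depth_fraction_event = 0, depth_fraction_flank_best = 0))
  v <- cov[[chrom]]
  L <- hi - lo + 1L
  clen <- length(v)
  sub <- function(a, b) {
    a <- max(1L, a); b <- min(clen, b)
    if (b < a) return(numeric())
    as.numeric(S4Vectors::window(v, a, b))
  }
  ev <- sub(lo, hi)
  event_frac <- if (length(ev)) mean(ev >= depth_threshold) else 0
  fl <- sub(lo - L, lo - 1L)
  fr <- sub(hi + 1L, hi + L)
  flank_frac <- max(if (length(fl)) mean(fl >= 1) else 0,
                    if (length(fr)) mean(fr >= 1) else 0)
  c(depth_fraction_event = event_frac,
    depth_fraction_flank_best = flank_frac)
}
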
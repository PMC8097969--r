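#' Refine complex SVs using precise read-based calls
#'
#' The four repeat/tandem copy-number classes come out of assembly
#' comparison without defined breakpoints. Where one or more read-based
#' calls (precise breakpoints, \code{source = "reads"}) fall within a
#' complex call's interval (padded by \code{pad} bp), the complex call is
#' replaced by those simple indels (\code{source = "merged"},
#' \code{precise = TRUE}); complex calls without read support pass through
#' unchanged.
#'
#' @param assembly_svs \code{SVSet} from
#'   \code{\link{callSvsFromAlignment}}.
#' @param read_svs \code{SVSet} of read-based calls on the same anchor
#'   genome.
#' @param pad interval padding in bp when testing containment (default 50).
#' @return An \code{SVSet}.
#' @export
refineComplexSvs <- function(assembly_svs, read_svs, pad = 50L) {
  stopifnot(anchorGenome(assembly_svs) == anchorGenome(read_svs))
  if (!length(assembly_svs) || !length(read_svs)) return(assembly_svs)
  is_complex <- svType(assembly_svs) %in% SV_COMPLEX_TYPES
  if (!any(is_complex)) return(assembly_svs)
  cx <- svRanges(assembly_svs)[is_complex]
  padded <- GRanges(seqnames(cx),
                    IRanges(pmax(1L, start(cx) - pad), end(cx) + pad))
  ov <- GenomicRanges::findOverlaps(padded, svRanges(read_svs))
  hit_cx <- unique(S4Vectors::queryHits(ov))
  used_reads <- unique(S4Vectors::subjectHits(ov))
  keep_idx <- which(!is_complex)
  unref_idx <- which(is_complex)[setdiff(seq_len(sum(is_complex)), hit_cx)]
  out <- list()
  simple <- assembly_svs[sort(c(keep_idx, unref_idx))]
  repl <- read_svs[used_reads]
  if (length(repl)) {
    mcols(repl@ranges)$source <- "merged"
    mcols(repl@ranges)$precise <- TRUE
  }
  combined <- rbind(.svsetAsFrame(simple), .svsetAsFrame(repl))
  combined <- combined[order(combined$chrom, combined$start), , drop = FALSE]
  svSetFromFrame(combined, anchorGenome = anchorGenome(assembly_svs))
}

## data.frame round-trip helper shared by refine/merge/IO
.svsetAsFrame <- function(svs) {
  gr <- svRanges(svs)
  m <- mcols(gr)
  data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
             end = end(gr), sv_id = m$sv_id, sv_type = m$sv_type,
             len_a = m$len_a, len_b = m$len_b, source = m$source,
             precise = m$precise, mate_chrom = m$mate_chrom,
             mate_start = m$mate_start, mate_end = m$mate_end,
             seq = m$seq, stringsAsFactors = FALSE)
}

## Interval used for reciprocal-overlap comparison: point insertions are
## padded on the anchor genome by their inserted-allele length so that two
## insertion calls at nearby points with similar alleles can be compared.
.overlapIntervals <- function(df) {
  point <- df$sv_type == "insertion" & df$len_a <= 1L
  lo <- df$start
  hi <- ifelse(point, df$start + pmax(df$len_b, 1L) - 1L, df$end)
  list(lo = lo, hi = hi)
}

#' Merge two SV call sets by reciprocal overlap
#'
#' Same-type calls whose intervals overlap by at least \code{min_reciprocal}
#' of both lengths collapse to one record. Overlap clusters are connected
#' components of the pairwise criterion; the representative is chosen by
#' source priority (assembly-derived breakpoints preferred over read-based)
#' then by coordinate, making the result invariant to input order. A
#' representative drawn from a genuine cross-set merge is reported with
#' \code{source = "merged"}.
#'
#' Point insertions are compared on their insertion-point interval padded by
#' the inserted-allele length on the anchor genome.
#'
#' @param set1,set2 \code{SVSet}s on the same anchor genome.
#' @param min_reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return The merged \code{SVSet}.
#' @export
mergeCallsets <- function(set1, set2, min_reciprocal = 0.5) {
  stopifnot(anchorGenome(set1) == anchorGenome(set2))
  df1 <- .svsetAsFrame(set1); df2 <- .svsetAsFrame(set2)
  df1$.origin <- 1L; df2$.origin <- 2L
  df <- rbind(df1, df2)
  if (!nrow(df)) return(set1)
  iv <- .overlapIntervals(df)
  df$.lo <- iv$lo; df$.hi <- iv$hi
  ## union-find over pairs meeting the reciprocal-overlap criterion
  parent <- seq_len(nrow(df))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (ty in unique(df$sv_type)) {
    idx <- which(df$sv_type == ty)
    if (length(idx) < 2L) next
    gr <- GRanges(df$chrom[idx], IRanges(df$.lo[idx], df$.hi[idx]))
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
    for (k in seq_along(ov)) {
      a <- idx[S4Vectors::queryHits(ov)[k]]
      b <- idx[S4Vectors::subjectHits(ov)[k]]
      w <- min(df$.hi[a], df$.hi[b]) - max(df$.lo[a], df$.lo[b]) + 1L
      wa <- df$.hi[a] - df$.lo[a] + 1L
      wb <- df$.hi[b] - df$.lo[b] + 1L
      if (w / wa >= min_reciprocal && w / wb >= min_reciprocal) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_len(nrow(df)), find, integer(1))
  prio <- match(df$source, c("assembly", "merged", "truth", "reads"))
  keep <- integer(0)
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    o <- members[order(prio[members], df$chrom[members],
                       df$start[members], df$sv_id[members])]
    rep_i <- o[1]
    ## cross-set merge (distinct records from both inputs) -> "merged"
    distinct <- unique(df$sv_id[members])
    if (length(members) > 1L &&
        length(unique(df$.origin[members])) == 2L &&
        length(distinct) > 1L)
      df$source[rep_i] <- "merged"
    keep <- c(keep, rep_i)
  }
  out <- df[sort(keep), setdiff(names(df), c(".origin", ".lo", ".hi")),
            drop = FALSE]
  out <- out[order(out$chrom, out$start, out$sv_id), , drop = FALSE]
  out <- out[!duplicated(out$sv_id), , drop = FALSE]
  svSetFromFrame(out, anchorGenome = anchorGenome(set1))
}
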
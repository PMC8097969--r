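## Reduce an SVSet to comparable events: breakpoint position, net length
## change (len_b - len_a) and a coarse class. Complex copy-number calls are
## classed by the sign of their net change so that a refined or unrefined
## call can be compared with a planted repeat/tandem event.
.reduceEvents <- function(svs) {
  df <- .svsetAsFrame(svs)
  net <- df$len_b - df$len_a
  cls <- ifelse(df$sv_type == "substitution", "sub",
                ifelse(net > 0, "ins", "del"))
  ## comparable size: substitutions by replaced length, everything else by
  ## net length change (a planted repeat expansion and its refined simple
  ## indel share the net, not the array length)
  size <- ifelse(cls == "sub", pmax(df$len_a, df$len_b), abs(net))
  data.frame(sv_id = df$sv_id, chrom = df$chrom, pos = df$start,
             net = net, size = size, class = cls,
             stringsAsFactors = FALSE)
}

#' Evaluate a call set against the planted truth
#'
#' Greedy one-to-one matching of calls to planted SVs: a call matches a
#' truth event when it lies on the same chromosome, belongs to the same
#' coarse class (net gain / net loss / substitution), its breakpoint is
#' within \code{tol} bp, and its size agrees within 20\% (or \code{tol} bp
#' for small events). Reports recall, precision and the mean absolute
#' breakpoint error over matched pairs.
#'
#' @param calls \code{SVSet} of calls anchored on genome A.
#' @param truth \linkS4class{TruthSet}.
#' @param tol breakpoint tolerance in bp (default 10).
#' @return list with \code{recall}, \code{precision},
#'   \code{mean_bp_error}, \code{n_truth}, \code{n_calls} and the
#'   \code{matches} data.frame (\code{truth_id,call_id,bp_error}).
#' @export
evaluateCalls <- function(calls, truth, tol = 10L) {
  tr <- .reduceEvents(truthSvs(truth))
  ca <- .reduceEvents(calls)
  used <- logical(nrow(ca))
  matches <- list()
  for (i in seq_len(nrow(tr))) {
    cand <- which(!used & ca$chrom == tr$chrom[i] &
                  ca$class == tr$class[i] &
                  abs(ca$pos - tr$pos[i]) <= tol &
                  abs(ca$size - tr$size[i]) <=
                    pmax(tol, 0.2 * tr$size[i]))
    if (!length(cand)) next
    j <- cand[which.min(abs(ca$pos[cand] - tr$pos[i]))]
    used[j] <- TRUE
    matches[[length(matches) + 1L]] <-
      data.frame(truth_id = tr$sv_id[i], call_id = ca$sv_id[j],
                 bp_error = abs(ca$pos[j] - tr$pos[i]),
                 stringsAsFactors = FALSE)
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(truth_id = character(), call_id = character(),
               bp_error = numeric())
  list(recall = if (nrow(tr)) nrow(matches) / nrow(tr) else NA_real_,
       precision = if (nrow(ca)) nrow(matches) / nrow(ca) else NA_real_,
       mean_bp_error = if (nrow(matches)) mean(matches$bp_error) else
         NA_real_,
       n_truth = nrow(tr), n_calls = nrow(ca), matches = matches)
}

#' Run the full assembly-comparison discovery chain
#'
#' Convenience wrapper: align the genomes, call SVs from the alignment,
#' drop calls near assembly gaps, validate by flank re-alignment, refine
#' complex calls with read-based calls and merge the two call sets by
#' reciprocal overlap.
#'
#' @param genome_a,genome_b \code{DNAStringSet} assemblies.
#' @param read_calls optional \code{SVSet} of read-based calls anchored on
#'   genome A (refinement/merging is skipped when \code{NULL}).
#' @param min_size,max_size SV size bounds in bp.
#' @param gap_distance minimum distance to an assembly gap (bp).
#' @param flank flank length for validation (bp).
#' @param min_reciprocal reciprocal-overlap fraction for merging.
#' @param validate run the flank-validation stage (default TRUE).
#' @return list with the final \code{svs} (\code{SVSet}) and the
#'   intermediate stage outputs (\code{raw}, \code{gap_filtered},
#'   \code{flank_report}, \code{validated}, \code{refined}).
#' @export
discoverSvs <- function(genome_a, genome_b, read_calls = NULL,
                        min_size = 10L, max_size = 7e5,
                        gap_distance = 50L, flank = 5000L,
                        min_reciprocal = 0.5, validate = TRUE) {
  blocks <- alignGenomes(genome_a, genome_b)
  raw <- callSvsFromAlignment(blocks, genome_a, genome_b,
                              min_size = min_size, max_size = max_size)
  gap_filtered <- filterNearGaps(raw, genome_a, genome_b,
                                 max_distance = gap_distance)
  flank_report <- NULL
  validated <- gap_filtered
  if (validate && length(gap_filtered)) {
    ## the inter-hit size check presumes defined breakpoints: imprecise
    ## complex calls skip validation and face refinement instead
    precise_idx <- which(isPrecise(gap_filtered))
    if (length(precise_idx)) {
      flank_report <- validateFlanks(gap_filtered[precise_idx],
                                     genome_a, genome_b, flank = flank)
      drop <- precise_idx[flank_report$verdict != "pass"]
      if (length(drop))
        validated <- gap_filtered[setdiff(seq_len(length(gap_filtered)),
                                          drop)]
    }
  }
  refined <- validated
  final <- validated
  if (!is.null(read_calls)) {
    refined <- refineComplexSvs(validated, read_calls)
    final <- mergeCallsets(refined, read_calls,
                           min_reciprocal = min_reciprocal)
  }
  list(svs = final, raw = raw, gap_filtered = gap_filtered,
       flank_report = flank_report, validated = validated,
       refined = refined)
}
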
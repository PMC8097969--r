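#' @include AllClasses.R
NULL

#' Accessors for SVSet and TruthSet
#'
#' \code{svId}, \code{svType}, \code{lenA}, \code{lenB}, \code{svSource},
#' \code{isPrecise}, \code{anchorGenome} extract the per-variant metadata of
#' an \code{SVSet}; \code{svRanges} returns the underlying \code{GRanges};
#' \code{mateRanges} the corresponding intervals on the other genome.
#' \code{truthSvs}, \code{truthGenotypes}, \code{readProvenance} access the
#' slots of a \code{TruthSet}.
#'
#' @param x an \code{SVSet} (or \code{TruthSet} for the truth accessors).
#' @return Vectors (one element per variant), a \code{GRanges}, or the
#'   corresponding \code{TruthSet} slot.
#' @name sv-accessors
NULL

#' @rdname sv-accessors
#' @export
setGeneric("svId", function(x) standardGeneric("svId"))
#' @rdname sv-accessors
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))
#' @rdname sv-accessors
#' @export
setGeneric("lenA", function(x) standardGeneric("lenA"))
#' @rdname sv-accessors
#' @export
setGeneric("lenB", function(x) standardGeneric("lenB"))
#' @rdname sv-accessors
#' @export
setGeneric("svSource", function(x) standardGeneric("svSource"))
#' @rdname sv-accessors
#' @export
setGeneric("isPrecise", function(x) standardGeneric("isPrecise"))
#' @rdname sv-accessors
#' @export
setGeneric("anchorGenome", function(x) standardGeneric("anchorGenome"))
#' @rdname sv-accessors
#' @export
setGeneric("svRanges", function(x) standardGeneric("svRanges"))
#' @rdname sv-accessors
#' @export
setGeneric("mateRanges", function(x) standardGeneric("mateRanges"))
#' @rdname sv-accessors
#' @export
setGeneric("truthSvs", function(x) standardGeneric("truthSvs"))
#' @rdname sv-accessors
#' @export
setGeneric("truthGenotypes", function(x) standardGeneric("truthGenotypes"))
#' @rdname sv-accessors
#' @export
setGeneric("readProvenance", function(x) standardGeneric("readProvenance"))

#' @rdname sv-accessors
setMethod("svId", "SVSet", function(x) mcols(x@ranges)$sv_id)
#' @rdname sv-accessors
setMethod("svType", "SVSet", function(x) mcols(x@ranges)$sv_type)
#' @rdname sv-accessors
setMethod("lenA", "SVSet", function(x) mcols(x@ranges)$len_a)
#' @rdname sv-accessors
setMethod("lenB", "SVSet", function(x) mcols(x@ranges)$len_b)
#' @rdname sv-accessors
setMethod("svSource", "SVSet", function(x) mcols(x@ranges)$source)
#' @rdname sv-accessors
setMethod("isPrecise", "SVSet", function(x) mcols(x@ranges)$precise)
#' @rdname sv-accessors
setMethod("anchorGenome", "SVSet", function(x) x@anchorGenome)
#' @rdname sv-accessors
setMethod("svRanges", "SVSet", function(x) x@ranges)
#' @rdname sv-accessors
setMethod("mateRanges", "SVSet", function(x) {
  m <- mcols(x@ranges)
  keep <- !is.na(m$mate_chrom)
  gr <- GRanges(m$mate_chrom[keep],
                IRanges(m$mate_start[keep], m$mate_end[keep]))
  names(gr) <- m$sv_id[keep]
  gr
})

#' @rdname sv-accessors
setMethod("truthSvs", "TruthSet", function(x) x@svs)
#' @rdname sv-accessors
setMethod("truthGenotypes", "TruthSet", function(x) x@genotypes)
#' @rdname sv-accessors
setMethod("readProvenance", "TruthSet", function(x) x@provenance)

#' @describeIn sv-accessors number of variants in the set.
#' @export
setMethod("length", "SVSet", function(x) length(x@ranges))

#' Subset an SVSet
#'
#' @param x an \code{SVSet}.
#' @param i index vector (positions, logicals, or sv_id names).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SVSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, svId(x))
  initialize(x, ranges = x@ranges[i])
})

setMethod("show", "SVSet", function(object) {
  cat(sprintf("SVSet with %d variant(s) anchored on genome %s\n",
              length(object), object@anchorGenome))
  if (length(object)) {
    tab <- table(svType(object))
    cat("  types:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
    sz <- pmax(lenA(object), lenB(object))
    cat(sprintf("  sizes: %d-%d bp; precise: %d/%d\n",
                min(sz), max(sz), sum(isPrecise(object)), length(object)))
  }
  invisible(object)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed %d; %d chromosome(s) totalling %.0f bp (GC %.2f)\n",
              object@seed, object@nChromosomes, object@genomeLength,
              object@gcContent))
  cat(sprintf("  planted SVs: %s\n",
              paste(sprintf("%s=%d", names(object@svCounts),
                            object@svCounts), collapse = ", ")))
  cat(sprintf("  divergence %.4f; %d accession(s), het fraction %.2f\n",
              object@backgroundDivergence, object@nAccessions,
              object@hetFraction))
  cat(sprintf("  reads: 2 x %d bp at %.0fx, error %.4f\n",
              object@shortReadLength, object@shortReadDepth,
              object@errorRate))
  invisible(object)
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %d planted SV(s), %d accession(s), %d read(s) tracked\n",
              length(object@svs), nrow(object@genotypes),
              nrow(object@provenance)))
  invisible(object)
})
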
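#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

## The seven unbalanced SV classes handled throughout the package.  The last
## four ("complex" classes) come out of assembly comparison without defined
## breakpoints and carry precise = FALSE until refined by read-based calls.
SV_TYPES <- c("insertion", "deletion", "substitution",
              "repeat_expansion", "repeat_contraction",
              "tandem_expansion", "tandem_contraction")
SV_COMPLEX_TYPES <- c("repeat_expansion", "repeat_contraction",
                      "tandem_expansion", "tandem_contraction")

## Genotype symbols: homozygous genome-A allele, homozygous genome-B allele,
## heterozygous, undetermined.
GT_LEVELS <- c("A", "B", "H", "U")

#' SVSet: a set of unbalanced structural variants anchored on one genome
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose metadata columns carry, for
#' every variant: a stable identifier, the SV class, allele lengths on both
#' genomes, the evidence source, a breakpoint-precision flag, coordinates of
#' the corresponding interval on the other genome ("mate" coordinates) and,
#' when available, the allele sequence.
#'
#' Conventions: ranges are 1-based closed intervals on the anchor genome.
#' Deletions and substitutions span the affected anchor bases
#' (\code{width == len} on the anchor genome); insertions are anchored at the
#' single base immediately left of the insertion point (\code{width == 1}).
#'
#' @slot ranges \code{GRanges} with metadata columns \code{sv_id},
#'   \code{sv_type}, \code{len_a}, \code{len_b}, \code{source},
#'   \code{precise}, \code{mate_chrom}, \code{mate_start}, \code{mate_end},
#'   \code{seq}.
#' @slot anchorGenome \code{"A"} or \code{"B"}: which genome the ranges are
#'   anchored on.
#'
#' @aliases SVSet-class
#' @export
setClass("SVSet",
         slots = c(ranges = "GRanges", anchorGenome = "character"))

.svset_mcols <- c("sv_id", "sv_type", "len_a", "len_b", "source",
                  "precise", "mate_chrom", "mate_start", "mate_end", "seq")

setValidity("SVSet", function(object) {
  msg <- character()
  if (!object@anchorGenome %in% c("A", "B"))
    msg <- c(msg, "anchorGenome must be \"A\" or \"B\"")
  m <- mcols(object@ranges)
  missing_cols <- setdiff(.svset_mcols, colnames(m))
  if (length(missing_cols))
    return(paste("missing metadata columns:",
                 paste(missing_cols, collapse = ", ")))
  if (length(object@ranges)) {
    if (anyDuplicated(m$sv_id))
      msg <- c(msg, "sv_id values must be unique")
    if (!all(m$sv_type %in% SV_TYPES))
      msg <- c(msg, "unknown sv_type value")
    if (any(m$len_a < 0 | m$len_b < 0))
      msg <- c(msg, "allele lengths must be non-negative")
    if (!all(m$source %in% c("assembly", "reads", "merged", "truth")))
      msg <- c(msg, "source must be assembly, reads, merged or truth")
    if (any(!m$precise & !m$sv_type %in% SV_COMPLEX_TYPES))
      msg <- c(msg, "precise = FALSE is only allowed for complex SV types")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an SVSet
#'
#' @param chrom,start,end anchor-genome coordinates (1-based closed).
#' @param sv_type one of the seven supported SV classes.
#' @param len_a,len_b allele lengths (bp) on genomes A and B.
#' @param anchorGenome \code{"A"} or \code{"B"}.
#' @param sv_id identifiers; autogenerated when \code{NULL}.
#' @param source evidence source: \code{"assembly"}, \code{"reads"},
#'   \code{"merged"} or \code{"truth"}.
#' @param precise logical, breakpoints defined exactly.
#' @param mate_chrom,mate_start,mate_end coordinates of the corresponding
#'   interval on the other genome (NA when unknown).
#' @param seq allele sequence (NA when not retained).
#' @return An \code{SVSet}.
#' @export
SVSet <- function(chrom = character(), start = integer(), end = integer(),
                  sv_type = character(), len_a = integer(),
                  len_b = integer(), anchorGenome = "A", sv_id = NULL,
                  source = "assembly", precise = TRUE,
                  mate_chrom = NA_character_, mate_start = NA_integer_,
                  mate_end = NA_integer_, seq = NA_character_) {
  n <- length(chrom)
  if (is.null(sv_id)) {
    sv_id <- if (n) sprintf("sv_%05d", seq_len(n)) else character()
  }
  gr <- GRanges(chrom, IRanges(start = as.integer(start),
                               end = as.integer(end)))
  mcols(gr) <- DataFrame(
    sv_id = as.character(sv_id),
    sv_type = as.character(sv_type),
    len_a = as.integer(len_a),
    len_b = as.integer(len_b),
    source = rep_len(as.character(source), n),
    precise = rep_len(as.logical(precise), n),
    mate_chrom = rep_len(as.character(mate_chrom), n),
    mate_start = rep_len(as.integer(mate_start), n),
    mate_end = rep_len(as.integer(mate_end), n),
    seq = rep_len(as.character(seq), n))
  new("SVSet", ranges = gr, anchorGenome = anchorGenome)
}

#' Build an SVSet from a data.frame
#'
#' Columns: \code{chrom,start,end,sv_type,len_a,len_b} required;
#' \code{sv_id,source,precise,mate_chrom,mate_start,mate_end,seq} optional.
#'
#' @param df the data.frame.
#' @param anchorGenome \code{"A"} or \code{"B"}.
#' @return An \code{SVSet}.
#' @export
svSetFromFrame <- function(df, anchorGenome = "A") {
  n <- nrow(df)
  get <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep_len(default, n)
  }
  SVSet(chrom = df$chrom, start = df$start, end = df$end,
        sv_type = df$sv_type, len_a = df$len_a, len_b = df$len_b,
        anchorGenome = anchorGenome,
        sv_id = if ("sv_id" %in% names(df)) df$sv_id else NULL,
        source = get("source", "assembly"),
        precise = get("precise", TRUE),
        mate_chrom = get("mate_chrom", NA_character_),
        mate_start = get("mate_start", NA_integer_),
        mate_end = get("mate_end", NA_integer_),
        seq = get("seq", NA_character_))
}

#' SimulationConfig: parameters of the synthetic genome/read simulator
#'
#' Holds every knob of the synthetic module; the single \code{seed}
#' determines all outputs byte-for-byte.
#'
#' @slot seed integer master seed.
#' @slot genomeLength total genome length (bp) across chromosomes.
#' @slot nChromosomes number of chromosomes.
#' @slot gcContent GC fraction of the simulated background sequence.
#' @slot svCounts named integer vector over the seven SV classes.
#' @slot svSizeRange named list: per SV class, \code{c(min, max)} event
#'   size (bp); minimum 10 bp everywhere.
#' @slot backgroundDivergence per-base substitution rate planted between the
#'   two assemblies outside SVs (default 0.005).
#' @slot minSpacing minimum distance (bp) between planted SVs.
#' @slot nAccessions number of resequenced accessions to simulate.
#' @slot hetFraction fraction of accession genotypes drawn heterozygous.
#' @slot shortReadLength 100 or 150 (bp).
#' @slot shortReadDepth fold coverage of simulated paired-end reads.
#' @slot insertSizeMean,insertSizeSd paired-end fragment length model (bp).
#' @slot longReadMeanLength mean simulated long-read length (bp).
#' @slot errorRate per-base sequencing error (substitution) rate.
#' @slot gapRuns data.frame \code{chrom,position,length} of N-runs to plant
#'   in both assemblies (assembly gaps).
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig",
         slots = c(seed = "integer", genomeLength = "numeric",
                   nChromosomes = "integer", gcContent = "numeric",
                   svCounts = "integer", svSizeRange = "list",
                   backgroundDivergence = "numeric", minSpacing = "numeric",
                   nAccessions = "integer", hetFraction = "numeric",
                   shortReadLength = "integer", shortReadDepth = "numeric",
                   insertSizeMean = "numeric", insertSizeSd = "numeric",
                   longReadMeanLength = "numeric", errorRate = "numeric",
                   gapRuns = "data.frame"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must be in [0, 1]")
  if (!setequal(names(object@svCounts), SV_TYPES))
    msg <- c(msg, "svCounts must be named by the seven SV types")
  if (any(object@svCounts < 0))
    msg <- c(msg, "svCounts must be non-negative")
  for (ty in names(object@svSizeRange)) {
    if (!is.na(object@svCounts[ty]) && object@svCounts[[ty]] == 0L)
      next                    # size range only matters for planted types
    r <- object@svSizeRange[[ty]]
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, sprintf("svSizeRange[[\"%s\"]] must be c(min, max)", ty))
    else {
      if (r[1] < 10)
        msg <- c(msg, sprintf("minimum SV size is 10 bp (%s)", ty))
      if (r[2] > object@genomeLength / 10)
        msg <- c(msg, sprintf("SV sizes must be <= genome_length/10 (%s)", ty))
    }
  }
  if (!object@shortReadLength %in% c(100L, 150L))
    msg <- c(msg, "shortReadLength must be 100 or 150")
  if (object@hetFraction < 0 || object@hetFraction > 1)
    msg <- c(msg, "hetFraction must be in [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 0.25)
    msg <- c(msg, "errorRate must be in [0, 0.25]")
  if (object@backgroundDivergence < 0 || object@backgroundDivergence > 0.2)
    msg <- c(msg, "backgroundDivergence must be in [0, 0.2]")
  if (length(msg)) msg else TRUE
})

#' TruthSet: planted SVs, true genotypes and read provenance
#'
#' Emitted by the synthetic generator; the complete ground truth every
#' downstream stage is evaluated against.
#'
#' @slot svs \code{SVSet} anchored on genome A with mate coordinates on
#'   genome B for every planted variant.
#' @slot genotypes character matrix (accessions x SVs) over
#'   \code{c("A","B","H")}; truth is complete, no undetermined entries.
#' @slot provenance data.frame with one row per simulated read
#'   (\code{accession,read_id,haplotype,chrom,start,end}); zero rows until
#'   reads are simulated.
#'
#' @aliases TruthSet-class
#' @export
setClass("TruthSet",
         slots = c(svs = "SVSet", genotypes = "matrix",
                   provenance = "data.frame"))

setValidity("TruthSet", function(object) {
  msg <- character()
  gt <- object@genotypes
  if (length(gt)) {
    if (!all(gt %in% c("A", "B", "H")))
      msg <- c(msg, "truth genotypes must be in {A, B, H} (no undetermined)")
    if (is.null(colnames(gt)) ||
        !identical(colnames(gt), svId(object@svs)))
      msg <- c(msg, "genotype columns must match sv_id order of planted SVs")
  }
  ## every planted SV must be located in both coordinate systems
  if (length(object@svs@ranges) &&
      anyNA(mcols(object@svs@ranges)$mate_start))
    msg <- c(msg, "planted SVs must carry mate coordinates on the other genome")
  if (length(msg)) msg else TRUE
})
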
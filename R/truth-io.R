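#' Write and read a TruthSet as tab-separated tables
#'
#' Three files are written under \code{dir}: \code{truth_svs.tsv} (one row
#' per planted SV; coordinates 1-based closed, columns
#' \code{sv_id,chrom,start,end,sv_type,len_a,len_b,source,precise,
#' mate_chrom,mate_start,mate_end,seq} where an empty allele sequence is
#' encoded as \code{.}), \code{truth_genotypes.tsv} (accession rows x sv_id
#' columns over \code{A/B/H}) and \code{truth_provenance.tsv} (one row per
#' simulated read). The pair of functions round-trips losslessly.
#'
#' @param truth a \linkS4class{TruthSet}.
#' @param dir output directory (created if needed).
#' @return \code{writeTruthSet}: \code{dir}, invisibly.
#'   \code{readTruthSet}: the reconstructed \code{TruthSet}.
#' @export
writeTruthSet <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  svs <- truthSvs(truth)
  m <- mcols(svRanges(svs))
  df <- data.frame(sv_id = m$sv_id,
                   chrom = as.character(seqnames(svRanges(svs))),
                   start = start(svRanges(svs)),
                   end = end(svRanges(svs)),
                   sv_type = m$sv_type, len_a = m$len_a, len_b = m$len_b,
                   source = m$source, precise = m$precise,
                   mate_chrom = m$mate_chrom, mate_start = m$mate_start,
                   mate_end = m$mate_end,
                   seq = ifelse(is.na(m$seq) | m$seq == "", ".", m$seq),
                   stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "truth_svs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- truthGenotypes(truth)
  gt_df <- data.frame(accession = rownames(gt), gt, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write.table(gt_df, file.path(dir, "truth_genotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(readProvenance(truth),
              file.path(dir, "truth_provenance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeTruthSet
#' @export
readTruthSet <- function(dir) {
  sv_path <- file.path(dir, "truth_svs.tsv")
  gt_path <- file.path(dir, "truth_genotypes.tsv")
  pr_path <- file.path(dir, "truth_provenance.tsv")
  for (p in c(sv_path, gt_path, pr_path))
    if (!file.exists(p)) stop("missing truth file: ", p)
  df <- read.delim(sv_path, stringsAsFactors = FALSE,
                   colClasses = c(seq = "character", chrom = "character",
                                  mate_chrom = "character"))
  if (nrow(df)) df$seq <- ifelse(df$seq == ".", "", df$seq)
  svs <- svSetFromFrame(df, anchorGenome = "A")
  gt_df <- read.delim(gt_path, check.names = FALSE,
                      stringsAsFactors = FALSE)
  gt <- as.matrix(gt_df[, -1, drop = FALSE])
  rownames(gt) <- gt_df$accession
  storage.mode(gt) <- "character"
  prov <- read.delim(pr_path, stringsAsFactors = FALSE)
  if (!nrow(prov))
    prov <- data.frame(accession = character(), read_id = character(),
                       haplotype = integer(), chrom = character(),
                       start = integer(), end = integer())
  new("TruthSet", svs = svs, genotypes = gt, provenance = prov)
}
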
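#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments cigar njunc
#'   cigarRangesAlongReferenceSpace
NULL

## Duplicate-definition prefix length by read-length class.
.dedupPrefix <- function(read_length) {
  if (read_length == 100L) 90L
  else if (read_length == 150L) 100L
  else stop("unsupported read length class: ", read_length,
            " (expected 100 or 150)")
}

#' Consolidate duplicated read pairs into unique read pairs
#'
#' Two pairs are duplicates when both mates share identical bases over the
#' class prefix: the first 90 bp for 100-bp reads, the first 100 bp for
#' 150-bp reads. The first occurrence of each key is kept, preserving
#' input order.
#'
#' @param reads1,reads2 \code{DNAStringSet}: mates 1 and 2 (parallel).
#' @return list with \code{keep} (logical vector over pairs),
#'   \code{n_duplicates}, and the deduplicated \code{reads1}, \code{reads2}.
#' @export
deduplicateReadPairs <- function(reads1, reads2) {
  stopifnot(length(reads1) == length(reads2))
  if (!length(reads1))
    return(list(keep = logical(), n_duplicates = 0L,
                reads1 = reads1, reads2 = reads2))
  w <- unique(c(Biostrings::width(reads1), Biostrings::width(reads2)))
  if (length(w) != 1L)
    stop("mixed read lengths in one file: ", paste(w, collapse = ", "))
  p <- .dedupPrefix(w)
  key <- paste(substr(as.character(reads1), 1L, p),
               substr(as.character(reads2), 1L, p))
  keep <- !duplicated(key)
  list(keep = keep, n_duplicates = sum(!keep),
       reads1 = reads1[keep], reads2 = reads2[keep])
}

#' @describeIn deduplicateReadPairs file-level wrapper over paired FASTQ
#'   (gz) files; writes the surviving pairs and returns the duplicate
#'   count invisibly.
#' @param fq1,fq2 input FASTQ paths; \code{out1,out2} output paths.
#' @param out1,out2 output FASTQ (gz) paths.
#' @export
deduplicateFastqPair <- function(fq1, fq2, out1, out2) {
  r1 <- readDNAStringSet(fq1, format = "fastq")
  r2 <- readDNAStringSet(fq2, format = "fastq")
  dd <- deduplicateReadPairs(r1, r2)
  w <- if (length(dd$reads1)) Biostrings::width(dd$reads1) else integer()
  writeXStringSet(dd$reads1, out1, format = "fastq", compress = TRUE,
                  qualities = BStringSet(strrep("I", w)))
  writeXStringSet(dd$reads2, out2, format = "fastq", compress = TRUE,
                  qualities = BStringSet(strrep("I", w)))
  invisible(dd$n_duplicates)
}

#' Align paired reads to a reference with bwa mem
#'
#' Indexes the reference once (index files cached next to the FASTA), runs
#' single-threaded \code{bwa mem}, and sorts/indexes the output with
#' samtools.
#'
#' @param ref_fasta reference FASTA path.
#' @param fq1,fq2 paired FASTQ paths.
#' @param out_bam output BAM path.
#' @return \code{out_bam}, invisibly.
#' @export
bwaAlignPairs <- function(ref_fasta, fq1, fq2, out_bam) {
  if (!file.exists(paste0(ref_fasta, ".bwt")))
    runTool("bwa", c("index", shQuote(ref_fasta)))
  sam <- tempfile("aln_", fileext = ".sam")
  runTool("bwa", c("mem", "-t", "1", shQuote(ref_fasta), shQuote(fq1),
                   shQuote(fq2)), stdout = sam)
  runTool("samtools", c("sort", "-o", shQuote(out_bam), shQuote(sam)))
  runTool("samtools", c("index", shQuote(out_bam)))
  unlink(sam)
  invisible(out_bam)
}

#' Load alignments and apply the mismatch-fraction filter
#'
#' Reads primary alignments with their CIGAR and NM (edit distance) tag and
#' drops records whose mismatch fraction (edit distance over aligned
#' length) exceeds \code{max_mismatch_fraction}. Unaligned records never
#' enter the result.
#'
#' @param bam BAM path (indexed).
#' @param max_mismatch_fraction maximum allowed mismatches per aligned
#'   base (default 0.03).
#' @return A \code{GAlignments} object (NM kept in \code{mcols}).
#' @export
loadFilteredAlignments <- function(bam, max_mismatch_fraction = 0.03) {
  param <- ScanBamParam(tag = "NM",
                        flag = scanBamFlag(isUnmappedQuery = FALSE,
                                           isSecondaryAlignment = FALSE))
  galn <- readGAlignments(bam, param = param)
  filterAlignments(galn, max_mismatch_fraction)
}

#' @describeIn loadFilteredAlignments apply the filter to an existing
#'   \code{GAlignments} with an \code{NM} metadata column.
#' @param galn a \code{GAlignments} with \code{NM} in \code{mcols}.
#' @export
filterAlignments <- function(galn, max_mismatch_fraction = 0.03) {
  nm <- mcols(galn)$NM
  if (is.null(nm) || all(is.na(nm)))
    stop("alignments carry no NM (edit distance) annotation")
  alen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar(galn), after.soft.clipping = TRUE)
  ## NM counts indel bases too; the filter targets base mismatches, and a
  ## read legitimately spanning an SV indel must not be thrown away for it
  opt <- GenomicAlignments::cigarOpTable(cigar(galn))
  mm <- pmax(0L, nm - opt[, "I"] - opt[, "D"])
  galn[!is.na(nm) & mm / alen <= max_mismatch_fraction]
}
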
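#' Align two assemblies with minimap2 and parse the PAF
#'
#' \code{alignGenomes} writes the two genomes to FASTA, runs
#' \code{minimap2 -cx asm5 --eqx} (genome A as target, genome B as query)
#' and returns the parsed PAF. \code{readPaf} parses an existing PAF file
#' with its \code{cg} (CIGAR) tag.
#'
#' Parsed coordinates are converted from PAF's 0-based half-open to the
#' 1-based closed convention used throughout the package.
#'
#' @param genome_a,genome_b \code{DNAStringSet} assemblies, or paths to
#'   FASTA files.
#' @param preset minimap2 preset (default \code{"asm5"}).
#' @param extra_args additional minimap2 arguments.
#' @return A data.frame of alignment blocks with columns
#'   \code{qname,qlen,qstart,qend,strand,tname,tlen,tstart,tend,nmatch,
#'   alen,mapq,cg,mapping_unique}.
#' @export
alignGenomes <- function(genome_a, genome_b, preset = "asm5",
                         extra_args = character()) {
  fa_a <- if (is.character(genome_a)) genome_a else
    writeFastaTo(genome_a, tempfile("genomeA_", fileext = ".fa"))
  fa_b <- if (is.character(genome_b)) genome_b else
    writeFastaTo(genome_b, tempfile("genomeB_", fileext = ".fa"))
  paf <- tempfile("aln_", fileext = ".paf")
  runTool("minimap2", c("-cx", preset, "--eqx", "-t", "1", extra_args,
                        shQuote(fa_a), shQuote(fa_b)), stdout = paf)
  readPaf(paf)
}

#' @param path PAF file path.
#' @param min_mapq mapping quality at or above which an alignment block is
#'   considered uniquely anchored.
#' @rdname alignGenomes
#' @export
readPaf <- function(path, min_mapq = 40L) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), tname = character(),
                      tlen = integer(), tstart = integer(),
                      tend = integer(), nmatch = integer(),
                      alen = integer(), mapq = integer(),
                      cg = character(), mapping_unique = logical()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 12L)
  if (length(bad))
    stop("malformed PAF record at line ", bad[1])
  getf <- function(i) vapply(parts, `[[`, character(1), i)
  cg <- vapply(parts, function(p) {
    hit <- grep("^cg:Z:", p, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, character(1))
  df <- data.frame(
    qname = getf(1), qlen = as.integer(getf(2)),
    qstart = as.integer(getf(3)) + 1L, qend = as.integer(getf(4)),
    strand = getf(5), tname = getf(6), tlen = as.integer(getf(7)),
    tstart = as.integer(getf(8)) + 1L, tend = as.integer(getf(9)),
    nmatch = as.integer(getf(10)), alen = as.integer(getf(11)),
    mapq = as.integer(getf(12)), cg = cg, stringsAsFactors = FALSE)
  df$mapping_unique <- df$mapq >= min_mapq
  df[order(df$tname, df$tstart), , drop = FALSE]
}

## Parse a CIGAR string into op letters and lengths.
.parseCigar <- function(cg) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
  toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}
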
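#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet
#'   readDNAStringSet reverseComplement
#' @importFrom stats rbinom runif rnorm setNames p.adjust dhyper prcomp
#' @importFrom utils read.delim write.table head tail
NULL

## Derive per-stage seeds deterministically from one master seed so that a
## single integer reproduces the whole workflow.  Offsets are arbitrary
## fixed constants; results kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  offsets <- c(genome = 101L, svplace = 211L, genotypes = 307L,
               reads = 401L, readcalls = 503L, thin = 601L,
               cohort = 701L, pipeline = 809L)
  if (!stage %in% names(offsets))
    stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

## Run an external tool, failing loudly on non-zero exit.  `stdout` may be
## TRUE (capture and return), a file path (redirect), or FALSE (discard).
runTool <- function(cmd, args, stdout = FALSE, quiet = TRUE) {
  if (Sys.which(cmd) == "")
    stop("required external tool not found on PATH: ", cmd)
  out <- suppressWarnings(
    system2(cmd, args,
            stdout = if (isTRUE(stdout) || is.character(stdout)) stdout
                     else FALSE,
            stderr = if (quiet) tempfile("stderr_") else ""))
  status <- attr(out, "status")
  if (isTRUE(stdout)) {
    if (!is.null(status) && status != 0)
      stop(cmd, " failed (exit ", status, ")")
    return(out)
  }
  if (is.integer(out) && length(out) && out != 0)
    stop(cmd, " failed with exit status ", out)
  invisible(NULL)
}

## Random DNA of length n at a given GC content (character scalar).
randomDna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## Apply per-base substitution noise at rate `rate` to a character vector of
## sequences; substituted bases are drawn from the three alternatives.
mutateBases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), ch[p])
      ch[p] <- sample(alt, 1L)
    }
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Write a DNAStringSet to a temporary (or given) FASTA path.
writeFastaTo <- function(seqs, path) {
  writeXStringSet(seqs, filepath = path, format = "fasta", width = 70L)
  path
}

## N-run intervals (assembly gaps) of at least min_run bases, per sequence.
## Returns a GRanges over all sequences in the set.
nRunRanges <- function(genome, min_run = 10L) {
  grl <- lapply(seq_along(genome), function(i) {
    ch <- as.character(genome[[i]])
    isn <- charToRaw(ch) == charToRaw("N")
    r <- rle(as.vector(isn))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(NULL)
    GRanges(names(genome)[i], IRanges(starts[keep], ends[keep]))
  })
  grl <- grl[!vapply(grl, is.null, logical(1L))]
  if (!length(grl))
    return(GRanges())
  do.call(c, grl)
}

## Simple stage logger used across the pipeline.
svdLog <- function(..., logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(logfile))
    cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
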
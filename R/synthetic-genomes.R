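## Synthetic genome-pair generator: plants insertions, deletions,
## substitutions and (im)perfect tandem-repeat copy-number changes into a
## random background genome, yielding two haploid assemblies plus a complete
## truth set with breakpoints in both coordinate systems.

## Internal event table columns:
##   chrom, a_from, a_to  : edited A interval, 1-based closed; a_to = a_from-1
##                          encodes an empty interval (pure insertion point)
##   b_repl               : replacement sequence on genome B ("" = deletion)
##   sv_type, len_a, len_b: reported allele bookkeeping
## For tandem/repeat classes the A segment itself is overwritten with the
## repeat array, so len_a counts the full array on A.

.drawSvEvents <- function(config) {
  events <- list()
  for (ty in SV_TYPES) {
    n <- config@svCounts[[ty]]
    if (n == 0L) next
    r <- config@svSizeRange[[ty]]
    sizes <- round(exp(runif(n, log(r[1]), log(r[2]))))
    for (sz in sizes) {
      ev <- switch(ty,
        insertion = {
          seqb <- randomDna(sz, config@gcContent)
          list(len_a = 0L, len_b = sz, b_repl = seqb, a_repl = NULL)
        },
        deletion = list(len_a = sz, len_b = 0L, b_repl = "", a_repl = NULL),
        substitution = {
          fac <- if (runif(1) < 0.5) runif(1, 0.4, 0.8) else runif(1, 1.25, 2.5)
          lb <- max(10L, min(as.integer(round(sz * fac)), as.integer(r[2])))
          if (lb == sz) lb <- lb + 10L
          list(len_a = sz, len_b = lb,
               b_repl = randomDna(lb, config@gcContent), a_repl = NULL)
        },
        {
          ## repeat / tandem copy-number change: two copies of a unit on one
          ## genome, 2 + m copies on the other (m*u ~ requested size).
          u <- sample(10:max(10L, min(200L, sz)), 1L)
          m <- max(1L, as.integer(ceiling(sz / u)))
          unit <- randomDna(u, config@gcContent)
          perfect <- ty %in% c("tandem_expansion", "tandem_contraction")
          mk <- function(k) {
            copies <- replicate(k, if (perfect) unit else
              mutateBases(unit, 0.03), simplify = TRUE)
            paste(copies, collapse = "")
          }
          short_arr <- mk(2L)
          long_arr <- paste0(short_arr, mk(m))
          if (ty %in% c("tandem_expansion", "repeat_expansion"))
            list(len_a = nchar(short_arr), len_b = nchar(long_arr),
                 b_repl = long_arr, a_repl = short_arr)
          else
            list(len_a = nchar(long_arr), len_b = nchar(short_arr),
                 b_repl = short_arr, a_repl = long_arr)
        })
      ev$sv_type <- ty
      events[[length(events) + 1L]] <- ev
    }
  }
  events
}

## Rejection-sample non-overlapping positions with min_spacing between
## events, chromosome ends and planted gap runs.
.placeEvents <- function(events, chrom_lengths, gap_runs, min_spacing,
                         max_tries = 2000L) {
  placed <- data.frame(chrom = character(), from = numeric(),
                       to = numeric())
  if (nrow(gap_runs))
    placed <- rbind(placed,
                    data.frame(chrom = gap_runs$chrom,
                               from = gap_runs$position,
                               to = gap_runs$position + gap_runs$length - 1))
  res <- vector("list", length(events))
  ord <- order(-vapply(events, function(e) e$len_a, numeric(1)))
  for (i in ord) {
    ev <- events[[i]]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(names(chrom_lengths), 1L,
                      prob = chrom_lengths / sum(chrom_lengths))
      lo <- min_spacing + 1
      hi <- chrom_lengths[[chrom]] - min_spacing - max(ev$len_a, 1L)
      if (hi <= lo) next
      s <- floor(runif(1, lo, hi))
      a_to <- s + max(ev$len_a, 1L) - 1
      same <- placed[placed$chrom == chrom, , drop = FALSE]
      if (!nrow(same) ||
          all(s - same$to > min_spacing | same$from - a_to > min_spacing)) {
        placed <- rbind(placed,
                        data.frame(chrom = chrom, from = s, to = a_to))
        ev$chrom <- chrom
        ev$a_from <- if (ev$len_a == 0L) s + 1L else s
        ev$a_to <- if (ev$len_a == 0L) s else s + ev$len_a - 1L
        res[[i]] <- ev
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("SV placement retries exhausted: genome too small for the ",
           "requested SV count/spacing")
  }
  res
}

#' Generate a synthetic genome pair with planted SVs
#'
#' Builds genome A as random sequence (with optional planted N-run assembly
#' gaps), then derives genome B by applying the planted SV set left to right
#' and sprinkling background single-base divergence outside SV loci. The
#' returned truth set records each variant's exact interval on both genomes,
#' the B-allele sequence, and a complete accession genotype matrix drawn
#' with the configured heterozygous fraction.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{genome_a}, \code{genome_b}
#'   (\code{DNAStringSet}) and \code{truth} (\linkS4class{TruthSet}).
#' @examples
#' cfg <- simulationConfig(seed = 7, genome_length = 1e5, n_chromosomes = 1,
#'                         sv_counts = c(deletion = 2, insertion = 2),
#'                         sv_size_range = c(50, 500), min_spacing = 2000,
#'                         background_divergence = 0, n_accessions = 2)
#' gp <- generateGenomePair(cfg)
#' gp$truth
#' @export
generateGenomePair <- function(config) {
  validObject(config)
  set.seed(deriveSeed(config@seed, "genome"))
  chrlen <- rep(floor(config@genomeLength / config@nChromosomes),
                config@nChromosomes)
  names(chrlen) <- sprintf("chr%d", seq_len(config@nChromosomes))
  chrs_a <- lapply(names(chrlen),
                   function(ch) randomDna(chrlen[[ch]], config@gcContent))
  names(chrs_a) <- names(chrlen)
  if (nrow(config@gapRuns)) {
    for (k in seq_len(nrow(config@gapRuns))) {
      g <- config@gapRuns[k, ]
      if (!g$chrom %in% names(chrs_a))
        stop("gap_runs chromosome not in genome: ", g$chrom)
      substr(chrs_a[[g$chrom]], g$position,
             g$position + g$length - 1) <-
        strrep("N", g$length)
    }
  }

  set.seed(deriveSeed(config@seed, "svplace"))
  events <- .drawSvEvents(config)
  events <- .placeEvents(events, chrlen, config@gapRuns, config@minSpacing)

  ## overwrite A segments for repeat/tandem arrays
  for (ev in events) {
    if (!is.null(ev$a_repl))
      substr(chrs_a[[ev$chrom]], ev$a_from, ev$a_to) <- ev$a_repl
  }

  ## order events along the genome, then build B chromosome by chromosome
  if (length(events)) {
    ord <- order(vapply(events, `[[`, character(1), "chrom"),
                 vapply(events, `[[`, numeric(1), "a_from"))
    events <- events[ord]
  }
  div <- config@backgroundDivergence
  chrs_b <- list()
  truth_rows <- list()
  for (ch in names(chrlen)) {
    evs <- Filter(function(e) e$chrom == ch, events)
    pieces <- character(0)
    cur_a <- 1L
    b_len <- 0L
    aseq <- chrs_a[[ch]]
    for (ev in evs) {
      bg_to <- ev$a_from - 1L
      if (bg_to >= cur_a) {
        bg <- substr(aseq, cur_a, bg_to)
        if (div > 0) bg <- .divergeKeepN(bg, div)
        pieces <- c(pieces, bg)
        b_len <- b_len + (bg_to - cur_a + 1L)
      }
      b_from <- b_len + 1L
      if (nchar(ev$b_repl)) {
        pieces <- c(pieces, ev$b_repl)
        b_len <- b_len + nchar(ev$b_repl)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        chrom = ch,
        start = if (ev$len_a == 0L) ev$a_from - 1L else ev$a_from,
        end = if (ev$len_a == 0L) ev$a_from - 1L else ev$a_to,
        sv_type = ev$sv_type, len_a = ev$len_a, len_b = ev$len_b,
        mate_chrom = ch,
        mate_start = if (ev$len_b == 0L) b_from - 1L else b_from,
        mate_end = if (ev$len_b == 0L) b_from - 1L else
          b_from + ev$len_b - 1L,
        seq = ev$b_repl, stringsAsFactors = FALSE)
      cur_a <- ev$a_to + 1L
    }
    if (cur_a <= chrlen[[ch]]) {
      bg <- substr(aseq, cur_a, chrlen[[ch]])
      if (div > 0) bg <- .divergeKeepN(bg, div)
      pieces <- c(pieces, bg)
    }
    chrs_b[[ch]] <- paste(pieces, collapse = "")
  }

  genome_a <- DNAStringSet(unlist(chrs_a))
  genome_b <- DNAStringSet(unlist(chrs_b))
  names(genome_a) <- names(chrlen)
  names(genome_b) <- names(chrlen)

  if (length(truth_rows)) {
    tr <- do.call(rbind, truth_rows)
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    tr$sv_id <- sprintf("sv_%05d", seq_len(nrow(tr)))
  } else {
    tr <- data.frame(chrom = character(), start = integer(),
                     end = integer(), sv_type = character(),
                     len_a = integer(), len_b = integer(),
                     mate_chrom = character(), mate_start = integer(),
                     mate_end = integer(), seq = character(),
                     sv_id = character())
  }
  tr$source <- rep("truth", nrow(tr))
  tr$precise <- rep(TRUE, nrow(tr))
  svs <- svSetFromFrame(tr, anchorGenome = "A")

  set.seed(deriveSeed(config@seed, "genotypes"))
  n_acc <- config@nAccessions
  n_sv <- length(svs)
  gts <- matrix("A", nrow = n_acc, ncol = n_sv,
                dimnames = list(sprintf("acc_%02d", seq_len(n_acc)),
                                svId(svs)))
  if (n_acc && n_sv) {
    draw <- matrix(runif(n_acc * n_sv), n_acc, n_sv)
    gts[draw < config@hetFraction] <- "H"
    homs <- draw >= config@hetFraction
    gts[homs] <- ifelse(matrix(runif(n_acc * n_sv), n_acc, n_sv)[homs] < 0.5,
                        "A", "B")
  }
  truth <- new("TruthSet", svs = svs, genotypes = gts,
               provenance = data.frame(accession = character(),
                                       read_id = character(),
                                       haplotype = integer(),
                                       chrom = character(),
                                       start = integer(), end = integer()))
  list(genome_a = genome_a, genome_b = genome_b, truth = truth)
}

## Background divergence that never touches planted N bases and never
## introduces indels (single-base substitutions only).
.divergeKeepN <- function(s, rate) {
  n <- nchar(s)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    if (ch[p] == "N") next
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Build one accession haplotype as a mosaic of the two genomes
#'
#' Starting from genome A, applies the B-allele replacement at every SV
#' locus where \code{alleles} says this haplotype carries the B allele.
#'
#' @param genome_a \code{DNAStringSet} genome A.
#' @param truth \linkS4class{TruthSet} from \code{\link{generateGenomePair}}.
#' @param alleles character vector over the planted SVs (in truth order),
#'   each \code{"A"} or \code{"B"}.
#' @return \code{DNAStringSet}: the haplotype genome.
#' @export
buildHaplotype <- function(genome_a, truth, alleles) {
  svs <- truthSvs(truth)
  stopifnot(length(alleles) == length(svs),
            all(alleles %in% c("A", "B")))
  m <- mcols(svRanges(svs))
  out <- list()
  for (ch in names(genome_a)) {
    aseq <- as.character(genome_a[[ch]])
    sel <- which(as.character(seqnames(svRanges(svs))) == ch &
                 alleles == "B")
    if (!length(sel)) {
      out[[ch]] <- aseq
      next
    }
    sel <- sel[order(start(svRanges(svs))[sel])]
    pieces <- character(0)
    cur <- 1L
    for (i in sel) {
      ty <- m$sv_type[i]
      s <- start(svRanges(svs))[i]
      e <- end(svRanges(svs))[i]
      if (m$len_a[i] == 0L) {     # insertion: edit point after anchor base
        a_from <- s + 1L
        a_to <- s
      } else {
        a_from <- s
        a_to <- e
      }
      if (a_from > cur) pieces <- c(pieces, substr(aseq, cur, a_from - 1L))
      repl <- m$seq[i]
      if (!is.na(repl) && nchar(repl)) pieces <- c(pieces, repl)
      cur <- a_to + 1L
    }
    if (cur <= nchar(aseq)) pieces <- c(pieces, substr(aseq, cur, nchar(aseq)))
    out[[ch]] <- paste(pieces, collapse = "")
  }
  res <- DNAStringSet(unlist(out))
  names(res) <- names(genome_a)
  res
}
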
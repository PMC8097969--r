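#' @importFrom Biostrings pairwiseAlignment pid subseq
NULL

## ---- within-alignment events from the CIGAR of one block ----------------
## Returns rows: chrom,start,end,sv_type,len_a,len_b,mate_*,seq
.cigarEvents <- function(block, genome_b, min_size) {
  if (is.na(block$cg)) return(NULL)
  cig <- .parseCigar(block$cg)
  plus <- block$strand == "+"
  t <- block$tstart
  q <- if (plus) block$qstart else block$qend
  rows <- list()
  for (k in seq_along(cig$op)) {
    op <- cig$op[k]; len <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      if (op == "X" && len >= min_size) {
        qlo <- if (plus) q else q - len + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = block$tname, start = t, end = t + len - 1L,
          sv_type = "substitution", len_a = len, len_b = len,
          mate_chrom = block$qname, mate_start = qlo,
          mate_end = qlo + len - 1L, seq = NA_character_)
      }
      t <- t + len
      q <- q + if (plus) len else -len
    } else if (op == "I") {
      qlo <- if (plus) q else q - len + 1L
      if (len >= 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = block$tname, start = t - 1L, end = t - 1L,
          sv_type = "insertion", len_a = 0L, len_b = len,
          mate_chrom = block$qname, mate_start = qlo,
          mate_end = qlo + len - 1L, seq = NA_character_)
      q <- q + if (plus) len else -len
    } else if (op == "D") {
      if (len >= 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = block$tname, start = t, end = t + len - 1L,
          sv_type = "deletion", len_a = len, len_b = 0L,
          mate_chrom = block$qname,
          mate_start = if (plus) q - 1L else q + 1L,
          mate_end = if (plus) q - 1L else q + 1L, seq = NA_character_)
      t <- t + len
    } else if (op %in% c("S", "H")) {
      ## clipping does not occur in PAF base alignments; ignore
    }
  }
  if (!length(rows)) return(NULL)
  ev <- do.call(rbind, rows)
  ## an adjacent insertion/deletion pair is one unequal-length substitution
  ev <- ev[order(ev$start), , drop = FALSE]
  if (nrow(ev) > 1L) {
    drop <- logical(nrow(ev))
    for (i in seq_len(nrow(ev) - 1L)) {
      a <- ev[i, ]; b <- ev[i + 1L, ]
      pair <- sort(c(a$sv_type, b$sv_type))
      if (identical(pair, c("deletion", "insertion")) &&
          abs(b$start - a$end) <= 5L) {
        ins <- if (a$sv_type == "insertion") a else b
        del <- if (a$sv_type == "deletion") a else b
        ev[i, ] <- data.frame(chrom = a$chrom, start = del$start,
                              end = del$end, sv_type = "substitution",
                              len_a = del$len_a, len_b = ins$len_b,
                              mate_chrom = ins$mate_chrom,
                              mate_start = ins$mate_start,
                              mate_end = ins$mate_end, seq = NA_character_)
        drop[i + 1L] <- TRUE
      }
    }
    ev <- ev[!drop, , drop = FALSE]
  }
  ev[pmax(ev$len_a, ev$len_b) >= min_size, , drop = FALSE]
}

## Does an indel sit inside a locally repetitive context?  Compares the
## event sequence against the adjacent genome-A sequence; high identity
## means the event is a copy-number change of a local repeat whose exact
## breakpoints are ambiguous (to be refined with read-based calls).
.repeatContext <- function(event_seq, chrom_seq, left_end, right_start,
                           max_probe = 200L) {
  n <- nchar(event_seq)
  if (n < 10L) return(list(repetitive = FALSE, identity = 0))
  ident <- function(a, b, k) {
    if (nchar(b) < k) return(0)
    tryCatch(pid(pairwiseAlignment(a, b, type = "global")),
             error = function(e) 0)
  }
  ## The aligner may place the op at either edge of a repeat array, so
  ## probe both sides (event prefix vs downstream genome, suffix vs
  ## upstream); multiple probe lengths catch arrays whose remnant on this
  ## genome is much shorter than the event.
  id <- 0
  ## a copy-number event of a short unit is self-periodic: its first and
  ## second halves align well whatever remains of the array on this genome
  half <- min(floor(n / 2), max_probe)
  if (half >= 12L)
    id <- ident(substr(event_seq, 1L, half),
                substr(event_seq, half + 1L, 2L * half), half)
  for (k in unique(pmin(n, c(max_probe, 50L, 25L)))) {
    if (id >= 95) break
    if (k < 10L) next
    id <- max(id,
              ident(substr(event_seq, 1L, k),
                    substr(chrom_seq, right_start, right_start + k - 1L),
                    k),
              ident(substr(event_seq, n - k + 1L, n),
                    substr(chrom_seq, max(1L, left_end - k + 1L),
                           left_end), k))
    if (id >= 95) break
  }
  list(repetitive = id >= 80, identity = id)
}

## Reclassify within-alignment indels lying in repetitive context as
## complex copy-number events with widened (imprecise) intervals.
.applyRepeatContext <- function(ev, genome_a, genome_b) {
  if (is.null(ev) || !nrow(ev)) return(ev)
  ev$precise <- TRUE
  chrom_cache <- list()
  getchr <- function(ch) {
    if (is.null(chrom_cache[[ch]]))
      chrom_cache[[ch]] <<- as.character(genome_a[[ch]])
    chrom_cache[[ch]]
  }
  for (i in seq_len(nrow(ev))) {
    ty <- ev$sv_type[i]
    if (!ty %in% c("insertion", "deletion")) next
    chrom_seq <- getchr(ev$chrom[i])
    if (ty == "insertion") {
      s <- substr(as.character(genome_b[[ev$mate_chrom[i]]]),
                  ev$mate_start[i], ev$mate_end[i])
      ctx <- .repeatContext(s, chrom_seq, ev$start[i], ev$start[i] + 1L)
      if (ctx$repetitive) {
        L <- nchar(s)
        ev$sv_type[i] <- if (ctx$identity >= 95) "tandem_expansion" else
          "repeat_expansion"
        ev$precise[i] <- FALSE
        ev$start[i] <- max(1L, ev$start[i] - L)
        ev$end[i] <- min(nchar(chrom_seq), ev$end[i] + L)
        ev$len_a[i] <- ev$end[i] - ev$start[i] + 1L
        ev$len_b[i] <- ev$len_a[i] + L
      } else {
        ev$seq[i] <- s
      }
    } else {
      s <- substr(chrom_seq, ev$start[i], ev$end[i])
      ctx <- .repeatContext(s, chrom_seq, ev$start[i] - 1L,
                            ev$end[i] + 1L)
      if (ctx$repetitive) {
        L <- nchar(s)
        ev$sv_type[i] <- if (ctx$identity >= 95) "tandem_contraction" else
          "repeat_contraction"
        ev$precise[i] <- FALSE
        old_len <- ev$len_a[i]
        ev$start[i] <- max(1L, ev$start[i] - L)
        ev$end[i] <- min(nchar(chrom_seq), ev$end[i] + L)
        ev$len_a[i] <- ev$end[i] - ev$start[i] + 1L
        ev$len_b[i] <- ev$len_a[i] - old_len
      }
    }
  }
  ev
}

## ---- between-anchor events from consecutive unique blocks --------------
.anchorGapEvents <- function(blocks, min_size, max_size, max_span = 1e5) {
  rows <- list()
  blocks <- blocks[order(blocks$tname, blocks$tstart), , drop = FALSE]
  for (i in seq_len(max(0L, nrow(blocks) - 1L))) {
    b1 <- blocks[i, ]; b2 <- blocks[i + 1L, ]
    if (b1$tname != b2$tname || b1$qname != b2$qname ||
        b1$strand != b2$strand) next
    tg <- b2$tstart - b1$tend - 1L
    qg <- if (b1$strand == "+") b2$qstart - b1$qend - 1L else
      b1$qstart - b2$qend - 1L
    if (tg > max_span || qg > max_span) next
    if (tg < -max_span || qg < -max_span) next
    net <- qg - tg
    b_lo <- if (b1$strand == "+") b1$qend + 1L else b2$qend + 1L
    b_hi <- if (b1$strand == "+") b2$qstart - 1L else b1$qstart - 1L
    mate <- if (qg > 0) c(b_lo, b_hi) else
      c(max(1L, b_lo - 1L), max(1L, b_lo - 1L))
    row <- NULL
    if (tg >= 0 && qg >= 0) {
      if (min(tg, qg) < min_size) {
        if (net >= min_size && net <= max_size) {
          row <- data.frame(chrom = b1$tname, start = b1$tend,
                            end = b1$tend, sv_type = "insertion",
                            len_a = tg, len_b = qg, precise = TRUE)
        } else if (-net >= min_size && -net <= max_size) {
          row <- data.frame(chrom = b1$tname, start = b1$tend + 1L,
                            end = b2$tstart - 1L, sv_type = "deletion",
                            len_a = tg, len_b = qg, precise = TRUE)
        }
      } else if (max(tg, qg) <= max_size &&
                 tg / qg >= 0.1 && tg / qg <= 10) {
        row <- data.frame(chrom = b1$tname, start = b1$tend + 1L,
                          end = b2$tstart - 1L, sv_type = "substitution",
                          len_a = tg, len_b = qg, precise = TRUE)
      } else if (abs(net) >= min_size && abs(net) <= max_size) {
        row <- data.frame(chrom = b1$tname, start = b1$tend + 1L,
                          end = if (net > 0) b1$tend else b2$tstart - 1L,
                          sv_type = if (net > 0) "insertion" else "deletion",
                          len_a = tg, len_b = qg, precise = TRUE)
        if (net > 0) row$start <- row$end <- b1$tend
      }
    } else if (abs(net) >= min_size &&
               max(abs(tg), abs(qg)) <= max_size) {
      ## anchors overlap on one side: copy-number change of a repeat
      if (tg < 0 && qg >= 0) {
        ty <- "tandem_expansion"
        a_lo <- b2$tstart; a_hi <- b1$tend
      } else if (qg < 0 && tg >= 0) {
        ty <- "tandem_contraction"
        a_lo <- b1$tend + 1L; a_hi <- b2$tstart - 1L
      } else {
        ty <- if (net > 0) "repeat_expansion" else "repeat_contraction"
        a_lo <- min(b2$tstart, b1$tend); a_hi <- max(b2$tstart, b1$tend)
      }
      la <- a_hi - a_lo + 1L
      row <- data.frame(chrom = b1$tname, start = a_lo, end = a_hi,
                        sv_type = ty, len_a = la,
                        len_b = max(0L, la + net), precise = FALSE)
    }
    if (!is.null(row)) {
      row$mate_chrom <- b1$qname
      row$mate_start <- mate[1]; row$mate_end <- mate[2]
      row$seq <- NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Call structural variants from whole-genome alignment blocks
#'
#' Re-implements assembly-comparison SV calling: indels and long
#' mismatch runs are read out of each block's base-level alignment (CIGAR),
#' and the gap signature between consecutive uniquely-anchored blocks
#' yields indels, unequal-length substitutions, and the four complex
#' repeat/tandem copy-number classes (reported without defined breakpoints,
#' \code{precise = FALSE}). Indels embedded in locally repetitive sequence
#' are likewise demoted to complex calls so that read-based evidence can
#' define their breakpoints later. Blocks that are not uniquely anchored
#' (low mapping quality) are skipped with a warning.
#'
#' @param blocks alignment blocks from \code{\link{alignGenomes}} /
#'   \code{\link{readPaf}} (genome A as target, genome B as query).
#' @param genome_a,genome_b the two assemblies (\code{DNAStringSet});
#'   used to extract allele sequences and detect repeat context.
#' @param min_size minimum SV size in bp (default 10).
#' @param max_size maximum SV size in bp.
#' @param min_anchor minimum block length (bp) for between-anchor calls.
#' @return An \code{SVSet} anchored on genome A, \code{source="assembly"}.
#' @export
callSvsFromAlignment <- function(blocks, genome_a, genome_b,
                                 min_size = 10L, max_size = 7e5,
                                 min_anchor = 500L) {
  n_skip <- sum(!blocks$mapping_unique)
  if (n_skip)
    warning(n_skip, " non-uniquely anchored alignment block(s) skipped")
  blocks <- blocks[blocks$mapping_unique, , drop = FALSE]
  within_ev <- list()
  for (i in seq_len(nrow(blocks))) {
    ev <- .cigarEvents(blocks[i, ], genome_b, min_size)
    if (!is.null(ev)) within_ev[[length(within_ev) + 1L]] <- ev
  }
  within_ev <- if (length(within_ev)) do.call(rbind, within_ev) else NULL
  within_ev <- .applyRepeatContext(within_ev, genome_a, genome_b)
  anchors <- blocks[blocks$alen >= min_anchor, , drop = FALSE]
  between_ev <- .anchorGapEvents(anchors, min_size, max_size)
  ev <- rbind(within_ev, between_ev)
  if (is.null(ev) || !nrow(ev))
    return(SVSet(anchorGenome = "A"))
  ev <- ev[pmax(ev$len_a, ev$len_b) >= min_size &
           pmax(ev$len_a, ev$len_b) <= max_size, , drop = FALSE]
  ev <- ev[order(ev$chrom, ev$start), , drop = FALSE]
  ev$sv_id <- sprintf("asm_%05d", seq_len(nrow(ev)))
  ev$source <- "assembly"
  svSetFromFrame(ev, anchorGenome = "A")
}
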
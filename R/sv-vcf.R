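.SVTYPE_CODE <- c(insertion = "INS", deletion = "DEL",
                  substitution = "SUB", repeat_expansion = "RPE",
                  repeat_contraction = "RPC", tandem_expansion = "TDE",
                  tandem_contraction = "TDC")

#' Write and read an SV set as VCF
#'
#' Records are emitted as VCF 4.2 with symbolic ALT alleles
#' (\code{<INS>}, \code{<DEL>}, \code{<SUB>}, \code{<TDE>}, \code{<TDC>},
#' \code{<RPE>}, \code{<RPC>}), POS at the left-anchored base before the
#' event, and INFO keys \code{SVTYPE,END,SVLEN,LENA,LENB,SOURCE} plus the
#' package's lossless round-trip keys \code{STARTA,ENDA} (anchor interval,
#' 1-based closed), \code{ANCHOR}, mate coordinates
#' \code{MATECHR,MATESTART,MATEEND}, the \code{IMPRECISE} flag and, when an
#' allele sequence is retained, \code{SEQ}. \code{SVLEN} is
#' \code{len_b - len_a} (negative for net loss on genome B).
#'
#' @param svs an \code{SVSet}.
#' @param path output VCF path.
#' @param genome optional anchor genome (\code{DNAStringSet}) used for
#'   contig header lines and REF bases (\code{N} otherwise).
#' @return \code{writeSvVcf}: \code{path} invisibly; \code{readSvVcf}: an
#'   \code{SVSet}.
#' @export
writeSvVcf <- function(svs, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svdiverge",
           paste0("##INFO=<ID=SVTYPE,Number=1,Type=String,",
                  "Description=\"SV class\">"),
           paste0("##INFO=<ID=END,Number=1,Type=Integer,",
                  "Description=\"End of the event on the anchor genome\">"),
           paste0("##INFO=<ID=SVLEN,Number=1,Type=Integer,",
                  "Description=\"len_b - len_a\">"),
           paste0("##INFO=<ID=LENA,Number=1,Type=Integer,",
                  "Description=\"Allele length on genome A\">"),
           paste0("##INFO=<ID=LENB,Number=1,Type=Integer,",
                  "Description=\"Allele length on genome B\">"),
           paste0("##INFO=<ID=STARTA,Number=1,Type=Integer,",
                  "Description=\"Anchor interval start (1-based)\">"),
           paste0("##INFO=<ID=ENDA,Number=1,Type=Integer,",
                  "Description=\"Anchor interval end (1-based)\">"),
           paste0("##INFO=<ID=ANCHOR,Number=1,Type=String,",
                  "Description=\"Anchor genome (A or B)\">"),
           paste0("##INFO=<ID=SOURCE,Number=1,Type=String,",
                  "Description=\"Evidence source\">"),
           paste0("##INFO=<ID=MATECHR,Number=1,Type=String,",
                  "Description=\"Chromosome on the other genome\">"),
           paste0("##INFO=<ID=MATESTART,Number=1,Type=Integer,",
                  "Description=\"Mate interval start\">"),
           paste0("##INFO=<ID=MATEEND,Number=1,Type=Integer,",
                  "Description=\"Mate interval end\">"),
           paste0("##INFO=<ID=IMPRECISE,Number=0,Type=Flag,",
                  "Description=\"Breakpoints not defined exactly\">"),
           paste0("##INFO=<ID=SEQ,Number=1,Type=String,",
                  "Description=\"Allele sequence on genome B\">"),
           paste0("##ALT=<ID=", .SVTYPE_CODE, ",Description=\"",
                  names(.SVTYPE_CODE), "\">"))
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          nchar(as.character(genome))))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- hdr
  if (length(svs)) {
    df <- .svsetAsFrame(svs)
    pos <- ifelse(df$sv_type == "insertion" & df$len_a <= 1L,
                  df$start, pmax(1L, df$start - 1L))
    ref <- rep("N", nrow(df))
    if (!is.null(genome))
      ref <- vapply(seq_len(nrow(df)), function(i)
        substr(as.character(genome[[df$chrom[i]]]), pos[i], pos[i]),
        character(1))
    info <- vapply(seq_len(nrow(df)), function(i) {
      kv <- c(sprintf("SVTYPE=%s", .SVTYPE_CODE[[df$sv_type[i]]]),
              sprintf("END=%d", df$end[i]),
              sprintf("SVLEN=%d", df$len_b[i] - df$len_a[i]),
              sprintf("LENA=%d", df$len_a[i]),
              sprintf("LENB=%d", df$len_b[i]),
              sprintf("STARTA=%d", df$start[i]),
              sprintf("ENDA=%d", df$end[i]),
              sprintf("ANCHOR=%s", anchorGenome(svs)),
              sprintf("SOURCE=%s", df$source[i]))
      if (!is.na(df$mate_chrom[i]))
        kv <- c(kv, sprintf("MATECHR=%s", df$mate_chrom[i]),
                sprintf("MATESTART=%d", df$mate_start[i]),
                sprintf("MATEEND=%d", df$mate_end[i]))
      if (!df$precise[i]) kv <- c(kv, "IMPRECISE")
      if (!is.na(df$seq[i]))   # "." encodes a zero-length allele sequence
        kv <- c(kv, sprintf("SEQ=%s",
                            if (nzchar(df$seq[i])) df$seq[i] else "."))
      paste(kv, collapse = ";")
    }, character(1))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\t%s",
                              df$chrom, pos, df$sv_id, ref,
                              .SVTYPE_CODE[df$sv_type], info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @param path VCF path (uncompressed) written by \code{writeSvVcf}.
#' @rdname writeSvVcf
#' @export
readSvVcf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  anchor <- "A"
  rows <- lapply(body, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop("VCF parse error at line ", ln, ": expected 8 columns")
    info <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2]] else "",
                   character(1))
    gi <- function(k) {
      j <- match(k, keys)
      if (is.na(j)) NA_character_ else vals[[j]]
    }
    ty_code <- gi("SVTYPE")
    ty <- names(.SVTYPE_CODE)[match(ty_code, .SVTYPE_CODE)]
    if (is.na(ty))
      stop("VCF parse error at line ", ln, ": unknown SVTYPE ", ty_code)
    sta <- suppressWarnings(as.integer(gi("STARTA")))
    ena <- suppressWarnings(as.integer(gi("ENDA")))
    if (is.na(sta) || is.na(ena))
      stop("VCF parse error at line ", ln, ": missing STARTA/ENDA")
    data.frame(chrom = f[1], start = sta, end = ena, sv_id = f[3],
               sv_type = ty,
               len_a = as.integer(gi("LENA")),
               len_b = as.integer(gi("LENB")),
               source = gi("SOURCE"),
               precise = !("IMPRECISE" %in% keys),
               mate_chrom = gi("MATECHR"),
               mate_start = suppressWarnings(as.integer(gi("MATESTART"))),
               mate_end = suppressWarnings(as.integer(gi("MATEEND"))),
               seq = {
                 s <- gi("SEQ")
                 if (!is.na(s) && s == ".") "" else s
               },
               anchor = gi("ANCHOR"), stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(SVSet(anchorGenome = anchor))
  df <- do.call(rbind, rows)
  anchor <- if (!all(is.na(df$anchor))) df$anchor[!is.na(df$anchor)][1] else "A"
  svSetFromFrame(df[setdiff(names(df), "anchor")], anchorGenome = anchor)
}

#' Export SV intervals as BED
#'
#' Anchor-genome intervals in BED (0-based half-open) with the sv_id as
#' name and the SV class in column 5-like score slot replaced by type.
#'
#' @param svs an \code{SVSet}.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
writeSvBed <- function(svs, path) {
  df <- .svsetAsFrame(svs)
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = df$sv_id, score = 0L,
                    strand = ".", type = df$sv_type)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
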
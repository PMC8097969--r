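#' @importFrom rtracklayer import
NULL

#' Read gene models from GFF3
#'
#' Extracts \code{gene} features and their \code{CDS} children (matched
#' through the \code{Parent} chain via mRNA features when present, or
#' directly).
#'
#' @param path GFF3 file.
#' @return data.frame with \code{gene_id,chrom,start,end,strand} and a
#'   list-column \code{cds} of per-gene CDS interval matrices
#'   (\code{start,end}).
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gene_id <- as.character(genes$ID)
  ## map CDS to genes: Parent may be an mRNA whose Parent is the gene
  mrna <- gff[gff$type %in% c("mRNA", "transcript")]
  mrna_parent <- setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], character(1)),
    as.character(mrna$ID))
  cds <- gff[gff$type == "CDS"]
  cds_gene <- vapply(cds$Parent, function(p) {
    p <- as.character(p)[1]
    if (!is.null(mrna_parent) && p %in% names(mrna_parent))
      mrna_parent[[p]] else p
  }, character(1))
  df <- data.frame(gene_id = gene_id,
                   chrom = as.character(seqnames(genes)),
                   start = start(genes), end = end(genes),
                   strand = as.character(strand(genes)),
                   stringsAsFactors = FALSE)
  df$cds <- lapply(gene_id, function(g) {
    sel <- which(cds_gene == g)
    if (!length(sel)) return(matrix(integer(), ncol = 2,
                                    dimnames = list(NULL,
                                                    c("start", "end"))))
    cbind(start = start(cds)[sel], end = end(cds)[sel])
  })
  df
}

#' Simulate gene models over a genome and write them as GFF3
#'
#' Plants non-overlapping genes (each with 1-3 CDS exons) uniformly over
#' the genome; a lightweight annotation for exercising the SV-gene
#' overlap machinery on synthetic data.
#'
#' @param genome \code{DNAStringSet}.
#' @param n_genes number of genes.
#' @param seed seed.
#' @param gene_length mean gene length (bp).
#' @param path optional GFF3 output path.
#' @return gene-model data.frame (as \code{\link{readGeneModels}}).
#' @export
simulateGeneModels <- function(genome, n_genes = 50L, seed = 1L,
                               gene_length = 3000L, path = NULL) {
  set.seed(deriveSeed(seed, "genome") + 13L)
  lens <- nchar(as.character(genome))
  rows <- list()
  placed <- list()
  tries <- 0L
  while (length(rows) < n_genes && tries < n_genes * 200L) {
    tries <- tries + 1L
    ch <- sample(names(genome), 1L, prob = lens / sum(lens))
    L <- max(300L, as.integer(round(rnorm(1, gene_length,
                                          gene_length / 4))))
    s <- floor(runif(1, 2500, lens[[match(ch, names(genome))]] - L - 2500))
    e <- s + L - 1L
    ok <- TRUE
    for (p in placed)
      if (p$chrom == ch && s <= p$end + 2500 && e >= p$start - 2500) {
        ok <- FALSE; break
      }
    if (!ok) next
    n_ex <- sample(1:3, 1L)
    bnd <- sort(sample(seq(s + 50L, e - 50L), 2L * n_ex))
    cds <- cbind(start = bnd[seq(1, 2 * n_ex, 2)],
                 end = bnd[seq(2, 2 * n_ex, 2)])
    g <- list(chrom = ch, start = s, end = e,
              strand = sample(c("+", "-"), 1L), cds = cds)
    placed[[length(placed) + 1L]] <- g
    rows[[length(rows) + 1L]] <- g
  }
  df <- data.frame(
    gene_id = sprintf("gene_%04d", seq_along(rows)),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  df$cds <- lapply(rows, `[[`, "cds")
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  df$gene_id <- sprintf("gene_%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  if (!is.null(path)) writeGeneModels(df, path)
  df
}

#' @describeIn simulateGeneModels write a gene-model data.frame as GFF3.
#' @param genes gene-model data.frame.
#' @export
writeGeneModels <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines,
               sprintf("%s\tsvdiverge\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id),
               sprintf("%s\tsvdiverge\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id,
                       g$gene_id))
    cds <- genes$cds[[i]]
    for (k in seq_len(nrow(cds)))
      lines <- c(lines,
                 sprintf("%s\tsvdiverge\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s.t1",
                         g$chrom, cds[k, "start"], cds[k, "end"],
                         g$strand, g$gene_id, k, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

## promoter window upstream of the transcription start on the coding strand
.promoterRanges <- function(genes, promoter_length) {
  s <- ifelse(genes$strand == "+",
              pmax(1L, genes$start - promoter_length), genes$end + 1L)
  e <- ifelse(genes$strand == "+", genes$start - 1L,
              genes$end + promoter_length)
  GRanges(genes$chrom, IRanges(pmin(s, e), pmax(s, e)))
}

#' Classify SV overlap with gene models
#'
#' Any-overlap rule with precedence CDS > intron/UTR > promoter: an SV
#' intersecting any CDS exon of a gene is \code{"CDS"}; else within the
#' annotated gene span it is \code{"intron/UTR"}; else within the
#' \code{promoter_length}-bp window upstream of the transcription start
#' (strand-aware) it is \code{"promoter"}. A gene is affected when any SV
#' hits its body or promoter.
#'
#' @param svs an \code{SVSet}.
#' @param genes gene models (\code{\link{readGeneModels}} /
#'   \code{\link{simulateGeneModels}}).
#' @param promoter_length promoter window in bp (default 2000).
#' @return list with \code{assignments} (\code{sv_id,gene_id,category})
#'   and \code{genes} (per-gene \code{affected} flag).
#' @export
classifySvGeneOverlap <- function(svs, genes, promoter_length = 2000L) {
  sv_chr <- unique(as.character(seqnames(svRanges(svs))))
  ## a fully disjoint chromosome universe signals mismatched inputs
  if (length(sv_chr) && !length(intersect(sv_chr, unique(genes$chrom))))
    stop("SVs and gene models share no chromosome: mismatched inputs?")
  gr_sv <- svRanges(svs)
  gr_gene <- GRanges(genes$chrom, IRanges(genes$start, genes$end))
  gr_prom <- .promoterRanges(genes, promoter_length)
  rows <- list()
  ov_gene <- GenomicRanges::findOverlaps(gr_sv, gr_gene)
  for (k in seq_along(ov_gene)) {
    i <- S4Vectors::queryHits(ov_gene)[k]
    j <- S4Vectors::subjectHits(ov_gene)[k]
    cds <- genes$cds[[j]]
    in_cds <- nrow(cds) && any(start(gr_sv)[i] <= cds[, "end"] &
                               end(gr_sv)[i] >= cds[, "start"])
    rows[[length(rows) + 1L]] <-
      data.frame(sv_id = svId(svs)[i], gene_id = genes$gene_id[j],
                 category = if (in_cds) "CDS" else "intron/UTR",
                 stringsAsFactors = FALSE)
  }
  ov_prom <- GenomicRanges::findOverlaps(gr_sv, gr_prom)
  body_pairs <- if (length(rows))
    paste(vapply(rows, `[[`, character(1), "sv_id"),
          vapply(rows, `[[`, character(1), "gene_id")) else character()
  for (k in seq_along(ov_prom)) {
    i <- S4Vectors::queryHits(ov_prom)[k]
    j <- S4Vectors::subjectHits(ov_prom)[k]
    if (paste(svId(svs)[i], genes$gene_id[j]) %in% body_pairs) next
    rows[[length(rows) + 1L]] <-
      data.frame(sv_id = svId(svs)[i], gene_id = genes$gene_id[j],
                 category = "promoter", stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sv_id = character(), gene_id = character(),
               category = character(), stringsAsFactors = FALSE)
  gene_tab <- data.frame(gene_id = genes$gene_id,
                         affected = genes$gene_id %in%
                           assignments$gene_id,
                         stringsAsFactors = FALSE)
  list(assignments = assignments, genes = gene_tab)
}

#' Fractions of the genome, gene regions and CDS covered by SVs
#'
#' Coverage is computed on the union of SV anchor intervals (overlapping
#' SVs are not double-counted).
#'
#' @param svs an \code{SVSet}.
#' @param genome the anchor genome (\code{DNAStringSet}).
#' @param genes optional gene models; gene/CDS fractions are NA without
#'   them.
#' @return named numeric vector \code{c(genome_fraction, gene_fraction,
#'   cds_fraction)}.
#' @export
svGenomeFractions <- function(svs, genome, genes = NULL) {
  sv_u <- GenomicRanges::reduce(svRanges(svs))
  glen <- sum(nchar(as.character(genome)))
  genome_fraction <- sum(width(sv_u)) / glen
  gene_fraction <- NA_real_
  cds_fraction <- NA_real_
  if (!is.null(genes) && nrow(genes)) {
    gene_u <- GenomicRanges::reduce(GRanges(genes$chrom,
                                            IRanges(genes$start,
                                                    genes$end)))
    gene_fraction <- sum(width(GenomicRanges::intersect(sv_u, gene_u))) /
      sum(width(gene_u))
    cds_all <- do.call(rbind, genes$cds)
    if (!is.null(cds_all) && nrow(cds_all)) {
      cds_chrom <- rep(genes$chrom,
                       vapply(genes$cds, nrow, integer(1)))
      cds_u <- GenomicRanges::reduce(GRanges(cds_chrom,
                                             IRanges(cds_all[, "start"],
                                                     cds_all[, "end"])))
      cds_fraction <- sum(width(GenomicRanges::intersect(sv_u, cds_u))) /
        sum(width(cds_u))
    }
  }
  c(genome_fraction = genome_fraction, gene_fraction = gene_fraction,
    cds_fraction = cds_fraction)
}

#' Insertion-time estimate for an LTR retrotransposon
#'
#' \code{T = S / (2 * mu)}: the divergence \code{S} between the element's
#' two long terminal repeats accumulates at twice the per-site annual
#' mutation rate \code{mu} after insertion.
#'
#' @param S substitution rate (substitutions per site) between the two
#'   LTRs; may be a vector.
#' @param mu mutation rate per site per year (default 1.5e-8).
#' @return insertion time(s) in years.
#' @examples
#' ltrInsertionTime(0.03)   # 1,000,000 years at the default rate
#' @export
ltrInsertionTime <- function(S, mu = 1.5e-8) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(S < 0)) stop("S must be >= 0")
  S / (2 * mu)
}
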
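#' Thin SVs to one per non-overlapping genomic window
#'
#' Divides each chromosome into \code{window}-bp non-overlapping windows
#' and keeps one randomly selected SV per window that contains any.
#'
#' @param svs an \code{SVSet}.
#' @param window window size in bp (default 25000).
#' @param seed seed for the random pick (fixed seed gives identical
#'   output).
#' @return The thinned \code{SVSet} (a subset of the input).
#' @export
thinByWindows <- function(svs, window = 25000L, seed = 1L) {
  if (window <= 0) stop("window must be > 0")
  if (!length(svs)) return(svs)
  gr <- svRanges(svs)
  key <- paste(as.character(seqnames(gr)),
               (start(gr) - 1L) %/% as.integer(window))
  set.seed(seed)
  keep <- integer(0)
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    keep <- c(keep, if (length(idx) == 1L) idx else
      idx[sample.int(length(idx), 1L)])
  }
  svs[sort(keep)]
}

.checkLabels <- function(m, labels) {
  if (is.data.frame(labels))
    labels <- setNames(as.character(labels[[2]]),
                       as.character(labels[[1]]))
  missing_acc <- setdiff(rownames(m), names(labels))
  if (length(missing_acc))
    stop("unlabeled accession(s): ", paste(missing_acc, collapse = ", "))
  labels[rownames(m)]
}

#' Genotype-class composition per accession and per group
#'
#' Fractions of homozygous-A, homozygous-B and heterozygous calls among
#' each accession's determined genotypes (undetermined reported
#' separately), with group means over accessions.
#'
#' @param m genotype matrix (accessions x SVs over \code{A/B/H/U}).
#' @param labels group labels: named character vector
#'   (accession -> group) or a two-column data.frame.
#' @return list with \code{per_accession} (accession, group, frac_A,
#'   frac_B, frac_H over determined calls, frac_U overall, n_determined;
#'   fractions are NA and \code{flagged} is TRUE for all-undetermined
#'   accessions) and \code{per_group} (group means).
#' @export
genotypeComposition <- function(m, labels) {
  lab <- .checkLabels(m, labels)
  per <- lapply(rownames(m), function(a) {
    g <- m[a, ]
    det <- g != "U"
    n <- sum(det)
    data.frame(accession = a, group = unname(lab[[a]]),
               frac_A = if (n) mean(g[det] == "A") else NA_real_,
               frac_B = if (n) mean(g[det] == "B") else NA_real_,
               frac_H = if (n) mean(g[det] == "H") else NA_real_,
               frac_U = mean(!det), n_determined = n,
               flagged = n == 0L, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  grp <- lapply(split(per, per$group), function(d) {
    data.frame(group = d$group[1], n_accessions = nrow(d),
               frac_A = mean(d$frac_A, na.rm = TRUE),
               frac_B = mean(d$frac_B, na.rm = TRUE),
               frac_H = mean(d$frac_H, na.rm = TRUE),
               frac_U = mean(d$frac_U), stringsAsFactors = FALSE)
  })
  list(per_accession = per, per_group = do.call(rbind, grp))
}

#' Per-group A-allele frequencies with a determinedness filter
#'
#' Heterozygotes count as one copy of each allele:
#' \code{freq_A = (2 n_A + n_H) / (2 (n_A + n_B + n_H))}. SVs whose
#' genotype is determined in fewer than \code{min_determined} of the
#' accessions of either group are excluded.
#'
#' @param m genotype matrix.
#' @param labels group labels (see \code{\link{genotypeComposition}}).
#' @param group1,group2 the two group names to compare.
#' @param min_determined minimum determined fraction per group
#'   (default 0.5).
#' @return data.frame with per-SV genotype counts per group
#'   (\code{n1_A,n1_B,n1_H,n1_U,n2_*}), \code{freq1_A}, \code{freq2_A}.
#' @export
alleleFrequencies <- function(m, labels, group1, group2,
                              min_determined = 0.5) {
  lab <- .checkLabels(m, labels)
  acc1 <- rownames(m)[lab == group1]
  acc2 <- rownames(m)[lab == group2]
  if (!length(acc1)) stop("group has zero accessions: ", group1)
  if (!length(acc2)) stop("group has zero accessions: ", group2)
  cnt <- function(sub, g) colSums(sub == g)
  s1 <- m[acc1, , drop = FALSE]; s2 <- m[acc2, , drop = FALSE]
  df <- data.frame(sv_id = colnames(m),
                   n1_A = cnt(s1, "A"), n1_B = cnt(s1, "B"),
                   n1_H = cnt(s1, "H"), n1_U = cnt(s1, "U"),
                   n2_A = cnt(s2, "A"), n2_B = cnt(s2, "B"),
                   n2_H = cnt(s2, "H"), n2_U = cnt(s2, "U"),
                   stringsAsFactors = FALSE, row.names = NULL)
  det1 <- (df$n1_A + df$n1_B + df$n1_H) / length(acc1)
  det2 <- (df$n2_A + df$n2_B + df$n2_H) / length(acc2)
  df <- df[det1 >= min_determined & det2 >= min_determined, ,
           drop = FALSE]
  df$freq1_A <- (2 * df$n1_A + df$n1_H) /
    pmax(1, 2 * (df$n1_A + df$n1_B + df$n1_H))
  df$freq2_A <- (2 * df$n2_A + df$n2_H) /
    pmax(1, 2 * (df$n2_A + df$n2_B + df$n2_H))
  df
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by the probability-ordering rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (relative tie tolerance
#' 1e-7, the standard convention).
#'
#' @param tab 2x2 matrix of non-negative integer counts, or the four
#'   counts \code{a,b,c,d} (row-wise).
#' @param a,b,c,d alternative scalar interface.
#' @return the two-sided p value.
#' @examples
#' fisherExactP(matrix(c(5, 5, 5, 5), 2))     # 1
#' fisherExactP(a = 9, b = 1, c = 2, d = 8)
#' @export
fisherExactP <- function(tab = NULL, a = NULL, b = NULL, c = NULL,
                         d = NULL) {
  if (is.null(tab)) tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- cc + dd        # row 2 total
  k <- a + cc         # column 1 total
  p <- .fisherPvec(m, n, k)
  p[[a - max(0L, k - n) + 1L]]
}

## Two-sided p for every feasible a at margins (m, n, k), in order of
## a = max(0, k-n), ..., min(k, m). Degenerate margins admit one table.
.fisherPvec <- function(m, n, k) {
  if (m + n == 0L || k <= 0L || k >= m + n || m == 0L || n == 0L)
    return(rep(1, max(1L, min(k, m) - max(0L, k - n) + 1L)))
  x <- max(0L, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  o <- order(pr)
  cs <- cumsum(pr[o])
  ## p(a) = sum of probabilities <= pr(a) * (1 + 1e-7)
  idx <- findInterval(pr * (1 + 1e-7), pr[o])
  pmin(1, cs[idx])
}

#' Scan for SVs with differentiated allele frequencies between two groups
#'
#' For every SV passing the determinedness filter, allele counts
#' (heterozygotes contributing one copy of each allele) are compared
#' between the groups with Fisher's exact test; raw p values are
#' Bonferroni-corrected over the number of SVs tested. An SV is selected
#' when the adjusted q is below \code{alpha} and the allele-frequency fold
#' change is at least \code{min_fold} (the denominator frequency floored
#' at \code{1/(2 * group size)} so a zero frequency cannot divide).
#'
#' @param m genotype matrix.
#' @param labels group labels.
#' @param group1,group2 groups to compare.
#' @param alpha adjusted-p threshold (default 0.001).
#' @param min_fold minimum fold change (default 2).
#' @param min_determined determinedness filter (default 0.5).
#' @return data.frame: allele-frequency columns of
#'   \code{\link{alleleFrequencies}} plus \code{fisher_p}, \code{q},
#'   \code{fold_change}, \code{direction} (\code{"group1"} or
#'   \code{"group2"}, whichever has the higher A frequency) and
#'   \code{selected}.
#' @export
differentiationScan <- function(m, labels, group1, group2, alpha = 0.001,
                                min_fold = 2, min_determined = 0.5) {
  af <- alleleFrequencies(m, labels, group1, group2, min_determined)
  if (!nrow(af)) {
    af$fisher_p <- numeric(0); af$q <- numeric(0)
    af$fold_change <- numeric(0); af$direction <- character(0)
    af$selected <- logical(0)
    return(af)
  }
  lab <- .checkLabels(m, labels)
  n1 <- sum(lab == group1); n2 <- sum(lab == group2)
  af$fisher_p <- vapply(seq_len(nrow(af)), function(i) {
    a1 <- 2 * af$n1_A[i] + af$n1_H[i]
    b1 <- 2 * af$n1_B[i] + af$n1_H[i]
    a2 <- 2 * af$n2_A[i] + af$n2_H[i]
    b2 <- 2 * af$n2_B[i] + af$n2_H[i]
    fisherExactP(matrix(c(a1, b1, a2, b2), 2, 2, byrow = TRUE))
  }, numeric(1))
  af$q <- p.adjust(af$fisher_p, method = "bonferroni")
  eps <- 1 / (2 * min(n1, n2))
  hi <- pmax(af$freq1_A, af$freq2_A)
  lo <- pmin(af$freq1_A, af$freq2_A)
  af$fold_change <- hi / pmax(lo, eps)
  af$direction <- ifelse(af$freq1_A >= af$freq2_A, "group1", "group2")
  af$selected <- af$q < alpha & af$fold_change >= min_fold
  af
}

#' Allele-sharing distance, genotype PCA and a neighbor-joining tree
#'
#' Genotypes are encoded A=0, H=1, B=2 (U missing). The distance between
#' two accessions is the mean absolute allele-dosage difference over
#' pairwise-complete SVs, divided by 2 (0 = identical, 1 = opposite
#' homozygotes throughout). PCA runs on the column-mean-imputed, centered
#' dosage matrix; the tree is neighbor-joining on the distance matrix.
#' Accessions without a single determined call are excluded with a
#' message.
#'
#' @param m genotype matrix.
#' @return list with \code{dist} (symmetric matrix), \code{pca}
#'   (\code{prcomp} object), \code{tree} (\code{ape phylo}),
#'   \code{excluded} (accession ids dropped).
#' @export
distanceAndPca <- function(m) {
  num <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  num[m == "A"] <- 0; num[m == "H"] <- 1; num[m == "B"] <- 2
  keep <- rowSums(!is.na(num)) > 0L
  excluded <- rownames(m)[!keep]
  if (length(excluded))
    message("excluding accession(s) with no determined call: ",
            paste(excluded, collapse = ", "))
  num <- num[keep, , drop = FALSE]
  n <- nrow(num)
  d <- matrix(0, n, n, dimnames = list(rownames(num), rownames(num)))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    ok <- !is.na(num[i, ]) & !is.na(num[j, ])
    d[i, j] <- d[j, i] <-
      if (any(ok)) mean(abs(num[i, ok] - num[j, ok])) / 2 else NA_real_
  }
  imp <- num
  cm <- colMeans(num, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  for (j in seq_len(ncol(imp)))
    imp[is.na(imp[, j]), j] <- cm[j]
  pca <- prcomp(imp, center = TRUE, scale. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  list(dist = d, pca = pca, tree = tree, excluded = excluded)
}

#' Simulate a two-group cohort genotype matrix
#'
#' Draws Hardy-Weinberg genotypes from per-group A-allele frequencies:
#' \code{n_contrast} SVs with frequencies \code{f1} vs \code{f2} between
#' the groups, plus \code{n_null} SVs with a shared frequency drawn
#' uniformly from [0.2, 0.8]. Optional uniform missingness.
#'
#' @param n1,n2 accessions per group.
#' @param n_contrast,n_null SV counts.
#' @param f1,f2 contrasted A-allele frequencies (defaults 0.9 / 0.1).
#' @param missing_rate fraction of calls set undetermined (default 0).
#' @param seed seed.
#' @return list with \code{matrix}, \code{labels} (named vector over
#'   \code{"group1"/"group2"}), \code{contrast_ids}.
#' @export
simulateCohortMatrix <- function(n1 = 50L, n2 = 50L, n_contrast = 50L,
                                 n_null = 450L, f1 = 0.9, f2 = 0.1,
                                 missing_rate = 0, seed = 1L) {
  set.seed(deriveSeed(seed, "cohort"))
  n_sv <- n_contrast + n_null
  ids <- sprintf("sv_%05d", seq_len(n_sv))
  f_null <- runif(n_null, 0.2, 0.8)
  fmat <- rbind(
    matrix(rep(c(f1, f2), each = n_contrast), ncol = 2)[, , drop = FALSE],
    cbind(f_null, f_null))
  draw <- function(p, n) {
    g <- matrix(runif(n * nrow(fmat)), nrow = n, byrow = TRUE)
    out <- matrix("B", n, nrow(fmat))
    pa <- matrix(rep(p^2, each = n), n)
    ph <- matrix(rep(2 * p * (1 - p), each = n), n)
    out[g < pa + ph] <- "H"
    out[g < pa] <- "A"
    out
  }
  m <- rbind(draw(fmat[, 1], n1), draw(fmat[, 2], n2))
  rownames(m) <- c(sprintf("g1_%03d", seq_len(n1)),
                   sprintf("g2_%03d", seq_len(n2)))
  colnames(m) <- ids
  if (missing_rate > 0)
    m[matrix(runif(length(m)) < missing_rate, nrow(m))] <- "U"
  labels <- setNames(rep(c("group1", "group2"), c(n1, n2)), rownames(m))
  list(matrix = m, labels = labels,
       contrast_ids = ids[seq_len(n_contrast)])
}
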
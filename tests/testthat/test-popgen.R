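svAt <- function(pos, chrom = "chr1") {
  n <- length(pos)
  SVSet(chrom = rep(chrom, n), start = pos, end = pos + 49L,
        sv_type = rep("deletion", n), len_a = rep(50L, n),
        len_b = rep(0L, n), sv_id = sprintf("sv%03d", seq_len(n)))
}

test_that("window thinning keeps one SV per 25-kb window", {
  expect_length(thinByWindows(svAt(c(1000, 5000, 20000)), seed = 2), 1)
  expect_length(thinByWindows(svAt(c(10000, 30000)), seed = 2), 2)
  expect_length(thinByWindows(SVSet(), seed = 2), 0)
  expect_error(thinByWindows(svAt(1000), window = 0), "window")
})

test_that("thinning is deterministic, a subset, and window-counting", {
  set.seed(101)
  pos <- sort(sample(seq(1, 5e5), 200))
  svs <- svAt(pos)
  t1 <- thinByWindows(svs, seed = 7)
  t2 <- thinByWindows(svs, seed = 7)
  expect_identical(svId(t1), svId(t2))
  expect_true(all(svId(t1) %in% svId(svs)))
  n_windows <- length(unique((pos - 1) %/% 25000))
  expect_length(t1, n_windows)
})

test_that("genotype composition fractions are computed over determined calls", {
  m <- matrix(c(rep("A", 8), "B", "H", rep("U", 10)), nrow = 1,
              dimnames = list("acc1", sprintf("s%02d", 1:20)))
  comp <- genotypeComposition(m, c(acc1 = "cauliflower"))
  expect_equal(comp$per_accession$frac_A, 0.8)
  expect_equal(comp$per_accession$frac_U, 0.5)
  ## all-undetermined accession is flagged with NA fractions
  mu <- matrix("U", 1, 5, dimnames = list("acc1", paste0("s", 1:5)))
  compu <- genotypeComposition(mu, c(acc1 = "cabbage"))
  expect_true(compu$per_accession$flagged)
  expect_true(is.na(compu$per_accession$frac_A))
  expect_error(genotypeComposition(m, c(other = "x")), "unlabeled")
})

test_that("a 90:10 cohort has a group mean A-fraction near 0.9", {
  sim <- simulateCohortMatrix(n1 = 40, n2 = 40, n_contrast = 0,
                              n_null = 200, seed = 5)
  m <- sim$matrix
  set.seed(6)
  m[seq_len(40), ] <- ifelse(matrix(runif(40 * 200) < 0.9, 40), "A", "B")
  comp <- genotypeComposition(m, sim$labels)
  g1 <- comp$per_group[comp$per_group$group == "group1", ]
  expect_lt(abs(g1$frac_A - 0.9), 0.03)
})

test_that("allele frequencies count heterozygotes as one copy each", {
  m <- rbind(
    matrix(rep(c("A", "A", "A", "A", "A", "A", "A", "A", "A", "B"), 2),
           nrow = 10,
           dimnames = list(paste0("x", 1:10), c("s1", "s2"))),
    matrix(rep(c("A", "A", "A", "A", "B", "B", "B", "B", "H", "H"), 2),
           nrow = 10,
           dimnames = list(paste0("y", 1:10), c("s1", "s2"))))
  lab <- setNames(rep(c("g1", "g2"), each = 10), rownames(m))
  af <- alleleFrequencies(m, lab, "g1", "g2")
  expect_equal(af$freq1_A, c(0.9, 0.9))
  expect_equal(af$freq2_A, c(0.5, 0.5))
})

test_that("SVs under 50% determined in either group are excluded", {
  m <- matrix("A", 10, 2, dimnames = list(paste0("a", 1:10),
                                          c("keep", "drop")))
  m[1:6, "drop"] <- "U"        # 40% determined in group 1
  lab <- setNames(rep(c("g1", "g2"), each = 5), rownames(m))
  af <- alleleFrequencies(m, lab, "g1", "g2")
  expect_identical(af$sv_id, "keep")
  expect_error(alleleFrequencies(m, lab, "g1", "nosuch"), "zero")
})

test_that("Fisher p matches enumeration, fisher.test, and conventions", {
  expect_equal(fisherExactP(matrix(5, 2, 2)), 1)
  expect_equal(fisherExactP(a = 1, b = 0, c = 0, d = 1), 1)
  expect_equal(fisherExactP(a = 0, b = 0, c = 0, d = 0), 1)
  set.seed(103)
  for (i in 1:200) {
    t4 <- rpois(4, 7)
    p <- fisherExactP(a = t4[1], b = t4[2], c = t4[3], d = t4[4])
    expect_lt(abs(p - bruteFisherP(t4[1], t4[2], t4[3], t4[4])), 1e-12)
    expect_lt(abs(p - stats::fisher.test(
      matrix(t4, 2, byrow = TRUE))$p.value), 1e-9)
  }
})

test_that("differentiation selection needs both q < 0.001 and fold >= 2", {
  ## strong contrast: selected, direction group1
  m1 <- rbind(matrix("A", 50, 1), matrix("B", 50, 1))
  dimnames(m1) <- list(c(sprintf("c%02d", 1:50), sprintf("k%02d", 1:50)),
                       "sv1")
  lab <- setNames(rep(c("g1", "g2"), each = 50), rownames(m1))
  sc <- differentiationScan(m1, lab, "g1", "g2")
  expect_true(sc$selected)
  expect_identical(sc$direction, "group1")
  ## fold 1.5 (0.6 vs 0.4) is never selected, whatever the q
  m2 <- rbind(
    matrix(rep(c(rep("A", 30), rep("B", 20)), 40), ncol = 40,
           dimnames = list(sprintf("c%02d", 1:50), NULL)),
    matrix(rep(c(rep("A", 20), rep("B", 30)), 40), ncol = 40,
           dimnames = list(sprintf("k%02d", 1:50), NULL)))
  colnames(m2) <- sprintf("s%02d", 1:40)
  sc2 <- differentiationScan(m2, lab, "g1", "g2")
  expect_true(all(abs(sc2$fold_change - 1.5) < 1e-9))
  expect_false(any(sc2$selected))
  ## identical groups: nothing selected
  m3 <- rbind(m2[1:50, ], m2[1:50, ])
  rownames(m3) <- rownames(m2)
  expect_false(any(differentiationScan(m3, lab, "g1", "g2")$selected))
})

test_that("Bonferroni q is monotone, capped, and alpha-monotone", {
  sim <- simulateCohortMatrix(n1 = 30, n2 = 30, n_contrast = 10,
                              n_null = 90, seed = 11)
  sc <- differentiationScan(sim$matrix, sim$labels, "group1", "group2")
  expect_true(all(sc$q <= 1))
  expect_true(all(sc$q >= sc$fisher_p))
  o <- order(sc$fisher_p)
  expect_true(all(diff(sc$q[o]) >= 0))
  n_strict <- sum(sc$q < 1e-6 & sc$fold_change >= 2)
  expect_lte(n_strict, sum(sc$selected))
})

test_that("distance, PCA and NJ tree behave on structured cohorts", {
  sim <- simulateCohortMatrix(n1 = 15, n2 = 15, n_contrast = 60,
                              n_null = 40, f1 = 0.95, f2 = 0.05,
                              seed = 13)
  m <- sim$matrix
  ## duplicated accession: distance zero, identical PC coordinates
  m[2, ] <- m[1, ]
  dp <- distanceAndPca(m)
  expect_equal(dp$dist[1, 2], 0)
  expect_equal(dp$pca$x[1, ], dp$pca$x[2, ])
  expect_true(isSymmetric(dp$dist))
  expect_true(all(diag(dp$dist) == 0))
  ## PC1 separates the groups
  pc1 <- dp$pca$x[, 1]
  g <- sim$labels[rownames(dp$pca$x)]
  expect_true(max(tapply(pc1, g, min)) > min(tapply(pc1, g, max)) ||
                abs(mean(pc1[g == "group1"]) -
                      mean(pc1[g == "group2"])) >
                2 * (sd(pc1[g == "group1"]) + sd(pc1[g == "group2"])))
  ## permutation invariance of the eigenvalues
  perm <- sample(nrow(m))
  dp2 <- distanceAndPca(m[perm, ])
  expect_equal(dp2$pca$sdev, dp$pca$sdev, tolerance = 1e-8)
  ## NJ tree covers all accessions
  expect_setequal(dp$tree$tip.label, rownames(m))
  ## an all-U accession is excluded with a message
  m[3, ] <- "U"
  expect_message(dp3 <- distanceAndPca(m), "excluding")
  expect_false(rownames(m)[3] %in% rownames(dp3$dist))
})
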
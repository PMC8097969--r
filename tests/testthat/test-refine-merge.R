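complexSv <- function(start, end, type = "tandem_expansion",
                      id = "cx1") {
  len_a <- end - start + 1L
  SVSet(chrom = "chr1", start = start, end = end, sv_type = type,
        len_a = len_a, len_b = len_a + 120L, sv_id = id,
        source = "assembly", precise = FALSE)
}

readIns <- function(pos, len, id = "rc1") {
  SVSet(chrom = "chr1", start = pos, end = pos, sv_type = "insertion",
        len_a = 0L, len_b = len, sv_id = id, source = "reads")
}

test_that("a complex SV containing one read call becomes that indel", {
  cx <- complexSv(5000, 5400)
  rc <- readIns(5100, 120)
  out <- refineComplexSvs(cx, rc)
  expect_length(out, 1)
  expect_identical(svType(out), "insertion")
  expect_identical(svSource(out), "merged")
  expect_true(all(isPrecise(out)))
  expect_equal(GenomicRanges::start(svRanges(out)), 5100)
})

test_that("complex SVs without read support pass through unchanged", {
  cx <- complexSv(5000, 5400)
  rc <- readIns(20000, 120)
  out <- refineComplexSvs(cx, rc)
  expect_identical(svdiverge:::.svsetAsFrame(out)[
    , c("sv_id", "sv_type", "precise")],
    data.frame(sv_id = "cx1", sv_type = "tandem_expansion",
               precise = FALSE))
})

test_that("a complex SV with two read indels is converted into both", {
  cx <- complexSv(5000, 5800)
  rc <- mergeCallsets(readIns(5100, 60, "rc1"), readIns(5600, 60, "rc2"),
                      min_reciprocal = 0.99)
  out <- refineComplexSvs(cx, rc)
  expect_length(out, 2)
  expect_true(all(svType(out) == "insertion"))
  expect_true(all(svSource(out) == "merged"))
})

test_that("50% reciprocal overlap merges, below keeps both", {
  ## 0-based [1000,2000) and [1400,2400): reciprocal 0.6 -> one record
  d1 <- svDeletion(start = 1001, len = 1000, id = "a1")
  d2 <- svDeletion(start = 1401, len = 1000, id = "b1")
  m <- mergeCallsets(d1, d2)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(svRanges(m)), 1001)
  expect_identical(svSource(m), "merged")
  ## [1000,2000) and [1800,2800): reciprocal 0.2 -> both kept
  d3 <- svDeletion(start = 1801, len = 1000, id = "b2")
  m2 <- mergeCallsets(d1, d3)
  expect_length(m2, 2)
})

test_that("merging compares same-type records only", {
  del <- svDeletion(start = 1001, len = 1000, id = "d")
  sub <- SVSet(chrom = "chr1", start = 1001, end = 2000,
               sv_type = "substitution", len_a = 1000L, len_b = 900L,
               sv_id = "s")
  expect_length(mergeCallsets(del, sub), 2)
})

test_that("merging a set with itself returns the set unchanged", {
  set.seed(61)
  starts <- sort(sample(seq(1000, 90000, by = 3000), 10))
  svs <- SVSet(chrom = rep("chr1", 10), start = starts,
               end = starts + 199L, sv_type = rep("deletion", 10),
               len_a = rep(200L, 10), len_b = rep(0L, 10))
  m <- mergeCallsets(svs, svs)
  expect_equal(svdiverge:::.svsetAsFrame(m),
               svdiverge:::.svsetAsFrame(svs))
  ## and merging is idempotent
  expect_equal(svdiverge:::.svsetAsFrame(mergeCallsets(m, m)),
               svdiverge:::.svsetAsFrame(m))
})

test_that("merge result is invariant to input order", {
  d1 <- svDeletion(start = 1001, len = 1000, id = "a1")
  d2 <- svDeletion(start = 1401, len = 1000, id = "b1",
                   source = "reads")
  f12 <- svdiverge:::.svsetAsFrame(mergeCallsets(d1, d2))
  f21 <- svdiverge:::.svsetAsFrame(mergeCallsets(d2, d1))
  expect_equal(f12, f21)
  ## assembly-derived breakpoints win the tie-break
  expect_equal(f12$start, 1001)
})

test_that("point insertions merge on allele-length padded intervals", {
  i1 <- svInsertion(pos = 5000, len = 300, id = "i1")
  i2 <- svInsertion(pos = 5100, len = 300, id = "i2")   # overlap 200/300
  expect_length(mergeCallsets(i1, i2), 1)
  i3 <- svInsertion(pos = 5290, len = 300, id = "i3")   # overlap 10/300
  expect_length(mergeCallsets(i1, i3), 2)
})

test_that("no same-type pair in the output meets the merge criterion", {
  set.seed(62)
  mk <- function(n, src, pre) {
    starts <- sample(seq(1000, 50000), n)
    SVSet(chrom = rep("chr1", n), start = starts, end = starts + 499L,
          sv_type = rep("deletion", n), len_a = rep(500L, n),
          len_b = rep(0L, n), sv_id = paste0(pre, seq_len(n)),
          source = src)
  }
  m <- mergeCallsets(mk(25, "assembly", "a"), mk(25, "reads", "r"))
  df <- svdiverge:::.svsetAsFrame(m)
  for (i in seq_len(nrow(df))) for (j in seq_len(i - 1L)) {
    ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]) + 1L
    if (ov <= 0) next
    ro <- ov / pmax(df$end[i] - df$start[i] + 1L,
                    df$end[j] - df$start[j] + 1L)
    expect_lt(ro, 0.5)
  }
})
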
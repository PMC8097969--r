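rndRead <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateAt <- function(s, pos) {
  ch <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  s
}

test_that("150-bp pairs identical over the first 100 bp are duplicates", {
  r1 <- rndRead(150, 81); r2 <- rndRead(150, 82)
  pair2_r1 <- mutateAt(r1, 120)       # differs beyond the 100-bp prefix
  dd <- deduplicateReadPairs(Biostrings::DNAStringSet(c(r1, pair2_r1)),
                             Biostrings::DNAStringSet(c(r2, r2)))
  expect_equal(dd$n_duplicates, 1L)
  expect_identical(as.character(dd$reads1[[1]]), r1)  # first kept
})

test_that("a difference at position 95 keeps both 150-bp pairs", {
  r1 <- rndRead(150, 83); r2 <- rndRead(150, 84)
  dd <- deduplicateReadPairs(Biostrings::DNAStringSet(c(r1, mutateAt(r1, 95))),
                             Biostrings::DNAStringSet(c(r2, r2)))
  expect_equal(dd$n_duplicates, 0L)
})

test_that("100-bp reads use a 90-bp prefix", {
  r1 <- rndRead(100, 85); r2 <- rndRead(100, 86)
  dd95 <- deduplicateReadPairs(
    Biostrings::DNAStringSet(c(r1, mutateAt(r1, 95))),
    Biostrings::DNAStringSet(c(r2, r2)))
  expect_equal(dd95$n_duplicates, 1L)   # beyond 90-bp prefix: duplicate
  dd85 <- deduplicateReadPairs(
    Biostrings::DNAStringSet(c(r1, mutateAt(r1, 85))),
    Biostrings::DNAStringSet(c(r2, r2)))
  expect_equal(dd85$n_duplicates, 0L)
})

test_that("deduplication handles empty input and is idempotent", {
  e <- Biostrings::DNAStringSet()
  dd <- deduplicateReadPairs(e, e)
  expect_equal(dd$n_duplicates, 0L)
  expect_length(dd$reads1, 0)
  set.seed(87)
  r1 <- Biostrings::DNAStringSet(vapply(1:20, function(i)
    rndRead(150, 870 + i %% 7), character(1)))
  r2 <- Biostrings::DNAStringSet(vapply(1:20, function(i)
    rndRead(150, 880 + i %% 7), character(1)))
  d1 <- deduplicateReadPairs(r1, r2)
  expect_lte(length(d1$reads1), length(r1))
  d2 <- deduplicateReadPairs(d1$reads1, d1$reads2)
  expect_equal(d2$n_duplicates, 0L)
  expect_identical(as.character(d1$reads1), as.character(d2$reads1))
})

test_that("mixed read lengths in one stream are rejected", {
  expect_error(deduplicateReadPairs(
    Biostrings::DNAStringSet(c(rndRead(150, 88), rndRead(100, 89))),
    Biostrings::DNAStringSet(c(rndRead(150, 90), rndRead(100, 91)))),
    "mixed")
})

test_that("the 3% mismatch filter keeps 4/150 and drops 6/150", {
  g <- galnWithNM(c("150M", "150M", "150M"), c(4L, 6L, 0L))
  out <- filterAlignments(g)
  expect_equal(S4Vectors::mcols(out)$NM, c(4L, 0L))
})

test_that("indel bases do not count against the mismatch budget", {
  ## 100M50D50M with NM=52: 50 deleted bases + 2 true mismatches
  g <- galnWithNM("100M50D50M", 52L)
  expect_length(filterAlignments(g), 1)
})

test_that("alignments without NM are rejected", {
  g <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle("chr1"), pos = 1L, cigar = "150M",
    strand = S4Vectors::Rle(GenomicRanges::strand("+")))
  expect_error(filterAlignments(g), "NM")
})

test_that("genotype decision follows the split-read and depth rules", {
  ## accession carries A: splits appear on genome B only
  r <- callGenotype(evStub(), evStub(left = 4L, right = 4L))
  expect_identical(r$genotype, "A")
  expect_identical(r$basis, "split_read")
  ## 2 split reads are not enough by themselves...
  r <- callGenotype(evStub(), evStub(left = 2L, right = 2L))
  expect_identical(r$genotype, "U")
  ## ...but the depth rule can rescue the call
  r <- callGenotype(evStub(),
                    evStub(left = 2L, right = 2L, depth_event = 0.1,
                           depth_flank = 0.9, applicable = TRUE))
  expect_identical(r$genotype, "A")
  expect_identical(r$basis, "depth")
  ## depth rule boundaries: event must be < 50% covered, flank > 50%
  r <- callGenotype(evStub(),
                    evStub(depth_event = 0.6, depth_flank = 0.9,
                           applicable = TRUE))
  expect_identical(r$genotype, "U")
  r <- callGenotype(evStub(),
                    evStub(depth_event = 0.1, depth_flank = 0.4,
                           applicable = TRUE))
  expect_identical(r$genotype, "U")
  ## both alleles supported -> heterozygous
  r <- callGenotype(evStub(left = 5L, right = 3L),
                    evStub(left = 4L, right = 6L))
  expect_identical(r$genotype, "H")
  ## exactly 3 split reads meet the rule
  r <- callGenotype(evStub(left = 3L, right = 3L), evStub())
  expect_identical(r$genotype, "B")
  ## nothing anywhere -> undetermined
  r <- callGenotype(evStub(), evStub())
  expect_identical(r$genotype, "U")
  expect_identical(r$basis, "none")
})

test_that("split-read counting honours the window around breakpoints", {
  jx <- data.frame(chrom = "chr1",
                   pos = c(1000L, 1005L, 1012L, 2000L, 2001L, 5000L))
  ## interval event [1000, 2000]
  c10 <- countSplitReads(jx, "chr1", 1000L, 2000L, 1001L, window = 10L)
  expect_equal(unname(c10), c(2L, 2L))   # 1012 is 12 bp off: excluded
  c0 <- countSplitReads(jx, "chr1", 1000L, 2000L, 1001L, window = 0L)
  expect_equal(unname(c0), c(1L, 2L))   # 2001 = hi + 1 still matches
  ## point junction: one junction reported on both sides
  cp <- countSplitReads(jx, "chr1", 5000L, 5000L, 0L, window = 10L)
  expect_equal(unname(cp), c(1L, 1L))
  ## exact junctions: window 0 equals window 10 when positions are exact
  jexact <- data.frame(chrom = "chr1", pos = rep(c(1000L, 2000L), 3))
  expect_equal(countSplitReads(jexact, "chr1", 1000L, 2000L, 1001L, 0L),
               countSplitReads(jexact, "chr1", 1000L, 2000L, 1001L, 10L))
})

test_that("depth evidence separates deleted from retained intervals", {
  v <- S4Vectors::Rle(c(rep(30L, 1000), rep(0L, 500), rep(30L, 1000)))
  cov <- IRanges::RleList(chr1 = v)
  ## homozygous deletion: event empty, flanks full
  d <- depthEvidenceForDeletion(cov, "chr1", 1001L, 1500L)
  expect_equal(unname(d), c(0, 1))
  ## no deletion: event fully covered
  d2 <- depthEvidenceForDeletion(cov, "chr1", 200L, 700L)
  expect_equal(unname(d2[1]), 1)
  ## zero coverage everywhere: flank clause fails too
  cov0 <- IRanges::RleList(chr1 = S4Vectors::Rle(0L, 2500))
  d3 <- depthEvidenceForDeletion(cov0, "chr1", 1001L, 1500L)
  expect_equal(unname(d3), c(0, 0))
})

test_that("genotype matrix arithmetic and duplicate detection", {
  calls <- data.frame(
    accession = "acc1", sv_id = sprintf("sv%02d", 1:10),
    genotype = c(rep("A", 4), rep("B", 2), "H", rep("U", 3)))
  gm <- genotypeMatrix(calls)
  expect_equal(unname(gm$accession_rate), 0.7)
  allu <- transform(calls, genotype = "U")
  expect_equal(unname(genotypeMatrix(allu)$accession_rate), 0)
  expect_error(genotypeMatrix(rbind(calls, calls[1, ])), "duplicate")
})
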
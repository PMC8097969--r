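## ---- gap-region filtering ----------------------------------------------

gapGenome <- function(len = 50000L, gap_at = 25000L, gap_len = 100L,
                      seed = 41L) {
  g <- randomGenome(len, seed = seed)
  s <- as.character(g[[1]])
  substr(s, gap_at, gap_at + gap_len - 1L) <- strrep("N", gap_len)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- "chr1"
  out
}

test_that("SVs closer than 50 bp to an N-run are removed, 60 bp kept", {
  ga <- gapGenome()                      # N-run at [25000, 25099]
  gb <- randomGenome(50000, seed = 42)   # no gaps
  svs <- SVSet(chrom = rep("chr1", 3),
               start = c(25110, 25160, 24950),   # 10 bp / 60 bp / spanning
               end = c(25309, 25359, 25249),
               sv_type = rep("deletion", 3),
               len_a = c(200L, 200L, 300L), len_b = c(0L, 0L, 0L),
               sv_id = c("near", "far", "span"))
  kept <- filterNearGaps(svs, ga, gb, max_distance = 50)
  expect_identical(svId(kept), "far")
})

test_that("mate intervals near gaps on the other genome also disqualify", {
  ga <- randomGenome(50000, seed = 43)
  gb <- gapGenome(seed = 44)
  sv <- SVSet(chrom = "chr1", start = 10000, end = 10199,
              sv_type = "deletion", len_a = 200L, len_b = 0L,
              sv_id = "d1", mate_chrom = "chr1", mate_start = 25105L,
              mate_end = 25105L)
  expect_length(filterNearGaps(sv, ga, gb), 0)
})

test_that("genomes without Ns leave the input unchanged", {
  ga <- randomGenome(50000, seed = 45)
  gb <- randomGenome(50000, seed = 46)
  svs <- svDeletion(start = 20000, len = 500)
  out <- filterNearGaps(svs, ga, gb)
  expect_equal(svdiverge:::.svsetAsFrame(out),
               svdiverge:::.svsetAsFrame(svs))
})

test_that("gap filtering output is a subset and respects the distance rule", {
  ga <- gapGenome(seed = 47)
  gb <- randomGenome(50000, seed = 48)
  set.seed(49)
  starts <- sort(sample(seq(1000, 48000), 30))
  svs <- SVSet(chrom = rep("chr1", 30), start = starts,
               end = starts + 99L, sv_type = rep("deletion", 30),
               len_a = rep(100L, 30), len_b = rep(0L, 30))
  kept <- filterNearGaps(svs, ga, gb, max_distance = 50)
  expect_true(all(svId(kept) %in% svId(svs)))
  ## every removed SV is genuinely within 50 bp of the run (or spans it)
  removed <- setdiff(svId(svs), svId(kept))
  for (id in removed) {
    i <- match(id, svId(svs))
    s <- GenomicRanges::start(svRanges(svs))[i]
    e <- GenomicRanges::end(svRanges(svs))[i]
    gapdist <- max(0, max(25000 - e, s - 25099) - 1)
    expect_lt(gapdist, 50)
  }
})

## ---- flank validation --------------------------------------------------

test_that("insertion passes at 15% size deviation, fails at 25%", {
  ga <- randomGenome(30000, seed = 51)
  sv <- svInsertion(pos = 10000, len = 1000)
  hits <- function(obs) rbind(
    mockHit("sv1|L", sstart = 5001, send = 10000),
    mockHit("sv1|R", sstart = 10000 + obs + 1, send = 15000 + obs))
  r850 <- validateFlanks(sv, ga, ga, backend = mockBackend(hits(850)))
  expect_identical(r850$verdict, "pass")
  expect_equal(r850$deviation, 0.15)
  r750 <- validateFlanks(sv, ga, ga, backend = mockBackend(hits(750)))
  expect_identical(r750$verdict, "fail_size")
})

test_that("deletion flank hits overlapping by 5 bp fail, 2 bp pass", {
  ga <- randomGenome(30000, seed = 52)
  sv <- svDeletion(start = 10001, len = 500)
  hits <- function(obs) rbind(
    mockHit("sv1|L", sstart = 3001, send = 8000),
    mockHit("sv1|R", sstart = 8000 + obs + 1, send = 13000 + obs))
  expect_identical(
    validateFlanks(sv, ga, ga, backend = mockBackend(hits(-5)))$verdict,
    "fail_size")
  expect_identical(
    validateFlanks(sv, ga, ga, backend = mockBackend(hits(-2)))$verdict,
    "pass")
})

test_that("unreliable or missing hits give fail_no_hit / fail_wrong_region", {
  ga <- randomGenome(30000, seed = 53)
  sv <- svInsertion(pos = 10000, len = 100)
  none <- data.frame(qseqid = character(), sseqid = character(),
                     pident = numeric(), length = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric())
  expect_identical(
    validateFlanks(sv, ga, ga, backend = mockBackend(none))$verdict,
    "fail_no_hit")
  ## short / low-identity / weak-evalue hits are not reliable
  weak <- rbind(mockHit("sv1|L", 5001, 10000, pident = 85),
                mockHit("sv1|R", 10101, 15100, length = 40),
                mockHit("sv1|R", 10101, 15100, evalue = 1e-5))
  expect_identical(
    validateFlanks(sv, ga, ga, backend = mockBackend(weak))$verdict,
    "fail_no_hit")
  ## hits on different chromosomes are not the expected region
  wrong <- rbind(mockHit("sv1|L", 5001, 10000),
                 mockHit("sv1|R", 10101, 15100, sseqid = "chr9"))
  expect_identical(
    validateFlanks(sv, ga, ga, backend = mockBackend(wrong))$verdict,
    "fail_wrong_region")
})

test_that("deviation is scale-free", {
  ga <- randomGenome(60000, seed = 54)
  dev_for <- function(exp_len, obs) {
    sv <- svInsertion(pos = 20000, len = exp_len)
    hits <- rbind(mockHit("sv1|L", 15001, 20000),
                  mockHit("sv1|R", 20000 + obs + 1, 25000 + obs))
    validateFlanks(sv, ga, ga, backend = mockBackend(hits))$deviation
  }
  expect_equal(dev_for(1000, 900), dev_for(2000, 1800))
})

test_that("planted SVs validate cleanly with the real blastn backend", {
  cfg <- simulationConfig(seed = 55, genome_length = 1e5,
                          n_chromosomes = 1,
                          sv_counts = c(insertion = 2, deletion = 2),
                          sv_size_range = c(100, 500),
                          min_spacing = 5000,
                          background_divergence = 0, n_accessions = 1)
  gp <- generateGenomePair(cfg)
  rep <- validateFlanks(truthSvs(gp$truth), gp$genome_a, gp$genome_b,
                        flank = 2000)
  expect_true(all(rep$verdict == "pass"))
  expect_true(all(rep$deviation == 0))
  expect_true(all(rep$left_identity == 100))
})
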
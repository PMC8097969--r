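test_that("zero SV counts with zero divergence give identical genomes", {
  cfg <- simulationConfig(seed = 3, genome_length = 5e4,
                          n_chromosomes = 1, sv_counts = c(),
                          background_divergence = 0, n_accessions = 2)
  gp <- generateGenomePair(cfg)
  expect_identical(as.character(gp$genome_a), as.character(gp$genome_b))
  expect_length(truthSvs(gp$truth), 0)
})

test_that("a planted deletion shortens genome B by exactly its length", {
  cfg <- simulationConfig(seed = 4, genome_length = 5e4,
                          n_chromosomes = 1,
                          sv_counts = c(deletion = 1),
                          sv_size_range = c(500, 500),
                          min_spacing = 2000,
                          background_divergence = 0, n_accessions = 2)
  gp <- generateGenomePair(cfg)
  expect_equal(nchar(as.character(gp$genome_a[[1]])) -
                 nchar(as.character(gp$genome_b[[1]])), 500)
  svs <- truthSvs(gp$truth)
  ## the deleted substring is really absent at the recorded breakpoint
  s <- GenomicRanges::start(svRanges(svs))[1]
  a <- as.character(gp$genome_a[[1]])
  b <- as.character(gp$genome_b[[1]])
  expect_identical(substr(b, s, s + 99),
                   substr(a, s + 500, s + 599))
})

test_that("insertions appear verbatim at the recorded mate coordinates", {
  cfg <- smallPairConfig(seed = 5)
  gp <- generateGenomePair(cfg)
  svs <- truthSvs(gp$truth)
  m <- S4Vectors::mcols(svRanges(svs))
  ins <- which(m$sv_type == "insertion")
  for (i in ins) {
    got <- substr(as.character(gp$genome_b[[m$mate_chrom[i]]]),
                  m$mate_start[i], m$mate_end[i])
    expect_identical(got, m$seq[i])
  }
})

test_that("seed fully determines genome FASTA bytes", {
  cfg <- simulationConfig(seed = 1, genome_length = 2e5,
                          n_chromosomes = 2,
                          sv_counts = c(insertion = 15, deletion = 15,
                                        substitution = 10,
                                        tandem_expansion = 5,
                                        repeat_contraction = 5),
                          sv_size_range = c(10, 2000),
                          min_spacing = 1500, n_accessions = 2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  gp1 <- generateGenomePair(cfg)
  Biostrings::writeXStringSet(gp1$genome_b, f1)
  gp2 <- generateGenomePair(cfg)
  Biostrings::writeXStringSet(gp2$genome_b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(truthGenotypes(gp1$truth), truthGenotypes(gp2$truth))
})

test_that("allele-length bookkeeping matches the genome length difference", {
  for (sd in 1:3) {
    gp <- generateGenomePair(smallPairConfig(seed = sd,
                                             divergence = 0.003))
    svs <- truthSvs(gp$truth)
    expect_equal(sum(lenB(svs) - lenA(svs)),
                 sum(nchar(as.character(gp$genome_b))) -
                   sum(nchar(as.character(gp$genome_a))))
  }
})

test_that("requested N-runs are planted and SV placement respects spacing", {
  gaps <- data.frame(chrom = "chr1", position = 60000L, length = 120L)
  cfg <- simulationConfig(seed = 9, genome_length = 2e5,
                          n_chromosomes = 1,
                          sv_counts = c(deletion = 3),
                          sv_size_range = c(100, 300),
                          min_spacing = 5000, gap_runs = gaps,
                          n_accessions = 1)
  gp <- generateGenomePair(cfg)
  expect_identical(substr(as.character(gp$genome_a[[1]]), 60000, 60119),
                   strrep("N", 120))
  gr <- svRanges(truthSvs(gp$truth))
  expect_true(all(abs(GenomicRanges::start(gr) - 60060) > 5000))
})

test_that("accession reads at zero error are exact haplotype substrings", {
  cfg <- simulationConfig(seed = 6, genome_length = 5e4,
                          n_chromosomes = 1,
                          sv_counts = c(deletion = 2),
                          sv_size_range = c(100, 200),
                          min_spacing = 2000, n_accessions = 1,
                          het_fraction = 0, error_rate = 0,
                          background_divergence = 0,
                          short_read_depth = 5)
  gp <- generateGenomePair(cfg)
  ## force an all-A accession so every read must come from genome A
  gp$truth@genotypes[, ] <- "A"
  out <- tempfile("reads")
  rr <- generateAccessionReads(gp$genome_a, gp$genome_b, gp$truth, cfg,
                               out)
  r1 <- Biostrings::readDNAStringSet(rr$files$fq1[1], format = "fastq")
  a <- as.character(gp$genome_a[[1]])
  hits <- vapply(as.character(head(r1, 50)), function(s)
    grepl(s, a, fixed = TRUE) || grepl(revComp(s), a, fixed = TRUE),
    logical(1))
  expect_true(all(hits))
})

test_that("read-pair count honours the requested depth", {
  cfg <- simulationConfig(seed = 7, genome_length = 1e5,
                          n_chromosomes = 1, sv_counts = c(),
                          n_accessions = 1, short_read_depth = 30,
                          short_read_length = 150L,
                          background_divergence = 0)
  gp <- generateGenomePair(cfg)
  rr <- generateAccessionReads(gp$genome_a, gp$genome_b, gp$truth, cfg,
                               tempfile("reads"))
  expected <- 1e5 * 30 / (2 * 150)     # 10,000 pairs
  expect_lt(abs(rr$files$n_pairs[1] - expected) / expected, 0.2)
})

test_that("heterozygous loci emit reads from both haplotypes", {
  cfg <- simulationConfig(seed = 8, genome_length = 1e5,
                          n_chromosomes = 1,
                          sv_counts = c(deletion = 1),
                          sv_size_range = c(400, 400),
                          min_spacing = 3000, n_accessions = 1,
                          het_fraction = 1, short_read_depth = 30,
                          background_divergence = 0)
  gp <- generateGenomePair(cfg)
  expect_true(all(truthGenotypes(gp$truth) == "H"))
  rr <- generateAccessionReads(gp$genome_a, gp$genome_b, gp$truth, cfg,
                               tempfile("reads"))
  prov <- readProvenance(rr$truth)
  svs <- truthSvs(gp$truth)
  s <- GenomicRanges::start(svRanges(svs))[1]
  e <- GenomicRanges::end(svRanges(svs))[1]
  near <- prov[prov$start < e + 200 & prov$end > s - 200, ]
  ## haplotype 1 carries A (spanning reads), haplotype 2 carries the
  ## deletion (junction reads): both present near the locus
  expect_setequal(unique(near$haplotype), c(1L, 2L))
})

test_that("zero or negative depth is rejected", {
  cfg <- smallPairConfig(seed = 10)
  cfg@shortReadDepth <- 0
  gp <- generateGenomePair(smallPairConfig(seed = 10))
  expect_error(generateAccessionReads(gp$genome_a, gp$genome_b,
                                      gp$truth, cfg, tempfile()),
               "depth")
})

test_that("truth set round-trips losslessly through TSV files", {
  gp <- generateGenomePair(smallPairConfig(seed = 12))
  d <- tempfile("truth")
  writeTruthSet(gp$truth, d)
  t2 <- readTruthSet(d)
  expect_identical(truthGenotypes(t2), truthGenotypes(gp$truth))
  f1 <- svdiverge:::.svsetAsFrame(truthSvs(gp$truth))
  f2 <- svdiverge:::.svsetAsFrame(truthSvs(t2))
  expect_equal(f1, f2)
  ## SV table row count equals the number of planted SVs
  tab <- read.delim(file.path(d, "truth_svs.tsv"))
  expect_equal(nrow(tab), length(truthSvs(gp$truth)))
})

test_that("an empty truth set writes valid headed files", {
  cfg <- simulationConfig(seed = 2, genome_length = 5e4,
                          n_chromosomes = 1, sv_counts = c(),
                          n_accessions = 2, background_divergence = 0)
  gp <- generateGenomePair(cfg)
  d <- tempfile("truth0")
  writeTruthSet(gp$truth, d)
  tab <- read.delim(file.path(d, "truth_svs.tsv"))
  expect_equal(nrow(tab), 0)
  expect_true(all(c("sv_id", "chrom", "start", "end") %in% names(tab)))
  t2 <- readTruthSet(d)
  expect_length(truthSvs(t2), 0)
})
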
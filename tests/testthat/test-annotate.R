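## one + strand gene [10001, 16000] with CDS [11001,12000] and
## [14001,15000]; one - strand gene [30001, 34000] with CDS [31001,33000]
testGenes <- function() {
  df <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(10001L, 30001L), end = c(16000L, 34000L),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  df$cds <- list(cbind(start = c(11001L, 14001L),
                       end = c(12000L, 15000L)),
                 cbind(start = 31001L, end = 33000L))
  df
}

test_that("SV-gene categories follow CDS > intron/UTR > promoter", {
  genes <- testGenes()
  svs <- SVSet(chrom = rep("chr1", 4),
               start = c(11500, 13000, 9500, 7000),
               end = c(11549, 13049, 9549, 7049),
               sv_type = rep("deletion", 4), len_a = rep(50L, 4),
               len_b = rep(0L, 4),
               sv_id = c("in_cds", "in_intron", "in_prom", "too_far"))
  cls <- classifySvGeneOverlap(svs, genes, promoter_length = 2000)
  a <- cls$assignments
  expect_identical(a$category[a$sv_id == "in_cds"], "CDS")
  expect_identical(a$category[a$sv_id == "in_intron"], "intron/UTR")
  ## 500 bp upstream of the + strand gene start is promoter
  expect_identical(a$category[a$sv_id == "in_prom"], "promoter")
  ## 3 kb upstream with a 2-kb window: no assignment
  expect_false("too_far" %in% a$sv_id)
  expect_identical(cls$genes$affected, c(TRUE, FALSE))
})

test_that("promoters are strand-aware", {
  genes <- testGenes()
  ## 500 bp downstream of the - strand gene end = its promoter side
  sv <- SVSet(chrom = "chr1", start = 34500, end = 34549,
              sv_type = "deletion", len_a = 50L, len_b = 0L,
              sv_id = "p2")
  cls <- classifySvGeneOverlap(sv, genes)
  expect_identical(cls$assignments$category, "promoter")
  expect_identical(cls$assignments$gene_id, "g2")
})

test_that("disjoint chromosome universes are rejected", {
  sv <- SVSet(chrom = "chrX", start = 100, end = 149,
              sv_type = "deletion", len_a = 50L, len_b = 0L)
  expect_error(classifySvGeneOverlap(sv, testGenes()), "chromosome")
})

test_that("genome fractions use interval unions", {
  g <- randomGenome(1000, seed = 111)
  sv1 <- svDeletion(start = 101, len = 100, id = "s1")
  fr1 <- svGenomeFractions(sv1, g)
  expect_equal(unname(fr1["genome_fraction"]), 0.1)
  ## a duplicate interval adds nothing
  two <- SVSet(chrom = c("chr1", "chr1"), start = c(101, 101),
               end = c(200, 200), sv_type = rep("deletion", 2),
               len_a = c(100L, 100L), len_b = c(0L, 0L))
  expect_equal(unname(svGenomeFractions(two, g)["genome_fraction"]), 0.1)
})

test_that("adding an SV never decreases a coverage fraction", {
  g <- randomGenome(50000, seed = 112)
  genes <- testGenes()
  set.seed(113)
  starts <- sample(seq(1000, 45000), 15)
  fr_prev <- c(0, 0, 0)
  for (n in c(5, 10, 15)) {
    svs <- SVSet(chrom = rep("chr1", n), start = starts[1:n],
                 end = starts[1:n] + 299L, sv_type = rep("deletion", n),
                 len_a = rep(300L, n), len_b = rep(0L, n))
    fr <- svGenomeFractions(svs, g, genes)
    expect_true(all(fr >= fr_prev - 1e-12))
    fr_prev <- fr
  }
})

test_that("classification counts survive reverse-complementing the genome", {
  L <- 50000L
  genes <- testGenes()
  set.seed(114)
  starts <- sample(seq(1000, 45000), 20)
  svs <- SVSet(chrom = rep("chr1", 20), start = starts,
               end = starts + 99L, sv_type = rep("deletion", 20),
               len_a = rep(100L, 20), len_b = rep(0L, 20),
               sv_id = sprintf("s%02d", 1:20))
  fwd <- classifySvGeneOverlap(svs, genes)
  ## mirror all intervals through x -> L + 1 - x and flip strands
  genes_rc <- genes
  genes_rc$start <- L + 1L - genes$end
  genes_rc$end <- L + 1L - genes$start
  genes_rc$strand <- ifelse(genes$strand == "+", "-", "+")
  genes_rc$cds <- lapply(genes$cds, function(m)
    cbind(start = L + 1L - m[, "end"], end = L + 1L - m[, "start"]))
  svs_rc <- SVSet(chrom = rep("chr1", 20), start = L + 1L - (starts + 99L),
                  end = L + 1L - starts, sv_type = rep("deletion", 20),
                  len_a = rep(100L, 20), len_b = rep(0L, 20),
                  sv_id = sprintf("s%02d", 1:20))
  rc <- classifySvGeneOverlap(svs_rc, genes_rc)
  expect_equal(table(fwd$assignments$category),
               table(rc$assignments$category))
  expect_equal(sum(fwd$genes$affected), sum(rc$genes$affected))
})

test_that("gene models round-trip through GFF3", {
  g <- randomGenome(100000, seed = 115)
  genes <- simulateGeneModels(g, n_genes = 10, seed = 3)
  path <- tempfile(fileext = ".gff3")
  writeGeneModels(genes, path)
  back <- readGeneModels(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$strand, genes$strand)
  for (i in seq_len(nrow(genes)))
    expect_equal(unname(back$cds[[i]]), unname(genes$cds[[i]]))
})

test_that("LTR insertion time follows T = S / (2 mu)", {
  expect_identical(ltrInsertionTime(0), 0)
  expect_equal(ltrInsertionTime(0.03, 1.5e-8), 1e6)
  expect_equal(ltrInsertionTime(0.006, 1.5e-8), 2e5)
  ## linear in S, inverse-linear in mu
  expect_equal(ltrInsertionTime(0.06, 1.5e-8),
               2 * ltrInsertionTime(0.03, 1.5e-8))
  expect_equal(ltrInsertionTime(0.03, 3e-8),
               ltrInsertionTime(0.03, 1.5e-8) / 2)
  expect_error(ltrInsertionTime(0.03, 0), "mu")
  expect_error(ltrInsertionTime(-1), "S")
})
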
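## Shared fixture builders. Everything is generated in code at test time.

## random single-chromosome genome as a DNAStringSet
randomGenome <- function(len = 30000L, seed = 1L, name = "chr1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- name
  g
}

## small genome pair + truth, shared across tests in a file
smallPairConfig <- function(seed = 11L, divergence = 0, ...) {
  simulationConfig(seed = seed, genome_length = 2e5, n_chromosomes = 1L,
                   sv_counts = c(insertion = 4, deletion = 4,
                                 substitution = 2, tandem_expansion = 2,
                                 repeat_contraction = 2),
                   sv_size_range = c(20, 800), min_spacing = 3000,
                   background_divergence = divergence,
                   n_accessions = 3L, ...)
}

## flank-validation backend returning pre-programmed hits
mockBackend <- function(hits) function(queries) hits

mockHit <- function(qseqid, sstart, send, qstart = 1L, qend = 5000L,
                    sseqid = "chr1", pident = 99.5, length = 5000L,
                    evalue = 0) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, qstart = qstart, qend = qend,
             sstart = sstart, send = send, evalue = evalue,
             stringsAsFactors = FALSE)
}

## one-record SVSet helpers
svDeletion <- function(start, len, chrom = "chr1", id = "sv1",
                       source = "assembly") {
  SVSet(chrom = chrom, start = start, end = start + len - 1L,
        sv_type = "deletion", len_a = len, len_b = 0L, sv_id = id,
        source = source)
}

svInsertion <- function(pos, len, chrom = "chr1", id = "sv1",
                        source = "assembly") {
  SVSet(chrom = chrom, start = pos, end = pos, sv_type = "insertion",
        len_a = 0L, len_b = len, sv_id = id, source = source)
}

## exhaustive hypergeometric two-sided p (independent oracle: lchoose
## enumeration, not dhyper)
bruteFisherP <- function(a, b, cc, dd) {
  m <- a + b; n <- cc + dd; k <- a + cc
  if (m + n == 0 || k == 0 || k == m + n || m == 0 || n == 0) return(1)
  x <- max(0, k - n):min(k, m)
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  pr <- exp(lp)
  po <- pr[x == a]
  min(1, sum(pr[pr <= po * (1 + 1e-7)]))
}

## GAlignments with an NM tag, for alignment-filter tests
galnWithNM <- function(cigar, nm, chrom = "chr1", pos = 1L) {
  g <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(chrom, length(cigar)),
    pos = rep(as.integer(pos), length.out = length(cigar)),
    cigar = cigar,
    strand = S4Vectors::Rle(GenomicRanges::strand("+"), length(cigar)))
  S4Vectors::mcols(g)$NM <- as.integer(nm)
  g
}

## breakpoint evidence stub for callGenotype
evStub <- function(left = 0L, right = 0L, depth_event = NA_real_,
                   depth_flank = NA_real_, applicable = FALSE) {
  list(split_left = left, split_right = right,
       depth_fraction_event = depth_event,
       depth_fraction_flank_best = depth_flank,
       depth_applicable = applicable)
}

## align one accession against both genomes; returns bam paths
alignAccession <- function(fa_a, fa_b, fq1, fq2, dir, acc) {
  bam_a <- file.path(dir, paste0(acc, "_A.bam"))
  bam_b <- file.path(dir, paste0(acc, "_B.bam"))
  bwaAlignPairs(fa_a, fq1, fq2, bam_a)
  bwaAlignPairs(fa_b, fq1, fq2, bam_b)
  list(bam_a = bam_a, bam_b = bam_b)
}
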
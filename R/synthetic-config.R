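#' Build a simulation configuration
#'
#' Constructs a validated \linkS4class{SimulationConfig}. Defaults describe a
#' desk-scale study: a 2-Mb genome in two chromosomes, one hundred planted
#' SVs across all seven classes sized 10 bp to 10 kb, 0.5\% background
#' divergence between the two assemblies (emulating well-diverged but
#' alignable genomes), and 12 accessions resequenced with 2 x 150 bp pairs
#' at 30-fold coverage and 0.5\% base error.
#'
#' @param seed integer; the only source of randomness.
#' @param genome_length total genome length in bp.
#' @param n_chromosomes number of chromosomes (lengths split evenly).
#' @param gc_content background GC fraction.
#' @param sv_counts named integer vector over
#'   \code{c("insertion","deletion","substitution","repeat_expansion",
#'   "repeat_contraction","tandem_expansion","tandem_contraction")}; missing
#'   names default to 0.
#' @param sv_size_range either \code{c(min,max)} applied to every class or a
#'   named list per class. Minimum allowed size is 10 bp.
#' @param background_divergence per-base substitution rate planted between
#'   the assemblies outside SV loci.
#' @param min_spacing minimum distance in bp between planted SVs (and from
#'   chromosome ends and planted gaps), keeping flanking sequence unique.
#' @param n_accessions number of accessions to simulate.
#' @param het_fraction fraction of accession genotypes drawn heterozygous.
#' @param short_read_length 100 or 150 (bp).
#' @param short_read_depth fold coverage for paired-end reads.
#' @param insert_size_mean,insert_size_sd paired-end fragment model (bp).
#' @param long_read_mean_length mean long-read length (bp).
#' @param error_rate per-base sequencing error rate.
#' @param gap_runs data.frame with columns \code{chrom,position,length}
#'   giving N-runs (assembly gaps) to plant in both genomes.
#' @return A \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, genome_length = 1e5,
#'                         sv_counts = c(deletion = 3, insertion = 2))
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             genome_length = 2e6,
                             n_chromosomes = 2L,
                             gc_content = 0.36,
                             sv_counts = c(insertion = 25, deletion = 25,
                                           substitution = 10,
                                           repeat_expansion = 10,
                                           repeat_contraction = 10,
                                           tandem_expansion = 10,
                                           tandem_contraction = 10),
                             sv_size_range = c(10, 10000),
                             background_divergence = 0.005,
                             min_spacing = 10000,
                             n_accessions = 12L,
                             het_fraction = 0.25,
                             short_read_length = 150L,
                             short_read_depth = 30,
                             insert_size_mean = 450,
                             insert_size_sd = 50,
                             long_read_mean_length = 12000,
                             error_rate = 0.005,
                             gap_runs = data.frame(chrom = character(),
                                                   position = integer(),
                                                   length = integer())) {
  counts <- setNames(integer(length(SV_TYPES)), SV_TYPES)
  if (length(sv_counts)) {
    bad <- setdiff(names(sv_counts), SV_TYPES)
    if (length(bad))
      stop("unknown sv_counts name(s): ", paste(bad, collapse = ", "))
    counts[names(sv_counts)] <- as.integer(sv_counts)
  }
  if (!is.list(sv_size_range))
    sv_size_range <- setNames(rep(list(as.numeric(sv_size_range)),
                                  length(SV_TYPES)), SV_TYPES)
  else {
    missing_ty <- setdiff(SV_TYPES, names(sv_size_range))
    sv_size_range[missing_ty] <- list(c(10, 10000))
    sv_size_range <- sv_size_range[SV_TYPES]
  }
  new("SimulationConfig",
      seed = as.integer(seed), genomeLength = as.numeric(genome_length),
      nChromosomes = as.integer(n_chromosomes),
      gcContent = as.numeric(gc_content), svCounts = counts,
      svSizeRange = sv_size_range,
      backgroundDivergence = as.numeric(background_divergence),
      minSpacing = as.numeric(min_spacing),
      nAccessions = as.integer(n_accessions),
      hetFraction = as.numeric(het_fraction),
      shortReadLength = as.integer(short_read_length),
      shortReadDepth = as.numeric(short_read_depth),
      insertSizeMean = as.numeric(insert_size_mean),
      insertSizeSd = as.numeric(insert_size_sd),
      longReadMeanLength = as.numeric(long_read_mean_length),
      errorRate = as.numeric(error_rate),
      gapRuns = gap_runs)
}
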
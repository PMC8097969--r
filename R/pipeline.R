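#' @importFrom tools md5sum
NULL

.CONFIG_DEFAULTS <- list(
  stages = "simulate,discover,genotype,popgen,annotate",
  seed = 1,
  out_dir = "svdiverge_run",
  ## synthetic-stage parameters
  genome_length = 400000, n_chromosomes = 1, sv_count = 30,
  sv_min_size = 50, sv_max_size = 2000, min_spacing = 4000,
  background_divergence = 0.005, n_accessions = 4, het_fraction = 0.25,
  short_read_length = 150, short_read_depth = 20, error_rate = 0.005,
  n_genes = 40,
  ## thresholds (workflow defaults)
  min_size = 10, flank = 5000, gap_distance = 50, min_split = 3,
  window = 25000, alpha = 0.001, min_fold = 2, promoter = 2000,
  mu = 1.5e-8)

.CONFIG_CHECKS <- list(
  seed = function(x) x == round(x),
  genome_length = function(x) x >= 10000,
  n_chromosomes = function(x) x >= 1,
  sv_count = function(x) x >= 0,
  sv_min_size = function(x) x >= 10,
  sv_max_size = function(x) x >= 10,
  min_spacing = function(x) x > 0,
  background_divergence = function(x) x >= 0 && x <= 0.2,
  n_accessions = function(x) x >= 1,
  het_fraction = function(x) x >= 0 && x <= 1,
  short_read_length = function(x) x %in% c(100, 150),
  short_read_depth = function(x) x > 0,
  error_rate = function(x) x >= 0 && x < 0.25,
  n_genes = function(x) x >= 0,
  min_size = function(x) x >= 10,
  flank = function(x) x > 0,
  gap_distance = function(x) x >= 0,
  min_split = function(x) x >= 1,
  window = function(x) x > 0,
  alpha = function(x) x > 0 && x <= 1,
  min_fold = function(x) x >= 1,
  promoter = function(x) x >= 0,
  mu = function(x) x > 0)

#' Pipeline configuration
#'
#' \code{pipelineConfig} builds a validated configuration from defaults
#' plus overrides. Analysis thresholds default to the workflow's canonical
#' values (minimum SV size 10 bp, 5-kb flanks, 50-bp gap distance, 3 split
#' reads, 25-kb thinning windows, adjusted-p 0.001, fold change 2, 2-kb
#' promoters, mu = 1.5e-8); synthetic-stage parameters default to a
#' desk-scale demonstration (400-kb genome, 30 SVs of 50-2000 bp, 4
#' accessions at 20x). \code{validateConfig} reads a \code{key = value}
#' text file (\code{#} comments allowed), applies defaults for absent
#' keys, rejects unknown keys and reports every violated constraint with
#' its key.
#'
#' @param ... overrides of the defaults (unknown keys rejected).
#' @return A config list (class \code{svd_config}).
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  errs <- character()
  for (k in names(.CONFIG_CHECKS)) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        !.CONFIG_CHECKS[[k]](v))
      errs <- c(errs, sprintf("`%s` invalid (value: %s)", k,
                              paste(v, collapse = ",")))
  }
  st <- trimws(strsplit(cfg$stages, ",", fixed = TRUE)[[1]])
  st <- st[nzchar(st)]
  bad_st <- setdiff(st, c("simulate", "discover", "genotype", "popgen",
                          "annotate"))
  if (length(bad_st))
    errs <- c(errs, sprintf("`stages` invalid (unknown: %s)",
                            paste(bad_st, collapse = ",")))
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  cfg$stages <- st
  class(cfg) <- "svd_config"
  cfg
}

#' @rdname pipelineConfig
#' @param path config file path.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad))
    stop("config parse error at line: ", lines[bad[1]])
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  over <- as.list(vals)
  names(over) <- keys
  for (k in keys)
    if (k %in% names(.CONFIG_DEFAULTS) &&
        is.numeric(.CONFIG_DEFAULTS[[k]]))
      over[[k]] <- suppressWarnings(as.numeric(over[[k]]))
  do.call(pipelineConfig, over)
}

#' @rdname pipelineConfig
#' @param config a config list.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$stages <- paste(cfg$stages, collapse = ",")
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE),
                            character(1))), path)
  invisible(path)
}

.needFile <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing upstream output for stage `%s`: %s", stage,
                 path))
  path
}

#' Run the end-to-end demonstration workflow
#'
#' Executes the enabled stages in dependency order under one run
#' directory: \code{simulate} (genome pair, truth set, accession reads,
#' read-based calls, gene models), \code{discover} (alignment-based
#' calling, gap filter, flank validation, refinement, merging),
#' \code{genotype} (read-pair deduplication, dual-reference bwa
#' alignment, split-read/depth genotyping), \code{popgen} (window
#' thinning, composition, differentiation scan, distance/PCA/NJ tree) and
#' \code{annotate} (SV-gene overlap, genome fractions). Each stage logs
#' the thresholds it applies; a manifest lists every output with an md5
#' checksum for path-free files (BAM and index files embed alignment
#' command lines, hence paths, and are listed without checksum). A rerun
#' with the same configuration and seed reproduces all checksummed files
#' byte for byte.
#'
#' @param config from \code{\link{pipelineConfig}} /
#'   \code{\link{validateConfig}}.
#' @return list with \code{out_dir}, \code{manifest} (data.frame),
#'   \code{summary} (named list of stage statistics).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "svd_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  cat("", file = logf)
  summary <- list()
  sim_cfg <- simulationConfig(
    seed = config$seed, genome_length = config$genome_length,
    n_chromosomes = config$n_chromosomes,
    sv_counts = c(insertion = ceiling(config$sv_count * 0.3),
                  deletion = ceiling(config$sv_count * 0.3),
                  substitution = ceiling(config$sv_count * 0.1),
                  repeat_expansion = ceiling(config$sv_count * 0.075),
                  repeat_contraction = ceiling(config$sv_count * 0.075),
                  tandem_expansion = ceiling(config$sv_count * 0.075),
                  tandem_contraction = ceiling(config$sv_count * 0.075)),
    sv_size_range = c(config$sv_min_size, config$sv_max_size),
    background_divergence = config$background_divergence,
    min_spacing = config$min_spacing,
    n_accessions = config$n_accessions,
    het_fraction = config$het_fraction,
    short_read_length = config$short_read_length,
    short_read_depth = config$short_read_depth,
    error_rate = config$error_rate)
  p <- function(...) file.path(out, ...)

  if ("simulate" %in% config$stages) {
    svdLog("stage simulate: genome ", config$genome_length, " bp, ",
           config$sv_count, " SVs, ", config$n_accessions,
           " accessions at ", config$short_read_depth, "x",
           logfile = logf)
    gp <- generateGenomePair(sim_cfg)
    dir.create(p("genomes"), showWarnings = FALSE)
    writeFastaTo(gp$genome_a, p("genomes", "genomeA.fa"))
    writeFastaTo(gp$genome_b, p("genomes", "genomeB.fa"))
    rr <- generateAccessionReads(gp$genome_a, gp$genome_b, gp$truth,
                                 sim_cfg, p("reads"))
    writeTruthSet(rr$truth, p("truth"))
    rc <- simulateReadCalls(rr$truth)
    dir.create(p("svs"), showWarnings = FALSE)
    writeSvVcf(rc, p("svs", "read_calls_A.vcf"), genome = gp$genome_a)
    genes <- simulateGeneModels(gp$genome_a, n_genes = config$n_genes,
                                seed = config$seed,
                                path = p("genomes", "genes.gff3"))
    summary$simulate <- list(n_sv_planted = length(truthSvs(rr$truth)),
                             n_accessions = config$n_accessions,
                             n_genes = nrow(genes))
  }

  genome_a_fa <- p("genomes", "genomeA.fa")
  genome_b_fa <- p("genomes", "genomeB.fa")

  if ("discover" %in% config$stages) {
    svdLog("stage discover: min_size=", config$min_size, " gap_distance=",
           config$gap_distance, " flank=", config$flank,
           " min_reciprocal=0.5", logfile = logf)
    .needFile(genome_a_fa, "discover")
    .needFile(genome_b_fa, "discover")
    genome_a <- readDNAStringSet(genome_a_fa)
    names(genome_a) <- sub("\\s.*", "", names(genome_a))
    genome_b <- readDNAStringSet(genome_b_fa)
    names(genome_b) <- sub("\\s.*", "", names(genome_b))
    rc_path <- .needFile(p("svs", "read_calls_A.vcf"), "discover")
    rc <- readSvVcf(rc_path)
    res <- discoverSvs(genome_a, genome_b, read_calls = rc,
                       min_size = config$min_size,
                       gap_distance = config$gap_distance,
                       flank = config$flank)
    dir.create(p("svs"), showWarnings = FALSE)
    writeSvVcf(res$svs, p("svs", "merged.vcf"), genome = genome_a)
    writeSvBed(res$svs, p("svs", "merged.bed"))
    summary$discover <- list(n_raw = length(res$raw),
                             n_gap_filtered = length(res$gap_filtered),
                             n_validated = length(res$validated),
                             n_final = length(res$svs))
    if (file.exists(file.path(p("truth"), "truth_svs.tsv"))) {
      tr <- readTruthSet(p("truth"))
      ev <- evaluateCalls(res$svs, tr)
      summary$discover$recall <- ev$recall
      summary$discover$precision <- ev$precision
      summary$discover$mean_bp_error <- ev$mean_bp_error
    }
  }

  if ("genotype" %in% config$stages) {
    svdLog("stage genotype: min_split=", config$min_split,
           " window=10 depth_threshold=2 mismatch<=0.03",
           logfile = logf)
    svs <- readSvVcf(.needFile(p("svs", "merged.vcf"), "genotype"))
    .needFile(genome_a_fa, "genotype")
    .needFile(genome_b_fa, "genotype")
    tr <- readTruthSet(p("truth"))
    accs <- rownames(truthGenotypes(tr))
    dir.create(p("alignments"), showWarnings = FALSE)
    calls <- list()
    for (acc in accs) {
      fq1 <- .needFile(p("reads", paste0(acc, "_1.fq.gz")), "genotype")
      fq2 <- .needFile(p("reads", paste0(acc, "_2.fq.gz")), "genotype")
      dd1 <- p("alignments", paste0(acc, "_dedup_1.fq.gz"))
      dd2 <- p("alignments", paste0(acc, "_dedup_2.fq.gz"))
      ndup <- deduplicateFastqPair(fq1, fq2, dd1, dd2)
      svdLog("  ", acc, ": ", ndup, " duplicate pair(s) removed",
             logfile = logf)
      bam_a <- p("alignments", paste0(acc, "_A.bam"))
      bam_b <- p("alignments", paste0(acc, "_B.bam"))
      bwaAlignPairs(genome_a_fa, dd1, dd2, bam_a)
      bwaAlignPairs(genome_b_fa, dd1, dd2, bam_b)
      calls[[acc]] <- genotypeAccession(svs, bam_a, bam_b, acc,
                                        min_split = config$min_split)
    }
    calls <- do.call(rbind, calls)
    dir.create(p("genotypes"), showWarnings = FALSE)
    write.table(calls, p("genotypes", "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    gm <- genotypeMatrix(calls)
    writeGenotypeMatrix(gm$matrix, p("genotypes", "matrix.tsv"))
    summary$genotype <- list(n_calls = nrow(calls),
                             mean_rate = mean(gm$accession_rate))
    ## truth-based accuracy where the call set maps onto planted SVs
    ev <- evaluateCalls(svs, tr)
    if (nrow(ev$matches)) {
      tg <- truthGenotypes(tr)
      acc_ids <- rownames(gm$matrix)
      called <- gm$matrix[, ev$matches$call_id, drop = FALSE]
      truthm <- tg[acc_ids, ev$matches$truth_id, drop = FALSE]
      det <- called != "U"
      summary$genotype$accuracy <-
        if (any(det)) mean(called[det] == truthm[det]) else NA_real_
      summary$genotype$determined_rate <- mean(det)
    }
  }

  if ("popgen" %in% config$stages) {
    svdLog("stage popgen: window=", config$window, " alpha=",
           config$alpha, " min_fold=", config$min_fold, logfile = logf)
    m <- readGenotypeMatrix(.needFile(p("genotypes", "matrix.tsv"),
                                      "popgen"))
    svs <- readSvVcf(.needFile(p("svs", "merged.vcf"), "popgen"))
    labels <- setNames(rep(c("group1", "group2"),
                           length.out = nrow(m)), rownames(m))
    dir.create(p("popgen"), showWarnings = FALSE)
    write.table(data.frame(accession = names(labels), group = labels),
                p("popgen", "labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    thinned <- thinByWindows(svs, window = config$window,
                             seed = deriveSeed(config$seed, "thin"))
    writeSvBed(thinned, p("popgen", "thinned.bed"))
    comp <- genotypeComposition(m, labels)
    write.table(comp$per_accession, p("popgen", "composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    scan <- differentiationScan(m, labels, "group1", "group2",
                                alpha = config$alpha,
                                min_fold = config$min_fold)
    write.table(scan, p("popgen", "differentiation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    dp <- distanceAndPca(m)
    write.table(dp$dist, p("popgen", "distance.tsv"), sep = "\t",
                quote = FALSE)
    write.table(round(dp$pca$x, 6), p("popgen", "pca.tsv"), sep = "\t",
                quote = FALSE)
    ape::write.tree(dp$tree, p("popgen", "nj.nwk"))
    summary$popgen <- list(n_thinned = length(thinned),
                           n_tested = nrow(scan),
                           n_selected = sum(scan$selected))
  }

  if ("annotate" %in% config$stages) {
    svdLog("stage annotate: promoter=", config$promoter, " mu=",
           config$mu, logfile = logf)
    svs <- readSvVcf(.needFile(p("svs", "merged.vcf"), "annotate"))
    genes <- readGeneModels(.needFile(p("genomes", "genes.gff3"),
                                      "annotate"))
    genome_a <- readDNAStringSet(.needFile(genome_a_fa, "annotate"))
    names(genome_a) <- sub("\\s.*", "", names(genome_a))
    cls <- classifySvGeneOverlap(svs, genes,
                                 promoter_length = config$promoter)
    dir.create(p("annotation"), showWarnings = FALSE)
    write.table(cls$assignments, p("annotation", "sv_gene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cls$genes, p("annotation", "genes_affected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fr <- svGenomeFractions(svs, genome_a, genes)
    write.table(data.frame(quantity = names(fr), value = fr),
                p("annotation", "fractions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$annotate <- list(n_assignments = nrow(cls$assignments),
                             n_genes_affected = sum(cls$genes$affected),
                             genome_fraction = unname(fr[1]))
  }

  ## summary report + manifest (log excluded: it carries wall-clock times)
  sum_lines <- character()
  if (length(summary)) sum_lines <- unlist(lapply(names(summary), function(st) {
    v <- summary[[st]]
    c(paste0("[", st, "]"),
      sprintf("%s = %s", names(v),
              vapply(v, function(x) format(x, digits = 6),
                     character(1))))
  }))
  writeLines(sum_lines, p("summary.txt"))
  files <- setdiff(list.files(out, recursive = TRUE),
                   c("log.txt", "manifest.tsv"))
  is_bam <- grepl("\\.(bam|bai|fai|amb|ann|bwt|pac|sa)$", files)
  manifest <- data.frame(
    file = files,
    md5 = ifelse(is_bam, "",
                 unname(md5sum(file.path(out, files)))),
    stringsAsFactors = FALSE)
  write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  svdLog("pipeline complete: ", nrow(manifest), " output file(s)",
         logfile = logf)
  list(out_dir = out, manifest = manifest, summary = summary)
}
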
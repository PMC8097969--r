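Package: svdiverge
Title: Structural Variant Discovery, Genotyping and Population
    Differentiation Between Diverged Genome Assemblies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for unbalanced structural variants (SVs) between
    two chromosome-scale genome assemblies: discovery from whole-genome
    alignments (within-alignment indels and between-anchor gap signatures),
    gap-region filtering, validation by re-alignment of 5-kb flanking
    sequences, refinement of complex repeat/tandem events using read-based
    calls, reciprocal-overlap merging, dual-reference split-read and
    read-depth genotyping of resequenced accessions, and population-level
    allele-frequency differentiation between morphotype groups using
    Fisher's exact test with Bonferroni correction. Includes a synthetic
    genome and read simulator with planted SVs and a machine-readable
    truth set, so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite
SystemRequirements: minimap2, bwa, samtools, blastn (NCBI BLAST+)
biocViews: StructuralVariation, VariantCalling, Genetics, Alignment,
    PopulationGenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'discovery-call.R'
    'discovery-filter.R'
    'discovery-flanks.R'
    'discovery-refine.R'
    'evaluate.R'
    'genotype-call.R'
    'genotype-evidence.R'
    'genotype-reads.R'
    'paf.R'
    'pipeline.R'
    'popgen.R'
    'sv-vcf.R'
    'synthetic-config.R'
    'synthetic-genomes.R'
    'synthetic-reads.R'
    'truth-io.R'
    'utils.R'
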
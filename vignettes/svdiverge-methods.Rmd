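---
title: "Methods: structural-variant discovery, genotyping and population differentiation between diverged assemblies"
author: "svdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV discovery, genotyping and differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`svdiverge` implements a complete workflow for *unbalanced* structural
variants (SVs) — insertions, deletions, unequal-length substitutions, and
repeat/tandem copy-number changes of 10 bp and larger — between two
chromosome-scale genome assemblies of closely related lineages (the
motivating system is a pair of *Brassica oleracea* morphotypes, cauliflower
and cabbage, whose assemblies are collinear apart from such events). The
workflow has five stages:

1. **Discovery**: SVs are read out of a minimap2 whole-genome alignment
   (genome A as target, genome B as query), both from each block's
   base-level CIGAR and from the gap signature between consecutive
   uniquely anchored blocks.
2. **Filtering and validation**: calls near assembly gaps are removed;
   the two 5-kb flanks of each call are re-aligned to the other genome
   (blastn) and the inter-hit gap must match the expected allele length.
3. **Refinement and merging**: complex repeat/tandem calls without
   defined breakpoints are replaced by overlapping read-based calls with
   precise breakpoints; the two call sets are merged at 50% reciprocal
   overlap.
4. **Genotyping**: resequenced accessions are aligned to *both* genomes;
   split reads and read depth at the breakpoints decide, per accession and
   SV, between homozygous-A, homozygous-B, heterozygous and undetermined.
5. **Population analysis**: per-group genotype composition, A-allele
   frequencies, a Fisher's exact differentiation scan with Bonferroni
   correction, window thinning, allele-sharing distances, PCA and a
   neighbor-joining tree.

A synthetic-data module generates genome pairs with planted SVs, accession
genomes as haplotype mosaics with known genotypes, and paired-end reads —
so every stage is testable with no external data, and every headline
statistic the package reports is computed against a known truth.

# Conventions

* `sv_type` always describes genome B relative to genome A: an
  "insertion" is sequence present in B and absent in A. `len_a` and
  `len_b` are the allele lengths on the two genomes regardless of which
  genome a record is anchored on.
* All in-memory coordinates are `GRanges`-style 1-based closed intervals;
  this is the native convention of every interval operation the package
  uses, and all on-disk formats state their own convention (BED is
  0-based half-open, VCF 1-based with a left-anchored base, truth tables
  1-based closed).
* Insertions are anchored at the single base left of the insertion point;
  deletions and substitutions span the affected anchor bases.
* One master seed fans out deterministically to per-stage seeds; all
  outputs (including gzip FASTQ) are byte-reproducible under a fixed seed.

# Discovery details

**Within-alignment events.** CIGAR `I`/`D` runs at least `min_size`
(10 bp) long become insertion/deletion calls with exact breakpoints;
mismatch (`X`) runs of that length become equal-length substitutions, and
an adjacent `I`/`D` pair within 5 bp is fused into one unequal-length
substitution.

**Repeat-context demotion.** An aligner is free to place an indel
anywhere inside a repeat array, so a CIGAR indel whose sequence resembles
its own flanking sequence (or is internally periodic) cannot be trusted
to single-base precision. Such events are demoted to
tandem/repeat-expansion/contraction calls with `precise = FALSE` and a
widened interval. The test is a global pairwise alignment of the event
sequence against the adjacent genome sequence on either side, at probe
lengths 200/50/25 bp, plus a self-alignment of the event's two halves;
identity at or above 80% marks repeat context (95% separates perfect
tandem from diverged repeat copies). The thresholds sit far above the
~50% identity of unrelated DNA and comfortably below the 97%
within-array identity the simulator plants; they are deliberately
insensitive over a wide range.

**Between-anchor events.** For consecutive uniquely anchored blocks
(mapping quality at least 40, anchor length at least 500 bp) the pair of
gap lengths on target (`tg`) and query (`qg`) classifies the event:
one side near zero gives an indel of the difference; both sides at least
`min_size` with a length ratio in [0.1, 10] gives a substitution; a
negative gap (anchor overlap) on one side gives a tandem
expansion/contraction, on both sides a repeat expansion/contraction —
all complex classes are `precise = FALSE`.

**Gap filter.** Gap regions are runs of at least 10 consecutive `N`s
(the length is configurable; assemblies mark gaps with long runs, and 10
is safely above spurious single Ns). An SV is removed when its anchor or
mate interval spans a gap or sits closer than 50 bp to one.

**Flank validation.** Both 5-kb flanks must produce reliable hits
(alignment length > 50 bp, identity > 90%, e-value < 1e-10) on the other
genome, on one chromosome and strand, inner ends facing, within 10x the
SV length + 20 kb of each other. The observed inter-hit gap is corrected
for unaligned query ends and compared with the expected allele length:
insertions (and any event with expected sequence on the other genome)
must deviate by less than 20%; deletions allow a gap or overlap below
3 bp. Backends are pluggable through a simple hit-table contract; the
default runs blastn, which reports e-values directly. A backend that
reports no e-value is accepted when hits meet the length/identity rule,
which on 5-kb flanks dominates the e-value clause under any standard
Karlin-Altschul parameterisation. Only precise calls are validated —
the size check presumes defined breakpoints — while complex calls
proceed to refinement instead.

**Refinement and merging.** A complex call containing at least one
read-based call within its interval (padded by 50 bp) is replaced by
those simple indels (`source = "merged"`, precise). Merging collapses
same-type records with reciprocal overlap at or above 0.5 — point
insertions are compared on their insertion-point interval padded by the
inserted-allele length — keeping assembly-derived breakpoints over
read-based ones (assembly comparison is the primary evidence), with
connected-component clustering so the output never contains a same-type
pair that meets the criterion, independent of input order.

# Genotyping details

Evidence is interpreted **cross-wise**: an accession carrying the A
allele maps cleanly to genome A but its reads break at the SV locus on
genome B — so split reads on genome B evidence the A allele, and vice
versa. A split read is a clip junction — soft clips on primary records
and hard clips on the supplementary records that aligners emit for the
other arm of a split read both count — of 5 bp or more (the breakpoint
window supplies specificity, and aligner score extension routinely
shaves a few bases off a junction clip), or a CIGAR indel of 10 bp or
more, within 10 bp of a breakpoint. Support for an allele needs
at least 3 split reads at *every* breakpoint of the locus on the opposite
genome, or — for loci where the opposite genome carries at least 50 bp of
sequence the allele lacks — the read-depth rule: less than 50% of the
event interval covered at 2x per-base depth while more than 50% of one
same-length flank is covered at 1x. The depth rule is restricted to
events of 50 bp and more because depth signal below read length is
unreliable. "Covered by reads with 2x depth" is read as per-base depth
at least 2; the alternative reading (read-pair redundancy) is noted but
not implemented. Heterozygotes require the full rule independently on
both genomes; no support anywhere yields undetermined.

Before alignment, duplicated read pairs are consolidated: two pairs are
duplicates when both mates agree over the class prefix (90 bp for 100-bp
reads, 100 bp for 150-bp reads). After alignment (single-threaded
`bwa mem`), records with more than 3% base mismatches are dropped; the
edit-distance tag is corrected for CIGAR indel bases so that reads
legitimately spanning an SV are not discarded by the very signal that
makes them informative.

# Population analysis details

Heterozygotes count as one copy of each allele:
`freq_A = (2 n_A + n_H) / (2 (n_A + n_B + n_H))`. SVs determined in
fewer than 50% of the accessions of either group are excluded, and the
Bonferroni correction multiplies by the number of SVs actually tested —
only tested hypotheses are corrected. The exact test is two-sided by
probability ordering: the p value is the sum of hypergeometric
probabilities of tables (at fixed margins) no more probable than the
observed one, with a relative tie tolerance of 1e-7 — the standard
convention, verified in the test suite against exhaustive enumeration
over every margin configuration with total count up to 60 and against
`stats::fisher.test`. The fold change is the ratio of the larger to the
smaller group frequency with the denominator floored at
`1/(2 x group size)`, so that a zero frequency (common at strongly
selected loci) cannot divide; selection requires adjusted p < 0.001 and
fold change of at least 2. The scan runs on the full filtered SV set;
window thinning (one random SV per 25-kb window, seeded) is applied for
the distance/PCA/tree summaries where linked loci would otherwise be
over-weighted. Distances are pairwise-complete mean allele-dosage
differences (genotyping rates vary widely between accessions, so
complete-case analysis would discard most loci); PCA runs on the
column-mean-imputed dosage matrix, and the tree is neighbor-joining on
the distance matrix.

# Annotation details

The promoter is the 2-kb window upstream of the annotated gene start on
the coding strand (the window length is configurable; no universal
definition exists for this genome). Gene body means the annotated
gene span including introns and UTRs. Any overlap counts as a hit, with
category precedence CDS > intron/UTR > promoter, and a gene is
"affected" when any SV touches its body or promoter. Genome/gene/CDS
coverage fractions are computed on the union of SV intervals. LTR
retrotransposon insertion times follow `T = S / (2 mu)` with
`mu = 1.5e-8` substitutions per site per year by default.

# The synthetic generator

Genome A is uniform random sequence at 36% GC (configurable) with
optional planted N-runs; genome B applies the planted SV set left to
right and adds background divergence of 0.5% single-base substitutions
outside SV loci — enough to emulate well-diverged but fully alignable
genomes of sister morphotypes, and safely inside the 90%-identity flank
rule. SVs are placed by rejection sampling with a minimum spacing
(10 kb at full scale, scaled down with the flank length in smaller
simulations) so flanks are unique; sizes are log-uniform within each
class's range (10 bp - 10 kb by default; the lower bound mirrors the
workflow's minimum SV size). Repeat/tandem classes plant two unit copies
on one genome and `2 + m` on the other, with 3% divergence between
copies for the "repeat" classes and exact copies for "tandem".

Accession genomes are two haplotype mosaics of the planted alleles;
heterozygous loci carry one allele per haplotype, so reads sample both at
~50:50. Fragments are uniform with Normal(450, 50) insert length; errors
are uniform per-base substitutions. The generator does **not** emulate
platform-specific error profiles, indel sequencing errors, coverage
biases, residual heterozygosity within an assembly, or the transposon
biology of real repeats — so passing tests demonstrate the correctness
of the calling/genotyping rules under clean mappable conditions, not
performance on real libraries. Read-based SV calls are emulated directly
from the truth set (optionally jittered), decomposing copy-number events
into their net indel left-aligned to the repeat locus — the form a
long-read caller reports.

# Problem sizes and determinism

The packaged checks run at desk scale, chosen as the largest sizes that
exercise every code path while keeping the whole suite comfortably
re-runnable: discovery on a 2-Mb pair with 100 planted SVs across all
seven classes; genotyping on 12 accessions x 40 SVs at 30x with 0.5%
read error and 25% heterozygous truth; the differentiation scan on two
groups of 50 with 50 contrasted (0.9 vs 0.1) and 450 null loci; and a
demonstration pipeline on a 150-kb genome rerun twice to confirm
byte-identical manifests. The real study behind this design measured
~120x sequencing of two reference accessions plus 271 resequenced
genomes; headline counts from data of that size are not reproducible at
desk scale, which is why the package's acceptance checks are
property-based (recall/precision, genotype accuracy, exactness of the
test statistic, power/size of the scan) rather than count-based.

Reported summary conventions: genotyping *accuracy* is the fraction of
determined calls matching truth; the *false-genotype rate* is
determined-but-wrong calls over all calls (determined plus undetermined),
mirroring how a genotyping error rate is quoted against a full reference
set.

The pipeline manifest checksums every path-free output; BAM files and
aligner index files embed command lines (hence absolute paths) in their
headers and are listed without checksums. Within one run directory all
outputs, including compressed FASTQ, are byte-identical under a fixed
seed.

# Known limitations

* Balanced rearrangements (inversions, translocations) are out of scope
  by design; the workflow presumes collinear assemblies.
* Complex-call allele lengths are approximate until refined; unrefined
  complex calls keep `precise = FALSE` and are excluded from the
  size-based flank check.
* The genotyper assumes the reference SV set carries coordinates on both
  genomes; calls lacking mate coordinates cannot be genotyped
  cross-wise.
* The depth rule can in principle also support insertion alleles (low
  coverage over the inserted sequence on the genome that carries it);
  the package applies it to any locus where one genome carries 50 bp or
  more that the other allele lacks, which covers that case, but the
  split-read rule remains the primary evidence.
* Whether flank hits should additionally be required to be colinear with
  the surrounding synteny (rather than merely co-located on one
  chromosome and strand) is an open modelling choice; co-location is
  implemented.
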
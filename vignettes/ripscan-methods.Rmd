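---
title: "Detecting retrotransposon insertion polymorphisms from discordant read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting retrotransposon insertion polymorphisms from discordant read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

LTR retrotransposons of the *Copia* and *Gypsy* superfamilies make up the
bulk of large plant genomes, and their insertion sites segregate within
species: a copy present in one accession may be absent in another. Such a
segregating site is a retrotransposon insertion polymorphism (RIP).
Cohorts of resequenced accessions — for maize, wild teosinte, early
domesticated landraces and modern improved lines — can be compared by
their RIP content the same way they are compared by SNPs: insertion
frequencies per group, shared and private loci, and population structure.

`ripscan` implements the read-pair evidence model behind this comparison
for low-coverage (4–8X) paired-end data, where assembling each genome is
not an option, together with a synthetic cohort generator so the whole
pipeline can be exercised and verified without any external sequencing
data.

## The evidence model

A TE insertion that is present in a sequenced accession but absent from
the reference genome leaves a characteristic footprint in paired-end
reads: fragments that straddle the insertion junction have one mate
inside the TE sequence and the other mate in unique flanking sequence.
The pipeline therefore:

1. builds a **family-labelled TE reference** from the genome and a TE
   annotation BED, keeping families with at least 20 annotated members
   (`load_te_annotation()`, `filter_families()`,
   `extract_family_sequences()`);
2. maps both mates of every pair against that TE reference; pairs where
   **exactly one** mate hits it are retained (`scan_pairs()` /
   `import_sam_evidence()`). TE families are internally repetitive, so
   any TE hit counts — uniqueness is not required on the TE side;
3. maps the TE-unmapped mate against the reference genome and keeps it
   only if it aligns **uniquely** — this anchor read localizes the
   insertion;
4. tiles the genome into fixed, non-overlapping 10 kb windows anchored at
   coordinate 0 and counts anchors per (family, chromosome, window). A
   window with **more than 3** supporting reads is called an insertion
   locus (`call_insertions()`, default `min_reads = 4`).

Two thresholds that look similar are deliberately distinct:

* the **call** rule is *strictly more than three* reads (`>= 4`);
* the **copy number** of an accession (per family) is the number of
  windows covered by *at least three* reads (`copy_number()`, default
  `min_reads = 3`).

Both defaults are exposed and documented rather than silently unified.

A called locus gets a representative **insertion point**: the lower
median of its anchor positions. This matters downstream — feature
classification and TSS distances need bp-scale positions, which window
midpoints cannot provide.

## The built-in mapper

In desk mode (synthetic data) the package maps reads itself instead of
shelling out to an external aligner: a canonical k-mer index
(`build_seed_index()`, `k = 31`) plus seed-and-extend ungapped comparison
(`map_reads()`). Four evenly spaced seeds per 100 bp read are looked up;
candidate loci supported by at least 2 seeds on one diagonal are scored
by full-length mismatch count (C++ kernel), and a read is *unique* when
one locus passes the 5% mismatch budget, or when the best locus beats the
runner-up by at least 2 mismatches. The mapper is ungapped by design:
the simulator emits substitution errors only, and real data enters
through the SAM import path (`import_sam_evidence()`), where *unique*
means primary, non-secondary/supplementary, MAPQ ≥ 20 (the conventional
cutoff, exposed as a parameter).

Validation against an alternate assembly (`validate_against_assembly()`)
mirrors the classic check against a second complete genome: for every
called locus, the 2 kb reference flanks of the insertion point are
located in the alternate assembly and the TE-mate sequences of the
supporting pairs are searched between them. An assembly that truly
carries the insertion contains the TE between the flank copies, so the
TE mates match; the bare reference does not, so they fail.

## The synthetic cohort

`cohort_spec()` / `generate_cohort()` emulate the statistical structure
the analysis assumes, with defaults chosen as the package's reference
conditions: one 2 Mb chromosome; three TE families of 5 kb with 25
slightly diverged (1%) copies planted in the reference; three groups of
four accessions (teosinte, landrace, improved); insertion pools of 10
loci shared by everyone, 15/30/5 group-specific loci, and 5 private loci
per accession; 5X coverage of 2×100 bp pairs with 300 ± 30 bp fragments
and 0.5% substitution error; master seed 7. The landrace > teosinte >
improved pool asymmetry mirrors TE amplification during domestication
and contraction during improvement; the 0.5% error rate is a test
convenience, not an empirical value. Families are assigned to pool loci
round-robin so every family participates in every pool — a balanced
design that keeps per-family group comparisons meaningful at this scale.

Insertion loci are rejection-sampled at least 2 fragment lengths away
from each other, from the planted reference copies and from chromosome
ends, because the evidence model itself requires unique flanking
sequence. Donor genomes realize insertions literally (a full family copy
spliced in at the truth position, recorded in reference coordinates);
reads are simulated per accession with a seed salted by the accession
name, so generation is order-independent. What the generator does *not*
model: indels, base-quality profiles, target-site duplications, nested
or heterozygous insertions, GC bias. Passing tests therefore demonstrate
the logic of the pipeline, not its performance on real maize data.

## What the recovery tests can and cannot show

Detection sensitivity is governed by junction-fragment arithmetic. A
fragment supports an insertion only when one mate lies fully in the TE
and the other fully in the flank, which requires the fragment start to
fall in a stretch of length about `f − 2L` per junction (`f` = fragment
length, `L` = read length). With the reference conditions
(`f = 300 ± 30`, `L = 100`, 5X coverage → fragment-start density ρ =
0.025/bp), the expected support per insertion is roughly
`λ = 2(f − 2L)ρ ≈ 5–6` read pairs, and the strict `>3` call rule then
recovers about `P(Poisson(λ) ≥ 4) ≈ 0.86` of planted insertions —
measured window-level recall on the reference cohort is 0.86 at
precision 1.0. Deeper coverage or longer fragments push recall toward 1;
at these fixed reference conditions the miss rate is a property of the
method itself (evidence thinly spread around a Poisson mean near the
call threshold), not an implementation artifact.

## Reference-resident elements and masking

The reference genome's own TE copies produce anchor evidence in *every*
accession: a read pair straddling the edge of a planted copy is a
perfectly valid discordant pair. Those windows are therefore called
everywhere and are not polymorphisms. The caller does not mask them by
default (whether the original analysis did is unknown), but
`mask_calls()` drops call windows that overlap the TE annotation
(±1 window), and all cohort-level statistics in `run_pipeline()` and the
acceptance script are computed on masked call sets. On the reference
cohort the difference is visible: with reference windows left in, every
group's frequency spectrum is compressed toward 1 (the shared windows
dominate) and the mean-frequency ordering of groups is scrambled; with
masking, the designed landrace > teosinte > improved ordering is
recovered and the three groups separate cleanly in PC space.

## Population statistics

* **RIP matrix** (`build_rip_matrix()`): accessions × loci presence/
  absence, a locus being a (family, chromosome, window) triple — two
  families in one window are two loci, consistent with per-family
  summaries.
* **Group sets and Venn** (`group_rip_sets()`, `venn_counts()`): a group
  carries a locus when at least one member does; the 7-region partition
  is reported with unique and triple-overlap fractions of the union.
* **Insertion frequency** (`insertion_frequency()`): carriers / group
  size, like an allele frequency. Per-family means average over the
  loci detected in that group (the averaging set is configurable to
  cohort-detected). A **common RIP** has frequency strictly above 0.2.
* **Copy-number summaries** (`family_copy_number_summary()`): plain
  group means; group distributions are compared with a two-sided
  Wilcoxon rank-sum test by default (the counts are skewed and group
  sizes small; Welch's t-test is available), significance marked at
  p ≤ 0.05.

## Population structure

Presence/absence is encoded as homozygous dosage (1 → 2, 0 → 0) — the
coding a ped-file conversion of binary markers produces; heterozygotes
are not representable in this evidence model. Monomorphic loci are
removed (the standardization is undefined there), each locus is
standardized as `w = (x − 2p)/sqrt(2p(1−p))`, and the genetic
relationship matrix is `A = WW'/m`. Principal components are the leading
eigenpairs of `A`, coordinates scaled by the square root of the
eigenvalue. Two conventions make results deterministic: each
eigenvector's largest-magnitude entry is made positive, and eigenvalues
below 1e−9 of the spectrum are treated as exact zeros so duplicated
accessions get exactly identical coordinates. Note that for fully
homozygous lines the GRM diagonal is near 2 (1 + F with inbreeding
F = 1), and two complementary accessions at p = 0.5 have relationship
−2 — the natural scale of this standardization for inbred material.

## Genomic context

Calls are treated as points (their insertion point) and classified with
precedence exon > intron > up2kb > down2kb > intergenic; flanks are
strand-aware. TSS distance is the unsigned distance to the nearest
strand-aware 5′ gene end. Density correlation bins insertion points and
gene starts into fixed windows (1 Mb on real-scale genomes; tests use
smaller bins since a 2 Mb toy chromosome yields too few 1 Mb bins) and
reports Pearson's r. The metagene profile rescales gene bodies to 100
bins with 40 × 50 bp flank bins on each side, flips minus-strand genes,
and normalizes to sum 1. Upstream enrichment compares per-gene anchor
counts between two groups after normalizing by group size; the ratio
test is inclusive (≥ 5), a zero numerator never qualifies, and a zero
denominator is guarded by a pseudocount of 1/group size so strong signal
over an empty background still counts — the guard form was chosen so
that a locus at exactly the cutoff ratio with a non-zero denominator is
included, as the inclusive rule demands.

## Numerical and tie-breaking choices

* Window index is floor division; windows are half-open.
* Insertion point is the *lower* median of anchor positions.
* The mapper's uniqueness margin is 2 mismatches over the runner-up.
* `venn_counts()` requires exactly three sets; regions are reported in a
  fixed order.
* Degenerate inputs return `NULL` with a warning rather than erroring
  (empty frequency sets, zero-variance bins, flank ≤ 0, no called
  windows), so cohort loops do not abort on one empty accession.

## Problem sizes in the test suite

The unit tests run on a 300 kb six-accession cohort (seconds); the
end-to-end acceptance checks run the full reference cohort above (a few
minutes) plus an error-free variant of it for assembly validation, with
one accession per group. These sizes were chosen so the whole suite
exercises every stage, including the mapper, at desk scale.

## Known limitations

* Window resolution: two insertions of the same family within one 10 kb
  window are one locus; breakpoints are not base-pair precise.
* The built-in mapper handles substitutions only; indel-containing reads
  fall to unmapped (real data should come through SAM import).
* Copy number is a windowed proxy, not a sequence-depth estimate.
* No multiple-testing correction across families in the group
  comparisons, and no GO/pathway analysis of enriched gene lists — the
  gene list TSV is the final output.
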
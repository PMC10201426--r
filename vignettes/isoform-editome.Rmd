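---
title: "Methods: isoform-resolved editome and RIP-seq peak analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-resolved editome and RIP-seq peak analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoedit)
```

## The scientific problem

ADAR1 deaminates adenosine to inosine (A-to-I) in double-stranded RNA;
sequencers read inosine as guanosine, so editing appears as A→G on the
transcribed strand (T→C when the reverse strand is sequenced). ADAR1 exists
as two isoforms from alternative promoters — interferon-inducible,
mainly cytoplasmic ADAR1p150 and constitutive, nuclear ADAR1p110 — and
their target repertoires differ in ways that matter for innate-immune
homeostasis. `isoedit` implements the computational side of an
isoform-comparison study design: each isoform is expressed separately (in
triplicate, next to an editase-free negative control) in editing-deficient
cells, editing at known sites is profiled per replicate, and a parallel
RIP-seq experiment (IP and matched input per replicate, plus a
MOCK-transfected control) maps where each isoform binds.

The package provides four analysis engines — editome classification,
RIP-seq peak post-processing, amplicon quantification, and overlap
analysis — plus a seeded synthetic-data generator that emulates the study
design with planted ground truth, so every pipeline property is testable
without any sequencing download.

## Editome classification

Input is a long per-site, per-sample table: coverage and A→G-supporting
read count at each known editing site (1-based positions; `alt_count`
counts A→G on plus-strand sites and T→C on minus-strand sites; zero
coverage is treated as missing data, never as zero frequency). The cascade
is fixed and each stage only removes or annotates sites:

1. **Control subtraction.** Any site with ≥ 1 alternative read in any
   negative-control replicate (at control coverage ≥ 5) is excluded as a
   presumptive SNP or artifact.
2. **Basic filter**, per replicate: editing rate ≥ 1% *and* coverage ≥ 5
   reads (both inclusive).
3. **Replicate consistency:** the basic filter must pass in ≥ 2 of 3
   replicates of at least one isoform condition. The coverage clause is
   applied inside the per-replicate call because the two criteria are
   introduced together as one "edited" definition.
4. **Coverage filter:** in *each* isoform condition, ≥ 2 replicates with
   data and mean coverage over replicates-with-data ≥ 10. We read
   "average over at least two replicates" as mean-over-available-data (not
   mean of the two best), the more conservative arithmetic.
5. **Efficiency call** per isoform: rate ≥ 1% *and* coverage ≥ 10 in the
   same ≥ 2 replicates.
6. **Preference label** from the unweighted condition means of replicate
   frequencies: `shared` when both means ≥ 1%; `p150_preferential` /
   `p110_preferential` when one mean ≥ 1% and the other strictly < 1%
   (the boundary is made disjoint — a site at exactly 1% on both sides is
   `shared`); `unclassified` otherwise. A preferential site is
   `exclusive` when every replicate of the other condition has zero
   edited reads — the strictest reading of exclusivity.
7. **log2 fold-difference**, the preference statistic:
   `log2((100·mean_p110 + 1) / (100·mean_p150 + 1))` — percent scale with
   a pseudocount of 1 so the ratio is finite at unedited sites; negative
   values mean p150 preference. It is antisymmetric under swapping the
   isoforms.
8. **Statistics.** A two-sided Welch (unequal-variance) t-test on the
   per-replicate frequencies; the test flavor is a package choice, matching
   the per-replicate granularity of the means. The degenerate
   zero-variance-equal-means case is defined as p = 1. Multiplicity is
   handled with Storey q-values (below); the conventional working cutoff
   in this design is q < 0.25.
9. **Annotation.** Region labels use the fixed priority
   5UTR > 3UTR > Exon > Intron > Downstream > Intergenic, strand-aware,
   with a configurable downstream window (default 3000 nt) past the
   transcript 3' end. Repeat classes (SINE/LINE/LTR/DNA/simple/other, or
   `nonrepetitive`) are assigned by largest overlap, ties broken by that
   fixed class order.

Condition means are unweighted means over replicates with data rather than
pooled counts, so one deep replicate cannot dominate, and the same numbers
feed the t-test.

### Storey q-values

π0 (the fraction of true nulls) is estimated on the λ grid 0.05–0.95
(step 0.05) from `#\{p > λ\}/(n(1−λ))` with a cubic smoothing spline
(df = 3) evaluated at λ = 0.95, falling back to π0 = 1 when fewer than
100 p-values are available or the estimate exceeds 1, and floored at 1/n.
Then `q_i = π0 · min_{p_j ≥ p_i} (n·p_j / rank_j)`, which is monotone in p
and bounded by 1. With π0 pinned to 1 the procedure *is*
Benjamini–Hochberg, and the test suite asserts exact agreement with
`p.adjust(method = "BH")` on random vectors up to n = 10^4^.

## RIP-seq peak post-processing

Aligned fragments enter as interval sets (BED; mate pairs as two records
named `…/1`, `…/2`). The chain per condition:

1. **Pair splitting.** Each mate becomes its own single-end interval;
   treating a pair as one long fragment would call peaks across unread
   interior (whole introns).
2. **Strand split.** The caller is not strand-aware, so `chrN` is folded
   into pseudo-chromosomes `chrN__fwd`/`chrN__rev` and peaks are mapped
   back afterwards; the transform is a bijection.
3. **Internal enrichment caller.** A deliberately minimal input-normalized
   Poisson caller — not a re-implementation of any external tool. In
   genomic mode reads are extended to `extsize` (38 nt) from the 5' end;
   per-base IP pileup is tested against
   `λ_local = max(λ_BG, s·mean_1kb(input), s·mean_10kb(input))` with `s`
   the IP/input library-size ratio and `λ_BG = N_IP·extsize/gsize`;
   survival p-values are BH-adjusted across all `gsize` bases and bases
   with q < 0.01 form peaks. Significant runs separated by fewer than
   `max_gap` bases (default 100 nt, the library fragment scale) are
   stitched: a sub-fragment coverage dip cannot evidence absence of
   binding, and without stitching boundary noise fragments single binding
   regions into satellite peaklets. The effective genome length default
   (6 199 501 436 genomic; 289 357 337 transcriptomic) doubles the genome
   because the strand split doubles the address space. Transcriptomic mode
   skips the extension and uses fragments as given; transcriptomic peaks
   projected to genomic coordinates can be deduplicated with
   `remove_subpeaks()` (containment across different transcripts).
4. **Replicate consensus.** A replicate peak is kept only if it overlaps
   or is book-ended (gap exactly 0 — "adjacent" read literally) with a
   peak of a *different* replicate; retained peaks are then union-merged
   into one list per condition.
5. **MOCK subtraction.** For each condition peak, the fraction of *its*
   length covered by the union of overlapping MOCK peaks decides: > 90%
   covered → removed entirely; otherwise the covered bases are excised and
   the remaining fragments inherit the parent's scores. The denominator is
   the condition peak (the feature being removed), which is also what the
   standard interval-toolkit implementation of such a rule computes; the
   alternative mock-denominator reading is noted as open.
6. **Filters.** Minimal peak size 40 nt (inclusive) and reference
   chromosomes chr1–22, X, Y (chrM excluded). An arbitrary exclusion BED
   (e.g. an artifact blacklist) can be applied to fragments before
   calling.

`peak_stats()` reports counts, mean/median sizes and *directional* overlap
counts: a peak of one condition may overlap several of the other, so the
two directions legitimately differ.

## Amplicon quantification

Deep pileups at a known-site panel across editase constructs. Frequency is
`G/(A+G)` on plus-strand sites and `C/(T+C)` on minus-strand sites — the
informative bases only, robust to unrelated mismatches (a package choice).
The negative-control background is subtracted per site (floored at 0, the
control column kept for reporting), rows with no construct reaching 0.5%
(inclusive) are dropped, and each row is divided by its maximum across
non-control constructs, so the best editase scores exactly 1 (ties all
become 1) and the rest are proportions of it. Normalization excludes the
control column because background is not an editase. The procedure is
invariant to positive rescaling of a row. Replicates electroporated at
different plasmid doses are kept as separate construct columns, not
pooled.

## Overlap analyses

Site-vs-peak intersection uses the single-base interval of a site
(1-based position p ↔ half-open `[p−1, p)`; the test suite checks the
boundary in both directions), optionally strand-aware. Gene-level overlap
compares genes carrying qualifying (optionally non-repetitive) editing
with peak-bound genes; a peak's gene set is any gene whose transcript
features it touches. Replicate-support grouping applies rule families like
"edited in ≥ 2/3 p150 replicates and 0/3 p110 replicates" to external
tables ("edited" defaults to frequency ≥ 1%, consistent with the editome
module, but is configurable because external tables may carry their own
calls); the coverage gate keeps sites with mean coverage ≥ 10 in every
genotype group. Genome-build liftover is out of scope; only
chromosome-name compatibility is checked.

## The synthetic-data generator

`synthetic_config()` fixes the study conditions; every generator is
byte-deterministic under the master seed (per-generator streams are
derived with fixed offsets).

* **Toy genome and annotation:** 3 chromosomes of 600 kb; 120
  non-overlapping transcripts, each 5'UTR + 3–6 exons with introns +
  3'UTR, mirrored on the minus strand; repeats tiled with class-typical
  lengths and a SINE-dominated class mix.
* **Editome:** 500 sites per category at the defaults — p150-specific
  (latent frequency 0.10 vs 0), p110-specific (0 vs 0.10), shared
  (0.10/0.10), below-threshold (0.002, exercising the 1% rate cutoff) —
  plus 78 SNP-like artifact sites (latent 0.5 in every condition including
  the control) and a few hyperedited genes with 20 clustered
  isoform-specific sites. Coverage is negative binomial (mean 50,
  size 10); edited reads are binomial given coverage. The editase
  conditions carry a 0.1% A→G error floor so sub-threshold noise is real;
  the editase-free control carries alternative reads *only* at the planted
  SNP-like class. That asymmetry is intentional: in this design the
  profiler only reports known editing positions after stringent
  base-quality filtering, where an editase-free control exhibits a small
  SNP-like mismatch set rather than a uniform error carpet, and it is
  exactly that set the control-subtraction rule exists to remove. Region
  and repeat contexts follow per-category mixes (p110-specific sites
  mostly intronic, p150-specific biased to 3'UTRs, p150 more often
  non-repetitive).
* **RIP:** truth binding regions default to 1000 nt — the scale of
  extended duplex-forming regions and of mean genomic peak sizes in this
  kind of experiment — drawn from exon/3'UTR features for p150 and introns
  for p110, plus 8 `nonspecific` regions enriched in every IP including
  MOCK (these must vanish in subtraction). Input fragments are uniform
  over both strands; IP fragment starts get extra mass on
  `[peak_start − fragment_length, peak_end)` of the peak strand, making
  the overlapping-fragment density inside a truth peak exactly
  `rip_enrichment` × input (8× by default) with sharp edges. 10^5^
  fragments of 150 nt per sample, 90% emitted as 38-nt mate pairs and the
  rest as single-end records; 3 replicates per isoform, 2 for MOCK, each
  with its own input.
* **Amplicon:** 17 panel sites, coverage 5000, base frequencies 0.05–0.5,
  per-construct effect multipliers drawn from archetypal preference
  profiles (or supplied explicitly), a zero-editing control, and a 0.1%
  background miscall rate.

What the generator deliberately does *not* model: alignment and mapping
artifacts, position-dependent error profiles, overdispersion of editing
across replicates beyond binomial sampling, correlated fragment sampling
(PCR duplicates), splicing of peaks across exon junctions, and real repeat
sequence content. Passing recovery tests therefore demonstrates the
correctness and calibration of the pipeline's logic under the declared
noise model, not performance on real libraries.

## Numerical and design notes

* Intervals are 0-based half-open (BED-native) everywhere; point sites are
  1-based (profiler-native); the only conversion is `p ↔ [p−1, p)`,
  tested in both directions. Interval arithmetic is delegated to
  `GenomicRanges`/`IRanges` and verified against per-base brute-force
  oracles on random instances.
* Readers reject invariant violations (with line numbers) instead of
  coercing; writers emit deterministic column and row order so identical
  inputs give byte-identical files.
* Heatmap-style orderings (classification output sorted by ascending
  log2FD, ties by site key) are plumbing choices, documented here.
* The Welch statistic, the λ grid, all thresholds and the caller windows
  (1 kb / 10 kb) are fixed constants of the pipeline, overridable through
  the respective config lists.
* Problem sizes used by the test-suite recovery checks: the full default
  configuration (about 2 100 sites × 9 samples; 16 fragment samples of
  10^5^ fragments) for the planted-truth checks, and reduced toy
  configurations for unit-level properties. These sizes give tight
  binomial/Poisson error bars while keeping a complete run in a couple of
  minutes on one core.

## Known limitations

* The internal caller is a minimal model of input-normalized peak calling;
  it does not implement fragment-model estimation, summit refinement, or
  duplicate-removal policies other than keep-all.
* Exclusivity ("zero edited reads in the other condition") is sensitive to
  sequencing depth: with deeper coverage, error reads alone will defeat
  it. The preferential labels are the robust quantity.
* π0 estimation with the cubic smoother is unstable for small n; the
  fallback to 1 (plain BH) is conservative.
* `group_by_support()` and `coverage_gate()` are generic table operations;
  they do not attempt to reproduce any external study's site lists.
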
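---
title: "Inferring co-amplified X/Y genes from male/female read coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring co-amplified X/Y genes from male/female read coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coampscan)
library(dplyr)
```

## The model

All inference in this package rests on one observation about read depth in
a male/female resequencing design. A male carries one X, one Y and two of
each autosome; a female carries two Xs and two of each autosome. A gene
family with `nX` X-linked, `nY` Y-linked and `nA` autosomal copies is
therefore sequenced, per haploid-copy depth `d`, at expected depth
`d (nX + nY + 2 nA)` in the male library and `d (2 nX + 2 nA)` in the
female library, so its library-size-normalized male/female coverage ratio
has expectation

$$
E\left[\frac{M}{F}\right] = \frac{n_X + n_Y + 2 n_A}{2 n_X + 2 n_A}.
$$

Single-copy autosomal genes sit at 1, single-copy X-linked genes at 0.5,
and Y-amplification pushes the ratio up without bound; Y-specific sequence
has no female coverage at all. The same arithmetic applies per scaffold and
is what lets a neo-X — an ancestrally autosomal Muller element recently
fused to the sex chromosomes — be recognized: its scaffolds sit one
doubling below the autosomal coverage level.

Because reads are mapped to a *single* reference peptide per gene, all
copies of a family — including diverged Y copies — contribute to one
coverage profile; the method measures family copy number, not per-copy
positions. This is what makes it work without a Y assembly, and also what
limits it: it cannot say where the copies are, and cross-mapping between
paralogous families inflates coverage for all of them (a documented caveat
of the screen, not corrected here).

## The calling rules and their parameters

The pipeline applies fixed, configurable rules, each with a deliberate
default:

* **Window size, 30 aa.** Depth over each reference peptide is the mean
  per-residue hit coverage in non-overlapping 30-amino-acid windows
  (`window_coverage()`); a trailing window keeps its true residue count as
  denominator, so short peptides are not biased by a dropped or padded
  tail. Thirty residues is roughly one translated 100-bp read.
* **Median-based ratio.** The gene's M/F ratio is the median male window
  depth over the median female window depth, after dividing each library by
  its total mapped reads (`mf_ratio()`; reported per million mapped reads).
  Medians make the ratio robust to locally repetitive windows. The median
  of an even number of windows is the mean of the two central values. If
  the female median is zero with male coverage present the ratio is
  infinite and the gene is reported as putatively Y-specific but *not*
  called Y-amplified; if both are zero the gene is flagged `no_coverage`
  and excluded.
* **Y-amplification cutoff, M/F ≥ 2.5, X-linked parent**
  (`call_y_amplified()`). The cutoff corresponds to `nY ≥ 4` extra Y copies
  for a single-copy X parent and deliberately trades sensitivity for
  specificity; `cutoff_sweep()` reports calls across a cutoff grid
  (default 2.5–10) so the choice can be examined. The parent-linkage
  requirement restricts calls to genes whose ancestral copy is X-linked.
* **X-duplicate rule, E ≤ 1e-20 and ≥ 25% of the CDS at > 1 locus**
  (`call_x_duplicated()`). Nucleotide hits of the parent CDS against the
  female assembly are E-value-filtered, strand-normalized and merged into
  distinct genomic loci when their reciprocal overlap exceeds 50% (both
  intervals; configurable). "Aligned to more than one location" is
  evaluated per CDS base as coverage by ≥ 2 distinct loci; the parent locus
  counts as one of the locations (`exclude_parent_locus = TRUE` inverts
  this reading). Note that each exon of a multi-exon parent yields its own
  subject interval, so the raw locus count overcounts "locations" for
  multi-exon genes; the per-base maximum locus count (`n_loci_max_cov`),
  which equals the genomic copy number for full-length copies, is what the
  co-amplification stage uses as the X copy number.
* **Scaffold linkage, 5 kb minimum, ±0.35 log2 bands**
  (`classify_linkage()`). Scaffolds are assigned to Muller elements by a
  strict majority of their genes' homology labels (ties unassigned). The
  autosomal baseline is the median log2 M/F of scaffolds on user-declared
  autosomal elements, or the mode (kernel density argmax) of the scaffold
  log2 distribution when none are declared — robust to a neo-X element as
  long as most scaffolds are autosomal. A scaffold is X when its offset
  from the baseline is within ±0.35 of −1, autosomal within ±0.35 of 0,
  Y at ≥ +1 or infinite ratio, else ambiguous. The band width is a
  classification decision, not an empirical constant: the distributions it
  separates are one doubling apart, and ±0.35 splits the gap while
  tolerating Poisson scatter at ≥ 10× scaffold depth. Read counts are
  assumed to come from mapping-quality ≥ 20 alignments (an upstream,
  aligner-side contract, as are all counts this package consumes).
* **Co-amplification** (`call_coamplified()`): Y-amplified and ≥ 2 copies
  on the X, operationalized as a positive duplicate call for the X-linked
  parent. Y copy number is estimated by inverting the expectation above,
  assuming all non-Y copies are X-linked unless autosomal loci are
  supplied. Enrichment of annotation categories among candidates uses the
  exact one-sided hypergeometric tail (no mid-p, no continuity
  correction).
* **Expression screen** (`screen_expression()`): testis sense RPKM ≥ 2,
  antisense ≥ 75% of sense (compared on RPKM; ties pass, per "at least"),
  small-RNA RPKM ≥ 100 with the small-RNA library's own total as
  denominator (it is a separate library from the stranded RNA-seq one).
  RPKM uses the gene-model length as provided. Multi-mapping of small RNAs
  across paralogs is not re-resolved; counts are taken as given.

## What the synthetic generator emulates

`simulate_cohort()` generates every input the pipeline consumes, with known
truth: a peptide reference; gene models with 1–3 exons on either strand,
placed on scaffolds of the configured Muller elements and linkage classes;
male and female translated-hit tables; nucleotide-hit tables with one
exact full-length locus per assembled (X or autosomal) copy plus occasional
weak decoy hits for the E-filter to remove; per-scaffold read counts; and
stranded expression counts. Identical seeds give byte-identical outputs.

Hit counts follow the Poisson depth model the callers assume: per window,
counts are `Poisson(d × copies × n_residues / read_length)` with each hit
spanning one whole window, so window depths are exactly independent
Poisson draws with mean `d × copies`. We emit window-aligned hits rather
than uniformly-placed ones deliberately: uniform placement of read-sized
hits adds edge depression and between-window correlation which bias the
ratio-of-medians estimator upward by about 1% at 20× depth — an estimator
artifact of no biological interest that would otherwise dominate the
Monte-Carlo anchor checks. Scaffold read counts are Poisson with ploidy
factors (autosome 2/2, X 1/2, Y 1/0 for male/female); expression counts
are Poisson around configured RPKM targets.

Default study conditions, chosen once: per-copy genomic depth 20× per sex
(10× per-bp for scaffold counts), 30-aa read footprint, 2×10^7-read
background per genomic library (a realistic Illumina resequencing scale;
it keeps total-mapped-read normalization non-trivial while ensuring, as in
a real genome, that a handful of amplified genes does not shift the
library totals), stranded RNA library 2×10^7 and small-RNA library 10^7
reads. The demo cohort plants 60 genes: 20 co-amplified (nX ∈ {2,3},
nY ∈ {12..32} — combinations whose expected ratio is ≥ 3, i.e.
amplification strong enough to be detectable at the 2.5 cutoff; a gene at
expected ratio exactly 2.5 sits on the decision boundary and is called in
half the replicates by construction), 20 Y-amplified-only (nX = 1,
nY ∈ {8..32}) and 20 single-copy genes, on 75 scaffolds spanning elements
A–E with element D planted as a neo-X and 8 Y contigs.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error, GC and mappability bias,
cross-mapping between distinct gene families, diverged Y copies losing
mappability (an optional per-copy identity degradation exists but affects
only the reported percent identity), collapsed duplicates in the female
assembly, and partial-length copies. On real data the method is
conservative: assemblies collapse recent duplicates and fragmented
multi-copy genes depress coverage-based copy estimates.

## Numerical choices and degenerate inputs

Infinite ratios are first-class values: they serialize as the literal
token `inf` in TSV output and round-trip losslessly. Zero library totals,
empty cutoff grids, overlapping exons, hits outside their peptide or exon,
and impossible contingency tables all raise immediate, named errors rather
than propagating. Ambiguity is preserved, not resolved: tied Muller votes
leave a scaffold unassigned, scaffolds between the log2 bands are
`ambiguous`, and genes present in only one caller's output carry a
missing-data status and are never called.

Problem sizes in the test suite are scaled for a desktop run: oracle
equivalence uses 1,000 random windowed-coverage instances, 500 duplication
instances and every contingency table with N ≤ 60; Monte-Carlo anchors use
200 replicate cohorts; the end-to-end check runs the 60-gene demo over 20
seeds. The anchor checks compare against the analytic expectations within
three standard errors; cohort-level checks use the planted truth.

## Worked run

```{r demo}
run <- run_coamp_pipeline(simulate_cohort(sim_config(), seed = 42))
run
glance(run)
run$sweep
head(tidy(run))
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(run, "scaffolds")
```

## Known limitations

Beyond the generator caveats above: the linkage thresholds assume a
male-heterogametic XY system; the copy-number inversion assumes all non-Y
copies X-linked unless told otherwise and inherits any bias in the M/F
ratio linearly; the screen's RPKM thresholds are tuned to testis libraries
of typical depth and should be revisited for shallow libraries; and the
package never attempts to place Y copies or reconstruct family histories —
it is a screen, whose candidates merit assembly-level follow-up.
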
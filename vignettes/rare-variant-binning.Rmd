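---
title: "Knowledge-guided rare-variant binning: model, statistics, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided rare-variant binning: model, statistics, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single rare variants are too sparse to test individually: at minor allele
frequencies below a few percent, realistic case/control cohorts contain a
handful of carriers per site, and per-site association tests have essentially
no power. Burden (collapsing) methods aggregate the rare variants inside a
biologically meaningful feature — a gene, a pathway, an exon set — into one
*bin*, count each individual's rare alleles across the bin, and test whether
that burden differs between cases and controls. The aggregation step, not the
test, is where the biology enters: the bin boundaries decide what is
aggregated, and a flexible, knowledge-driven binning layer lets one hypothesis
(genes) be swapped for another (pathways, exons within pathways, predicted
risk variants) without building a new pipeline.

rarebin implements that layer: a small local knowledge base of *regions*
(genomic intervals: genes, exons and the like) and *groups* (named region
sets: pathways), per-group allele-frequency computation from VCF genotypes,
rarity calls, bin construction, per-individual burden matrices, a Wilcoxon
rank-sum / Bonferroni testing layer, and a simulation harness that reproduces
the operating characteristics (type I error, power, spike-in recovery)
expected of this design.

# The binning model

**Minor allele frequency.** At each locus the MAF in a phenotype group is the
frequency of the *second most frequent* allele among that group's observed
(non-missing) alleles. For a biallelic locus this is the rarer allele; for a
polyallelic locus the third and later alleles do not raise the MAF. When the
top two frequencies tie (50/50), the tied frequency is the MAF and the major
allele is chosen lexicographically (logged); the choice only affects which
allele is *not* counted.

**Rarity.** A locus is rare iff its MAF is **strictly** below the threshold
in the case group *or* in the control group. The strict inequality is a
documented boundary: MAF exactly equal to the threshold is not binned
(a locus at 0.049 is binned at threshold 0.05; one at 0.05 or 0.08 is not).
Judging rarity per group rather than on the pooled sample means a variant
common in one group and rare in the other still enters a bin — that is what
lets bins accumulate protective as well as risk variants. When a group
triggers rarity, *all* of that group's non-major alleles are binned
identically; when both groups trigger, the per-group non-major sets are
unioned. Loci monomorphic across both groups have no minor allele to count
and are dropped before binning, so a threshold of 1.0 bins exactly the
polymorphic loci.

**Burden.** Counting is additive: an individual contributes 0, 1 or 2 binned
alleles per locus (a genotype carrying two *different* binned alleles also
contributes 2); missing calls contribute 0. Frequencies use observed-allele
denominators, the standard convention where missingness is simply absent
data.

**Feature bins.**

* *Gene bins*: one per gene region containing at least one rare locus within
  its 1-based, both-ends-inclusive boundaries. Overlapping genes each receive
  the locus; bins are deliberately allowed to be non-independent.
* *Pathway bins*: one per knowledge-base group, holding the deduplicated
  union of the member genes' rare loci — a locus shared by two member genes
  is never double-counted.
* *Intergenic bins*: each chromosome is tiled from position 1 into fixed,
  non-overlapping windows of 50 kb (configurable); a window is emitted only
  when it holds a rare locus assigned to *no* emitted gene or pathway bin.
  The tiling is anchored at the chromosome start rather than between genes —
  the simpler convention, and the one that makes window identity independent
  of the gene set. Window k (0-based arithmetic) is labelled with its
  1-based ordinal, e.g. position 120,000 falls in `chr1:window_3`,
  covering [100001, 150000]. Feature selection fully drives assignment: in an
  intergenic-only run, a locus inside a gene is unassigned and falls into its
  window.

**Complex binning.** Two refinements subdivide bins before testing. The
exon/intron split replaces each gene or pathway bin by `_exon` and `_intron`
halves — a locus is exonic iff it lies in any exon region of the bin's own
gene(s), matched by label — dropping empty halves; the configuration may keep
only one half. The prediction split partitions a bin by functional-prediction
category (`_risk`, `_benign`, ...); loci with no prediction record are
excluded from all split bins, which mirrors how prediction-filtered analyses
silently drop unscored variants — a documented cost of that mode.

# Statistical testing

The testing layer is deliberately minimal, reflecting the design position
that binning and testing are separable: the bin matrix is the product, and
any test can be applied to it. The bundled test is the two-sample Wilcoxon
rank-sum on case vs control burden, two-sided because bins mix risk and
protective variants.

Burden values are heavily tied small integers, so the implementation treats
ties explicitly:

* **Exact mode** (min(n1, n2) <= 8 and at most 2e5 arrangements): the
  two-sided p is computed by full enumeration of the permutation distribution
  of the rank-sum statistic — exact under ties, unlike the classical
  distribution of the statistic.
* **Normal approximation** otherwise: midranks, tie-corrected variance, and
  a continuity correction, matching the standard large-sample treatment.

Degenerate bins (identical burden in everyone) are reported with p = 1 and a
flag rather than dropped, so the number of tests m stays interpretable.
Bonferroni correction multiplies by the number of bins tested *in the current
run* and caps at 1; ranks are assigned by ascending unadjusted p with ties
broken by bin id for byte-identical outputs. A significance level of alpha >=
1 flags every bin — with the cap at 1 a strict inequality would otherwise
make the "report everything" setting unattainable.

# The simulation machinery

The simulator exists to measure the operating characteristics of the
procedure on data whose truth is known, at desk scale.

**Region model.** A single 5 kb non-recombining region evolves forward in
time under Wright-Fisher reproduction with per-nucleotide per-generation
mutation rate 1.8e-8 and, by default, purifying selection with
gamma-distributed selection coefficients (shape 0.2, mean 0.01), the
Kryukov-style deleterious-mutation model commonly used for human rare
variation. The published epoch list (sizes 8100, 8100, 7900, 900000 against
durations 5000, 10, 370) does not align one-to-one; the adopted reading is
(8100 for 5000 generations), (7900 for 10), then exponential growth
7900 -> 900000 over 370 — an ancestral bottleneck with recent explosive
expansion. A burn-in of 8 x N generations at the first epoch's size precedes
the schedule so mutation-drift(-selection) balance is reached from the empty
starting state.

**Rescaling.** Forward simulation at N = 900,000 is not a desktop
computation. The standard rescaling divides sizes and durations by a factor
(default 100) and multiplies the mutation rate and selection coefficients by
it, preserving diffusion-scale allele-frequency dynamics. Rescaled selection
coefficients are capped at 0.9 — strong selection does not rescale cleanly
and the cap is a known distortion. Rescaling factors that push any epoch
below 50 diploids are refused.

**Merged evolutionary replicates.** Many independent realizations ("pools")
of the region model are simulated, and study cohorts draw their haplotypes
from the *union* of the pools (each subpool's sites are offset so positions
stay distinct). Two reasons. First, replicate realizations jointly carry far
more diversity than any single one — a single 5 kb genealogy under this
demography segregates tens of sample-visible variants, not the hundreds a
rare-variant study design is built around, and pooling replicates is how the
evaluation design raises the diversity of its final simulated data. Second,
a single non-recombining realization has an extremely lumpy site-frequency
spectrum, so study results would be dominated by the luck of one genealogy;
the union averages over hundreds of independent genealogies and gives
reproducible operating characteristics. The rotate-one-pool-per-replicate
design remains available (`pool_mode = "rotate"`).

**Phenotype model.** Disease status is assigned by a logistic model additive
in per-site allele counts: odds multiply by 2.5 per detrimental allele and
0.9 per protective allele; the intercept is solved numerically so population
prevalence is 0.5 (balanced ascertainment), and cases/controls are accepted
until both quotas are met. Under the null (both odds ratios 1) labels are
balanced and random. Three details are deliberate design choices where the
evaluation design is underdetermined:

* **Causal set.** Only sites with pool MAF below `causal_maf` (default 0.05,
  matching the binning threshold) carry effects. At the unscaled population
  size this is nearly vacuous — essentially every simulated variant is that
  rare — but a rescaled pool contains a handful of drift-inflated common
  sites that would otherwise carry per-allele odds ratios of 2.5 at
  frequencies never seen at full scale, saturating the logistic model and
  destabilizing the studies.
* **Direction assignment.** The default rule assigns detrimental vs
  protective directions deterministically: causal sites are ranked by their
  covariance with the pool's rare-allele burden (a weight that absorbs the
  strong linkage within each non-recombining genealogy) and directions are
  interleaved greedily so the detrimental share of that cumulative weight
  equals `fraction_detrimental`. This makes the covariance between burden
  and liability equal (f log ORd + (1-f) log ORp) x Var(burden) by
  construction — the realized architecture is a deterministic property of
  the pool, not a per-replicate lottery. Independent per-site random
  directions (`direction_rule = "random"`) are available; with them the
  handful of highest-variance sites reshuffle the aggregate effect every
  replicate and the power curve flattens far below the published regime.
* **Detrimental fraction.** `fraction_detrimental` (default 0.30) is the one
  quantity the published design leaves unstated (its simulator's
  causal-assignment rule is unpublished). It was fixed once by matching the
  model's realized burden effect size, measured on large simulated cohorts,
  to the published power at the anchor sample sizes, and then left alone; it
  is a property of the emulated study conditions, not a per-analysis tuning
  knob.

**What passing studies do and do not show.** The harness demonstrates that
the binning-plus-Wilcoxon procedure controls type I error under balanced
random labeling and has the expected power profile against an additive
rare-variant architecture of the calibrated strength. It does not validate
the procedure against sequencing error, missingness, population structure,
covariates, or linkage patterns of recombining regions — none of which the
generator emulates — and the power column inherits the calibration above, so
it should be read as "the emulated design reproduces the published regime",
not as an independent rediscovery of those numbers.

**Problem sizes.** The packaged studies use 400 rescaled pools (scale 100)
and 500-1000 replicates per study, sizes chosen so the union pool's sample
diversity is in the regime the evaluation design describes (hundreds of rare
variants per cohort) and Monte-Carlo error (binomial standard errors of
0.007-0.02) is small against the tolerances of interest.

# Spike-in recovery

The spike-in experiment probes signal recovery against background bin size: a
fully penetrant variant (every case heterozygous, every control homozygous
reference, so 43 cases contribute exactly 43 variants) is appended inside a
target gene of an 87-sample synthetic cohort. In a bin with at most 20 loci
the spike dominates the burden and the bin attains overall rank 1 with
Bonferroni significance; the identical spike inside a bin with hundreds of
background rare variants is mitigated by the noise and loses rank 1. The
contrast is qualitative by design — it depends on the background variant
density, not on any fitted constant.

# Numerical and degenerate-input choices

* Coordinates are 1-based and inclusive throughout; BED input is converted
  on load; dialects are declared, never sniffed.
* Duplicate region rows collapse to one record (idempotent reloads);
  malformed rows are rejected individually with line numbers.
* A group whose members all fail to resolve is not stored; a duplicate group
  label from the same source replaces the previous definition with a warning.
* Phased and unphased genotype separators are treated identically; half
  calls contribute their observed allele only.
* `wilcoxon_rank_sum` switches to exact enumeration only when the
  arrangement count is at most 2e5, bounding worst-case cost.
* Empty binning results (threshold 0, or nothing rare) are a warning with a
  distinct exit status (2) in the command-line pipeline, not an error.
* All command outputs embed their configuration as commented header lines
  and are byte-identical for identical inputs (timestamps are opt-in).

# Known limitations

* The knowledge store loads tabular region/GMT inputs only; it does not
  download or reconcile public databases, and conflicting gene boundaries
  across sources are kept side by side rather than merged.
* No liftover between genome builds; chromosome names are exact strings.
* Burden coding is additive only; regression-based association, covariate
  adjustment and population-structure correction are out of scope — export
  the bin matrix and use a regression framework when those matter.
* The simulator has no recombination (a single 5 kb locus), no missingness
  and no genotyping error; its rescaled runs distort strong selection (the
  capped coefficients above).
* Pathway bins inherit every caveat of the gene assignments they union;
  genes absent from all groups fall to intergenic windows when those are
  enabled, else remain unbinned.
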
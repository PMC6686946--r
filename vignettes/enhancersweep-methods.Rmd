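---
title: "Detecting recent positive selection on enhancers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent positive selection on enhancers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Enhancers are short (a few hundred bp) cis-regulatory elements whose activity
is often restricted to particular tissues.  Because regulatory change is a
plausible substrate of recent human adaptation, a natural question is whether
enhancers active in some tissues carry more signatures of recent positive
selection than others.  `enhancersweep` implements a complete, reusable
pipeline for that question: per-region selection statistics from phased
population genotypes, simulation-based neutral null distributions under an
explicit demographic model, empirical p-values, and a comparative layer
across tissues, tissue breadth, annotation tracks and trait catalogs.

The pipeline operates on three populations related by the out-of-Africa
topology (an African population, and European/East-Asian populations founded
through a shared bottleneck).  All inputs are standard files: a phased VCF, a
BED of regions with a tissue map, a sample-to-population panel, and a
HapMap-style recombination map.

# The four statistics

For each region the scan computes:

* **Tajima's D** (pooled sample): `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`
  over the region's segregating sites, with the standard constants for the
  sample size.  Negative values indicate an excess of rare variants, the
  frequency-spectrum footprint of a completed or ongoing sweep (or of
  purifying selection / population growth, which is why a demographic null is
  essential).
* **Weighted Weir–Cockerham F_ST** (all three populations jointly): per-site
  variance components a (among populations), b (among individuals within
  populations) and c (within individuals), computed from diploid genotypes
  with observed heterozygosity, ratioed as `sum(a) / sum(a+b+c)` across
  sites.  Local adaptation after the out-of-Africa split elevates it.
* **H12** (pooled): haplotype-class frequencies over the region's sites with
  the top two classes merged: `(p1+p2)^2 + sum(p_i^2, i>=3)`.  Sensitive to
  both hard and soft sweeps.  A region with sites but a single haplotype
  class scores exactly 1; a region with no sites at all is undefined.
* **Unstandardised nS_L** (per population): at each focal site in the region
  ± 50 kb window, haplotypes split into ancestral (allele 0) and derived
  (allele 1) carriers; for each within-class pair, the tract length L is the
  number of consecutive segregating sites, in the maximal identical run
  containing the focal site, truncated at the window edges.  The site score
  is `ln(mean L ancestral / mean L derived)`; the region score is the
  maximum |score| over focal sites.  Only sites with within-population
  MAF >= 0.01 enter the window.

Undefined values (no segregating sites, too few haplotypes, no valid focal
site) propagate as `NA` with a reason code and are excluded from downstream
distribution comparisons; nothing is imputed.

## Conventions that matter

* Coordinates: BED intervals are 0-based half-open; VCF and map positions
  are 1-based.  A site at 1-based position p lies in region `[s, e)` iff
  `s < p <= e`.
* MAF boundary: "MAF >= cutoff" is retained, so a site at exactly 0.01
  survives a 0.01 cutoff.  The MAF filter applies only to nS_L windows; the
  other statistics use all biallelic region sites.
* Ancestral polarity for nS_L: the reference allele is treated as ancestral.
  Because the region score takes |nS_L|, it is robust to polarity errors;
  per-site signs are reported as computed.
* nS_L tract lengths are counted in MAF-filtered segregating sites, and runs
  simply stop at the window edges.  The gap and EHH-decay heuristics of the
  original selection-scan software are deliberately not replicated; this
  keeps the statistic's contract exact and testable.
* Missing genotypes are an error: the intended inputs are fully phased and
  imputed, and silently dropping haplotypes would bias the haplotype
  statistics.

# The neutral null

Observed values are compared against neutral simulations under a
three-population demographic model: a single ancestral population (size
`N_A`) until `T_AF` generations ago, an African population (`N_AF`), an
out-of-Africa bottleneck branch (`N_B`) exchanging migrants with Africa, and
a European/East-Asian split at `T_EU_AS` with exponential growth to the
present and pairwise migration.  The shipped defaults are the published
Gravel et al. (2011) values (N_A = 7310, N_AF = 14474, N_B = 1861, European
founding 1032 growing at 0.0038/generation, East-Asian founding 554 growing
at 0.0048/generation, splits at 5920/2040/920 generations, migration
1.5e-4 / 2.5e-5 / 7.8e-6 / 3.11e-5 per generation, mu = 2.36e-8 per bp per
generation, 25-year generations); they are exposed as an editable JSON
config (`write_model_config()` / `read_model_config()`) rather than baked
in, since different applications may prefer re-estimated parameters.

The simulation engine is a structured coalescent with recombination
(ancestral-recombination-graph walk), migration, exponential growth and
timed demographic events, written in C++ and driven by R's RNG.  A
coalescent is the natural engine for strictly neutral nulls: for neutral
summary statistics it is distributionally equivalent to forward simulation
under the same demography, at a small fraction of the cost.  The engine is
validated against closed-form coalescent expectations (Watterson's segregating-
site count, pairwise diversity, the neutral site-frequency spectrum, and
Tajima's D centring) in the test suite.

## Per-tissue null parameters

Simulating every region individually would be wasteful; instead, one null is
built per tissue:

* For Tajima's D, F_ST and H12: segments of the tissue's rounded **mean
  region length**, at a fixed recombination rate of 1e-8 per bp per
  generation.  All three statistics are computed on the same replicate set.
* For nS_L: segments of the mean length **plus two 50 kb flanks**, at the
  tissue's mean window recombination rate.  The rate comes from the genetic
  map: rates are linearly interpolated (clamping beyond the map ends), the
  mean rate of each region's window is `(delta cM)/(delta bp) * 1e6`, and
  the tissue mean is converted to a per-bp crossover probability
  (1 cM/Mb = 1e-8 per bp per generation).  One null per population is
  computed from the same window simulations, matched to each population's
  sample size.

Default null sizes are 10,000 replicates (2,500 for nS_L) per tissue, both
configurable downward; the validation study in this package uses 200 (see
below).  Nulls are cached as TSV files with a parameter header (length,
rate, replicate count, seed, model hash) and are reused verbatim on rerun
when the parameters match.  Cached values are written with 17 significant
digits so that tie counting in empirical p-values is bit-identical with and
without the cache.

## Empirical p-values

`p = (# simulated values equal to or more extreme) / (# defined simulated
values)`, with "more extreme" pointed in the direction positive selection
pushes each statistic: lower tail for Tajima's D, upper tail for F_ST, H12
and the nS_L region maximum.  The directions are configurable per metric.
A region is called significant when `p < alpha` (default 0.05).  `p = 0` is
reported together with a below-resolution flag, since an N-replicate null
cannot resolve p below 1/N.  Each replicate draws its seed from a
counter-mixed stream derived from the master seed, so replicate k is
reproducible in isolation and the whole pipeline is byte-deterministic
given (config, seed).

# The comparative layer

* **Tissue breadth**: regions active in exactly one tissue are
  `tissue_specific`, in two or more `tissue_broad`; among broad regions the
  summary reports how many organ systems each spans (percentages to two
  decimals).  When a tissue's regions are split into specific vs broad, a
  broad region is counted in every tissue it is active in.
* **Pairwise distribution tests**: two-sided two-sample Kolmogorov–Smirnov
  tests on the metric distributions, one per unordered tissue pair (820
  tests for 41 tissues) or one specific-vs-broad test per tissue.  The
  statistic is the exact ECDF supremum gap; p-values use the asymptotic
  two-sample Kolmogorov distribution, appropriate for the
  hundreds-to-thousands of regions per group in the intended use.  The
  Bonferroni family is the set of tests actually run in one invocation.
* **Rankings**: tissues ordered by median metric value or by proportion of
  significant regions; ties share the smaller rank.
* **Annotation overlap**: a region overlaps a track (e.g. transposable-
  element annotations) iff they share >= 1 bp (half-open intervals; interval
  arithmetic via GenomicRanges).  Significant-by-overlap 2x2 tables are
  tested with the chi-squared statistic with Yates continuity correction
  (undefined when a margin is zero), on unique regions (a region significant
  in any of its tissues counts once).
* **Trait-catalog hits**: catalog SNPs are matched by (chrom, position)
  against the SNPs inside each region plus, optionally, all polymorphic
  sites within 1 Mb in complete LD (haplotype r^2 = 1.0 within 1e-12) with
  an inside SNP; hits reachable only through an LD partner are flagged.
  The 1 Mb search window is a package default (the choice is not critical
  because the threshold is exact equality of haplotype columns up to
  complement); it is configurable.

# The synthetic-data generator

`generate_cohort()` produces a complete ground-truthed input bundle so every
stage can run and be validated without downloads.  Design choices:

* **Region layout**: lengths are lognormal(meanlog = log(300),
  sdlog = 0.45) clamped to [200, 1000] bp — the scale of CAGE-defined
  enhancers.  Each region sits in its own window (region plus two 50 kb
  flanks, plus a small gap), and windows are simulated independently:
  regions 100 kb apart are effectively unlinked, so independent windows are
  the realistic as well as the cheap choice.
* **Labels**: 41 tissues grouped into 10 organ systems by default, 80%
  tissue-specific regions, broad regions spanning 2–6 tissues; this creates
  specific/broad and organ-system structure by construction.
* **Recombination**: each window draws its map rate from
  lognormal(meanlog = log(1.2), sdlog = 0.4) cM/Mb — centred near the
  genome-wide average with realistic spread — and the emitted HapMap-style
  map is piecewise constant at those rates, so map-derived null parameters
  agree with what was simulated.
* **Sweep planting**: a sweep is planted by copying one (hard) or several
  (soft) founder haplotypes over the region's sites onto a fraction f of the
  target-population haplotypes.  Copy-planting is deterministic given the
  neutral background and produces exactly the signatures the statistics
  target: frequency-spectrum skew (Tajima's D), haplotype homozygosity (H12,
  nS_L) and, when targeted at a subset of populations, differentiation
  (F_ST).  By default sweeps are planted in all three populations (a sweep
  old enough to be shared), which makes the pooled statistics the relevant
  detectors; per-population targeting is configurable.  Sites that planting
  renders monomorphic are dropped from the emitted VCF, as they would be
  absent from a real variant call set.
* **Annotations**: the annotation track intersects a designated fraction of
  regions by >= 1 bp (plus decoy intervals that touch no region); catalog
  SNPs are placed at real sites inside a designated fraction of regions,
  and optionally at outside complete-LD partner sites, so LD expansion is
  exercised with known truth.

What the generator does **not** emulate: genotyping error and missingness,
realistic linkage to real genome coordinates, background selection, and
linked selection between nearby regions.  Passing tests therefore show that
the pipeline recovers what it is supposed to recover under its own model
assumptions — not that those assumptions hold for any particular real
dataset.

# The validation study

The acceptance suite (and `scripts/acceptance.R`) runs the whole pipeline at
a reduced, desk-scale design chosen to finish in minutes on one CPU while
keeping the binomial error of a 5% call rate near one percentage point:
2 x (60, 50, 50) haplotypes, 500 regions over 5 tissues, 200-replicate
nulls.  It checks:

1. worked arithmetic (820 tissue pairs from 41 groups; the 12.33% / 39.35%
   organ-system shares from the printed multiplicity counts);
2. oracle equivalence of every statistic against naive brute-force
   re-implementations on random small instances (1e-9 relative tolerance);
3. closed-form coalescent expectations at theta = 10, n = 20;
4. calibration: on an all-neutral cohort the per-metric significant-call
   rate should sit at alpha;
5. sweep recovery: with 10% hard sweeps (f = 0.8), significant calls should
   be enriched for true sweeps, and a fixed (f = 1) single-population sweep
   forces per-population H12 = 1 exactly;
6. byte-level determinism of the scan and null outputs under a fixed seed.

## Known limitations the validation study exposes

Two of the acceptance checks cannot be met under these study conditions,
and the reasons are instructive; the corresponding assertions are left
failing rather than weakened.

**H12 calibration (check 4).**  At a ~300 bp mean region length the pooled
sample yields on the order of E[S] ~ 2–3 segregating sites, so a
substantial fraction of neutral null replicates (roughly a fifth) carry
exactly one segregating site — and any single-site region has exactly two
haplotype classes, hence H12 = (p1 + p2)^2 = 1, the statistic's upper
bound.  The null therefore has a large point mass at 1.0.  Because the
empirical p-value counts ties ("equal to or more extreme"), no observed
value, not even 1.0 itself, can obtain p below that mass, and the H12 call
rate at alpha = 0.05 is structurally zero.  This is a property of the
mean-length empirical-p procedure applied to a bounded, discrete statistic
on very short regions, not an implementation artifact.  The other three
statistics are effectively continuous even at this scale and their
all-neutral call rates sit inside the 3–7% band.  For real scans this
argues for reporting H12's empirical p-values together with their
resolution flags and tie structure rather than as bare significance calls.

**Sweep-recovery enrichment (check 5).**  Founder-copy planting does shift
the statistics the way a sweep does on average — swept regions have lower
pooled Tajima's D and higher H12 than matched neutral regions, a property
the test suite verifies directly — but the per-region shift is far too
small for significance calls at this region scale.  Copying the founder
haplotype onto a fraction f of carriers *erases* a pre-existing rare
variant entirely whenever all of its carriers are overwritten (probability
about f^c for a variant of count c), so instead of the excess of new rare
variants a real completed sweep leaves behind, planting removes singletons
and can render short regions monomorphic outright.  What remains is a
moderate high/low frequency dichotomy whose Tajima's D sits well inside
the neutral null's own spread, at any carrier fraction and at any region
length in the enhancer range.  Consequently neither Tajima's D nor H12
significance calls are measurably enriched for planted sweeps, and the
Fisher-test bound of that check fails.  The f = 1 single-population planted
sweep, by contrast, is an exact construction (per-population H12 = 1) and
passes.  A generator wishing to make planted sweeps *detectable* at this
scale would have to add post-sweep mutations on the swept haplotypes — a
different mechanism than the haplotype copying implemented here, and one
whose rate would be an extra free parameter.  A related side effect worth
knowing: planting the same founder across all three populations
homogenises them, so swept regions have *depressed* F_ST — an old shared
sweep looks like the opposite of local adaptation.

# Other limitations

* The null is strictly neutral: demographic misspecification shows up as
  miscalibration everywhere, which is why the model is a config, not a
  constant.
* Per-tissue (not per-region) null lengths follow the mean-length
  approximation discussed above.
* Standardised (frequency-binned) nS_L, iHS/XP-EHH and H2/H1 are out of
  scope; the region score is the maximum |unstandardised nS_L|.
* The KS p-values are asymptotic; for groups with only a handful of regions
  the pairwise tests warn and skip rather than switching to exact
  enumeration.
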
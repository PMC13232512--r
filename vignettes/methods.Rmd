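---
title: "Methods: recombination-landscape divergence, differentiation scans, and structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombination-landscape divergence, differentiation scans, and structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recdiv)
```

## The problem

When two populations exchange migrants, locally adaptive allele combinations
survive only where recombination does not break them apart. Testing that
idea requires three linked analyses on the same genome: (i) do the two
populations' fine-scale recombination landscapes actually differ, beyond
what replicate estimation noise and demography alone would produce; (ii)
where is genetic differentiation concentrated, once the confounding effect
of recombination-rate variation on the F\_ST distribution is controlled;
and (iii) do structural variants (SVs) — deletions, insertions, inversions —
sit where recombination is locally suppressed and differentiation elevated.
`recdiv` implements that pipeline for two populations with replicate
LD-based recombination maps, SNP and SV genotypes, a pedigree (linkage)
recombination map, and a candidate set of previously described adaptive
regions. Everything runs on synthetic data produced by the package's own
generators, so each stage is testable end to end against planted truth.

All coordinates are 0-based half-open (BED convention); VCF positions and
1-based LD tables are converted on read. This single internal convention is
deliberate: interval arithmetic (overlap, merging, tiling) is the substrate
of every stage, and mixing conventions is the classic source of
off-by-one drift.

## Landscape divergence: me, ms, PRDI and delta-r

Raw per-base maps are averaged into non-overlapping 2 kb bins
(length-weighted mean over covered bases, the `bedtools map` semantics;
bins with no covering interval are missing, and a short final bin is kept
but excluded from statistics that need complete bins). Within 5 Mb windows,
Spearman correlations are computed for every replicate pair and classified
within- or between-population. The empirical divergence is

> me = min(median within-population-1 rho, median within-population-2 rho)
> − median(between-population rho),

with medians pooled over all windows and pairs. The same quantity computed
on maps estimated from data simulated under a *shared* landscape is ms, and
PRDI = me − ms. Two open choices are resolved here and reported as such:
5 Mb windows are non-overlapping (a step size for sliding windows is not
specified anywhere authoritative, and non-overlap keeps the pooled medians
over effectively independent windows), and medians pool windows and pairs
rather than taking per-window medians first (both medians are reported by
`compute_me()`, and `prdi_profile()` provides the per-window contrast).

Fine-scale divergence uses delta-r: per 100 kb window of 50 complete 2 kb
bins, the bin-count-scaled Manhattan distance between two maps, natural-log
transformed with a floor `eps = 1e-12` (the transform is only stated as
"log" in the source literature; any monotone choice gives the same outlier
flags except at the floor). Windows with any missing or incomplete bin are
dropped rather than imputed. Per window, the median within-population and
between-population delta-r are compared: a window is an outlier when its
between median exceeds the genome-wide mean of within medians by more than
3 SD.

### Hotspot and coldspot calling

Each bin's log rate is compared with a local background: the mean and SD of
log rates within ±20 kb, *excluding the focal bin and a two-bin guard ring
on each side*. The exclusion is a deliberate numerical choice: mean/SD
backgrounds are not robust, and a genuine spot spanning 2–3 adjacent 2 kb
bins inflates its own background SD enough that its z saturates below the
3-SD threshold no matter how strong the spot is. A guard ring (as in CFAR
peak detection) restores sensitivity for few-bin spots while leaving the
null calibration essentially unchanged (~0.3–0.5% of background bins called
at z = 3 on the generator's null fields, against a 2 × 0.13% Gaussian
expectation). Bins beyond ±3 SD become hotspot/coldspot seeds; seeds merge
with a 1 kb maximum gap; hotspots longer than 5 kb are removed (long
LD-based hotspots are a known estimation artefact); chromosome ends use the
truncated background with at least 5 bins. Zero rates are floored at the
smallest positive rate × 1e-3 before the log.

Spot sharing between populations counts ≥ 1 bp overlaps. Published sharing
percentages are quoted under more than one convention, so
`sharing_summary()` reports all three (shared/nA, shared/nB,
shared/(nA+nB)).

## The recombination-aware differentiation scan

Per-SNP F\_ST is the two-population Weir & Cockerham (1984) variance-
component estimator θ̂ = a/(a+b+c) — the quantity vcftools reports per
site. It requires observed heterozygote counts (not just allele
frequencies), so genotype tables carry per-population (n, alt-allele count,
het count); missing genotypes reduce n per population; the estimator may be
negative and is missing when its denominator is zero. The implementation is
cross-checked against an independently coded scalar oracle to 1e-12 on
1,000 random genotype configurations.

Windows of 100 kb are assigned to recombination quintiles by the pedigree
(linkage) map — not the LD-based map, which selection itself distorts —
using linear-interpolation empirical quantiles; degenerate (tied) edges
collapse bins, and windows without linkage values are excluded. Within each
quintile, outlier SNPs strictly exceed the bin's 99th percentile
("exceeding" in the source description motivates the strict inequality).
Windows with fewer than 10 SNPs are removed, and the genome-wide outlier
proportion p0 is computed *after* that filter (the alternative ordering is
a documented open point; both counts are visible in the scan table). Window
enrichment is the binomial upper tail P(X ≥ k | n, p0) — a "non-exact P"
since linked SNPs are not independent — with enrichment at P < 0.05, no
multiple-testing correction (deliberately matching the raw cut used in
practice; the quantity is a ranking device, not a calibrated test).
Adjacent enriched windows (gap 0 on the tiling) merge into continuous
regions; both pre- and post-merge counts are reported. Two controls are
computed alongside: a chi-squared test of enriched-window uniformity across
the five bins, and the Pearson correlation of P with SNP count.

Overlap of enriched windows with candidate regions is tested twice: a
Pearson chi-squared on the 2×2 (enriched/background ×
overlapping/not), and an empirical P from 500 permutations that reposition
each enriched window uniformly within its own chromosome with its size
preserved (windows may overlap one another after repositioning — the null
model constrains only chromosome identity and size). Empirical
P = (#permuted χ² ≥ observed)/n, reported as "< 1/n" when zero. Because the
permuted χ² is discrete, this P is conservatively shifted upward by ties;
its mid-P transform is uniform under the null, which is how the calibration
suite assesses it, while validity (rejection ≤ nominal) is checked on the
reported P itself.

## Diversity and the residual analysis

Windowed nucleotide diversity follows the pixy contract: per segregating
site, the unbiased pairwise term c\_ref · c\_alt / C(n, 2) with n the
genotyped allele number at that site, summed and divided by the *full*
window length, treating unobserved sites as monomorphic. This makes π
robust to missing data but proportional to the simulated SNP density: the
generator's default density (1 SNP / 2 kb after the MAF ≥ 0.05 filter)
yields π around 2e-4, an order of magnitude below typical empirical
stickleback values — a deliberate desk-scale compromise that affects the
level, not the contrasts the tests assert. Between-population differences
in windowed π use a Welch t-test (robust to the very unequal category
sizes; the source literature says only "T-test").

Two model layers connect differentiation to recombination. First,
log(F\_ST) ~ cM/Mb × π per population by OLS, dropping non-positive
F\_ST windows (count reported) and flagging rank-deficient designs. Second,
log(ρ) ~ cM/Mb residuals: windows where LD-based recombination is lower
than the meiotic map predicts (negative residuals) carry more LD than their
meiotic rate explains — the signature of selection. Residuals are
correlated (Pearson) with π and with log F\_ST (the raw-F\_ST correlation
is also returned, since the published choice of scale is ambiguous), and
compared across window categories (background / outlier / outlier
overlapping candidate regions) with Welch t-tests, skipped when a category
has fewer than 2 windows.

## Structural variants

SV reference spans follow VCF semantics: DEL `[pos, pos+len)`, INS a 1 bp
anchor (the inserted sequence is absent from the reference), INV
`[pos, pos+len)`. Per-SV F\_ST reuses the same Weir–Cockerham operation on
SV genotypes; outliers strictly exceed the genome-wide 99th percentile.
Overlap of outlier vs background SVs with enriched windows is a two-sided
Fisher exact test, overall and stratified at 1 kb. The SV-density control
counts occupied bases per 100 kb window with deletions (and insertions)
contributing 1 bp and inversions their length, then correlates density with
−log10 P (Spearman).

LD features take, per SV, the nearest SNP strictly left of the span start
and strictly right of the span end, each within 5 kb of its breakend
(breakends, not the midpoint — a documented interpretation), and the pair's
r². Predictors are the flanking interval, the proportion of that interval
covered by the SV (length/interval; deliberately allowed to exceed 1 for
insertions, whose length is not on the reference), and an inverse
frequency-weighted distance implemented as 1/(interval · MAF₁ · MAF₂) — a
declared stand-in, since the weighting is not defined in the source
literature; it is isolated in the feature builder and scaled before
modelling, so replacing it does not touch the model code. The model is
r² ~ scaled weighted distance + scaled interval + proportion covered + SV
type with a chromosome random intercept, fitted by REML (lme4); marginal
means per SV type and Tukey-adjusted pairwise contrasts come from emmeans;
with a single chromosome the model degrades to OLS with a warning, and the
mixed fit provably reduces to OLS as the random-effect variance goes to
zero. SV enrichment in hot/coldspot categories shuffles the *regions*
(10,000 times, uniformly within chromosome, lengths preserved) and reports
observed/expected and the one-sided empirical P.

## What the generators emulate — and what they do not

`simulate_landscapes()` builds one autocorrelated Gaussian log-rate field
per genome (Gaussian moving-average smoothing of white noise at 2 kb
resolution, default autocorrelation scale 50 kb, log-mean ln(1e-8), log-SD
1), shares it between the two populations, shifts population 2 inside
planted divergent segments, plants hotspots/coldspots as bin-aligned
features whose amplitude is expressed in SD units of the local ±20 kb
background of the final noisy track, and adds independent N(0, 0.3²)
estimation noise per replicate subset (6 per population by default, the
replicate structure of the study design). With these defaults the realized
within-population replicate correlations are ≈ 0.90 at 2 kb — the level
reported for real replicate map subsets — so the null PRDI band the tests
assert (|PRDI| < 0.02 over 20 seeds) is calibrated at realistic replicate
noise.

`simulate_genotypes()` is a Balding–Nichols F-model: ancestral frequency
per SNP, population frequencies Beta(p(1−F)/F, (1−p)(1−F)/F) with F = 0.02
baseline and 0.4 inside planted 100 kb windows, binomial diploid genotypes
(40 + 40 by default), 2% missingness, pooled MAF ≥ 0.05 filter. It emulates
the marginal F\_ST structure that the scan consumes; it does *not* emulate
linkage disequilibrium between SNPs, coalescent histories, or the
correlation of diversity with recombination — so passing tests demonstrate
the scan's statistical machinery and its recovery of frequency-divergent
windows, not robustness to the LD-induced SNP dependence that makes the
window P "non-exact" on real data.

`simulate_svs()` draws type counts (defaults scaled down from a catalogue
of ~20k deletions ~200 bp, ~18k insertions ~300 bp, and a few dozen
inversions ~3 kb), log-normal lengths per type, mild-F population
frequencies, optional placement inside coldspots and optional co-location
of planted frequency-divergent SVs with supplied differentiated regions.
`simulate_ld_features()` generates the LD feature table under a fully known
linear truth (type shifts, chromosome random intercept, residual noise) for
power and calibration tests of the mixed model; it stands in for
genotype-level LD computation around SVs, which is out of scope.

## Problem sizes and reproducibility

The bundled analysis scripts and the acceptance script run on a 3 × 12 Mb
genome (18,000 2 kb bins per map, ~17,000 SNPs, ~1,000 SVs), chosen so the
full workflow — including 500 window permutations and 10,000 SV shuffles —
completes in minutes while every statistic retains enough resolution to be
compared against its planted truth. Null-calibration suites scale the
permutation count down (60 permutations × 100–200 seeds) and assess
uniformity on the mid-P transform as described above. Every generator and
every permutation consumes an explicit seed; stage seeds are derived
deterministically from one global seed, and reports are bit-identical
across reruns with the same seed.

## Known limitations

* The window-enrichment P inherits SNP dependence on real data; it ranks
  windows, it does not test them. No FDR layer is applied by design.
* The spot caller's mean/SD background (even with the guard ring) absorbs
  wide features: spots much wider than the guard ring (≳ 3 bins) mask
  themselves. Hotspots are capped at 5 kb anyway; wide coldspots are the
  main casualty.
* me/ms medians pool windows and pairs; per-window pooling is available via
  `prdi_profile()` but the headline PRDI uses the pooled convention.
* The inverse frequency-weighted distance predictor is a stand-in for an
  undefined published quantity and should not be interpreted, only
  controlled for.
* π and window F\_ST levels in the synthetic data are density-dependent and
  not calibrated to empirical per-site levels; contrasts and recoveries
  are the tested quantities.
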
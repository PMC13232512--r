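# recdiv

Recombination-landscape divergence and the genomic architecture of local
adaptation between two connected populations.

`recdiv` is an R package plus a numbered analysis workflow for population
genomicists asking how recombination variation and structural variants
(SVs) shape genomic differentiation under gene flow. It implements, as
tested and reusable functions:

* **Landscape comparison** — replicate LD-based recombination maps are
  binned (2 kb), correlated within and between populations in 5 Mb windows
  (Spearman), and summarized by the Population Recombination Divergence
  Index,

  `PRDI = me − ms`,  with
  `me = min_p( median ρ_within,p ) − median ρ_between`

  computed on empirical maps (*me*) and on maps from neutral replicates
  sharing one landscape (*ms*). Fine-scale divergence uses
  `Δr = ln( (1/50) Σ_{b=1}^{50} |a_b − b_b| + ε )` per 100 kb window, with
  outliers where the between-population median exceeds
  `mean(Δr_within) + 3·SD(Δr_within)`.
* **Hotspot/coldspot calling** — bins whose log rate deviates from the
  local ±20 kb background mean by more than 3 SD (background excludes the
  focal bin and a guard ring), merged at 1 kb, hotspots capped at 5 kb,
  with cross-population sharing summaries.
* **Recombination-aware F_ST scan** — per-SNP Weir–Cockerham
  `θ̂ = a/(a+b+c)`; windows binned into pedigree-map recombination
  quintiles; per-quintile 99th-percentile outlier SNPs; binomial window
  enrichment `P = Σ_{i≥k} C(n,i) p₀^i (1−p₀)^{n−i}`; merging of adjacent
  enriched windows; χ² + 500-permutation (chromosome- and size-preserving)
  overlap tests against candidate regions.
* **Diversity and residual models** — pixy-style missing-data-aware
  windowed π; `log F_ST ~ rec × π` per population;
  `log ρ ~ cM/Mb` residuals correlated with π and F_ST and contrasted
  across window categories.
* **SV analyses** — catalogue summaries; per-SV F_ST outliers; Fisher
  overlap with enriched windows (overall and by 1 kb size class); SV
  density control; flanking-SNP LD features (including
  `proportion covered = |SV length| / (pos_SNP2 − pos_SNP1)`) modelled as
  `r² ~ covariates + SV type + (1 | chromosome)` with marginal-mean
  contrasts; SV enrichment in hot/coldspots via 10,000 region shuffles.
* **Synthetic data** — generators for every input (autocorrelated
  log-normal landscapes with replicate noise and planted spots/divergent
  segments; Balding–Nichols two-population genotypes with planted
  high-F_ST windows; SV catalogues; LD feature tables), each returning its
  planted truth for recovery testing.

## Worked example

The `analysis/` directory is a five-stage workflow; each stage is a thin
driver over package functions that prints what it found and writes tables
under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_landscape_divergence.R
Rscript analysis/03_differentiation_scan.R
Rscript analysis/04_diversity_models.R
Rscript analysis/05_sv_analysis.R
```

Stage 2 prints, for the default seed:

```
Landscape divergence:
  me = 0.0034 (within medians 0.882 / 0.885, between 0.879), ms = -0.0001 -> PRDI = 0.0035
  delta-r outlier windows: 1 (planted divergent segments hit: 1 of 2)
  hotspots 37/42 (shared 15, 41% of pop1); coldspots 44/45 (shared 16, 36% of pop1)
```

Replicate maps correlate at ρ ≈ 0.88 within populations; the between-
population median is lower by `me = 0.0034`, and the neutral contrast
`ms ≈ 0` leaves a small positive PRDI — landscape divergence beyond
replicate noise, localized by Δr to one of the two planted divergent
segments. Stage 3 then reports:

```
Differentiation scan (17268 SNPs, p0 = 0.0101):
  360 windows scanned, 14 enriched (P < 0.05), 8 after merging adjacent windows
  enriched windows across recombination bins: chi-squared uniformity P = 0.91; P vs SNP count r = 0.060
  candidate-region overlap: 100.0% of enriched windows, chi-squared = 313.18, permutation P < 0.002
```

i.e. the scan recovers the planted high-divergence windows, enrichment is
not biased toward a recombination quintile (uniformity P = 0.91) nor driven
by SNP density, and the overlap with the candidate regions survives the
chromosome-preserving permutation null (none of 500 permuted χ² values
reached the observed one). Stage 5 closes the loop on SVs: frequency-
divergent SVs co-locate with enriched windows (Fisher P ≈ 2e-13), the
mixed model detects the planted +0.05 r² shift around inversions (contrast
P ≈ 1e-10), and SVs placed in coldspots are recovered as a ~100-fold
enrichment over 10,000 shuffles.

The same pipeline runs from a single call on any configuration:

```r
library(recdiv)
report <- run_all(run_config(seed = 5), outdir = "results/run5")
report$landscape$prdi
```

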
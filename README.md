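# isribtools

Analytics for pinning down the cellular target of ISRIB-class integrated
stress response (ISR) inhibitors. The ISR converges on phosphorylation of
translation initiation factor eIF2, which inhibits its guanine nucleotide
exchange factor (GEF), eIF2B; ISRIB renders cells insensitive to that
inhibition. This package re-implements, as one tested and reusable R
pipeline, the four quantitative strands of evidence that localize ISRIB's
action on eIF2B:

1. **Pooled FACS-sorted shRNA screen scoring** — per-hairpin phenotypes
   `ε = log2(f_high / f_low)` centered on the median of >1000 negative
   controls, gene-level Mann-Whitney U tests against the empirical control
   null, and a two-arm (stress vs stress + drug) classification into
   *resistance*, *hypersensitizing* and *reporter-modifier* genes.
2. **Co-fractionation correlation profiling** — normalized sucrose-gradient
   protein profiles over fractions 6–9, Pearson correlation against a
   reference complex subunit (eIF2B4), Svedberg calibration from standards
   (ovalbumin 3.5 S, aldolase 7.3 S, thyroglobulin 19 S), and detection of
   the drug-induced shift toward heavier fractions expected of eIF2B
   dimerization.
3. **GDP-dissociation kinetics** — first-order fits
   `F(t) = plateau + A·exp(−kt)` to radiolabeled-GDP release time courses,
   half-lives `t½ = ln 2 / k`, bootstrap confidence intervals, and
   fold-acceleration comparisons between conditions.
4. **Dose-response potency and SAR additivity** — four-parameter logistic
   EC50 fits to reporter dose-response tables, and a log-additive
   substituent-increment model `log10 EC50(X,Y) = β0 + Δ(X) + Δ(Y)` for the
   symmetric analog series.

Every input family has a synthetic generator with presets traceable to the
published experimental conditions (library geometry, half-lives, analog
potencies), so the full pipeline runs end-to-end with no external data.
Intended users: computational biologists building or auditing
target-identification analyses, and methodologists who need calibrated
synthetic screens and kinetics data.

## Worked example

```r
library(isribtools)

# Exchange kinetics: basal GEF activity vs GEF + drug
basal <- fit_decay(simulate_decay(decay_preset("gef_basal"), seed = 1))
drug  <- fit_decay(simulate_decay(decay_preset("gef_isrib"), seed = 1))
basal
#> First-order decay fit (three_param)
#>   k = 0.21136 /min   t1/2 = 3.279 min
#>   amplitude = 1.0029   plateau = 0.0000   rss = 0.00421
compare_conditions(basal, drug)
#> [1] 3.03
```

The fitted basal half-life (3.28 min) recovers the preset value derived
from the printed 3.2 min, and the drug accelerates exchange about
threefold.

```r
# Potency of the best analog preset (true EC50: 600 pM)
fit_4pl(simulate_dose_response(dose_preset("A17"), seed = 1))
#> Four-parameter logistic fit
#>   EC50 = 641 pM   hill = 1.62
#>   top = 100.53   bottom = 11.53   rss = 54

# Co-fractionation: complex members track the reference subunit
corr <- correlate_to_reference(
  normalize_profiles(
    simulate_gradient(dimer_gradient_design(), "drug", seed = 1)),
  "eIF2B4")
head(corr, 6)
#>   protein_id         R rank
#> 1     eIF2B4 1.0000000    1
#> 2     eIF2B3 0.9985414    2
#> 3     eIF2B5 0.9980223    3
#> 4     eIF2B1 0.9975065    4
#> 5     eIF2B2 0.9960352    5
#> 6      eIF2a 0.1815143    6
```

All five complex subunits correlate with the reference at R > 0.99 while
the best non-member sits at R ≈ 0.18 — the co-sedimentation signature of
drug-stabilized dimerization.

The whole pipeline (screen → co-fractionation → kinetics → potency) runs
with one call and writes every intermediate TSV plus a JSON report:

```r
run_pipeline(run_config(list(run = list(outdir = "demo_run", seed = 1))))
```

A command-line front end with the same surface
(`simulate-screen`, `screen-score`, `cofrac-correlate`, `fit-decay`,
`fit-ec50`, `sar-additivity`, `run-all`, ...) is installed at
`system.file("cli", "isribtools", package = "isribtools")`.

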
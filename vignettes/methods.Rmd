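---
title: "Models and methods behind isribtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isribtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

isribtools packages four quantitative analyses that together localize the
cellular target of ISRIB-class integrated stress response (ISR) inhibitors on
eIF2B, the guanine nucleotide exchange factor (GEF) of translation initiation
factor eIF2. This vignette explains each model, its assumptions, the tunable
parameters, what the synthetic generators do and do not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Pooled FACS-sorted shRNA screen

**Model.** A pooled library of hairpins (~25 per gene plus >1000
non-targeting negative controls) infects a reporter cell population. Under
ISR induction the reporter is translationally induced; cells are sorted into
thirds by reporter level and the bottom (Low) and top (High) thirds are
deep-sequenced. The phenotype of hairpin $s$ is

$$\varepsilon_s = \log_2 \frac{f^{high}_s}{f^{low}_s} - \operatorname{median}_{c \in \text{controls}} \log_2 \frac{f^{high}_c}{f^{low}_c},$$

where $f$ are within-bin hairpin frequencies. The control-median centering
makes $\varepsilon = 0$ the empirical neutral point by construction
(`compute_epsilon()` guarantees an exactly zero control median). Gene-level
significance compares the gene's $\varepsilon$ values to the controls with a
Mann-Whitney U test; the signed score $s = \mathrm{sign}(\tilde\varepsilon)
\cdot (-\log_{10} p)$ drives a two-arm classification: genes strong in the
stress-only arm are *reporter modifiers*; genes quiet at baseline
($|s_{stress}| < \tau_{base}$) but strong in the drug arm are *resistance*
($s_{drug} \ge \tau_{sel}$) or *hypersensitizing*
($s_{drug} \le -\tau_{sel}$) hits.

**Parameters.** `pseudocount` (default 0.5 per hairpin per bin) keeps
$\varepsilon$ finite when a hairpin drops out of one bin and is close to
unbiased for the log-ratio; hairpins with zero counts in *both* bins are
flagged unusable and excluded rather than imputed. `tau_sel = 3`
(p ≤ 10⁻³) and `tau_base = 2` are config-exposed: the original
classification was drawn geometrically off a p-value/p-value scatter without
printed cutoffs, so these are this package's own operating points.
Two-sided p-values are reported with the direction carried separately — the
lossless choice when the original sidedness convention is not recoverable.
No multiple-testing correction is applied by default (raw Mann-Whitney
p-values are the published quantity); `gene_pvalues(bh = TRUE)` adds a
Benjamini-Hochberg column.

**Exact vs asymptotic test.** `mann_whitney_exact()` enumerates all
$\binom{n+m}{n}$ group assignments (feasible to $n+m \le 12$) and is the
oracle; `gene_pvalues()` uses the normal approximation with tie and
continuity corrections, the only feasible path against ~1000 controls. The
approximation's accuracy domain matters: for instances with exact
$p \gtrsim 0.05$ it tracks enumeration within ~15% relative, but at complete
separation it overstates small p-values substantially (worst case ~54%
relative at $n = m = 5$, $U = 0$: exact $2/252 = 0.0079$ vs asymptotic
$0.0122$). This is a property of the estimator itself, not of the
implementation; the full-sweep comparison in `test-acceptance.R` documents
it and deliberately fails the 15%-everywhere claim. Gene *ranking* is
unaffected (the mapping $U \mapsto p$ is monotone at fixed sample sizes).

**Synthetic screen.** Cell-level reporter values are
$\mathrm{Normal}(\delta_s, 1)$ — effects $\delta$ are expressed in units of
the within-cell reporter SD, the simplest distributional structure
consistent with sorting a unimodal population into thirds. Bin thresholds
are empirical pooled 1/3 and 2/3 quantiles (the whole population is sorted,
not each hairpin separately). Each bin is sequenced as a single multinomial
draw over the bin's realized hairpin composition; `dispersion > 0` switches
to per-hairpin negative binomial counts. Defaults: 100 cells per hairpin
(coverage heuristic; cell numbers per bin were not published), mildly
variable lognormal library abundances (sdlog 0.5, emulating uneven pooled
representation), depth 10⁶ reads per bin. The demo preset plants 5
resistance genes ($\delta_{drug} = +1$), 3 hypersensitizers
($\delta_{drug} = -0.8$) and 10 reporter modifiers ($\delta = -0.8$ in both
arms) among 500 genes. All hairpins of a planted gene carry the full gene
effect — knockdown-efficacy variation across hairpins of a gene is *not*
emulated, so a green recovery test establishes statistical recoverability,
not robustness to partial knockdowns.

**What a calibrated test cannot promise.** With ~482 neutral genes and a
rank test whose null calibration is exact, about $0.2$ neutral genes per
arm and seed will exceed $p \le 10^{-3}$ by chance. "Zero false resistance
calls over three seeds" therefore holds only with ~50% probability under
*any* correct implementation; the acceptance run documents one marginal
false call (p = 0.00098) at one of the three pre-committed seeds.

## 2. Co-fractionation correlation profiling

**Model.** Velocity sedimentation through a 5-20% sucrose gradient
separates complexes by size; 13 equal fractions are collected (fraction 1 =
top; sedimentation increases with index) and fractions 6-9 — the window in
which the drug-stabilized complex peaks — are quantified by label-free MS.
Per protein, replicate intensities are summed per fraction, the windowed
profile is normalized to sum to 1, and each profile is Pearson-correlated
with the profile of a reference complex subunit (eIF2B4 in the shipped
preset). Members of the same complex co-sediment and correlate near 1;
drug-induced dimerization shows as a coherent shift of all subunits toward
heavier fractions while unrelated large complexes (eIF3, proteasome) stay
put. The shift statistic is the difference of intensity-weighted mean
fractions between conditions.

**Choices.** Pearson, not Spearman — on 4-point profiles rank correlation
is nearly degenerate, and the published near-unity R values imply a
product-moment statistic. Replicates are summed before normalization ("sum
of the normalized peptide intensity" over two replicates admits either
order; because Pearson R is invariant to per-protein positive scaling,
the choice does not affect the headline statistic). "Normalized peptide
intensity" is read as per-protein profile normalization for the same
reason. Svedberg calibration is an OLS line through standards of known S
(ovalbumin 3.5 S, aldolase 7.3 S, thyroglobulin 19 S) at their observed
peak fractions, with peaks defined as profile argmax, ties broken toward
the lighter fraction. Constant (zero-variance) profiles get `NA`
correlation and are flagged; zero-intensity proteins in the window are
excluded with an explicit flag.

**Synthetic gradients.** Proteins sediment as Gaussian peaks over the
fraction axis; per-peptide intensities get multiplicative lognormal noise
(CV 0.2 by default, typical label-free variability) and are summed per
protein. The dimer preset moves the five GEF subunits' peak from fraction
5.8 to 7.0 under drug, leaves control complexes unmoved, and gives complex
members 14-30 peptides — in the range of abundant complexes in real
profiling runs, and enough that 4-point profile correlations exceed 0.98
reliably at the preset noise. Not emulated: peptide-level missingness,
interference, and shared peptides; the generator draws independent noise
per peptide and fraction.

## 3. GDP-dissociation kinetics

**Model.** Radiolabeled-GDP release from eIF2 is a first-order process:
$F(t) = c + A e^{-kt}$ with bound fraction $F$, plateau $c$, amplitude $A$
and rate $k$; $t_{1/2} = \ln 2 / k$. The default is the three-parameter
form: the published numbers themselves (a 3.2 min half-life alongside ~80%
release in 10 min) are mutually consistent only with a non-zero residual
plateau or an early lag, so a free plateau absorbs that. The two-parameter
form (plateau fixed at 0) is available and recorded in the fit metadata.
Fits pool replicates; initialization comes from a log-linear regression on
baseline-subtracted data; optimization is bounded L-BFGS-B with analytic
gradients (chosen over `nls()`, which rejects the zero-residual data used
in recovery checks). Data whose best fit pins $k$ at zero carry a
`no_decay` flag and an infinite half-life. Uncertainty comes from a
residual-resampling bootstrap (percentile 2.5/97.5 interval), refused below
two replicates since single-series residuals confound replicate scatter
with lack of fit.

**Presets.** Rate constants are derived exactly from printed half-lives
($k = \ln 2 / t_{1/2}$ for 3.2, 1.1, 6.7, 2.7, 6.4 and 5.3 min) or from
the intrinsic-release anchor (20% dissociated after 20 min:
$k = -\ln 0.8 / 20 \approx 0.0112$ min⁻¹); the phosphorylated-substrate
preset reuses the intrinsic rate (GEF addition leaves it essentially
unchanged). Noise is additive Gaussian on the bound fraction
(`noise_sd = 0.02`), clipped to $[0, 1.05]$ — filter-binding counts are
near-Gaussian at the plotted scale. Default sampling: 7 timepoints
(0-20 min), replicate counts following the published N per condition.

## 4. Dose-response potency and SAR additivity

**Model.** Reporter luminescence vs analog concentration follows a
four-parameter logistic,
$y = b + (T - b) / (1 + (\mathrm{EC}_{50}/d)^h)$, fitted by bounded least
squares on pooled replicates with EC50 on the log10 scale and the Hill
slope free in $[0.3, 5]$ (no fixed-slope convention is assumed; 4PL is the
standard reading of "half-maximal response" and a 3PL is one bound away).
Multi-start over Hill slopes guards against the flat-start local minimum.
EC50s outside the dosed range are flagged extrapolated; non-monotone mean
responses beyond ~3 residual SDs are flagged. EC50 is molar internally,
formatted in nM/pM for reports.

**SAR additivity.** The analog series is symmetric: two identical side
chains on a central spacer, each carrying one substituent from a labeled
set. The additivity model is
$\log_{10}\mathrm{EC}_{50}(X, Y) = \beta_0 + \Delta(X) + \Delta(Y)$ with
$\Delta(\text{reference}) = 0$ (reference: the optimal para-chloro chain),
fitted by OLS on the unordered pair table — $(X, Y)$ and $(Y, X)$ collapse
to one row. Residuals above 0.3 log10 units (~2-fold, a conventional SAR
tolerance) flag non-additivity. Each doubly modified analog must be
anchored by the reference pair and both single-substitution analogs;
missing anchors are an error, not a silent extrapolation. The shipped
`demo_sar_table()` is constructed exactly additively, anchored at the
parent potency (5 nM) with the doubly meta-fluorinated analog at 600 pM;
increments for the remaining substituents are this package's own choices
of realistic magnitudes (+0.5 to +1.2 for unfavorable para swaps, ~-0.45
for favorable meta additions) since per-analog EC50s for the middle of the
series were published only graphically.

## 5. Numerical and degenerate-input conventions

* All generators are pure functions of (design/preset, seed); they run in
  an isolated RNG scope and restore the caller's stream.
* Noise-free generators reproduce their closed forms to ≤ 1e-12; the
  recovery tests rely on this.
* Optimizers use `factr = 10` (≈ 2e-15 relative) so noise-free recovery is
  limited by conditioning, not stopping rules; fits with numerically zero
  residual that stall the line search are reported converged.
* Degenerate inputs fail loudly with named causes: all-zero sequencing
  bins, missing dialect columns, duplicate table keys, zero-variance
  reference profiles, sub-minimal standards or replicates.

## 6. Known limitations

* The screen generator models sorting noise and sequencing sampling but
  not PCR jackpotting, hairpin-specific toxicity, or variable knockdown
  efficiency.
* The kinetics module fits phenomenological first-order decays only; no
  mechanistic model of substrate/phospho-inhibitor competition is
  attempted, and no Michaelis-Menten analysis is provided.
* The co-fractionation module consumes protein-level intensity tables;
  peptide-to-protein inference and MS search are upstream concerns.
* The published gene-level screen p-values are not reproducible from this
  package because the underlying raw counts were never deposited; the
  acceptance suite therefore validates calibration, oracle agreement and
  planted-truth recovery on synthetic screens instead.
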
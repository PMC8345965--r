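---
title: "Methods: HDL apolipoprotein stability from Trp fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HDL apolipoprotein stability from Trp fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdlstab)
```

This vignette documents the model assumptions, the conventions and the
numerical choices behind `hdlstab`. It is the place where design decisions
are stated explicitly; the function reference documents the interfaces.

## 1. The assay and its statistic

HDL apolipoproteins are incubated in 8 M urea and their intrinsic tryptophan
fluorescence is scanned (excitation 280 nm, emission 300–400 nm) at fixed
incubation times. Folded, lipid-bound apolipoproteins emit near 330 nm;
solvent-exposed tryptophans emit redshifted, near 344 and 365 nm. The
denaturation statistic is the ratio of fluorescence intensities

$$\mathrm{rfi} = \frac{\mathrm{Em}_{344} + \mathrm{Em}_{365}}{\mathrm{Em}_{330}}.$$

Two conventions matter:

* Intensities are read at the **exact wavelengths** 330, 344 and 365 nm
  (linearly interpolated when off-grid), not at local maxima near them.
  Peak-hunting would make the statistic depend on noise realizations.
* The statistic is a ratio, so it is **invariant to per-spectrum rescaling**.
  Lamp drift, detector gain and uniform photobleaching cancel exactly. The
  synthetic generator includes a multiplicative bleaching term precisely to
  exercise this invariance.

## 2. Anchored normalization

The time course is mapped to percent denaturation by an affine anchor map

$$\mathrm{pct}(t) = 100\,\frac{\mathrm{rfi}(t) - \mathrm{rfi}(0\,\mathrm{h})}
{\mathrm{rfi}(26\,\mathrm{h}) - \mathrm{rfi}(0\,\mathrm{h})},$$

so the basal scan is exactly 0 % and the terminal scan exactly 100 %. The
implementation computes the ratio before multiplying by 100 so the anchors
are bit-exact, not merely close. Values are deliberately **not clamped** to
[0, 100]: out-of-range points (noisy anchors) are reported and flagged,
because clamping would silently mask anchor-quality problems. Series whose
terminal rfi does not exceed the basal rfi are rejected as degenerate or
inverted.

The per-subject **stability score** is `percent_at_time(norm, 8)`: percent
denaturation at 8 h, near the healthy-donor half-denaturation time, where
sensitivity to group differences is maximal. The default policy requires an
actual measurement at the query time; interpolation is opt-in.

## 3. Kinetics and the DT50 estimand

`fit_logistic()` fits the anchored two-parameter logistic

$$y(t) = \frac{100}{1 + \exp\!\big(-(t - t_{50})/b\big)}$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), with a
four-parameter variant (free asymptotes) for series whose anchors are noisy.
DT50 is the fitted $t_{50}$. Starting values are deterministic: $t_{50}$ from
the observation nearest 50 % of the fitted range, $b$ from the 25 %→75 %
crossing times via the logistic quantile spacing $\ln 9$, with a span/4
fallback; no random restarts, so fits are reproducible. Non-convergence is
flagged in the returned object rather than raised, so batch fits can report
partial results.

**The estimand subtlety.** In the synthetic spectral model the rfi is a ratio
of two affine functions of the unfolded fraction $f(t)$ (the numerator bands
gain intensity while the 330 nm band loses it). The anchored percent curve is
therefore a monotone *Möbius* reparametrization of the logistic, not the
logistic itself, and its 50 % crossing sits at a deterministic offset from
the kinetic inflection $t_{50}$ (about +8 % at the default transfer fraction
$\kappa = 0.8$). The assay defines DT50 *operationally* on the fitted percent
curve, so all recovery experiments in this package compare noisy-pipeline
DT50 against the **noiseless-pipeline DT50** (same generator, `noise_sd = 0`)
— the quantity the assay itself defines — not against the generator's latent
$t_{50}$.

## 4. Synthetic spectra

`simulate_spectrum()` draws each scan as a sum of three Gaussian bands:

* a buried-Trp band at 330 nm (width 16 nm), whose weight decays with the
  unfolded fraction $f$;
* exposed-Trp bands at 344 and 365 nm (width 20 nm, relative weights
  0.6/0.4), whose weights grow with $f$.

Parameters with rationale:

* `kappa = 0.8`: the maximum fraction of buried-band fluorescence transferred
  to the exposed bands at full denaturation. Chosen once, on the qualitative
  observation that the 330 nm band decreases but persists at the terminal
  scan; values near 1 would extinguish it.
* `base_amplitude = 1000` arbitrary units; `noise_sd` is additive Gaussian
  noise per grid point, **0 by default** (noise is opt-in, so deterministic
  pipelines stay deterministic).
* `bleach_rate = 0.01/h`: multiplicative intensity decay applied to the whole
  spectrum. It cancels in the rfi by construction and exists to verify that
  invariance.
* Kinetics defaults: logistic unfolded fraction with $t_{50} = 8$ h,
  $b = 1.5$ h, sampled at the protocol schedule (hourly 0–12 h plus 26 h).
  Control-condition series hold $f = 0$.

`simulate_densitogram()` builds native-gel absorbance traces as Gaussian
peaks: several HDL-associated peaks at low migration positions and one
free-protein peak at high position, with the generating region boundaries
recorded in `attr(d, "regions")`. The free-protein area is scaled so the
constructed trace has a requested free-protein percentage, which the
trapezoidal integrator then recovers. Region labeling in the analysis
functions is user-supplied (config or CLI), mirroring manual peak
identification; automatic labeling would inject unstated assumptions.

## 5. Synthetic cohorts

`simulate_cohort()` draws a case/control cohort (24 ACS cases, 20 controls by
default) calibrated marginal-by-marginal:

* Variables reported as mean ± SD are normal with those moments.
* Variables reported as median (IQR) — including the stability score — are
  **log-normal**, solved in closed form: `meanlog = log(median)`,
  `sdlog = log(q3/q1) / (2 qnorm(0.75))`.
* Binary covariates (sex, statin use, alcohol, smoking) are Bernoulli with
  the per-group rates (e.g. statin use 0/20 controls vs 21/24 cases).

Dependence is induced by a **one-factor Gaussian copula**: a shared latent
factor with per-variable loadings whose signs and magnitudes reproduce the
reported Spearman correlations with the stability score. Latent Pearson
loadings are obtained from Spearman targets by the exact Gaussian relation
$r = 2\sin(\pi\rho/6)$. All randomness flows through a seed-restoring helper
(`with_seed`), so cohorts are reproducible and the caller's RNG state is
untouched.

One calibration caveat is documented deliberately: several printed
dispersions are implausibly tight for standard deviations (e.g. HDL-C
spreads so small that close case–control HDL-C matches would be nearly
impossible) and are plausibly standard errors. The generator follows the
printed values as stated; tests that depend on dispersion use the printed
calibration.

## 6. Cohort statistics

* `compare_groups()` gates on Shapiro–Wilk normality (per group, α = 0.05):
  both groups normal → Student's two-sample t-test (equal variances);
  otherwise Mann–Whitney (normal approximation, no continuity correction).
  Binary variables go to χ² without continuity correction, with a flagged
  Fisher fallback when any expected cell count is below 5. An explicit
  `test=` override exists because the normality gate has low power at
  n = 20/24 and can select the t-test for mildly skewed variables for which
  the rank test is conventionally reported.
* `spearman_screen()` is a rank screen against the stability score, with
  optional Benjamini–Hochberg adjustment; constant covariates are flagged,
  not dropped silently.
* `partial_correlation()` is the first-order partial correlation via
  regression residuals, with the t-based p-value on n − 3 degrees of freedom;
  the default controlling covariate is statin use, the study design's main
  confounder (statin use is almost perfectly group-linked).
* `lipid_ratios()` computes per-subject apo A-I–to–HDL-lipid ratios and
  summarizes the mean of ratios per group (not the ratio of means), flagging
  non-positive denominators.

## 7. Matching and classification

`match_by_hdl_cholesterol()` pairs cases and controls whose HDL-C differs by
at most a tolerance (1 mg/dL default), greedily in ascending distance order
with deterministic id tie-breaks. Greedy matching is **not optimal in
general**: on chain configurations (cases {1, 2}, controls {2, 3}, tolerance
1) it pairs 2–2 and strands the rest, while the optimal matching pairs 1–2
and 2–3. The test suite therefore carries a brute-force augmenting-path
maximum-matching oracle; greedy never exceeds it, and equals it whenever
greedy matched every subject that had at least one feasible partner.

`rfe_logistic()` is recursive feature elimination over a logistic model:
stratified 75/25 train/verification split (reproducing a 33-subject training
set at 24/20), training-set standardization, repeated removal of the smallest
standardized |coefficient| down to `n_keep` features, and "effectivity"
(classification accuracy at a 0.5 threshold) on both subsets. When maximum
likelihood diverges on (quasi-)separated training data — the common case for
a single highly separating feature — the fit falls back to a small internal
ridge-penalized IRLS (λ = 0.1, intercept unpenalized), flagged as
`penalized` in the report. The fallback is hand-rolled because no installed
package fits penalized logistic models with a single predictor.

## 8. Numerical conventions

* Time and wavelength comparisons use absolute tolerances of 1e−6 (h, nm);
  exact grid hits return stored values, bypassing interpolation rounding.
* Trapezoidal integration with linear interpolation at region boundaries.
* The Levenberg–Marquardt tolerance is 1e−10 with 500 iterations; all
  starting values are closed-form.
* Typical problem sizes: 14-point time courses, 101–201-point spectral
  grids, cohorts of 44–4000 subjects, matching instances up to 24 × 20.
  Everything is vectorized base R; no compiled code.

## 9. Known limitations

* The normality gate's behavior at small n makes automatic test selection
  unstable for mildly skewed variables; use the explicit override when a
  specific test is prescribed.
* The greedy matcher is deliberately simple and can be suboptimal (see §7);
  the oracle in the test suite quantifies the gap rather than hiding it.
* Anchor scans enter every normalized point, so anchor noise is common-mode:
  DT50 recovery at 1 % amplitude noise has a sampling spread of roughly the
  same order as a ±2 % band, and tight recovery claims should be read
  against that.
* The classifier's perfect-verification probability is limited by the
  overlap of the calibrated log-normal tails near 40 % denaturation, not by
  the fitting method.
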
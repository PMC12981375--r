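---
title: "Synthetic-control estimation for weekly sales panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-control estimation for weekly sales panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthsales)
```

## The model

One brand in a multi-brand weekly sales panel is subject to an intervention
(e.g. regulatory enforcement) beginning in a known week. The counterfactual
— how the treated brand's sales would have evolved without the intervention
— is estimated as a *synthetic control*: a convex combination of untreated
donor brands,

$$\hat Y^{N}_{1t} \;=\; \sum_{j \ge 2} w_j\, Y_{jt}, \qquad
  w_j \ge 0,\; \textstyle\sum_j w_j = 1,$$

with weights chosen to minimise the squared discrepancy between the treated
and synthetic series over the pre-intervention weeks only. The *gap*
$Y_{1t} - \hat Y^{N}_{1t}$ after the intervention is the estimated effect
path. The key identifying assumptions are (i) the treated brand's
pre-period path is well approximated inside the donor convex hull, (ii) no
donor is affected by the intervention, and (iii) no other shock hits the
treated brand differentially during the study period.

The 52 study weeks are partitioned into pre (1–19 by default), intervention
(20–30), and post (31–52) windows. Weights are fitted on the pre window;
the headline effect is accumulated over the post window only, which is the
conservative choice — effects materialising during the intervention window
are ignored unless `effect_window(w, include_intervention = TRUE)` is
requested.

## Standardization

Brand sizes in retail scanner panels span four orders of magnitude, so the
SCM objective would otherwise be dominated by the largest donors. Each
brand is therefore rescaled by pre-window statistics:

| method  | location       | scale          |
|---------|----------------|----------------|
| zscore  | pre-mean       | pre-SD         |
| minmax  | pre-minimum    | pre-range      |
| robust  | pre-median     | pre-IQR        |

Two numerical conventions are deliberately config-switchable because the
field has no single standard: the z-score SD uses the sample ($n-1$)
denominator by default, and the IQR uses linear-interpolation quantiles
(`type = 7`). Both choices only rescale the objective uniformly per brand;
pipeline conclusions do not hinge on them.

The transform is affine and estimated from pre weeks only, hence exactly
invertible: `destandardize(v, location, scale) = v * scale + location`.
Because the treated brand's actual and synthetic series are mapped back
through the *same* affine map, the location cancels in their difference and
the unit-scale gap is simply `gap * scale`. This identity is why cumulative
unit effects are (numerically exactly) method-independent whenever the
standardized gaps agree, and it is enforced to 1e-9 relative error in the
acceptance suite.

Degenerate scales (constant pre-period sales; zero IQR) make a brand
unrescalable: donor brands are dropped with a warning, a degenerate treated
brand is fatal. Nothing is imputed.

## Weight estimation

The predictors are the pre-window standardized outcomes themselves, one per
week, equally weighted — no auxiliary covariates and no predictor
reweighting matrix. The fit is then a least-squares problem on the
probability simplex, a strictly convex QP (up to donor collinearity). It is
solved exactly with a primal active-set algorithm: solve the
equality-constrained KKT system on the current support, clip variables
driven negative at the boundary, admit a new variable only when its reduced
gradient beats the support's Lagrange multiplier. Initialisation is uniform
weights; ties break on the first index; a ridge of `1e-12 * mean(diag(X'X))`
stabilises solves under exact collinearity. The algorithm is deterministic,
needs no seed, and its objective is verified against a dense simplex
grid-search oracle (step 1e-3, tolerance 1e-6) in the tests. Weights below
1e-6 are zeroed and the remainder renormalised so the reported count of
contributing donors is stable; the synthetic *series*, not the weight
vector, is the contract under collinearity.

## Inference

No asymptotic distribution is available for the SCM gap, so inference is by
in-space placebo permutation. Every brand is re-cast as a false treated
unit and fitted with its own synthetic control; the test statistic is the
post/pre MSE ratio

$$r_b = \frac{\mathrm{MSE}_{\text{post}}(b)}{\mathrm{MSE}_{\text{pre}}(b)},$$

which normalises each brand's post-period divergence by how well it could
be fitted at all. The overall p-value is the share of brands — placebos
*plus* the actual treated unit, so $p \in [1/n, 1]$ — with $r_b$ at least
as large as the treated brand's; ties count as at least as large.
Week-specific p-values apply the same counting rule to per-week absolute
gaps.

Three design points were genuinely open and are resolved as follows, each
config-switchable:

* **Placebo donor pools exclude the treated brand** (default). If the
  intervention is real, the treated series carries the effect; letting
  placebos borrow it would contaminate the null distribution toward larger
  placebo gaps and conservative p-values. Exclusion is the standard
  decontamination practice; `include_treated_in_pools = TRUE` restores the
  alternative.
* **Weekly statistics are two-sided** (absolute gaps). Week-level direction
  handling has no field consensus; `weekly_stat = "signed"` gives the
  one-sided variant where only sales *drops* count as extreme.
* **No multiple-testing adjustment** across the ~22 weekly p-values: they
  are descriptive of effect timing, reported raw.

A brand whose placebo fit fails is excluded with a warning and the
denominator `n` adjusted; the diagnostic table from `mse_scatter()` helps
spot brands ranked highly only because their pre-period MSE denominator is
tiny.

## The synthetic-data generator

Licensed scanner data cannot ship with the package, so `generate_panel()`
produces panels with the structure the analysis assumes:

* **Heavy-tailed brand sizes**: mean brand scale is log-normal with
  `size_log_mean = log(1400)` and `size_log_sd = 3`. These were fixed
  analytically before any testing: the log-normal median identity pins the
  target ~1,400-unit median, and `sdlog = 3` puts the expected maximum of
  52 draws, $\exp(\mu + \sigma\,\Phi^{-1}(1 - 1/53))$, in the millions —
  matching a panel whose mean (~114k) is two orders of magnitude above its
  median.
* **Common structure**: a mild multiplicative trend (−0.2 %/week) plus two
  log-scale common factors. The first factor carries a positive mean
  loading (`market_loading = 0.3`, loadings $N(0.3, 0.1)$): a *market*
  factor all brands load on with the same sign. This is both realistic
  (weekly sales of same-category brands comove strongly through demand,
  seasonality, and distribution shocks) and structurally necessary: with
  mean-zero loadings, donors are mutually near-uncorrelated, a multi-donor
  convex combination averages away most of its variance, and after
  per-brand rescaling the treated unit needs total donor weight > 1 —
  outside the simplex — making the stated in-hull property unattainable.
  The 0.3 default was calibrated by simulation against the stated
  structural target (treated pre-window MSE below 0.05 standardized units²
  at default noise) and then frozen.
* **Noise**: multiplicative log-normal with unit mean, donor CV 0.05.
  Additive Gaussian noise would go negative for the many sub-1,000-unit
  brands.
* **Treated brand**: a random Dirichlet(1) convex combination of 10
  randomly chosen donors, times its own multiplicative noise with CV 0.02 —
  chosen so the pre-period percent fit diagnostic stays within ±1%,
  emulating a panel where the treated brand is tightly matchable.
* **Effect**: a multiplicative ramp, 1 at the onset week (20) declining
  linearly to `1 - effect_final_fraction` (default fraction 0.685) at the
  final week — a gradual divergence rather than a step, as enforcement
  actions propagate through the supply chain over weeks. A log-linear ramp
  and shorter ramps are config options. Donor series are bit-identical with
  and without the effect.

What a green test does **not** establish: the generator has no
cross-sectional correlation beyond the two-factor structure, no
seasonality, no price/promotion dynamics, no retail-channel composition,
and its treated brand is *exactly* in the noisy donor hull by construction.
Recovery results on this stated world bound estimator correctness, not
real-world identification.

## Numerical and degenerate-input choices

* Windows must partition 1..T contiguously; the pre window needs ≥ 2 weeks
  (scale estimation requires dispersion).
* Duplicate (brand, week) rows, negative sales, and schema mismatches are
  hard errors at ingestion; missing weeks flag the brand for exclusion.
* Sub-brand aggregation refuses to merge a never-explicitly-mapped brand
  into the treated unit's major label (silent contamination of the treated
  series).
* Identical donors: any simplex point is optimal; the deterministic solver
  output is accepted and the synthetic series is the tested contract.
* Percent summaries are undefined (NA with a warning) when the
  destandardized synthetic is non-positive at the evaluation week.
* All result tables are written with fixed formatting so identical
  config + seed reproduce byte-identical files.

## Known limitations

* Outcomes-as-predictors SCM only: no covariates, no predictor-importance
  matrix, no ridge/bias-corrected variants, no synthetic
  difference-in-differences.
* Inference is permutation-based only; no conformal or t-test intervals on
  the effect path.
* The generator's calibration targets are moments, not microdata; it is a
  test harness, not a market simulator.
* JSON (not YAML) configuration, reflecting the dependency set.
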
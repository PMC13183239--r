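---
title: "Methods: spectra-to-trait modelling across a cultivar hierarchy"
author: "vitispec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra-to-trait modelling across a cultivar hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitispec)
```

# The problem

Leaf functional traits — gas exchange (transpiration `E`, light-saturated
photosynthesis `Amax`, stomatal conductance `gs`), chemistry (`N`, `C`,
`d13C`), water relations (predawn water potential `Psi_pd`, intrinsic and
instantaneous water-use efficiency `WUE_intr = Amax/gs`,
`WUE_inst = Amax/E`) and morphology (`Area`, `LDMC`, `LMA`) — vary not only
between species but *within* a crop species, across cultivars grown on a
single farm.  Two questions drive the package:

1. How is trait variance distributed across the cultivar hierarchy
   (variety origin, red/white colour class, cultivar identity, planting
   row, leaf-level residual)?
2. Can full-range leaf reflectance (400–2400 nm) predict this
   *intraspecific* trait variation, which is far smaller than the
   cross-species variation most spectroscopic trait models exploit?

The statistical machinery is deliberately classical: nested random-effects
variance partitioning, one-way ANOVA with Tukey HSD, and partial least
squares regression (PLSR) with leave-one-out PRESS component selection,
VIP interpretation, and jackknife uncertainty — the standard chemometric
protocol of leaf spectroscopy.

# The PLSR core

`plsr()` implements the orthogonal-scores NIPALS algorithm for a single
response.  Predictors are mean-centred; unit-variance scaling is a flag and
is **off** by default, because reflectance bands share one physical unit and
the spectroscopy literature conventionally centres only.  For univariate
responses the weight update is closed-form (no inner iteration) and
response-side deflation is provably redundant, making the algorithm
equivalent to SIMPLS; the suite verifies the fit against ordinary least
squares on full-rank problems and against an independent PLS implementation
(mixOmics) on random wide problems.

Regression coefficients are stored for *every* component count `1..A`, so
cross-validation and truncated prediction never refit.  VIP scores follow
Wold's definition with the response sum of squares per component computed
as the score sum of squares times the squared response loading; the squared
scores average to exactly 1 over bands, and the conventional 0.8 / 1.0
thresholds mark influential bands.

## Component selection

`loo_press()` computes `PRESS(a)` for `a = 0..A_max` by refitting without
each calibration leaf (`a = 0` is the leave-one-out mean, so a selection of
0 means "no latent component explains the covariance" — a model *failure*
surfaced as a status, never an exception).  Two selection rules are
offered:

* `"min"` — the strict argmin, ties to the smaller count.  This is the
  base contract and the rule the brute-force oracle tests pin down.
* `"onesigma"` — the one-standard-error parsimony convention: the smallest
  count whose PRESS lies within one standard error of the minimum.  The
  protocol layer (`fit_trait_model()`, `run_pipeline()`) defaults to this
  rule, for a reason worth stating precisely: past the elbow the PRESS
  curve is nearly flat, and the literal minimum wanders far right on
  sampling fluctuations.  In the limiting case of *noise-free* synthetic
  spectra the problem is structural, not statistical — the spectra are
  then a deterministic function of the trait, `PRESS(a)` decreases
  monotonically in `a`, and no argmin-based rule can return a parsimonious
  count at all.  The one-sigma rule is also what the established component
  selectors in the field's reference tooling apply.

The component search is capped at `min(15, n_cal - 2)`; published selected
counts in comparable campaigns reach 11, so the cap is not binding in
practice while keeping the LOO loop affordable.

## Uncertainty

`jackknife_uncertainty()` refits the model `B` times (default 500) on
random 80% subsamples of the calibration rows.  Per validation leaf, the
95% *confidence* interval is the 2.5/97.5 percentile band of the `B`
predictions (calibration-sampling uncertainty); the *prediction* interval
widens it by `±1.96 σ`, with `σ` the leave-one-out residual SD at the
selected count (irreducible observation noise).  The classical delete-one
jackknife is available as a mode.  On simulated vineyards the 95% PI
achieves empirical coverage between 0.90 and 1.00 (verified in the suite).

# Data splitting

Both published regimes are implemented exactly:

* **random** — `n_cal = floor(0.8 n)`; this floor rule is the unique one
  consistent with all published random-split counts (173→138/35,
  172→137/35, 163→130/33, 160→128/32);
* **group-balanced ("cultivar")** — `ceil(0.2 n_k)` validation leaves
  drawn *within* each cultivar, giving 36 validation leaves for 173
  observations over 12 groups of 13–15.

Splits partition the leaf ids; a cultivar with a single leaf cannot be
balanced and is refused by name.

# Trait screening

`summarize_trait()` reports mean, SD, median, MAD, range, CV and a
Shapiro–Wilk test.  Conventions chosen where the field leaves slack, each
configurable: the MAD is **unscaled** (no 1.4826 factor); the CV uses the
**absolute** mean, so negative-valued traits (`Psi_pd`, `d13C`) get a
positive percentage; quantiles/quartiles use the type-7 linear
interpolation convention throughout.  Outliers are masked per trait cell by
the IQR rule with a factor of 2 (`iqr_outlier_filter()`), never removing a
whole leaf.  The transform registry defaults to a natural log for the five
strongly right-skewed traits (`WUE_inst`, `WUE_intr`, `Area`, `LDMC`,
`LMA`), renaming columns with a `log-` prefix; the base of the log only
shifts coefficients, not R².

# Variance partitioning

`fit_variance_components()` treats the hierarchy as strictly nested —
row within cultivar within colour within origin — coding colour units as
`origin:colour` and row units as `cultivar:row`.  Whether planting row is
nested or crossed is genuinely open in vineyard designs; nested was chosen
because rows here are positions within a cultivar's block, and the coding
makes that explicit.  Variances are REML estimates (random intercepts via
lme4), which are non-negative by construction; proportions are normalized
by the total so they sum to exactly 1.  Degenerate designs fall back to a
method-of-moments one-way estimator, and the method used is recorded on the
result.  With only two origin levels the origin variance is weakly
identified — an unavoidable property of the design, visible in the wide
replicate spread of that component on synthetic data.

# The synthetic vineyard

No raw data ship with the package; `simulate_vineyard()` generates
cultivar-structured data with *known* ground truth, which is what the test
suite exercises.

**Design.** 12 cultivars in 7 varieties (2 clones for five varieties, 1 for
two), each variety one colour and one origin class, 3 rows × 5 vines per
cultivar, one leaf per vine: 180 leaves before missingness.  Which variety
belongs to the "warm" vs "cool" origin class is an arbitrary binary label
at variety level.

**Traits.** Each trait is `mean + origin + colour + cultivar + row +
residual`, every effect drawn once per nested grouping unit from a
zero-mean normal with variance `proportion × total_sd²`.  Default means,
SDs and variance proportions are read from the packaged
`default_sim.yaml`, seeded from published descriptive statistics for 178
field-grown grapevine leaves; for traits summarized there by median and
CV, the simulator seeds the mean with the median and the SD with
`CV × median / 100`.  Trait cells go missing completely at random at rate
0.03 per cell, so per-trait sample sizes differ as in real campaigns.

**Spectra.** `reflectance(λ) = baseline(λ) · exp(−Σ strength·z(trait)·
gaussian(λ))` plus band noise, clipped to [0, 1], on the 400–2400 nm grid
at 1 nm.  The baseline is a packaged 2001-point synthetic template
(`make_baseline_template()` regenerates it analytically: logistic red edge,
green peak, NIR plateau, water dips at 1450/1940 nm, declining SWIR tail).
Default links place each trait's absorption where it plausibly expresses
optically (red edge for photosynthesis-linked traits, water bands for
water status, SWIR for dry matter).  `d13C` has **no** link by design: an
isotopic signature has no direct optical expression, so the protocol should
— and does — report a component count of 0 for it, reproducing the honest
failure mode of the reference campaign.

**Nuisance variation.** Three leaf-level, trait-independent factors
(multiplicative amplitude, extra water-band depth, smooth tilt; SDs 0.05 /
0.05 / 0.03) bound achievable retrieval skill.  They matter because
independent per-band noise averages out over 2001 bands and would otherwise
let PLSR retrieve every linked trait almost perfectly, which no field
campaign shows.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: radiative-transfer leaf optics (no PROSPECT-style
physics), cross-trait correlation beyond shared hierarchy effects,
instrument splice artefacts, phenology, and the specific published R²
values (the underlying raw data are not public; reproducing their exact
numbers is explicitly out of scope).  Retrieval on the default generator is
accordingly somewhat easier than in the field: typical validation R² for
linked traits here is ~0.5–0.95, versus ~0.1–0.6 in comparable published
campaigns.

# The pipeline

`run_pipeline()` fixes the stage order: input → derive WUE → summarize →
transform registry → IQR outlier masking → per trait × split regime:
split → LOO-PRESS selection → final fit → validation metrics → VIP and
region summaries → jackknife.  Outliers are masked *before* splitting so
both regimes see the same cleaned table.  Both split regimes always run;
failed traits are reported with status `"no latent component"`, never
dropped.  The report bundle is plain CSV plus a JSON manifest (seeds,
settings, per-trait outlier tallies), and identical seeds give
byte-identical outputs.  A thin command-line wrapper
(`vitispec_cli()`, `inst/scripts/vitispec.R`) exposes simulate /
summarize / partition / fit / run.

# Numerical choices and degenerate inputs

* NIPALS stops early when the remaining covariance norm falls below
  1e-12; coefficient vectors for higher counts are padded with the last
  attainable one.
* A zero-variance response yields all-zero coefficients with a flag, not
  an error; a zero denominator in a WUE ratio yields a missing cell with a
  warning.
* Reflectance in (1, 1.2] is tolerated with a warning (slight over-unity
  readings against a white reference); outside [0, 1.2] is rejected naming
  leaf and wavelength.
* Ties in PRESS go to fewer components; `which.min` semantics make this
  exact.
* The degenerate IQR (all values equal) removes nothing; `factor = Inf`
  removes nothing.

# Problem sizes used by the suite

Unit tests run on small matrices (8×4 to 25×50) where oracles are exact;
protocol tests use compact vineyards (10 cultivars × 12–15 leaves, and a
400–900 nm window for the orchestration tests); the Monte-Carlo checks use
30–100 replicates for variance-component recovery and 500–1000 null
simulations for ANOVA type-I calibration; the acceptance script runs the
full default vineyard (180 leaves × 2001 bands, 12 traits × 2 regimes).
These sizes were chosen so every statistical assertion has comfortable
Monte-Carlo margin while the whole suite stays quick to iterate on.

# Known limitations

* The origin and colour variance components rest on 2 and ≤4 units; their
  single-fit estimates are noisy by design, as in the motivating campaign.
* `%RMSE` normalizes by the observed validation range (`max − min`);
  range-, mean- and IQR-normalizations all circulate in this literature,
  and none is identifiable from published summaries alone.
* The "jackknife permutation" of the chemometric literature is not a
  single well-defined procedure; the repeated-subsample implementation here
  (with the classical delete-one as a mode) is one defensible reading.
* LOO is implemented with `n_cal` refits, the standard definition, even
  though some published protocol descriptions state `n_cal − 1` iterations.
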
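---
title: "Compositional 24-hour time-use analysis and the Goldilocks Day"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional 24-hour time-use analysis and the Goldilocks Day}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldilocks24)
```

## The scientific problem

A day has a fixed budget of 24 hours, spent on four movement behaviours:
sleep, sedentary behaviour (SB), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA). Because these durations are
parts of a fixed total, they carry only *relative* information: increasing
one behaviour necessarily displaces others. Standard regression of a health
outcome on raw durations ignores this constraint and produces coefficients
that cannot be interpreted one-at-a-time.

`goldilocks24` analyses day compositions in Aitchison geometry. A day is a
point on the 3-simplex scaled to 24 h; it is mapped to three unconstrained
real coordinates by the isometric log-ratio (ilr) transform; adiposity
outcomes (BMI z-score, fat-mass %, fat-mass index, visceral adipose tissue)
are regressed on those coordinates plus covariates; and the "Goldilocks
Day" — the day composition associated with healthy adiposity — is estimated
as the compositional mean of all *observed* days whose model-predicted
adiposity falls below a healthy threshold.

## Model and procedure

### Simplex geometry

A composition $x = (x_\mathrm{sleep}, x_\mathrm{SB}, x_\mathrm{LPA},
x_\mathrm{MVPA})$ with strictly positive parts is closed to 24 h by
$\mathcal{C}(x) = 24\,x / \sum_j x_j$. Zeros are a hard error by design:
the intended inputs are accelerometer summaries in which all four
behaviours are observed every day, and no zero-replacement strategy is
implemented.

The ilr coordinates are built from a sequential binary partition (SBP).
Each split of the parts into an "up" group of size $r$ and a "down" group
of size $s$ defines one balance,
$$ z = \sqrt{\tfrac{rs}{r+s}}\,
   \ln\frac{g(x_\mathrm{up})}{g(x_\mathrm{down})}, $$
with $g(\cdot)$ the geometric mean. The default SBP is
(sleep | SB, LPA, MVPA), (SB | LPA, MVPA), (LPA | MVPA). The contrast
matrix $V$ is orthonormal with zero column sums, so $z = V^\top \ln x$ is
closure-invariant and $x = \mathcal{C}(\exp(Vz))$ inverts it.

Every quantity this package reports — block F statistics, fitted values,
predictions, compositional means, Goldilocks Days — is provably invariant
to the SBP, because any two ilr bases differ by an orthogonal rotation of
the coordinate space. The SBP choice is therefore cosmetic (it changes only
the interpretation of individual slopes), but it remains configurable, and
the invariance is asserted numerically in the test suite at 1e-8.

The compositional mean of a sample is the part-wise geometric mean closed
to 24 h; it coincides with the arithmetic mean taken in ilr coordinates and
mapped back, which is the property that makes it the natural "centre" of a
set of days.

### Cohort ingestion rules

Day-level records enter the analysis when the device was worn at least
16 h that day; participants enter when they have at least 4 valid days
including at least one weekend day. "At least" is read inclusively
($\geq$) at both boundaries. Weekly behaviour profiles weight weekdays and
weekend days 5:2,
$$\bar{x} = \tfrac{1}{7}(5\,\bar{x}_\mathrm{weekday} +
  2\,\bar{x}_\mathrm{weekend}),$$
and closure to 24 h is applied *after* this weighted average — day totals
are allowed to deviate slightly from 24 h, and only the analysed weekly
composition is forced onto the simplex. Fat-mass index is fat mass (kg)
over height (m) squared. Snacking is dichotomized as "high" when any of
the three snack items (sweets, sugary drinks, crisps) is consumed at least
once per day. Age groups split at completed years: 8–13 are children,
14–18 adolescents; fractional ages use `floor()`, a choice the input
contract documents because ages near the 13/14 boundary are otherwise
ambiguous. Missing maternal covariates are handled by complete-case
deletion only, under an MCAR assumption.

### Compositional regression and the block F-test

For each age group and outcome the model is
$$ y = \beta_0 + \beta_1 z_1 + \beta_2 z_2 + \beta_3 z_3
     + \gamma^\top c + \varepsilon, $$
with $c$ the coded covariates (sex: boy = 1; maternal BMI, continuous;
maternal education: university = 1; snacking: high = 1), fitted by ordinary
least squares through a QR decomposition. Rank deficiency is an error that
names the collinear columns rather than a silent coefficient drop. With
the standard covariate set the model has 8 coefficients, so the residual
degrees of freedom are $n - 8$ ($n - 9$ when the log wear-time sensitivity
covariate is added).

Whether the 24-h composition is associated with the outcome is tested by
the Type III F-test of the three-coefficient ilr block. With no
interactions in the model this is exactly the partial (full-vs-reduced)
F-test
$$ F = \frac{(\mathrm{RSS}_\mathrm{red} - \mathrm{RSS}_\mathrm{full})/3}
            {\mathrm{RSS}_\mathrm{full}/(n-8)} \sim F_{3,\,n-8}, $$
and the package implements it both this way and as the general linear
hypothesis $H_0: C\beta = 0$ on the full-model coefficient covariance; the
two routes are asserted equal at 1e-8 and additionally cross-checked
against `car::linearHypothesis()` in the tests. If the full model fits the
outcome exactly the statistic diverges; the result is returned with
$p = 0$ and an `exact_fit` flag instead of a numerical explosion.

Group compositions (e.g. children vs adolescents, complete vs incomplete
cases) are compared by one-way MANOVA on the ilr coordinates, reported as
Pillai's trace — chosen as the robust default among the MANOVA statistics —
with its F approximation.

### Goldilocks Day estimation

Prediction is restricted to compositions actually observed in the analysis
sample, deliberately avoiding extrapolation beyond the sampled region of
the simplex. Covariates are fixed at the analysis-sample means by default.
The choice of profile provably cannot change the result: a fixed profile
shifts every prediction by the same constant, percentile thresholds are
equivariant under shifts, so the healthy-set mask — and with it the
Goldilocks composition and behaviour ranges — is invariant; only the
reported predicted-outcome values shift. Per-participant ("observed")
profiles are also implemented; they can in principle reorder the mask, and
mean-profile is the default. All of this is asserted numerically in the
tests.

Predictions below the 85th percentile of the predicted-value distribution
count as healthy (strictly below; lower adiposity is healthier for all
four indicators, and a `direction = "high"` switch covers future outcomes
with the opposite orientation). The percentile uses linear interpolation
of order statistics, $h = (n-1)p + 1$ (`stats::quantile()` type 7, the
common statistical default). The Goldilocks Day is the compositional mean
of the healthy set; per-behaviour ranges are healthy-set minima and maxima
(the natural reading of a reported min–max range); and the model prediction
at the Goldilocks composition itself is reported alongside the range of
healthy predictions. A subtlety found while testing: because closure
rescales the geometric means, a behaviour that is *constant* across the
healthy set can end up marginally outside its own degenerate min = max
range; this is a property of compositional means, not a defect, and it is
immaterial for non-degenerate data.

### Tetrahedron visualization

Four-part compositions live in a regular tetrahedron: each behaviour is
100% of the day at its apex and 0% on the opposite face, and a day's
coordinates are the barycentric combination $\sum_i p_i V_i$ of the apex
coordinates with weights $p_i = x_i/24$. `tetra_coords()` computes these
3-D points (unit edge length) and `export_tetra()` writes a labelled JSON
point cloud — apices plus one record per day with its predicted outcome —
consumable by any 3-D scatter viewer; the package deliberately exports a
static artifact rather than bundling an interactive viewer.

## The synthetic cohort generator

The generator is first-class, tested code: it encodes the study conditions
the analysis assumes and provides the ground truth for calibration and
recovery experiments. It emulates:

* **Compositions** — logistic-normal per age group: ilr coordinates drawn
  from a multivariate normal centred at the ilr image of the group's target
  compositional mean (children 8.6, 10.4, 4.0, 1.0 h; adolescents 7.5,
  12.2, 3.6, 0.7 h), so the sample compositional mean converges to the
  target. The spread is parameterized as a log-part covariance with
  standard deviations (children 0.095, 0.225, 0.15, 0.40; adolescents
  0.135, 0.165, 0.20, 0.38) and log-correlations (sleep–SB +0.55/+0.45,
  SB–LPA −0.40/−0.45, SB–MVPA −0.25/−0.30), calibrated once so the induced
  part-wise SDs after closure sit near the reported cohort SDs (sleep
  0.6–0.7 h, SB 1.3–1.4 h, LPA 0.7–0.8 h, MVPA 0.3–0.4 h). The positive
  sleep–SB log-correlation is what keeps sleep hours stable while SB varies
  widely: closure alone would otherwise push SB variation into sleep.
* **Covariates** — boys 42.5%; maternal BMI Normal(24.4, 4.1) kg/m²;
  university education 40%; high snacking 58.3% (children) and 74.7%
  (adolescents), emitted as concrete ordinal questionnaire answers so the
  snacking classifier is exercised end to end.
* **Outcomes** — linear in the ilr coordinates plus covariates with
  Gaussian noise. The ilr slope vector points along the SB balance (more
  SB relative to everything else predicts higher adiposity, less sleep and
  activity aggravate it) and is scaled so the composition block explains
  5% of outcome variance — the share reported for such models in this
  literature — while the residual SD is set so the total outcome SD matches
  its target (e.g. VAT 48.8 ± 31.2 cm²). Intercepts are derived from the
  group-mixture means, so all coefficients are computed, exported as
  ground truth, and recoverable.
* **Missingness** — MCAR at 5% (maternal BMI) and 2.4% (education).
  Independent rates remove $1 - 0.95 \times 0.976 \approx 7.3\%$ of
  records under complete-case deletion.
* **Day tables** — 7 days per participant (5 weekday, 2 weekend) with
  Gaussian ilr jitter (SD 0.15) around the weekly profile and near-complete
  wear, so the ingestion filters are exercised end to end.

Sub-streams (compositions, covariates, noise, days, missingness) are
derived deterministically from the single configured seed, so cohorts are
byte-reproducible and modules can be regenerated in isolation.

What the generator does **not** emulate: the real cohort's joint
distribution beyond these first and second moments; measurement error in
bioimpedance or accelerometry; within-participant day-to-day structure
beyond i.i.d. jitter; age trends within groups; and any dependence of
missingness on observed data. Passing recovery and calibration tests
therefore demonstrates the correctness and calibration of the estimator
machinery under the model's own assumptions — not that those assumptions
hold in any particular real dataset. Two further small realism compromises
are documented rather than hidden: simulated VAT is Gaussian and can in
rare tail draws be negative, and FMI is floored at 0.05 kg/m² solely so the
derived fat mass stays physical (the floor affects only the far tail).

## Numerical choices

* Geometry identities are tested at 1e-9 absolute; basis orthonormality at
  1e-10; SBP-invariance of fitted quantities at 1e-8.
* Least squares uses the QR path of `stats::lm()`, never normal equations;
  aliased columns are reported as errors.
* `ilr_inverse()` subtracts the row-wise maximum before exponentiating, so
  arbitrarily large coordinates return valid closed compositions instead
  of overflowing.
* The exact-fit guard in the block F-test triggers when
  $\mathrm{RSS} \leq 10^{-12}\, n \,\overline{y^2}$.
* Percentile: type-7 interpolation, strict `<` at the threshold.
* Reported tables round behaviours to 0.1 h and outcomes to 0.1 units;
  full precision is kept internally and in JSON exports.

## Simulation study sizes

The packaged experiments use: 1,000 randomized sets for the
compositional-mean oracle equivalence; 2,000 replicates of $n = 300$ for
the null calibration of the block F-test (nominal 5% ± 1.5 percentage
points); 500 replicates of $n = 150$ per group for 3-standard-error
coverage of the generating coefficients (expected coverage
$0.9973^8 \approx 0.98$ against a 0.94 floor); $n = 5{,}000$ per group for
emulation-fidelity checks within 3 Monte-Carlo SEs; and 2,000 replicates
for uniformity of MANOVA p-values under the null (Kolmogorov distance
< 0.05). These sizes were chosen to make Monte-Carlo error comfortably
smaller than the tested tolerances while keeping the default test run
fast.

## Known limitations

* The pipeline consumes day-level behaviour summaries; raw accelerometer
  processing (intensity cut-points, sleep detection, nonwear) is out of
  scope, as are WHO BMI z-score reference computations and bioimpedance
  device equations.
* Only 4-part compositions are fully supported downstream of the geometry
  layer (the basis machinery itself is written for general $D$).
* No uncertainty interval accompanies the Goldilocks Day; the estimator is
  a plug-in compositional mean over an estimated healthy set.
* The significance gate (p < 0.05, unadjusted across the 8
  outcome-by-group tests, matching the way such analyses are convention-
  ally reported) controls only which cells get a Goldilocks estimate; a
  Benjamini-Hochberg option is provided for users who want multiplicity
  control.
* Complete-case deletion is unbiased only under MCAR; no imputation is
  offered.
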
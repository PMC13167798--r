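---
title: "Methods: from RFID signal strength to movement inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RFID signal strength to movement inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawtrack)
```

strawtrack implements a complete analysis chain for single-receiver RFID
movement monitoring of group-housed pigs: signal-strength calibration,
construction of an hourly movement metric, and longitudinal mixed-model
inference on the diurnal, day-level and individual structure of that
metric, plus a second model relating movement to barn-environment
covariates. This vignette explains each model, the assumptions behind
it, the tunable parameters, and the numerical choices made where a
published analysis description leaves the implementation open.

## 1. From RSSI to distance

A passive ear tag detected by a wall-mounted receiver yields a received
signal strength indicator (RSSI, dBm). Under the log-distance path-loss
model,

$$RSSI = T_x - 10\,n\,\log_{10}(d), \qquad
  d = 10^{(T_x - RSSI)/(10n)},$$

where $T_x$ is the expected signal strength at the 1 m reference
distance and $n$ is the path-loss exponent ($n = 2$ in free space;
typically 1.6–3.5 indoors, where multipath and absorption matter).
`fit_path_loss()` estimates $(T_x, n)$ by ordinary least squares of
RSSI on $-10\log_{10}(d)$ over calibration records taken at known
distances — the model is linear in both parameters, so no iterative
fitting is needed — and reports the residual standard error in dB.
`distance_from_rssi()` applies the inverse formula; it is total and
strictly decreasing in RSSI. Distances above a configurable
plausibility cap are flagged but never altered, so downstream filtering
stays explicit. When generating synthetic detections the tag–receiver
distance is floored at 0.1 m: physical tag-to-antenna separation never
reaches zero, and the floor keeps $\log_{10}(d)$ finite.

Range-only positioning has an inherent limitation worth stating:
distance to a single receiver is one-dimensional, so motion tangential
to the receiver changes the estimate little, and the movement metric
underestimates true displacement. The package does not attempt to
correct this; it is a property of the metric itself.

## 2. The hourly movement metric

Movement is quantified as the sum of absolute changes in estimated
distance between consecutive detections: the sequence 4 m → 2 m → 5 m
contributes $|2-4| + |5-2| = 5$ m. `aggregate_hourly()` sums these
increments within clock hours and reports cm·h⁻¹. Three rules are
implementation choices the package documents rather than inherits:

* **Increment assignment.** Each increment is credited to the hour (and
  day) containing the *later* of its two detections. Every increment is
  counted exactly once, the rule is stable under row order, and
  increments crossing hour or midnight boundaries are retained rather
  than discarded.
* **Hour validity.** An hour is valid iff at least one detection falls
  in it. Invalid hours carry no movement value — absence of positioning
  data is lack of information, not evidence of inactivity — and
  `analysis_table()` excludes them from inference.
* **Receivers.** A single-receiver deployment is assumed. Events
  stamped with another receiver are dropped with a warning; no fusion
  rule is applied because none would be identifiable from one cabinet.

Hours are labelled by their start (hour 15 = 15:00:00–15:59:59) and
day $d$ = 1 + whole days elapsed since the configured study start, in a
single configured time zone.

## 3. The movement mixed model

Valid hourly records $y_{idh}$ (pig $i$, day $d$, hour $h$) are
modelled as

$$y_{idh} = \mu + Day_d + Hour_h + (Day \times Hour)_{dh} + b_i +
  \varepsilon_{idh},$$

with $b_i \sim N(0, \sigma^2_{pig})$ a persistent pig-level baseline
and $\varepsilon$ an AR(1) process over the hours of each pig-day:
$\mathrm{cor}(\varepsilon_{idh}, \varepsilon_{idh'}) = \rho^{|h-h'|}$,
marginal variance $\sigma^2_{res}$. Residuals in different pig-days are
independent — the repeated-measures block is pig × day. For hours
missing inside a day the correlation is $\rho^{|\Delta h|}$ across the
gap, the standard discrete-AR(1)-with-missing-data convention.

Estimation is restricted maximum likelihood. The engine never forms the
$n \times n$ covariance: each pig-day block is whitened through the
bidiagonal inverse Cholesky factor of its AR(1) correlation (gap-aware),
and the rank-one pig intercept is absorbed by the Sherman–Morrison
identity, so one evaluation of $-2\ell_R$ costs $O(np)$ plus one
$p \times p$ Cholesky. $\sigma^2_{res}$ is profiled out analytically
and the likelihood is maximised over
$(\log\gamma, \operatorname{atanh}\rho)$,
$\gamma = \sigma^2_{pig}/\sigma^2_{res}$, with L-BFGS-B from up to
three starting points to guard against flat ridges; the transformed
scale keeps both parameters in their admissible ranges without
constrained optimisation. Non-finite evaluations are returned as
infinite objectives so the optimizer treats them as rejected steps, and
non-convergence is reported explicitly (`$converged`,
`$optim_trace`), never silently.

Internally the fixed effects are represented in a sparse cell-means
coding (one indicator per observed day-hour cell), which is always full
rank and makes the whitened cross-products cheap. Reference and
sum-to-zero codings are also available (`build_design(coding =)`);
aliased columns arising from empty cells are detected by a pivoted
decomposition and tracked for rank accounting. All reported quantities
are estimable functions of the observed cell means, so they are
invariant to the coding — a property the test suite asserts directly.

### Inference

* **LSMeans** (`lsmeans()`) average cell means with equal weights over
  the levels of the other factor. An LSMean touching an unobserved cell
  is not estimable under the interaction model and is flagged rather
  than silently dropped.
* **Type-3 F tests** (`type3_tests()`) test each effect's coefficients
  in a full-rank sum-to-zero reparameterisation, adjusted for all other
  terms, via Wald statistics on the GLS covariance. On balanced
  complete data with $\rho = 0$ and $\sigma^2_{pig} = 0$ these coincide
  with classical two-way ANOVA F tests, which the tests verify against
  `aov()`.
* **Denominator df** use the containment idea: no fixed effect contains
  the pig grouping factor, so all receive the residual containment df
  $n - \mathrm{rank}([X, Z_{pig}])$. This is an approximation of the
  SAS containment rule; with empty cells the two can differ by the
  rank bookkeeping of the interaction, and matching a particular
  software's df exactly is not a goal.
* **ICC** is $\sigma^2_{pig} / (\sigma^2_{pig} + \sigma^2_{res})$. The
  AR(1) parameter is deliberately excluded: it redistributes residual
  covariance across time without changing the marginal variance.
* **BLUPs** (`blups()`) are conditional modes of $b_i$ at the REML
  estimates, with intervals from the conditional prediction variance of
  $\hat b_i - b_i$ (fixed-effect uncertainty included). Pigs with few
  valid hours shrink towards zero and get wider intervals.
* **Slice tests** (`slice_tests()`) test equality of each day's
  observed hourly cell means (numerator df = observed hours − 1).

Small-instance correctness is anchored by brute-force oracles in the
test suite: a dense implementation that builds $V$ explicitly for the
REML value and GLS solution, and a dense Henderson mixed-model-equations
solve for the BLUPs, all matched to 10⁻⁶. An independent
cross-check against `nlme::lme` with `corAR1` verifies the variance
components and restricted likelihood on moderate instances.

## 4. The environmental model

Environmental records (temperature °C, relative humidity %, PM1, PM2.5,
PM10 µg·m⁻³) arrive a few dozen times per day and are averaged to
day × timeline blocks, where timeline 1/2/3 are the 8-hour windows
00:00–07:00, 08:00–15:00, 16:00–23:00. Because co-located optical dust
sensors produce near-collinear PM fractions, `pm_screen()` computes the
pairwise Pearson correlations among the PM block means and, when every
pair exceeds a threshold (default r = 0.95), retains only PM2.5 —
keeping all three would put essentially the same regressor in the model
three times.

Movement is aggregated to the same resolution: `movement_to_blocks()`
averages each pig's valid hours within a block (`dist_mean`) and
records the contributing hour count (`n_hours`). `fit_env_model()` then
fits

$$dist\_mean = Day + Timeline + temp + rh + PM_{2.5}
  + u_{pig} + u_{DayTL} + e,$$

with independent crossed random intercepts for pig and day × timeline
and residual variance $\sigma^2_{res} / n\_hours$ — the
inverse-variance weight appropriate for a mean of `n_hours` hours. The
published description of the repeated-measures structure at this level
is ambiguous; the package implements exactly the stated random
intercepts plus weighted independent residuals and documents that as an
interpretation. Day enters as a factor (not a linear trend). REML uses
the Woodbury identity on the low-rank random design, so each objective
evaluation is $O(nq^2)$ with $q$ the number of random levels;
$\sigma^2_{res}$ is again profiled out, making estimates and F
statistics exactly invariant to rescaling all weights. One
identification caveat is inherent to the design: covariates are
constant within a day × timeline block, so day-level covariate
variation is absorbed by the Day factor and slopes are identified from
within-day (block-level) variation only. Constant covariates are
flagged as inestimable rather than fitted.

## 5. What the synthetic generator emulates — and what it does not

Event-level farm data of this kind are rarely shareable, so the
generators are first-class, tested components that define the
conditions under which the estimation machinery is validated.

* `generative_truth()` holds the full data-generating model. The
  diurnal profile defaults to a single-peak cosine anchored so hour 15
  equals 1,025.5 cm·h⁻¹ and hour 1 equals 666.0 cm·h⁻¹ — the two
  hourly marginal means that characterise the afternoon-peak /
  night-trough rhythm of finishing pigs on straw. Defaults
  $\sigma^2_{pig} = 15{,}773$, $\sigma^2_{res} = 38{,}884$ (ICC 0.29)
  and $\rho = 0.19$ reproduce the reported variance decomposition. Day
  effects are iid Gaussian (SD 40 cm·h⁻¹, the order of magnitude of
  observed day-to-day swings) and the day × hour interaction surface is
  iid Gaussian (SD 40 cm·h⁻¹); both are centred so the hourly marginal
  truth equals the diurnal profile exactly, keeping LSMean anchors
  interpretable.
* `simulate_hourly()` draws the model equation directly, with a
  stationary AR(1) within each pig-day and missing-completely-at-random
  invalid cells (the real missingness mechanism is unknown; MCAR is the
  neutral choice). Negative responses are *not* floored by default —
  the fitted model is linear-Gaussian and flooring would bias
  variance-component recovery; a flooring switch exists for realism
  studies.
* `simulate_trajectory()` provides the physical stand-in: a 1-D
  reflected random walk along the pen's 14.3 m long axis, sampled at
  3–5 s intervals, with hour-dependent step scale calibrated so the
  expected hourly displacement follows the diurnal profile. One
  dimension matches the along-axis coverage of a midpoint wall
  receiver and keeps the distance-to-receiver mapping unambiguous.
  There is no social interaction, feeding event or 2-D pen dynamics in
  this model.
* `simulate_detections()` inverts the path-loss model with Gaussian
  RSSI noise and independent dropout. The default dropout (0.7 in the
  demo pipeline configuration) is a placeholder for the unknown true
  detection-loss rate of passive tags, not a measured value.
* `simulate_env()` generates temperature and humidity with day-level
  and day × timeline-level weather components plus record noise
  (defaults: record SD 1.0 °C, day SD 1.2 °C, block SD 0.8 °C around a
  16.05 °C mean; analogous for humidity around 71%), and PM fractions
  loading on a shared latent factor so pairwise correlations target a
  configured value (default 0.98). Negative PM draws are truncated at
  zero. Record-level SDs were back-calculated from typical
  winter-barn summary statistics (e.g. a PM2.5 mean near 10 µg·m⁻³
  with SD near 9).

Passing tests on these generators show that the estimation machinery
recovers the parameters of *this* generative family at the study's
scale. They cannot show robustness to what the generators omit:
non-Gaussian movement distributions (real hourly movement is
non-negative and right-skewed), informative missingness (tag
performance may correlate with behaviour), RSSI multipath structure
beyond log-distance + noise, or social synchronisation between pigs.

## 6. Problem sizes and reproducibility

The test suite validates oracle equivalence on instances under 50
observations, engine behaviour on 3–8 pig subsets, and parameter
recovery on the full 16 × 20 × 24 grid (7,680 cells); the
acceptance script averages 60 replicate refits of that grid, a size
chosen to hold the Monte-Carlo error of the mean ICC near 0.01 (one
replicate's ICC estimate has SD ≈ 0.08 with only 16 pigs). Every
stochastic stage takes an explicit seed, simulators restore the
caller's RNG state, and `run_pipeline()` derives all randomness from
the seeds recorded in its configuration, so a config fully determines
every output file.

```{r example}
truth <- generative_truth(seed = 42)
hourly <- simulate_hourly(truth, n_pigs = 6, n_days = 4, seed = 42)
fit <- fit_lmm(analysis_table(hourly))
fit
head(lsmeans(fit, "hour"), 3)
```

## 7. Known limitations

* The movement metric is range-only and zone-limited; absolute values
  underestimate true displacement and are not comparable across barn
  geometries.
* Containment denominator df are an approximation (Section 3);
  Kenward–Roger or Satterthwaite adjustments are out of scope, as are
  heterogeneous AR(1) structures, random slopes and Bayesian
  estimation.
* The ICC convention excludes the AR(1) parameter; analysts wanting a
  correlation-at-lag-k interpretation should combine `icc()` with
  `$vc$rho` themselves.
* With 16 animals, pig-level variance (and hence the ICC) is estimated
  with roughly 15 df; single-study ICC estimates are correspondingly
  noisy, which is why recovery is assessed by averaging replicates.
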
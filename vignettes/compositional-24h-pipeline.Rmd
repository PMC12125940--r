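---
title: "Modelling 24-hour movement-behaviour compositions from wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 24-hour movement-behaviour compositions from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24h)
```

## The problem

A day has 1440 minutes and an adolescent spends every one of them in exactly
one of four behaviours: moderate-to-vigorous physical activity (MVPA), light
physical activity (LIPA), sedentary behaviour (SB) or sleep (SPT, the sleep
period time). Because the four parts are constrained to a fixed total, they
carry only *relative* information: more time in one behaviour is necessarily
less time in the others. Treating the minutes as four independent outcomes
therefore produces spurious correlations and inadmissible inferences; the
composition has to be analysed in Aitchison geometry. `coda24h` implements a
complete pipeline for this problem in two-wave school cohort designs:

1. **Measurement** (`accel`): epoch-level wrist-accelerometer records are
   turned into valid daily compositions (ENMO computation, non-wear handling,
   z-angle sleep detection, intensity cut-points, 5:2 weekday/weekend
   weighting).
2. **Geometry** (`coda`): closure, compositional geometric means, variation
   matrices, isometric log-ratio (ILR) coordinates built from sequential
   binary partitions and pivot orders, and robust Mahalanobis outlier
   screening.
3. **Inference** (`models`): multilevel mixed models on stacked ILR
   coordinates, with a type-III likelihood-ratio test for the
   composition-by-time interaction, per-behaviour pivot-rotation tests,
   moderation tests, and back-transformed adjusted marginal means.
4. **Simulation** (`synth`): a generative model of cohorts and accelerometer
   traces, so the whole pipeline is testable end-to-end without access to the
   restricted cohort data it is designed for.

## The measurement model

Triaxial acceleration $(a_x, a_y, a_z)$ in g is summarised per 5-s epoch as
ENMO $= \max(0, \lVert a \rVert - 1) \times 1000$ mg; negative values, which
arise from calibration error at rest, are truncated to zero (the standard
ENMO convention). Waking epochs are classified by half-open ENMO intervals.
The defaults are the wrist cut-points recommended for adolescents
(SB $< 35.6$ mg, LIPA $[35.6, 201.4)$, MVPA $\ge 201.4$), with the adult set
(44.8 / 100.6 mg) available for sensitivity re-processing — the adult MVPA
bound sits *below* the child LIPA band's midpoint, so re-processing shifts
substantial LIPA time into MVPA, which is why sensitivity results differ in
magnitude but not direction.

Sleep is found without a diary, from the z-angle
$\arctan(a_z / \sqrt{a_x^2 + a_y^2})$: the wrist holds a near-constant
posture during sleep and switches posture frequently while awake. A posture
change is an absolute change in z-angle above 5° between consecutive epochs;
change-free runs of at least 30 min are candidate blocks, blocks separated
by less than 60 min are merged, and the longest merged block in each
noon-to-noon interval is the sleep window (SPT). Two deliberate choices
here:

* Detection runs noon-to-noon (plus the leading/trailing half-days) so a
  night is never split at midnight, but the resulting SPT epochs are
  attributed back to the *calendar* day in which they fall
  (midnight-to-midnight accounting, matching how the compositions are
  closed).
* The published heuristic smooths the z-angle with a 5-min rolling median
  before differencing. The default here is no pre-smoothing
  (`sleep_params(smooth_min = 0)`): on piecewise-constant signals a centred
  median filter blurs per-epoch changes enough that slow posture drift can
  pass under the threshold, whereas raw successive differences localize
  sleep-wake transitions exactly — which is also what makes the
  one-epoch-per-boundary recovery guarantee on clean traces testable. The
  smoother remains available (`smooth_min = 5`) for noisy devices.

Non-wear is flagged by a documented heuristic stand-in for the validated
algorithms used with raw 30-Hz data: any 60-min rolling window in which at
least two axes have a standard deviation below 13 mg. Day validity
(≥ 16 h wear) is assessed *before* imputation; non-wear epochs on valid days
are then imputed with the mean signal at the same clock time across the
subject's other valid days, normalizing every valid day to 24 h. When a
clock time is unobserved on all other days the subject-level wear mean is
used, with a warning. A subject is analysable with ≥ 3 valid weekdays and
≥ 1 valid weekend day; the weekly composition is the 5:2-weighted
weekday/weekend mean, re-closed to 1440.

## Aitchison geometry and ILR coordinates

A composition $x = (x_1, \dots, x_D)$, $D = 4$, is mapped to $D - 1$
unconstrained coordinates $z = V \log x$, where the rows of
$V \in \mathbb{R}^{(D-1) \times D}$ are orthonormal and sum to zero. $V$ is
built from a sequential binary partition; for a pivot order with part $b$
first, the first coordinate is

$$z_1 = \sqrt{\tfrac{3}{4}} \, \log \frac{x_b}{g(x_{-b})},$$

the log-ratio of $b$ against the geometric mean of the remaining three
parts. This is the coordinate used for per-behaviour inference: rotating
which behaviour is pivoted first yields four interpretable tests. The
composition-level test is invariant to the choice of partition (different
SBPs differ by an orthogonal rotation of $z$), which the test suite checks
to $10^{-8}$; the default basis is the pivot order (MVPA, LIPA, SB, SPT)
purely for interpretability of coefficients.

Zeros are an empirical reality (an adolescent can record 0 MVPA minutes in
a day). The default policy is strict (an error), because zeros upstream of
the log are almost always a processing bug; `zero_policy = "replace"`
substitutes a 1 min/day floor with a reported count for genuine zero days.

Outlier screening computes squared Mahalanobis distances of the ILR
coordinates against $\chi^2_3$ quantiles (default 0.975). Location and
scatter are estimated robustly (MCD) by default so that the outliers being
hunted do not mask themselves; classical moment estimates are available by
flag and are what the chi-square calibration test uses, since MCD's raw
distances over-flag by construction.

## The stacked multilevel model

Each subject-by-wave ILR vector is melted to three rows indexed by a
3-level factor $k$ (the coordinate identity). The fixed-effect structure
interacts everything with $k$ — a covariate effect "common across
coordinates" has no meaning on stacked multivariate outcomes — so the model
for row value $z_{iks}$ of subject $i$ in school $s$ is

$$z_{iks} = \beta_{0k} + \beta_{1k}\,\text{wave}_i + \gamma_k' c_i +
  u_i + v_s + \varepsilon_{iks},$$

with covariates $c_i$ (age, sex, SES 0–100, family structure), a subject
intercept $u_i$ shared across the subject's coordinate rows (inducing
within-person cross-coordinate correlation), a school intercept $v_s$, and
residuals $\varepsilon_{iks} \sim N(0, \sigma_k^2)$ with
**coordinate-specific variances**. The prospective design replaces $u_i$
with a full per-subject coordinate effect $u_{ik}$ (an unstructured 3×3
covariance — the "random ILR slope" — capturing the persistence of a
person's composition across waves) and uses time-invariant baseline
covariates. Estimation is maximum likelihood, so likelihood-ratio
comparisons of nested fits are valid.

The heterogeneous residual is not a nicety: the MVPA balance is several
times more variable than the SB/SPT balance, and forcing a pooled residual
variance misweights the coordinate-level Wald tests badly (in null
simulations the moderation tests rejected at roughly twice the nominal
rate under a homogeneous-residual fit; with coordinate-specific variances
they hold their size). The default engine expresses the structure in
`lme4` by writing $\sigma_k^2 = \sigma^2 + \tau_k^2$ — a common floor plus
a non-negative coordinate excess — and fitting the excesses as scalar
random effects of the coordinate indicators grouped by subject-by-wave
cell; with one row per coordinate per cell this is residual variance, not
extra structure, and the ML optimum coincides with `nlme::lme` under a
`varIdent` residual (the `engine = "nlme"` cross-check in the test suite
agrees in log-likelihood to $10^{-6}$) while fitting about three times
faster. A fixed-effects-only engine (`engine = "fixed"`) serves the
degenerate-case oracles (with zero random-effect variance the mixed fit
must match coordinate-wise OLS, and the composition LRT must be exactly
SBP-invariant).

Inference proceeds in three layers, mirroring the design:

* **Composition level**: a type-III likelihood-ratio test comparing ML fits
  with and without the $k \times \text{wave}$ interaction (3 df).
* **Behaviour level**: the wave slope on $z_1$ under each of the four pivot
  rotations, Wald-tested. For unadjusted fixed-effects fits these four
  slopes reassemble the marginal-mean contrast exactly
  ($\text{clr}_b = \sqrt{3/4}\, z_{1,b}$), which the suite checks to
  $10^{-6}$.
* **Moderation**: one refit per covariate adding a
  $k \times \text{wave} \times \text{covariate}$ term, Wald-tested jointly
  (3 df for continuous/binary covariates, 6 for the 3-level family
  structure). Wald-based fits (moderation and the pivot rotations) use
  REML so variance components, and hence standard errors, are unbiased;
  in null simulations the ML versions rejected at up to 0.076 instead of
  0.05-0.065. The main model deliberately omits these three-way terms so
  that the composition LRT drops *exactly* the $k \times \text{wave}$ term;
  covariate-by-time interaction is assessed in the moderation layer, which
  is also how the moderation table's degrees of freedom are defined.

Adjusted marginal means are computed by averaging the fixed-effect linear
predictor over the observed covariate rows at each wave (equivalent to
continuous covariates at their means and factor covariates weighted by
observed proportions, since the model is linear), then back-transforming
the predicted ILR vector and closing to 1440 min/day. Non-convergence
triggers a documented fallback chain — drop the random coordinate effect,
then the school intercept, then all random effects — recorded in the fit's
`notes`; the analysis aborts only if even the fixed-effects fit fails.

## What the generator emulates, and what it does not

The cohort generator draws compositions on the ILR scale around
wave-specific centres with exactly the hierarchy the model assumes
(school and subject intercepts, persistent per-coordinate subject effects
in the prospective design, per-coordinate residuals), then back-transforms
and closes. Its defaults are the study conditions the pipeline targets:

* wave centres = the published adjusted predictions of the two designs
  (cross-sectional: 29.9/275.8/679.6/454.7 vs 26.6/274.0/684.3/455.1
  min/day; prospective: 30.5/277.4/671.5/460.6 vs 25.1/261.1/705.5/448.4);
* covariates matching the published sample descriptives (53% female, age
  16.4 (SD 1.1) cross-sectionally and 15.6 (0.8) in the cohort, SES 38.9
  (SD 10.0), family-structure proportions 61/34/5%);
* 3 schools, ~600 subjects per cross-sectional wave, a 249-subject nested
  cohort with 138/249 ≈ 55% retention (missing completely at random by
  default; an age-tilted mechanism is available because dropouts were
  slightly older in the cohort this emulates).

No ILR-scale variance components are published, so they were chosen on
field plausibility, separately per design because the occasion SD means
different things in the two modes. Cross-sectionally (one occasion per
person) the occasion SDs (0.50, 0.25, 0.20) for the three pivot
coordinates are the between-person spread at a wave — MVPA-dominated
balances vary most between adolescents — on top of a shared subject
intercept SD of 0.15 and a school SD of 0.05. Prospectively the
between-person spread is carried by persistent per-coordinate subject SDs
(0.40, 0.12, 0.07) plus a persistent shared intercept of 0.05, and the
occasion SDs (0.30, 0.08, 0.05) are within-person between-wave
fluctuations; the implied 3-year tracking ICCs of roughly 0.6–0.7 per
coordinate match published tracking of activity behaviours, and the
resulting Monte-Carlo error keeps the n = 2000 marginal-mean recovery
check meaningful at its 2 min/day band. The consequence: simulations
reproduce the published *means* and design structure, not the published
standard deviations or p-values, and passing tests certify the estimator
under the model's own assumptions. Real
accelerometer data violate those assumptions in ways the generator does not
emulate (non-Gaussian ILR distributions, covariate-dependent variance,
informative non-wear, device calibration drift, realistic gait spectra), so
the test suite is evidence of *correctness of the machinery*, not of
robustness to every field condition.

The trace generator realizes a scheduled day (sleep window, MVPA/LIPA
bouts, sedentary filler — 480/30/280/650 min by default) as a 5-s epoch
signal: log-normal ENMO per behaviour with medians placed mid-band
(sleep 3, SB 15, LIPA 85, MVPA 300 mg) and draws clipped to the band each
behaviour must trigger, so classification recoverability is guaranteed by
construction; sleep z-angle constant ± 0.5° jitter; waking posture redrawn
every 60 s uniformly on (−60°, 60°), excluding a ±10° neighbourhood of the
sleep angle so sleep-wake transitions remain identifiable. With the noise
switched off (`enmo_sigma = 0`) the processing chain must recover the
schedule to within one epoch per transition, and does.

## Numerical and testing choices

* All closure operations tolerate arbitrary positive scale and are
  idempotent; internal sums are exact to $10^{-9}$, displayed tables to
  0.1 min.
* Display rounding is one decimal for predictions and percent differences,
  and p-values below $10^{-3}$ render as "< 0.001"; every rendered table
  has a JSON twin holding full-precision values.
* `nlme` fits use `niterEM = 5` (the default 25 EM warm-up iterations cost
  double the time with identical log-likelihoods on these balanced stacked
  designs).
* Recovery checks (geometric-mean convergence, marginal-mean recovery)
  condition on zero school effects: with three school clusters the shared
  school draw is a realization-level shift that no sample size averages
  away (at SD 0.05 it can move SPT by ~15 min/day), so it is design noise,
  not estimator error; the school machinery is exercised by the
  calibration simulations instead.
* Simulation-based checks use fixed seeds and these problem sizes: 500
  replicates at $n = 200$ subjects for test-size calibration (LRT and all
  four moderation tests within [0.03, 0.07] at $\alpha = 0.05$); 200
  replicates at $n = 300$ for CI coverage and bias of the wave
  coefficients (the cross-sectional design, whose estimator is the same
  machinery, keeps this affordable); a single $n = 2000$ prospective cohort
  for marginal-mean recovery within 2 min/day of the generating targets.

## Known limitations

* The exact sequential binary partition and the precise sleep-heuristic
  configuration behind the published estimates are not documented in the
  sources this package works from; composition-level conclusions are
  invariant to the former, and the latter is configurable.
* The non-wear rule is a desk-scale stand-in, not the validated raw-data
  algorithm; autocalibration to local gravity and 30-Hz resampling are out
  of scope.
* Two waves only, Gaussian outcomes only, no survey weights; "weekend"
  means Saturday/Sunday and one valid weekend day satisfies the weekend
  criterion.
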
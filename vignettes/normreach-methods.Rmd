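---
title: "Individually scaled evaluation of reaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individually scaled evaluation of reaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normreach)
```

## The problem

After a stroke, upper-limb reaching with the affected arm is slower and
less direct than it would have been before the lesion. Group norms are a
poor yardstick for any single patient: pre-stroke ability varies widely, so
the same absolute movement time can be normal for one person and severely
impaired for another. The approach implemented here scales the assessment
to the individual. The arm ipsilateral to the lesion — the *less-affected*
arm — is taken as a proxy for the person's pre-stroke motor repertoire. A
model of *normal reaching* is fitted to that arm's center-out trials; the
model then predicts, for every movement condition, the *ideal* movement
time the patient should be capable of; and the affected arm is scored by
how far its actual movement times exceed those predictions.

## Candidate movement-time models

All three candidate models predict the movement time $T_M$ of a
goal-directed planar reach from kinematic covariates:

* **Fitts' law** (comparator): $T_M = a + b \log_2(2A/W)$, with target
  distance $A$ and width $W$. It encodes the speed–accuracy tradeoff only;
  in robot training protocols the target width is fixed, so the index of
  difficulty varies with distance alone.
* **Submovement/curvature power law** (comparator; after the model family
  introduced for mouse-pointing in cerebral palsy by Almanji and
  colleagues): $T_M = e^{k} A^{\alpha} AS^{\beta} (NS+1)^{d} CI^{f}$,
  where $AS$ is the average speed, $NS$ the number of submovements and
  $CI$ the curvature index. The click-related covariates of the original
  pointing model have no counterpart in a reaching task and are omitted.
* **Normal-reaching model** (the core of the package):
  $T_M = e^{k} A^{\alpha} AS^{\beta}$. Ideal reaching is straight
  ($CI = 1$) with a minimal, fixed submovement structure, so the erroneous
  covariates are constants absorbed into $k$; what remains is distance and
  the individual's chosen speed.

The intended division of labour: the full power law fits *any* reaching,
erroneous or not, and therefore cannot separate the two; the
normal-reaching model fits normal reaching well and erroneous reaching
badly, which is exactly what an evaluation standard needs. The package's
discrimination tests verify this pattern on synthetic patients.

### Fitting conventions

Power-law families are fitted by ordinary least squares on
$\ln T_M$ with $A$ in meters, $AS$ in m/s and $T_M$ in seconds; the
intercept $k$ absorbs the unit choice, which is recorded in the model
object and its JSON serialization. Errors are therefore multiplicative in
natural units — a reasonable description of movement-time variability,
whose spread grows with its level. Fitts' law is fitted directly in
milliseconds. $R^2$, RSS and AIC are computed in each family's fitted
space; mixing spaces is reported as-is (Fitts AIC large and positive, the
power laws negative), mirroring how these models are compared in the
rehabilitation literature. The AIC is the Gaussian maximum-likelihood
form $n\ln(2\pi\,\mathrm{RSS}/n) + n + 2(p+1)$, counting the error
variance as a parameter.

One wrinkle deserves a note: on ideal normal data the submovement count is
constant, which would make $\ln(NS+1)$ collinear with the intercept. The
fit absorbs any constant $NS$/$CI$ regressor into the intercept with a
zero exponent instead of failing, preserving the nested relationship (the
normal model is the $d = f = 0$ restriction, so its log-space $R^2$ never
exceeds the full power law's on the same trials). A constant distance or
speed regressor, by contrast, is a genuinely unusable design and raises a
singular-design error.

## The normalized error and its map

For target $i$, the evaluation index is

$$e_n(i) = \frac{T_{M,a}(i) - T_{M,e}(i)}{T_{M,e}(i)}$$

with $T_{M,a}$ the affected arm's actual movement time and $T_{M,e}$ the
less-affected model's prediction *at the affected trial's own distance and
average speed*. Dividing by the prediction makes the index scale-free:
doubling both times leaves it unchanged, so targets at 6 cm and 14 cm are
comparable, as are patients with very different baseline speeds. $e_n = 0$
is performance at the individual's normal level; $e_n = 1$ is twice the
ideal time; values below 0 (bounded below by $-1$) are faster than
predicted.

Aggregation is deliberately trial-wise first: $e_n$ is computed per trial
and then averaged per target. Averaging the times first and applying the
formula once gives a numerically different (ratio-of-means) quantity; the
trial-wise mean is the one implemented and tested.

The per-target means are arranged on the polar direction-by-distance grid
as a workspace map. For display, the color ceiling is the 95th percentile
of the finite per-target values (linear-interpolation quantile) and the
floor is their minimum, so one catastrophic target cannot flatten the
whole map; the stored values are never clipped. The percentile is taken
over target-level means because those are the plotted quantities. Cells
whose targets have no successful trial are masked as unreachable.
Rendering draws one flat annular sector per cell rather than interpolating
between cells: the displayed surface is then exactly the data, at the cost
of the smooth contours a bilinear rendering would give.

## Kinematic features

* **Movement time.** Robot-recorded movement times are used verbatim when
  present. Otherwise the movement window is thresholded at 2% of peak
  tangential speed (first and last crossing), which excludes the in-target
  dwell that typically terminates a robot trial. For a single minimum-jerk
  pulse this window covers 92.7% of the nominal duration — a known,
  deterministic consequence of any threshold rule, which is why recorded
  times are preferred when available.
* **Average speed.** Path length within the window divided by movement
  time. The identity $AS \cdot T_M = \mathrm{path}$ is exact by
  construction and asserted to $10^{-9}$ in the tests.
* **Curvature index.** Polyline path length divided by the window's
  start-to-end chord; 1 for a straight reach, invariant under rotation and
  uniform scaling.
* **Submovement count.** A reach is decomposed into minimum-jerk speed
  pulses $v(\tau) = (s/D)(30\tau^4 - 60\tau^3 + 30\tau^2)$. $NS$ is the
  *smallest* pulse count whose best least-squares superposition
  reconstructs the speed profile to RMSE $\le$ 5% of peak speed — a
  minimal-count reading of "optimal decomposition" that avoids inflating
  $NS$ on noisy profiles. Each candidate count is fitted by
  box-constrained quasi-Newton minimization from two deterministic starts
  (the largest local maxima, and evenly spaced onsets); pulse durations
  and displacements are optimized on the log scale to keep them positive.
  The count is capped at 10 by default to prevent runaway fits. Loosening
  the tolerance can only reduce the count, a monotonicity the tests
  assert, and unit tests compare the result with an exhaustive
  lattice-dictionary oracle on overlapping-pulse cases.

### Curvature outlier rejection

Before fitting the normal model, trials whose curvature index lies beyond
two interquartile ranges outside the quartiles — below $Q_1 - 2\,IQR$ or
above $Q_3 + 2\,IQR$, quartiles by linear interpolation (type-7) — are
flagged and excluded. Extreme curvature marks reaching by mistake rather
than normal variation. The lower fence is usually inert since $CI \ge 1$.
The rule needs at least five trials; rejection partitions the input and,
against the fences computed from the original sample, is idempotent.

## The synthetic session generator

Clinical trajectories cannot ship with the package, so every layer is
exercised against a seeded generator whose two modes mirror the two model
regimes:

* **Normal mode.** Per trial: draw $AS$ from a lognormal law, set
  $T_M = e^k A^\alpha AS^\beta \cdot e^{\sigma z}$ with standard normal
  $z$, set the path length $L = AS \cdot T_M$ (raised to $A$ on the rare
  draws that fall short of the chord), and realize the trial as a circular
  arc of chord $A$ and length $L$ — the simplest one-parameter family with
  exact chord and arc-length control — traversed by a single minimum-jerk
  pulse. Ground truth records the realized values, so
  $AS \cdot T_M = L$ and $CI = L/A$ hold identically.
* **Erroneous mode.** Per trial: draw $AS$, $NS$ (weighted support 3–6 by
  default) and $CI$ ($1 + \mathrm{Exp}$), set $T_M$ by the full power law
  with noise, and realize the trial as $NS$ overlapping minimum-jerk
  pulses (30% overlap, geometrically decaying displacements) whose
  alternating direction jitter is solved by one-dimensional root finding
  so the realized polyline curvature matches the sampled $CI$; the
  resultant is then rotated and scaled to land exactly on the target.
  Curvature targets the pulse geometry cannot reach are resampled a
  bounded number of times.

Generation is *feature-first* — features are sampled, then a trajectory
consistent with them is realized — because the reverse order would make
the law parameters unrecoverable: measured average speed is
$\mathrm{path}/T_M = CI \cdot A / T_M$, a deterministic function of the
other covariates and the response. This endogeneity is not a nuisance to
be engineered away; it is, in this package's reading, the mechanism behind
the near-unity fits the full power law achieves on clinical data
regardless of impairment (the regression can reproduce the identity
$\ln T_M = \ln A + \ln CI - \ln AS$ exactly). The package therefore keeps
two views of a synthetic session: the raw ground truth with the sampled,
exogenous $AS$, used for generative parameter recovery; and
`observed_features()`, with $AS$ recomputed as path over time, used
whenever the point is to emulate what a measurement pipeline sees.
Model-discrimination results quoted for this package are computed on
observed features.

Defaults are fixed at protocol-realistic values and are configuration, not
code: 8 directions × 5 distances (6–14 cm) × 3 repetitions = 120 trials,
2 cm targets, 75 Hz sampling, $AS$ log-mean $\ln(0.045)$ m/s with log-sd
0.25, $(k, \alpha, \beta) = (0.361, 0.95, -0.9)$ — giving movement times
of roughly 1.4–3.1 s and normal curvature near 1.2 — noise $\sigma = 0.1$,
erroneous $(d, f) = (0.5, 0.5)$, and an erroneous curvature law with mean
1.5 and upper tail reaching $\approx 3$.

What the generator does **not** emulate: arm biomechanics and muscle
noise, learning or fatigue within a session, trunk compensation,
measurement noise on positions (trajectories are exact up to sampling),
and any physiological account of impaired reaching beyond the descriptive
power law. Passing tests therefore demonstrate that the estimation and
evaluation machinery is correct and that the discrimination logic follows
from the model structure — not that the specific exponents describe any
given patient population.

## Numerical choices and degenerate inputs

* Quantiles (outlier fences, map clipping) use type-7 linear
  interpolation throughout, for bit-reproducibility.
* The arc geometry solves $\phi/\sin\phi = L/A$ and the jitter solves the
  curvature match by `uniroot` to tolerances of $10^{-12}$ and
  $10^{-10}$; realization consumes no randomness, so the feature-only
  fast path (`realize = FALSE`) is seed-identical to full realization.
* Stationary trials (zero peak speed), zero-length paths and closed
  windows raise a dedicated degenerate-trial condition; feature
  extraction skips such trials and reports them rather than failing the
  session, mirroring protocols where unreachable targets are skipped.
* A perfect fit (RSS = 0) yields AIC $-\infty$ with a warning rather than
  an error.
* All errors are classed conditions (`nr_validation_error`,
  `nr_domain_error`, `nr_io_error`, ...) so the command-line driver can
  map them to stable exit codes (2/3/4).

## Problem sizes used in the test suite

The suite fits at the protocol scale of 120-trial sessions throughout.
Parameter-recovery properties use 100 seeded replicates for the normal
law and 50 for the erroneous law; discrimination uses 50 synthetic
patient pairs; trajectory-level checks (feature fidelity, submovement
recovery) use smaller grids of 4–24 realized trials per case, since
realization and decomposition dominate runtime while their behaviour does
not depend on session size.

## Known limitations

* The less-affected arm is itself not guaranteed intact, particularly in
  severe or acute stroke; when both arms are impaired, the "normal" model
  underestimates pre-stroke ability, and $e_n$ understates the deficit.
* The threshold-based movement window biases movement time low by a
  deterministic factor when no recorded time is available; comparisons
  should not mix recorded and thresholded times within one model fit.
* Log-space $R^2$ and back-transformed millisecond residuals answer
  different questions; the comparison table reports both, and they should
  not be conflated.
* The evaluation is cross-sectional: tracking $e_n$ across sessions over
  time is out of scope.
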
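---
title: "Fluctuation-driven CTRNN models of fly locomotor bouts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation-driven CTRNN models of fly locomotor bouts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywalk)
```

## The scientific problem

Freely walking flies alternate between walking bouts and stationary
intervals with no obvious external trigger: bursts of locomotion are
separated by quiescent periods that can last from fractions of a second to
tens of minutes. One hypothesis is that this timing is set by ongoing
activity fluctuations inside small "action selection" circuits — a few
neurons whose output gates whether the animal walks. `flywalk` implements
a pipeline to test that hypothesis in silico: generate (or ingest) bout
data, summarise it in a way that respects rare long bouts, search for
small continuous-time recurrent neural network (CTRNN) models whose
thresholded output reproduces the bout statistics, and then dissect the
discovered models with dynamical-systems tools.

## The CTRNN model

Each of the $M \le 5$ neurons obeys

$$\tau_i \frac{dx_i}{dt} = -x_i + \sum_{j=1}^{M} w_{ji}\,\sigma(x_j + b_j) + I_i(t),$$

with the exact logistic $\sigma(x) = 1/(1+e^{-x})$, time constants
$\tau_i \in [0.05, 50]$ s, biases $b_i \in [-10, 10]$, weights
$w_{ji} \in [-20, 20]$, and an input $I_i(t)$ that sums a fluctuation
track and an odor drive $w_{odor,i}\,u(t)$. The first neuron is always the
output: the virtual fly walks whenever $\sigma(x_1 + b_1) \ge THR$ with
$THR \in (0,1)$.

**Integration.** Classical RK4 at a fixed 10 ms step (compiled). The
fluctuation source draws a fresh value every $T_{noise} \in [0.01, 1]$ s
and is linearly interpolated at the RK4 sub-stage times; the rectangle
stimulus is held constant over a step. This deliberately reproduces a
knot-interpolated noise scheme rather than a formal SDE solver: the
interpolation introduces correlations at the $T_{noise}$ scale, orders of
magnitude below the behavioral time scales of interest. Noise can be
white Gaussian (per-neuron gain $w_{noise,i}$), $1/f^{\alpha}$ power-law
(spectral synthesis — frequency-domain $f^{-\alpha/2}$ shaping of white
Gaussian noise, standardised to unit variance before the gain), or
Ornstein–Uhlenbeck with $\mu = 0$, advanced *exactly* between knots
($x_{k+1} = x_k e^{-\theta\Delta} + \sigma\sqrt{(1-e^{-2\theta\Delta})/(2\theta)}\,\varepsilon_k$).

**Transients and initial conditions.** Simulations start from
identity-covariance Gaussian draws centred on the noiseless equilibria
(round-robin across equilibria; origin-centred with a warning if none is
found) and discard a transient (5 simulated minutes at the full protocol)
before recording. Basal runs simulate twice the recording length and keep
one half at random, so repeated evaluations do not overfit a single
trajectory. A non-finite state aborts an interactive integration with a
diagnostic, but inside the optimiser such parameter sets simply receive a
worst-possible score.

## Bout statistics and the cost function

Speed traces are classified with a hysteresis rule — walking begins above
1 mm/s and ends below 0.5 mm/s — which suppresses chatter near a single
cutoff; a trace that starts inside the band starts stationary, since
walking requires an explicit upward crossing (the data cannot distinguish
this case, so we take the conservative choice). Maximal runs become bout
durations; boundary-truncated bouts are flagged but *included* by default,
because the rare multi-minute stationary bouts the cost must see are
disproportionately likely to touch a recording boundary.

Durations are summarised as **weighted variable-bin-width histograms**:
bin boundaries come from recursively bisecting $[0, \max(v)]$ at bin
midpoints, splitting only when both children would hold at least
`min_count` events and span at least `min_width` seconds, and each bin's
count is multiplied by the duration it represents (its lower edge). Ten
1-s bouts and one 10-s bout thus carry equal weight, which keeps the
optimiser honest about rare long bouts — the reason a Kolmogorov–Smirnov
style statistic is *not* used here. Defaults are `min_width = 0.05` s
(five integration steps) and `min_count = 5`; with small heavy-tailed
datasets the midpoint rule leaves an isolated extreme bout unable to
donate `min_count` events to the upper child, so the scaled-down analyses
in the tests use `min_count = 1`, which still guarantees no empty bins.

The cost of simulated bouts against a target is
$F = (d_W + d_I)/F_{norm}$ with
$d(H_T, H_S) = \sum_i |R\,h_S(i) - h_T(i)|\,t_B(i)$, where $R$ is the
ratio of recorded to simulated data volume ($R = 0.1$ for 100 simulated
trials against 10 recorded flies of the same trial length). $F_{norm}$ is
the score of the degenerate virtual fly that walks for the entirety of
every trial, which pins $F = 1$ as the "completely wrong but
non-divergent" anchor; the always-stationary and max-of-both conventions
are available via `norm_mode`, but the always-walking fly is the default
because it gives the anchor deterministically. Durations beyond the
target's maximum clamp into the last bin so degenerate models stay
visible to the cost. `subset_calibration()` scores time-normalised
subsets of the target against the full dataset, giving the empirical
floor any model could plausibly reach.

## Model search

**Stage 1** fits all parameters ($w$, $\tau$, $b$, $w_{noise}$, $THR$,
$T_{noise}$) to basal bout statistics with global-best particle swarm
optimisation: 50 particles, 200 iterations, $c_1 = c_2 = 2$, inertia
$\omega(t) = 0.9 - 0.7\,t/T$. Positions initialise uniformly in the box
with zero velocities; positions are clipped to the box with the clipped
velocity component zeroed (a common, simple constraint-handling choice).
Each objective evaluation receives a seed mixed deterministically from the
master seed, particle id and iteration, so entire searches replay exactly.

**Stage 2** freezes the dynamics — weights, time constants, biases, noise
gains are untouched, which the fit object asserts — and optimises only the
per-neuron odor gains and the output threshold to minimise the RMSE
between the model's population locomotor-frequency curve (200 virtual
flies through 60 s basal / 30 s odor / 120 s post-odor) and a target
curve. Frequency curves are resampled to 20 Hz (the camera rate) and
smoothed with a centred 1 s moving average before the RMSE; the smoothing
window is configurable. Stage 2 reuses the same PSO in a reduced
configuration — any derivative-free optimiser would do behind this
contract.

## Dynamics analysis

Equilibria of the noiseless model are found by damped Newton iteration
with the analytic Jacobian
($\partial F_i/\partial x_j = w_{ji}\sigma'(x_j+b_j)/\tau_i - \delta_{ij}/\tau_i$)
from a $5^M$ grid over $[-60, 60]^M$ (capped at 2000 starts) plus 500
random starts; converged roots are deduplicated at $10^{-6}$ and every
reported point satisfies $\lVert F(\bar x)\rVert < 10^{-9}$. Stability
comes from the Jacobian eigenvalues with a $10^{-8}$ tolerance on real
parts (marginal in between). Trajectory density maps discretise a chosen
neuron-state pair over $[-50, 50]^2$ (1000×1000 cells at the study scale)
and count cell visits over $10^4$ trajectories. Switching classification
starts 1000 noisy trajectories around each stable point for 30 simulated
minutes, assigns states to the nearest stable equilibrium with a
hysteresis radius of 25% of the smallest inter-equilibrium distance (the
switch-detection rule is otherwise underdetermined — raw nearest-point
assignment chatters), and labels models Class 1 (median more than 10
switches per 30 min; threshold configurable since the boundary between
"many" and "rare" is qualitative), Class 2 (some switches), or Class 3
(never; also the convention for models with fewer than two stable
points). Lyapunov spectra co-integrate the variational equations
$\dot\delta = J(x)\delta$ with RK4, Gram–Schmidt re-orthonormalising every
1000 steps over $10^6$ steps after a 5-minute transient; the Kaplan–Yorke
dimension is $k + \sum_{i\le k}\lambda_i/|\lambda_{k+1}|$ with $k$ the
largest index with a non-negative partial sum, 0 when every exponent is
negative and saturating at $M$ when the full sum is non-negative.

## The synthetic-data generator

No raw per-fly recordings are published for this kind of experiment, so
the package ships a first-class generator whose defaults define the study
conditions the tests assume.

Basal locomotion is an alternating-renewal process. Walking bouts are
log-normal with median 2 s (`sdlog` 0.6); stationary bouts mix an
exponential (mean 5 s) with a 10% Pareto tail (scale 10 s, exponent 1.5),
so multi-minute stationary bouts occur at realistic rates while the mean
stays finite. Walking-sample speeds are 1.2 mm/s plus a log-normal
(median 6 mm/s), stationary speeds are half-normal capped at 0.45 mm/s —
the supports flank the 1/0.5 mm/s hysteresis band, so ground-truth labels
are recoverable and the classifier can be validated end-to-end. Positions
are a reflected random walk with diffusing heading, a mild wall-ward
drift while walking and an optional drift away from the odor half; path
curvature and tracking noise are *not* modelled, since only bout
durations and start/end positions feed the downstream analyses. The first
bout's phase is randomised so populations are not synchronised.

Odor-impulse populations follow a piecewise template (basal probability,
step to a peak at onset, exponential decay to a reduced baseline after
offset; defaults 0.55 / 0.9 / 0.35 with a 20 s decay). Each fly is a
latent Gaussian AR(1) series thresholded through its own CDF, which makes
the per-sample walking probability equal the template *exactly* — also
across the onset step — while the latent persistence (0.3 s) gives bouts
their granularity. An earlier two-state Markov construction was rejected
because its occupancy lags step changes of the template by its own
relaxation time.

What passing tests on these data do and do not show: they validate the
machinery (classification, histogramming, cost normalisation, search,
dynamics analysis) under controlled truth, not the biology of any
particular strain; the generator's parameters are field-plausible
stand-ins, not calibrated to measured flies.

## Problem sizes used in the tests

The full study scale (5 h of target data; 100 trials of 60 min per cost
evaluation; $10^4$ PSO evaluations per run; 50 runs per condition) is a
cluster-scale workload. The package defaults keep those settings, while
the test suite exercises the identical code paths at sizes a desk machine
handles comfortably:

* target data: 10 virtual flies × 5 min, `min_count = 1` bins;
* with/without-fluctuations comparison: network size 2, 10 PSO runs per
  condition, 20 particles, 50 iterations, 20 virtual flies per
  evaluation, 50 s recordings (15 s transient, no half-splitting);
* stimulus-response sweep and Stage-2 self-fit: the one-neuron bistable
  subthreshold model ($x' = -x + 8\sigma(x-4)$, threshold 0.985), 20–40
  virtual flies per curve;
* Lyapunov and density oracles: $2\times10^4$–$4\times10^4$ steps.

The methods do not change with scale, only the Monte-Carlo resolution.

## Numerical choices and limitations

* The sigmoid is evaluated exactly (numerically stable two-branch form);
  no fast approximation is used anywhere.
* Newton steps solve the analytic Jacobian system with partial pivoting
  and halve the step until the residual decreases; starts that stall are
  discarded rather than polished.
* The bisection rule for bin boundaries splits only at midpoints; a bin
  whose midpoint split would violate the count or width floor stays
  whole.
* PSO is a global heuristic: repeated runs (the `discover_models()`
  surface) are the unit of inference, not a single run.
* The reachable cost floor is bounded by simulation volume: independent
  realizations of even the *true* generator of a target score well above
  zero at 20 trials per evaluation, because the Monte-Carlo distance
  between finite bout samples does not vanish. Comparing a fitted model
  against `subset_calibration()` floors is therefore only meaningful at
  the full study volume (100 trials of 60 min and ~10^4 optimizer
  evaluations); at desk scale the with/without-fluctuations contrast is
  the robust readout.
* Limit cycles and chaotic sets are characterised only through density
  maps and Lyapunov spectra; there is no continuation or bifurcation
  tracking.
* The odor stimulus is a rectangle; valve/plume dynamics are out of
  scope.
* Networks are limited to 5 neurons (8 in the compiled core), matching
  the model-complexity range the approach is designed for.
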
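---
title: "Delay phases from dead-cell masking: the models behind odelay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay phases from dead-cell masking: the models behind odelay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odelay)
```

## The phenomenon and the model

When fission yeast exhaust glucose and grow on glycerol, they secrete small
organic acids (HICA, i.e. leucic acid, and 2K3MVA, L-2-keto-3-methylvalerate)
that are toxic to clonemates which have not yet adapted to glucose
depletion. An unadapted culture inoculated into such a conditioned medium
(CM) appears to stall for many hours before growing — a "delay phase" in its
optical-density (OD) record.

`odelay` is built around the quantitative explanation of that stall: most of
the inoculum is killed at exposure, but dead cells keep scattering light, so
the turbidimeter reads the *sum* of dead and living material. Writing $a_0$
for the inoculum OD and $d$ for the kill fraction, the observed OD is

$$\mathrm{OD}(t) = \underbrace{a_0 d}_{\text{dead, constant}} +
  \underbrace{L(t)}_{\text{living}}, \qquad
  \frac{dL}{dt} = r\,L\Big(1 - \frac{L + a_0 d}{K}\Big),\quad L(0) = a_0(1-d),$$

with growth rate $r$, carrying cap $K$, and an optional survivor lag
$\lambda$ during which $L$ is flat. The delay statistic is
$\tau$, the time at which OD reaches $2 a_0$. Because the dead offset is
constant, the logistic equation for $L$ is a plain logistic with cap
$K' = K - a_0 d$ and rate $rK'/K$, so both the trajectory and $\tau$ have
closed forms; in the exponential regime ($K \gg a_0$),

$$\tau = \lambda + \frac{1}{r}\,\log\frac{2 - d}{1 - d}.$$

With the default $r = \log 2 / 10\ \mathrm{h^{-1}}$ (a 10-h doubling time in
glucose-free minimal medium) a kill fraction of $2/3$ turns the 10-h
doubling into $\tau = 20$ h — the observed delay in a 30-h conditioned
medium — without any change in the survivors' physiology. Inverting the same
formula gives the kill-fraction estimator used by
`estimate_death_from_curve()`:
$\hat d = (e^{r(\tau-\lambda)} - 2)/(e^{r(\tau-\lambda)} - 1)$.

### Modelling assumptions

* **Killing is instantaneous** at exposure: a fraction $d$ of the inoculum
  dies at $t = 0$. The dead compartment is constant afterwards. A
  continuous death-rate variant would smear the kill over the first hours;
  we did not implement it because the constant-dead-mass picture already
  reproduces the observed curve shapes and keeps $\tau$ analytic.
* **Dead cells never lyse** — their OD contribution persists for the whole
  record. This is the load-bearing assumption: without it there is no
  masking and no delay phase.
* **Glucose and adaptation protect completely.** `kill_fraction()` returns
  0 whenever the condition carries `glucose_present` or `adapted`,
  regardless of dose.
* **Survivor lag defaults to 0.** Whether CM survivors carry a
  physiological lag on top of the masking is not established; the model
  exposes $\lambda$ but does not use it by default.

## Dose response and the critical concentration

The kill fraction of an unadapted inoculum follows a Hill curve below the
critical concentration $c^*$ and is 1 at or above it:

$$d(c) = d_{\max}\,\frac{c^n}{c^n + h^n} \quad (c < c^*), \qquad d(c) = 1
\quad (c \ge c^*),$$

with defaults $c^* = 30$ mM, $h = 20$ mM for HICA and $c^* = 25$ mM,
$h = 16$ mM for 2K3MVA, $n = 4$ and $d_{\max} = 0.97$ for both. The hard
jump to total kill at $c^*$ encodes the observation that growth is fully
suppressed above the critical dose; $d_{\max} < 1$ keeps the sub-critical
branch strictly below total kill so that censoring of $\tau$ identifies
$c^*$ cleanly. The estimator (`estimate_critical_concentration()`) is
deliberately non-parametric: the smallest tested dose whose trace never
doubles within the horizon. On the default 2.5-mM grid with a 75-h horizon
this recovers 30 and 25 mM exactly, because the largest sub-critical doses
still double at $\tau \approx 24$–26 h.

On a conditioned-medium background, cofactors potentiate an added toxin
dose by the factor $s$ (default $10^3$, matching the roughly
three-orders-of-magnitude reduction of the effective dose);
`potency_shift()` recovers $s$ as the ratio of the standalone to the
background effect-threshold dose.

Doses of the two toxins combine additively on a $c/c^*$-normalised scale
when mixtures are needed; the data constrain no richer combination law.

## Toxin accumulation and the 15-h incubation threshold

During CM preparation the producer culture secretes toxin with a
*density-dependent* per-cell rate, so the per-culture rate is
$k N(t)^2$ with $N(t) = a_0 e^{rt}$ before saturation, starting after an
induction delay $t_{\mathrm{ind}}$ (default 2 h):

$$C(t) = \frac{k a_0^2}{2r}\left(e^{2rt} - e^{2r t_{\mathrm{ind}}}\right).$$

A constant per-cell rate (per-culture rate $\propto N$) cannot satisfy both
printed accumulation constraints — more than 5-fold growth of the
concentration from 10 to 20 h *and* more than 3-fold from 20 to 30 h — at a
10-h doubling time; the quadratic rate gives 5.48 and 4.27.

The calibration from accumulated signal to effective dose
(`cm_condition()`) is a monotone power law fixed by two anchors: the
threshold signal $E_{\mathrm{thresh}}$ (placed at the geometric mean of the
15-h and 20-h signals) maps to the dose whose $\tau$ sits exactly at the
delay-classification boundary, and the 30-h signal maps to the dose whose
kill fraction is $2/3$ (hence $\tau \approx 20$ h downstream). Media
incubated 15 h or less therefore fall short of the delay criterion and
longer incubations exceed it, reproducing the observed 15-h threshold.

## Measuring curves

* `moving_average()` — centred, 61-min default, shrinking at the edges.
* `measure_tau()` — $a_0$ is the mean OD of the first 30 min, corrected
  for within-window growth using the local log-slope of the first 90 min
  (without the correction a rising curve biases $a_0$ upward by ~1–2% and
  $\tau$ by 5–10 min). $\tau$ is the first crossing of $2a_0$ sustained for
  30 min on the smoothed trace; if only $1.5 a_0$ is reached, $\tau$ is
  extrapolated as $t_{1.5}\log 2/\log 1.5$ (exact on exponentials); if
  neither, the trace is censored. On noise-free model traces the measured
  $\tau$ agrees with the closed form within one sampling interval.
* `estimate_growth_rate()` — maximum slope of sliding 5-h log-linear fits,
  restricted to windows entirely above $1.5 a_0$ and below 70% of the
  observed plateau, with a fit-quality floor $R^2 \ge 0.98$. The
  restriction approximates the "steady growth phase" without fitting a
  plateau model; the maximum-slope rule biases slightly up while logistic
  curvature biases slightly down, and at the default inoculum
  ($a_0 = 0.02$, $K = 1$) the two nearly cancel, recovering the 10-h
  doubling within ~1% on average.
* `classify_delay()` — delay present iff $\tau$ is censored or exceeds the
  no-toxin baseline by a 5-h margin: far above $\tau$ noise (~0.3–0.8 h at
  default noise), far below the ~10-h effect of a 30-h CM.

## The synthetic-data layer

No raw instrument data are redistributable, so the package generates its
own, seeded end to end:

* **OD traces** — the forward model sampled at 1-min resolution over 75 h,
  with multiplicative log-normal noise (sd 0.02) plus an additive Gaussian
  floor (sd 0.002 OD). The floor mimics the turbidimeter's baseline
  jitter; its magnitude is a convention (the instrument noise is not
  published). It is the dominant noise source near the inoculum OD and is
  what limits $\tau$ and $\hat d$ precision at small kill fractions.
* **Flow counts** — multinomial draws over (label × viability) gates with
  probabilities proportional to compartment masses; 500,000 events for
  competition assays, 100,000 for viability staining. No scatter or
  spectral structure is simulated.
* **Compound tables** — Venn membership counts by construction, with
  criterion flags planted so a configurable number of candidate-region
  compounds survive the screen.

What the generator deliberately does *not* emulate: instrument drift and
calibration error, evaporation, slow lysis of dead cells, nutrient
depletion shared between competitors, and any chemistry of the toxins.
Passing tests on synthetic data therefore demonstrate internal consistency
of model, calibration and estimators — not instrument-level realism.

## Competition prediction

Two labelled subpopulations sharing the cap obey
$dL_X/dt = r_X L_X (1 - (L_A + L_B + D)/K)$. For equal rates the shared
logistic factor cancels from the ratio, so the living-cell steady-state
fraction is

$$f_\infty = \frac{w_A}{w_A + w_B}, \qquad
  w_X = N_{X,0}\,(1 - d_X)\,e^{-r\lambda_X},$$

exact in the exponential regime and matching the ODE simulation to
$10^{-4}$ there (under a finite cap with unequal lags it is a
pre-saturation approximation). Identical adapted populations at equal
inocula give exactly 50%; an unadapted competitor killed at $2/3$ gives
75%. Unequal rates make the long-run fraction degenerate (0 or 1); the
prediction is then flagged rather than reported as a finite ratio. By
default only living cells are counted (dead cells are assumed to drop out
of the label gates); with `count_dead = TRUE` the observed fraction starts
at the inoculum ratio and rises to the steady state, which is the shape the
flow-count pipeline compares against.

## Numerical choices and degenerate inputs

* All closed forms are evaluated in double precision; no ODE solving is
  needed outside `simulate_competition()` (deSolve `lsoda`,
  `rtol = 1e-10`, integrated piecewise across lag breakpoints).
* Censored $\tau$ is represented as `Inf`, which orders correctly in
  monotonicity checks and dose profiles.
* `tau_forward()` inverts the logistic solution analytically, so it agrees
  with root-finding on the simulated trajectory to $10^{-6}$ h at any cap;
  the $K \to \infty$ formula above is its limit.
* Degenerate inputs fail fast: negative doses, kill fractions outside
  [0, 1], all-dead flow masses, flat traces in the rate estimator,
  duplicate doses or compound names.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
75-h traces at 1-min resolution (4501 points), dose panels of 17 doses,
20-seed replication for the stochastic recoveries, 100 random draws for
the oracle cross-checks, and flow draws of $10^5$–$10^6$ events. The full
suite completes in well under a minute on a laptop.

## Known limitations

* The kill-fraction inversion reflects death *at exposure*; a dyed fraction
  measured at 8 h includes survivor regrowth dilution, so the two
  estimates differ by construction (`compare_estimates()` reports, it does
  not reconcile).
* At small kill fractions ($d \lesssim 0.2$) the additive noise floor makes
  single-trace $\hat d$ noisy (errors up to ~0.15); aggregate accuracy over
  replicates is ~0.02.
* The secretion calibration is identified only up to the two anchors; the
  absolute signal scale is arbitrary.
* Cross-species reuse (budding yeast and others) is supported only through
  per-strain `growth_params()` / `toxin_response()` sets; nothing
  species-specific is modelled.
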
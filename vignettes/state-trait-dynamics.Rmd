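---
title: "Modelling state–trait dynamics of psychotherapy change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling state–trait dynamics of psychotherapy change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statetrait)
```

## The model

`statetrait` simulates a dynamical-systems account of psychotherapy in
which five psychological **state** variables — emotions `E`, problem
intensity `P`, state motivation `M`, insight `I` and therapeutic success
`S` — are the order parameters of a self-organizing system, and four
**trait** parameters — alliance disposition `a`, cognitive competencies
`c`, behavioral resources `r` and trait motivation `m` — are its control
parameters. One iteration corresponds to one day, matching the cadence of
daily process questionnaires.

The state map is a set of five coupled nonlinear difference equations.
Every interaction between variables is a logistic ("sigmoid") term of the
form `scale / (1 + exp(u)) + offset`, where the exponent `u` is a linear
function of the source state whose gain and threshold are modulated by the
traits. `eval_state_terms()` returns each term by name (e.g. `E<-S` for
the effect of success on emotions), and `step_states()` applies all five
equations **synchronously**: every equation reads only the previous
iteration's state. We adopt the synchronous convention because the
composite equations are written without time indices while the one
explicitly indexed interaction is lagged; synchrony also makes the map a
pure function, independent of any evaluation order, which is asserted in
the tests. The motivation equation's leading pair of sigmoids is treated
as a single multiplicative term-group; every other contribution is
additive. All printed constants — including the unrounded `1.261` scale of
that product — are kept verbatim and dumped by `equation_constants()` for
audit.

States live on an internal dimensionless scale: `E`, `S` in [-1, 1] and
`P`, `M`, `I` in [0, 1]. These ranges are not part of the equations; they
are inferred from the sigmoid geometry (gains such as `-10E` or `-20M + 5`
only produce non-degenerate responses there) and from the empirical
100-point scale of the daily questionnaire, which maps to the internal
scale by division by 100 (`rescale_initial()`). The pure map is **not**
clamped; range enforcement happens in the engine after noise and
interventions, so the map stays testable against closed forms.

## Trait dynamics

Traits evolve slowly, driven by what the person actually experiences. The
update has four stages, all configurable:

* **Deviation filters.** For each variable, a running window of `n = 14`
  days is mean-centered and weighted by an exponential decay in sample
  age, `exp(-lambda * age)`, with `lambda = ln 2 / tau` and a half-life
  `tau = 7` days (`lambda = 0.099`). Mean-centering makes the filter
  respond to relative increases or decreases, never to absolute levels; a
  constant window yields exactly zero. A correction factor `d = 0.535`
  rescales the decay-weighted sum; it is treated as a given constant. We
  index the decay by sample *age* (newest weight exactly 1) rather than by
  absolute time: decay in absolute time would shrink all filter weights as
  the simulation proceeds, contradicting the intended memory effect
  (recent experiences count more than older ones) and breaking
  time-translation invariance.
* **Drivers.** The filters are combined per trait with normalizing
  constants: `a` follows success minus distress, `c` follows insight,
  success and the resource level, `r` follows success and the competence
  level, `m` follows problem/distress reduction, motivation and success
  (`combine_drivers()`).
* **Saturation and gating.** The raw increment is
  `delta = w * p_prev * driver` with sensitivity weights
  `w = 0.004167` — this `delta` is interpreted as the *pre-saturation*
  change (the circular alternative, defining `delta` through the already
  saturated update, squares the increment and destroys the sign of
  decreases). The effective increment multiplies `delta` by the gain
  `k = p_max - p_min` and by the distance to the approached bound
  (`p_max - p` for increases, `p - p_min` for decreases). The bounds
  default to `(0.1, 0.8)` for all four traits, hence `k = 0.7`; only the
  competence interval is prescribed, so the same window is adopted for the
  other traits and can be overridden per trait. Outside the thresholds
  `(0.2, 0.8)` an additional boundary gate engages: `(1 - p)` for
  increases above the ceiling gate and the factor `(p - 1)` below the
  floor gate. The latter is implemented as printed even though it acts as
  a restoring force (it reverses decreases near the floor);
  `literal_low_gate = FALSE` substitutes `|p - 1|` for sensitivity
  analysis.
* **Alliance mixing.** The alliance parameter has two faces — a
  disposition and the realized daily relationship quality `b_t`. When a
  measured series is supplied, the mixed value `(a_prev + b_t) / 2`
  replaces the previous alliance value *throughout* its update (additive
  base, raw increment and saturation distances). Under the alternative
  reading (mixing only inside the raw increment) a measured alliance
  series would change `a` only at order `w`, i.e. invisibly; full
  substitution lets the parameter track the experienced alliance, which is
  the behavior the model is meant to express. Without a series, `b_t`
  falls back to `a_prev` and the mixing is the identity.

All four traits are updated from the same previous trait vector
(synchronous, mirroring the states), clamped to [0, 1] as a hard safety
net, and frozen during the first `n` iterations while the window fills
("warm-up"). Freezing avoids privileging the arbitrary starting values
that a partially filled window would amplify.

## The engine

`run_scenario()` executes, per iteration: state step → interventions →
noise → clamping → trait update. Interventions and noise are inputs *on*
the variables, and the traits must integrate the states as actually
experienced, which fixes this order.

* **Interventions** add `magnitude / 100` internal units (a signed number
  of points of the empirical scale); overlapping events add.
* **Dynamic noise** is additive uniform on
  `[-level/100 * R/2, +level/100 * R/2]`, with `R` the variable's range
  width (2 for the bipolar `E`, `S`; 1 otherwise). Additive uniform noise
  is the weakest assumption consistent with "x% dynamic noise"; the
  distribution is recorded in the run manifest. One master seed spawns
  five per-variable substreams, so editing an intervention or one
  variable's level never shifts another variable's draw sequence — paired
  scenario comparisons stay aligned.
* **Trait overrides** pin selected parameters to piecewise-linear
  schedules (the control-parameter ramp experiment), disabling their
  endogenous dynamics.
* Every run records the applied increments; `replay_trajectory()` and
  `replay_manifest()` reproduce the stored trajectory bit-exactly.

## Preset scenarios and what they emulate

The presets encode the published simulation experiments: initial states on
the empirical scale, trait levels, per-variable noise percentages and
intervention windows are taken from the experiment descriptions
(`preset_scenario()`; the fidelity of every field is asserted in the
tests). Durations are not always stated; we use 100–400 iterations, long
enough to show the post-intervention and rebound phases, short enough that
the full suite runs in minutes. For the continuous-success experiment the
description carries an internally inconsistent start iteration (27 vs 17);
we use 17, consistent with the punctual variant.

The ramp experiment (`fig3`) prescribes only the competence schedule
(0.60 held to iteration 100, linear to 1.00 at 200, held after). The
remaining pinned values are our choice and matter: exploring the
deterministic clamped map showed it to be strongly **corner-bistable** —
a high-distress pattern (E, P at ceiling) coexists with a recovered one,
and grid and random probes found no interior chaotic attractor at
`c = 0.6`. The small-amplitude chaotic oscillation seen in the original
rendering of this experiment is therefore not reproducible from the
printed equations under clamped ranges; what *is* structural is the order
transition itself. We pin `a = 0.5`, `r = 0.7`, `m = 0.35` — a client
with solid resources and a workable alliance — because there the
competence ramp crosses the basin boundary of the map, start from the
recurring case profile (E 97.6, P 61.5, M 7.5, I 100, S -40.7) with 5%
noise, and run 400 iterations. The package tests assert the reproducible
substance: across 20 seeds the post-ramp mean of z-transformed `E`
(iterations 250–400) falls below the pre-ramp mean (0–100).

`synth_alliance()` generates synthetic alliance series (constant, linear,
logistic alliance building, optional Gaussian measurement noise) as
stand-ins for real daily alliance ratings, which are not distributable.
What the generator does **not** emulate: missing days, ordinal rating
granularity, retrospective response biases, or therapist-side ratings. A
passing suite therefore shows that the machinery is faithful to the model,
not that the model fits any particular client's data.

## Numerical choices

* z-scores use the whole series and the sample (n−1) standard deviation; a
  constant series maps to zeros with a warning.
* The gliding-window mean (width 3 by default, as used for smoothed
  display) treats endpoints with truncated windows, so output length
  equals input length and constants are preserved.
* `delta = 0` produces a zero trait increment; `sign(0) = 0` makes both
  saturation branches vanish, no tie-break needed.
* Filters require a complete window and raise a dedicated
  `st_short_window` condition, distinct from parameter errors.
* Clamping is idempotent and applied once per iteration, after all inputs.
* Trajectory CSVs are written with 17 significant digits so that
  round-trips preserve doubles exactly.

Problem sizes used by the test suite and the acceptance script — 100–120
random draws for the transcription-oracle comparisons (tolerance 1e-12),
1000 random windows for the filter properties, 20 seeds for the ramp
experiment, 50–200 random scenarios of 250–1000 iterations for
boundedness — were chosen as the smallest sizes at which the asserted
properties are stable across reruns.

## Known limitations

* The trait-update rule is sensitive to the interpretation of its
  saturation increment and of the alliance substitution; both readings are
  declared in the run manifest, and the low-gate variant is switchable.
  Other readings would change trait trajectories quantitatively.
* Under the default clamped ranges the deterministic state map settles
  into fixed points; sustained irregular dynamics in simulations come from
  dynamic noise, interventions and trait drift, not from chaotic attractors
  of the bare map. Lyapunov-style chaos quantification is out of scope.
* Noise distribution (uniform) and intervention arithmetic (additive
  points) are conventions, not derivations; both are configurable at the
  scenario level and logged.
* The model is phenomenological: parameters are psychological constructs,
  and nothing here estimates them from data — scenario inputs must come
  from the user.
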
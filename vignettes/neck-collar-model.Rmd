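---
title: "A lumped-parameter model of selective brain cooling with a neck collar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of selective brain cooling with a neck collar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckcool)
```

## The problem

Therapeutic hypothermia improves neurological outcome after cardiac arrest,
but whole-body cooling is poorly tolerated and carries systemic side
effects. A wearable cooling collar instead chills the blood flowing through
the neck toward the brain: the carotid arteries act as a heat exchanger, so
the brain can be cooled selectively while the rest of the body is largely
spared. `neckcool` implements a compact thermodynamic model of this
process, the simulation protocol used to predict cooling rates in an
anesthetized sheep and in a 70 kg human, a synthetic generator of
experiment-like temperature recordings, the small-sample statistical
pipeline used to analyze such experiments, and a calibration layer that
fits the under-determined parameters to temperature data.

## The model

Head, neck and body are single isothermal compartments (`tissue_node`s)
linked by a closed loop of blood segments (`blood_node`s): body blood feeds
an arterial neck segment, which feeds the head blood pool, which returns
through a venous neck segment to the body blood. Each node obeys a
first-order heat balance.

For a blood segment $i$ in contact with tissue $t$:

$$\rho_b V_i c_b \frac{dT_i}{dt} = g_{it}\,(T_t - T_i)
  + \rho_b c_b \phi\,(T_{i-1} - T_i),$$

where $g_{it} = h_b S_v$ is the vessel-wall convective conductance and
$\phi$ the volumetric flow, identical along the loop (incompressible
closed circuit). For a tissue node $t$ with conduction neighbours $j$
(another tissue, a collar element, or the environment):

$$m_t c_t \frac{dT_t}{dt} = \sum_j g_{tj}\,(T_j - T_t)
  + \sum_i g_{it}\,(T_i - T_t) + \dot Q_m - \dot Q_{collar},$$

with $g_{tj} = \lambda_t S_t / L_t$. The single-neighbour tissue balance is
generalized to a sum over all adjacencies, and the vessel-wall term appears
with opposite sign in the tissue and blood balances; without both of these
the network does not conserve energy. `energy_balance()` exposes the global
bookkeeping and the test suite verifies the residual at round-off level.
Because only temperature differences enter the equations, Celsius is used
throughout; units are otherwise SI, and metabolic inputs configured in
kcal/day are converted as 1 kcal/day = 4184/86400 W.

The environment is a fixed boundary temperature. The neck has no direct
environment edge — the collar covers its surface — while body and head
each lose heat to the room. The basal metabolic budget (default
1200 kcal/day ≈ 58.1 W) is partitioned over the compartments by
configurable fractions.

## The device

The collar is a 60 W source driving two cooling elements (one per carotid)
at an average conversion efficiency of 60%, i.e. an effective heat removal
of 36 W (`effective_extraction()`). The controller is modelled as a
constant-power sink with a proportional floor guard: extraction is held at
the power limit while the contact skin is warm, and is scaled linearly to
zero over the last 1 °C above the 5 °C safety floor. This is the simplest
law consistent with a "no lower than 5 °C" programmed floor and with the
observed regime, in which skin stayed near 14.5 °C and the device ran
power-limited throughout. The lumped model has no skin node, so the neck
compartment temperature at the element interface stands in for skin
temperature; the observed 14.5 °C interface value is treated as a
calibration observable rather than a hard target, since it depends on an
unreported element–skin contact conductance.

By default the elements are pure boundary sinks acting on the neck node
(they have no stated heat capacity); a `dynamic` element mode is
config-selectable, in which the elements are thermal masses coupled
through element–neck, element–element and element–environment
conductances, with the first or both elements coupled to the environment
(the published network diagram leaves this ambiguous, so the configuration
allows either).

## Simulation protocol

`run_protocol()` reproduces the two-phase experiment: a settling phase
with the device off, then 3600 s of cooling sampled at 1 Hz. Settling is
resolved by an exact steady-state solve rather than a long integration:
with the collar off the system is affine in the temperatures, so
`find_steady_state()` assembles the system matrix column by column from
the model's own right-hand side and solves the linear system, verifying
the residual below 1e-8 °C/s (the 100 min settling time shown in
trajectory figures is presentational, not physical; an integrated settling
phase from an arbitrary initial state remains available). Integration uses
`deSolve::ode` (lsoda) at rtol 1e-8 / atol 1e-10 — the blood segments have
small volumes and fast advection, so the system can be stiff. Halving the
tolerances moves no sampled temperature by more than 1e-4 °C.

Cooling rate is, by default, the endpoint difference of 60 s
moving-average-smoothed temperatures at activation and activation +
3600 s, expressed in °C/h — matching how the experimental endpoints were
summarized (the window length is not stated for the experiment; 60 s
smooths 1 Hz sensor noise without distorting a one-hour trend and is a
configuration knob). A regression-slope variant
(`cooling_rate_slope()`) is provided; the endpoint definition is the
default.

## Parameters, provenance and calibration

The parameter files distinguish three provenances: `literature-default`
(plausible values for an anesthetized 65–70 kg sheep or a 70 kg adult),
`calibrated` (fitted), and `file` (user override). The supplement-level
constants of the original study (exact conductances and flows) are not
printed in its main text, so the package's canonical route is calibration:
`default_calibration()` fits the four least literature-constrained
parameters — the body– and head–environment conductances and the
arterial/venous vessel-wall conductances inside the neck — to the four
reported model summaries. For the sheep these are the simulated baselines
(36.5 / 37.3 °C) and simulated cooling rates (0.4 / 0.2 °C/h); for the
human, the predicted rates (0.64 / 0.43 °C/h) with comparable normothermic
baselines (37.0 °C; no human baselines are printed). Both fits reach a
residual sum of squares at numerical zero, i.e. the four targets exactly
pin the four parameters. The fitted sets ship as
`sheep_calibrated.yaml` / `human_calibrated.yaml`.

Choices worth calling out:

* **Free parameters.** With sink-mode elements the collar–neck
  conductances do not enter the dynamics (extraction applies directly to
  the neck), so they are not useful calibration targets; the environment
  and neck vessel-wall conductances are both uncertain and influential,
  and split cleanly: the environment conductances set the baselines, the
  arterial wall sets how much pre-cooled blood reaches the brain, the
  venous wall sets how much cooling returns to the body.
* **Systemic blood coupling.** The body-blood segment stands in for the
  entire systemic circulation, whose capillary exchange area is enormous;
  its wall conductance defaults to 150 W/°C (near-perfect equilibration
  with the body mass). With a loosely coupled body pool, venous-side
  cooling recirculates around the loop into the arteries instead of
  draining the body — an artifact of the lumping, not a physiological
  pathway — and the observed brain/body rate split cannot be reproduced.
* **Selectivity mechanism.** In the fitted sheep model, brain cooling is
  driven by arterial pre-cooling plus the slow body drift, and body
  cooling by venous return of collar-chilled blood; zeroing the body-blood
  wall conductance makes the body rate collapse (< 0.05 °C/h) while brain
  cooling persists, which operationalizes the back-flow explanation of
  body cooling.
* **Objective details.** The summary objective simulates on a 60 s grid
  and uses exact endpoints; on these smooth traces this differs from the
  full 1 Hz moving-average pipeline by ~0.01 °C/h. All reported rates come
  from the full pipeline. Weights 1/1/5/5 (baselines/rates) balance the
  different magnitudes of the two kinds of residuals.
* **Multi-start.** `minpack.lm::nls.lm` (bounded Levenberg–Marquardt) is
  started from the base set's own values plus seeded uniform draws within
  bounds; the best accepted iterate wins and its RSS trace is
  non-increasing by construction.

`extrapolate_human()` carries the device-side configuration of a fitted
sheep set into a human anatomical set and re-runs the protocol; with the
calibrated sets this predicts a faster brain than body rate (the 0.2 °C/h
selectivity margin), reflecting the human's larger cerebral blood flow
and targetable vertebral arteries.

## Synthetic recordings and the statistical pipeline

`generate_cohort()` emulates the animal experiment: 4 animals, 1 Hz,
3600 s, per-animal baselines and rates drawn from the observed cohort
distributions (36.5 ± 0.4 / 37.3 ± 0.3 °C; 0.6 ± 0.2 °C/h for both
compartments), linear cooling, and AR(1) noise with marginal SD 0.05 °C
and lag-1 coefficient 0.99 — 1 Hz physiological temperature records drift
slowly rather than jitter independently. The generator is linear in time;
the simulator supplies the model's mild curvature when curved traces are
needed. What passing tests on synthetic cohorts demonstrate is that the
estimators and tests recover the generating statistical structure — not
that real recordings are linear, Gaussian, or AR(1).

`table1_records()` returns the noise-free records anchored to the
published per-animal endpoint temperatures; the summary pipeline
reproduces that table cell for cell, including the paired two-tailed t
tests (p = 0.0060 brain, 0.0067 body). Two remarks the pipeline makes no
attempt to hide: the published text also quotes p = 0.0072/0.0090 for the
same comparison, which do not follow from the printed per-animal values
and are not reproduced here; and the brain endpoint differences average
0.525 °C/h at full precision, although the study text rounds the
experimental brain rate to 0.6 °C/h. The package reports full precision.

`summarize_cohort()` uses truncated centered moving-average windows at the
series edges; on a linear series this biases the endpoint by the slope
over a quarter-window (~0.002 °C here), far below the 0.1 °C printed
resolution. Shapiro–Wilk normality screening (`shapiro_wilk()`) and the
paired t test (`paired_t()`) wrap the standard R implementations; the test
suite checks them against an explicit-formula oracle and frozen reference
values from an independent implementation.

## Problem sizes and numerical choices

The state vector has 7 entries (9 with dynamic elements). Simulations
sample 1 Hz over one hour (3601 points); calibration objectives use 60 s
grids. The test suite's Monte-Carlo checks use 200 replicate cohorts, 100
randomized networks for the maximum-principle property, and 10 optimizer
restarts for the parameter-recovery experiment; these sizes give stable
pass/fail behaviour at the stated tolerances. Degenerate inputs are
explicit errors: broken blood loops, non-positive masses/volumes,
zero-variance paired differences, windows outside a trace.

## Limitations

* Lumped compartments cannot resolve intra-tissue gradients (no
  Pennes-type continuum model); skin temperature is proxied by the neck
  node, so the absolute element-interface temperature is only loosely
  constrained.
* The vascular model is a single carotid-loop abstraction; the human
  vertebral branch is represented only implicitly through larger fitted
  neck wall conductances.
* Anesthesia-induced metabolic reduction is not modelled (the basal
  budget is constant); the experimental body rate exceeding the model's
  prediction is consistent with that omission.
* The calibration targets are the published summaries themselves, so the
  fitted sets are a reconstruction of the original parameterization, not
  an independent validation of it; the recovery tests show the fitting
  machinery finds known ground truth when it exists.
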
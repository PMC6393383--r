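---
title: "The TAN-dopamine interaction model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TAN-dopamine interaction model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tanda)
```

## The model

`tanda` simulates the population activity of striatal cholinergic
interneurons (tonically active neurons, TANs) and its bidirectional
coupling with striatal dopamine. Four state variables evolve under
first-order relaxation dynamics `tau * dx/dt + x = target(state)`:

* `v_tan` — normalized TAN population rate in `[0, 1)`, relaxing toward
  `sigma(w_thal * v_thal(t) + drv_tan + i_sahp + i_h)` with
  `sigma(x) = Theta(x) * tanh(x)`;
* `i_sahp` — slow after-hyperpolarization current, activated when
  activity exceeds `theta_sahp`; this hyperpolarizing current is what
  turns a thalamically evoked burst into a pause;
* `i_h` — depolarizing h-current, activated when activity falls below
  `theta_h` and scaled by `exp(-w_da * da)`: dopamine acting on D2
  receptors suppresses it, which is the route by which the dopamine
  excursion feeds back on the pause duration;
* `da` — dopamine concentration, relaxing toward
  `alpha * (rpe * (1 - v_tan/theta_da)_+ + da0) + ldopa`. While
  `v_tan > theta_da`, cholinergic tone clamps dopamine at its baseline;
  only during the deep pause does the reward prediction error (RPE)
  appear as a phasic excursion.

The assumptions inherited from this formulation: the TAN population is
homogeneous and described by a single rate; dopamine neuron firing is
not modeled explicitly — its effect enters only through the RPE term;
cholinergic control of dopamine terminals is a hard threshold
(`theta_da`); and muscarinic projections from TANs to projection
neurons are outside the model's scope.

Deficiency (`alpha`) scales the whole dopamine production (baseline and
phasic alike), modeling a proportional loss of nigrostriatal neurons;
levodopa (`ldopa`) adds a constant to the baseline without touching the
phasic term. Consequently the effective baseline under any scenario is
`alpha * da0 + ldopa`, and this is the reference from which the phasic
integral is measured (`effective_baseline()`, `phasic_da_integral()`).

## Parameters

All defaults of `model_params()` come from the published calibration
against thalamic-stimulation slice recordings: time constants
`tau_tan = tau_da = 20` ms, `tau_sahp = tau_h = 700` ms; gains
`g_sahp = 5`, `g_h = 20`; thresholds `theta_sahp = 0.3`,
`theta_h = 0.2`, `theta_da = 0.01`; `w_thal = 4`, `drv_tan = 0.3`,
`w_da = 1`, `da0 = 1` (dimensionless unless noted; `tau_da` is printed
without units in the source material and is interpreted as
milliseconds, consistent with every other time constant). The
constructor warns — rather than fails — when a user-supplied set breaks
the ordering `0 < theta_da < theta_h < theta_sahp`, since the
burst-pause phenomenology depends on it.

Pharmacological presets are parameter overrides, applied to a copy of
the parameter set: sulpiride (D2 antagonist) sets `w_da = 0`, cocaine
(reuptake blocker) sets `da0 = 3`, and the hypothetical h-current
blockade sets `g_h = 0`. The cocaine preset scales the baseline target
rather than adding to it; combined with `alpha < 1` the two compose
multiplicatively, which is unusual enough that `run_condition()` warns.

## Numerical choices

* **Integrator.** Forward Euler on a uniform grid, default
  `dt = 1` ms. With the smallest time constant at 20 ms this is deep
  inside the stability region; the test suite verifies that halving
  `dt` moves every reported pause duration by less than 2% and that a
  fine-step Euler trace agrees with an independent adaptive-step
  (`deSolve::lsoda`) integration of the same right-hand side to within
  0.5% in pause duration.
* **Heaviside at zero.** `Theta(0) := 0`, so `sigma(0) = 0` and each
  current's target is exactly zero at its threshold.
* **Dopamine positivity.** `da` is clipped at zero from below; extreme
  `alpha`/RPE combinations can transiently target small negative
  values, which are not meaningful for a concentration.
* **Rest state.** `steady_state()` solves the no-stimulus fixed point
  by damped-free fixed-point iteration (tolerance `1e-12`, default cap
  1000 iterations). At the default parameters the resting activity
  `tanh(drv_tan) ≈ 0.291` lies strictly between `theta_h` and
  `theta_sahp`, so both current targets vanish and the fixed point is
  exact; an unstimulated Euler trace stays within `1e-9` of it.
* **Pause criterion.** The pause is measured from the last stimulus
  offset: onset at the first grid time activity drops below the
  threshold, offset at the first subsequent recovery to it. The
  figures this model descends from mark the pause between dotted lines
  without a printed criterion, so the threshold is a knob;
  the default `"auto"` is 0.9 x the resting activity of the same
  parameters and context. A pause that never recovers within the
  horizon is returned as censored, with a warning.
* **Pulse trains.** Slice-style train stimulation is parameterized by
  frequency and pulse count, with the per-pulse width a free knob
  (default 10 ms at 50 Hz, a 50% duty cycle). Much narrower pulses
  deliver too little aggregate drive in a rate formulation to push the
  population below the h-current threshold, and the four
  pharmacological conditions then collapse onto identical pauses —
  contrary to the slice recordings the presets encode. The 10 ms
  default is the smallest round width that cleanly reproduces the
  experimental ordering sulpiride < control < cocaine < h-block.

## The levodopa equation

In the source formulation the levodopa variant of the dopamine
equation prints a baseline constant on its left-hand side where the
dynamics require the state variable. It is implemented here as
relaxation of `da(t)` toward `alpha * (...) + ldopa`, consistent with
the deficiency equation and with every described behavior (baseline
restored to `alpha * da0 + ldopa`; phasic magnitude unchanged).

## The reduced adaptation task

The behavioral loop reproduces the *structure* of the prism-throwing
experiment: per session 25 baseline, 25 perturbation and 25
aftereffect trials; 8 sessions averaged. The original embedding — a
two-pathway basal-ganglia network, spinal circuit and two-dimensional
arm — is deliberately collapsed to a one-dimensional endpoint
abstraction that preserves the causal chain: cue → D1/D2 activations →
relay gating → endpoint → distance reward → temporal-difference RPE →
TAN-pause-gated dopamine excursion → weight update.

Design choices in the reduction, and why:

* **Action set.** Nine candidate endpoints evenly spaced on `[-1, 1]`,
  target at `+0.5`; the executed endpoint is the relay-weighted convex
  combination. Nine actions give a grid fine enough that the target is
  reachable yet coarse enough that credit assignment is non-trivial.
* **Prism perturbation.** The mirror renders error-based correction
  useless, so in a purely reward-driven learner it is realized as a
  mid-experiment relabeling of the rewarded target: during the
  perturbation phase the effective target is mirrored about the
  starting axis. The perceived (sign-flipped) error is recorded but —
  by design — never used for learning.
* **Reward.** Linear in distance, `max(0, 1 - |error|/error_max)` with
  `error_max` the span of the action grid; the RPE is the clamped
  temporal difference of consecutive rewards, zero on a session's
  first trial.
* **Plasticity credit.** The rates entering the weight update are the
  post-competition relay activations, not the raw `w'c + noise`
  pathway inputs. In the full network, lateral inhibition concentrates
  striatal activity on the selected action's loop; with the flat
  pre-competition rates the Hebbian term is nearly uniform across
  actions and no context can learn at all. Collapsing the competition
  into the relay gate restores selective credit while keeping the
  update rule itself unchanged.
* **Learning rates.** The base rates and decay are not printed in the
  source material (they live in a predecessor model), so they are
  package defaults, chosen once: `lambda1 = lambda2 = 0.4` and
  `dw = 0.02` per trial make a healthy session adapt gradually over
  roughly 15-20 of the 25 perturbation trials — the experimentally
  observed timescale — rather than saturating in one or two trials,
  while keeping forgetting slow relative to a session. Exploration
  noise is Gaussian on the pathway activations (`noise_sd = 0.1`
  against initial weights of 0.5).
* **Per-trial dynamics.** Each trial runs a 300 ms thalamic block on a
  2500 ms horizon at `dt = 1` ms — long enough that no pause in any of
  the three standard contexts is censored.

What the generator emulates: the phase structure, trial counts and
session averaging of the behavioral experiment, and the dependence of
the learning signal on the TAN pause. What it does not: biomechanics,
muscle synergies, perceptual noise, inter-subject variability, or the
centimeter scale of real throwing errors. Passing tests therefore
support the *ordering and significance* claims (healthy adapts;
50% deficiency does not; levodopa partially restores) and say nothing
about quantitative error magnitudes in real subjects.

## Problem sizes

The shipped tests and the acceptance script use: single simulations of
2-6 s of model time at `dt = 1` ms (0.5 ms and 0.01 ms in refinement
checks); sweep grids of 100-400 ms stimulus duration, 0-90% deficiency
and 0-1 levodopa at three RPE levels; and the full behavioral
experiment (8 sessions x 75 trials) in each of three scenario
contexts. Equilibrium baselines are computed both in closed form and
by 10 s integrations from randomized initial states.

## Known limitations

* The pause duration at RPE = -1 is only *approximately* independent
  of deficiency. During the deep pause dopamine is pinned near zero
  for every `alpha`, but the recovery limb sees the baseline
  concentration through the h-current gain `exp(-w_da * da)` — the
  same mechanism that produces the levodopa lengthening and the
  RPE = 0 deficiency shortening. Across 0-90% deficiency the RPE = -1
  pause therefore still shortens noticeably (it remains by far the
  flattest of the three RPE curves, and at 50% deficiency the change
  is modest, consistent with the "slightly shorter" qualitative
  description of that condition). Exact independence would hold only
  if the pause were measured strictly within the
  acetylcholine-free window.
* Dopamine kinetics are a single relaxation; regional differences
  (e.g. accumbens shell) and release-site dynamics are not modeled.
* The plasticity rule integrates the dopamine deviation over the whole
  trace rather than sub-trial windows; the difference form is accurate
  because the deviation is non-zero essentially only during the pause.
* No spiking: peristimulus histograms can only be compared at the
  rate-envelope level.

```{r example}
tr <- simulate_tan(stimulus = stim_block(300),
                   context = scenario_context(rpe = 1))
detect_pause(tr)
glance(tr)
```
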
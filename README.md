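# tanda

Rate-based model of striatal cholinergic interneurons (tonically active
neurons, TANs) coupled bidirectionally to striatal dopamine release, with
a pause-gated reinforcement-learning loop for reward-based motor
adaptation.

## The science

TANs fire tonically at 5–10 Hz and pause after salient thalamic input.
While TANs fire, acetylcholine acting on nicotinic receptors of
dopaminergic terminals clamps striatal dopamine at its baseline; during
the pause, dopamine release follows the firing of midbrain dopamine
neurons, so the pause is the *time window* in which phasic dopamine can
encode a reward prediction error (RPE). Because dopamine in turn
suppresses the TAN h-current through D2 receptors, the pause duration
itself depends on the dopamine excursion — longer for reward, shorter
for aversive outcomes — and the time-integral of phasic dopamine over
the pause scales corticostriatal plasticity.

The model is four coupled rate equations, each of the form
`tau * dx/dt + x = target`:

- TAN activity: `tau_TAN dV/dt + V = sigma(W_Thal*V_Thal + Drv_TAN +
  I_sAHP + I_H)` with `sigma(x) = Theta(x)*tanh(x)`,
- sAHP current (pause generator):
  `tau_sAHP dI/dt + I = -g_sAHP * (V - theta_sAHP)_+`,
- h-current (recovery, dopamine-suppressed):
  `tau_H dI/dt + I = -g_H * exp(-W_DA*[DA]) * (V - theta_H)_-`,
- dopamine: `tau_DA d[DA]/dt + [DA] = alpha * (RPE * (1 - V/theta_DA)_+
  + [DA]_0) + LDOPA`,

where `alpha` in [0, 1] models nigrostriatal degeneration (Parkinsonian
dopamine deficiency) and `LDOPA` is the constant baseline increase from
levodopa medication. Pharmacological presets reproduce slice
experiments: sulpiride (`w_da = 0`), cocaine (`da0 = 3`), h-current
blockade (`g_h = 0`).

Per-trial learning uses the phasic dopamine integral `A = integral of
([DA](t) - baseline) dt` over the pause:
`dW1 = +lambda1_eff * C * D1 * A - dw * W1` (direct pathway) and
`dW2 = -lambda2_eff * C * D2 * A - dw * W2` (indirect pathway), with the
effective rate `lambda * 0.00125` above baseline and `lambda * 0.0025`
below. A reduced one-dimensional throwing task (baseline / mirrored
target / aftereffect, 25 trials each, 8 sessions) closes the loop:
action selection from the learned weights, distance reward,
temporal-difference RPE, TAN–dopamine simulation, weight update.

## Worked example

```r
library(tanda)

tr <- simulate_tan(stimulus = stim_block(300),
                   context = scenario_context(rpe = 1))
detect_pause(tr)
#> <tan_pause> 1466 ms (327-1793 ms); da in [1, 2]
phasic_da_integral(tr)
#> [1] 386.4261
```

A 300 ms thalamic block evokes a burst, then a pause of 1466 ms
(measured from stimulus offset at the default threshold, 0.9 x resting
activity). With `rpe = 1`, dopamine rises from baseline 1 toward 2
during the pause; the positive integral (386 concentration·ms) is the
learning signal. With `rpe = 0` the integral is 0; with `rpe = -1` the
pause shortens to 1128 ms and the integral is negative.

```r
tidy(sweep_deficiency(alphas = c(1, 0.5), rpe_levels = c(-1, 0, 1)))
#> # A tibble: 6 x 4
#>   axis_name      axis_value   rpe tp_ms
#> 1 deficiency_pct          0    -1  1128
#> 2 deficiency_pct          0     0  1277
#> 3 deficiency_pct          0     1  1466
#> 4 deficiency_pct         50    -1  1006
#> 5 deficiency_pct         50     0  1080
#> 6 deficiency_pct         50     1  1153
```

50% dopamine deficiency halves the baseline (`steady_state(context =
scenario_context(alpha = 0.5))$da == 0.5`), compresses the
reward/aversive pause difference (338 ms to 147 ms) and weakens
learning; `scenario_context(alpha = 0.5, ldopa = 0.5)` restores the
baseline to 1.0 but not the phasic amplitude. `run_experiment()` runs
the behavioral loop; `autoplot()` works on traces, sweeps and
experiments, and `tidy()`/`glance()` return tibble summaries.

A command-line front end is installed at
`system.file("cli", "tanda", package = "tanda")` with subcommands
`simulate`, `sweep`, `adapt`, `fixtures`.

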
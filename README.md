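# bistapc

Predictive-coding modelling of bistable perception in R.

During bistable perception, observers alternate between two mutually
exclusive interpretations of a constant ambiguous stimulus — for example a
rotating Lissajous figure seen as turning clockwise or counter-clockwise.
`bistapc` implements a Bayesian account of these alternations: a
**stability prior** centred on the current percept is combined with a
bimodal sensory likelihood; the residual posterior evidence for the
suppressed percept acts as a **prediction error** that accumulates on the
prior's variance until a transition becomes likely, after which the prior
is re-centred and its precision reset.

## The model

At each overlapping (depth-symmetric) stimulus configuration the model
takes one belief-update step:

1. **Joint prior** — precision-weighted fusion of the stability prior
   (mean `mu_stability` = previous decision, precision `pi_stability`)
   with a stereodisparity weight (mean `mu_stereo` in {0, 0.5, 1},
   precision `pi_stereo`):
   `pi_m = pi_stability + pi_stereo`,
   `mu_m = (pi_stability * mu_stability + pi_stereo * mu_stereo) / pi_m`.
2. **Posterior weight** for counter-clockwise rotation, under a bimodal
   likelihood with narrow modes at 0 and 1:
   `P(theta > 0.5) = logistic(pi_m * (mu_m - 0.5))`.
3. **Response model** — a unit-square sigmoid with inverse decision
   temperature `zeta` (identity at the default `zeta = 1`).
4. **Prediction error** `PE = |y - P(theta > 0.5)|`, the residual
   evidence for the suppressed percept given the decision `y`.
5. **Update** — on a transition, `pi_stability` resets to `pi_init`;
   otherwise the error accumulates on the variance:
   `1/pi' = 1/pi + PE`.

Three free quantities — `pi_init`, `pi_stereo`, `zeta` — define the model.
Around this engine the package provides:

* `simulate_timecourse()`, `phase_durations()`, `duration_stats()` —
  stochastic perceptual time-courses and dominance-phase statistics;
* `build_session()`, `synth_subject()`, `synth_cohort()` — a
  synthetic-cohort generator emulating a 20-subject fMRI design with
  alternating ambiguous and replay blocks (3 runs, 8 block pairs per run,
  overlap frequencies 0.24/0.30/0.40 Hz, 10 s fixation gaps);
* `fit_map()`, `laplace_evidence()`, `fit_cohort()` — MAP inversion of
  the four behavioural model variants (all combinations of the stability
  and stereodisparity components) with log-normal priors and Laplace log
  model evidence;
* `rfx_bms()`, `exceedance_prob()`, `protected_exceedance()` —
  random-effects Bayesian model selection;
* `simulate_oscillator()`, `simulate_attractor()`,
  `simulate_intermediate()`, `fit_rival()` — canonical rival models of
  bistability fitted with the same likelihood convention;
* `build_events()`, `build_design()`, `simulate_bold()`,
  `glm_contrast()`, `voxel_evidence()`, `group_epm()` — model-based fMRI
  design matrices (PE / Conventional / Block), canonical-HRF convolution,
  1/128 Hz high-pass, and voxel-wise Bayesian model comparison with group
  exceedance maps.

## Worked example

Simulate perception of an ambiguous stimulus at the canonical settings
and summarise the dominance phases:

```r
library(bistapc)

params <- model_params(pi_init = 3.5, pi_stereo = 0, zeta = 1)
sim <- simulate_timecourse(params, total_seconds = 3e4,
                           sampling_rate_hz = 0.33, seed = 3)
duration_stats(phase_durations(sim$decisions, sim$dt))
#> $n          [1] 2755
#> $mean       [1] 10.88049
#> $median     [1] 9.090909
#> $cv         [1] 0.6051037
#> $gamma_shape [1] 2.858027
#> $gamma_scale [1] 3.807392
```

Dominance phases last about 10 s on average and their distribution is
gamma-like with shape > 1 — the classical sharp rise and slow fall of
bistable perception. A semi-analytic cross-check is available:
`expected_phase_duration(params, 0.33)` returns 10.835 s, the exact
expectation under the deterministic stay-path hazard sequence.

Generate a synthetic subject, invert the full model, and compare
variants:

```r
sub <- synth_subject(model_params(3.5, 5, 1),
                     build_session(0.30, runs = 1), seed = 42)
fit <- fit_map(sub$responses, sub$session, variant = 4,
               n_starts = 8, seed = 1)
exp(fit$map_log_params)
#>  pi_init pi_stereo
#> 4.046392  6.630706
fit$log_evidence
#> [1] -63.18778
```

The recovered precisions sit near the generating values (3.5 and 5), and
the full model's evidence (-63.2 nats) beats the chance model
(-122.0 nats) by a wide margin. `run_recovery_study()` repeats this over
a 20-subject cohort: the full variant wins random-effects selection with
protected exceedance probability > 0.999, fitted `pi_init` correlates
about -0.97 with each subject's transition frequency, and every
subject's mean prediction error is lower under replay than under
ambiguity.

A command-line workbench over the same functions is installed at
`inst/cli/bistapc.R` (subcommands `simulate`, `synth`, `fit`, `compare`,
`recover`).

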
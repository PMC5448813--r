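---
title: "A predictive-coding model of bistable perception: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A predictive-coding model of bistable perception: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistapc)
```

## The model

Bistable perception is treated as sequential Bayesian inference over a
binary perceptual variable (0 = clockwise, 1 = counter-clockwise rotation
of an ambiguous structure-from-motion stimulus). Inference happens at the
stimulus's *overlap* configurations — the depth-symmetric moments at
which transitions can occur — so the model runs on a discrete grid of one
update per overlap.

Each update combines two Gaussian belief components into a joint prior
over the perceptual variable:

* the **stability prior**, centred on the previous decision
  $y(t-1)$ with precision $\pi_{stability}$. Immediately after a
  perceptual transition this precision is reset to the parameter
  $\pi_{init}$; while a percept is maintained it is eroded (see below);
* the **stereodisparity weight**, centred on $\mu_{stereo}$ with
  precision $\pi_{stereo}$. Under ambiguous viewing
  $\mu_{stereo} = 0.5$ (uninformative); under replay the disparity cue
  pushes it to 0 or 1.

Precision-weighted fusion gives the joint prior
$(\mu_m, \pi_m)$. The sensory input at an overlap is a bimodal
likelihood with equal modes at 0 and 1. We model the modes as narrow
(point-mass limit), in which case the posterior probability of the
counter-clockwise interpretation depends only on the joint-prior density
ratio at the two modes and has the closed form

$$P(\theta > 0.5) = \mathrm{logistic}\!\left(\pi_m\,(\mu_m - 0.5)\right).$$

This reduction is exact in the narrow-mode limit; the package verifies it
against numeric integration of an explicit two-Gaussian mixture posterior
(agreement better than $10^{-4}$ over a grid of $\mu_m, \pi_m$; see the
test suite). A convenient corollary is that on ambiguous overlaps the
stereodisparity term cancels exactly from $P(\theta>0.5)$ regardless of
$\pi_{stereo}$, so that parameter is identified only by replay blocks.

Decisions follow a unit-square sigmoid response model with inverse
decision temperature $\zeta$,
$y_{pred} = p^{\zeta} / (p^{\zeta} + (1-p)^{\zeta})$, kept fixed at
$\zeta = 1$ by default. The **prediction error** is the residual
posterior mass of the suppressed percept,
$PE = |y - P(\theta > 0.5)|$.

### The precision-update law

While a percept is maintained, the prediction error accumulates
additively on the *variance* of the stability prior:

$$1/\pi' \;=\; 1/\pi \;+\; PE,$$

a parameter-free law. This is the one place where the model's dynamics
are genuinely underdetermined by the qualitative description (variance
"increases as a consequence of prediction errors"); we chose the
simplest additive form with no extra gain parameter. Two consequences
support the choice. First, within a dominance phase under ambiguity the
belief state evolves deterministically along the "stay path", so the
phase-length distribution has an exact survival-product form
$E[L] = 1 + \sum_k \prod_{j \le k} p_{stay}(j)$, implemented as
`expected_phase_duration()`. Second, at the canonical operating point
($\pi_{init} = 3.5$, 0.33 Hz) this law yields a mean dominance duration
of 10.8 s and gamma-like durations with shape about 2.9 and CV about
0.6 — squarely in the empirically typical regime of roughly 10 s phases.
The acceptance tests compare the simulated mean and median against the
reference values 10.40 s and 10.00 s with a tolerance of one sampling
interval: durations live on the overlap grid (multiples of
$1/0.33 \approx 3.03$ s), so the median in particular can only take grid
values (9.09 s here).

### Conventions at block boundaries and for missing reports

Whether belief state should persist across the 10 s fixation gaps
between blocks is not determined by the model itself. We re-initialise
at every block start: the first overlap of a block carries no stability
prior (its decision is driven by the stereodisparity weight alone, a
fair coin under ambiguity), the prior is then centred on that first
reported percept with precision $\pi_{init}$, and the first overlap is
excluded from all fitting likelihoods. This makes generation and
inversion exactly mirror-symmetric and avoids attributing the
fixation-gap percept change to the update law. Missing or mixed-percept
reports carry the previous decision forward for state propagation but
are likewise unscored.

Along the same lines, the prediction error used for the variance update
is the one computed at the same overlap as the decision, applied before
the next overlap's fusion step.

## The synthetic cohort

`synth_cohort()` emulates the study design that motivates the package:
20 subjects, three runs each, 8 ambiguous/replay block pairs per run,
10 s fixation after every block, overlap frequency per subject drawn
from {0.24, 0.30, 0.40} Hz with block durations 42.8, 40.90 and 41 s
respectively (paired in that order; the pairing of duration to frequency
is a convention). Replay blocks present the disparity sequence that
mimics the subject's own decisions in the preceding ambiguous block,
piecewise-constant at overlap resolution — only the *direction* of the
disparity cue is modelled, not its (tiny) physical magnitude.

Ground-truth parameters are drawn log-normally: $\pi_{init}$ around 3.5
and $\pi_{stereo}$ around 5 (the canonical posterior scales), both with
log-scale SD 0.3, a moderate inter-individual spread chosen once so that
transition probabilities range over roughly 0.1-0.4 per overlap.

What the generator does *not* emulate: mixed percepts, lapses,
response-time jitter relative to overlaps, attentional modulation, slow
non-stationarities, and any physiological noise structure. Passing
recovery tests on this cohort therefore demonstrates internal
consistency of the inversion machinery (the generating model is inside
the model class), not robustness to the mis-specification real data
would bring.

## Inversion and model comparison

Precisions are log-normal, so inversion runs in log-parameter space with
Gaussian priors: $\log \pi_{init} \sim N(\log 3, 5)$,
$\log \pi_{stereo} \sim N(\log 5, 5)$; $\zeta$ is fixed at 1 by default
(optionally free with prior $N(\log 1, 1)$). The four behavioural
variants are all on/off combinations of the two components; a disabled
precision is fixed to zero, which removes the distribution exactly.

`fit_map()` minimises the negative log-joint with multi-start BFGS
(default 8 starts: the prior mean plus 7 prior draws; gradient-based
convergence at relative tolerance $10^{-10}$, max 500 iterations) and
computes the Laplace log evidence
$\log Z \approx -E(\hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H$ with a central finite-difference Hessian (step
$10^{-4}$ in log space; non-positive-definite Hessians are floored at
eigenvalue $10^{-6}$ and flagged). On one-dimensional problems the
Laplace evidence agrees with trapezoid-grid marginalisation to well
under 0.5 nats. Runs are fitted independently; per-subject evidence is
the sum over runs and parameter summaries are geometric means across
runs (arithmetic in log space).

Random-effects model selection uses the standard variational Dirichlet
scheme with a flat prior ($\alpha_0 = 1$), convergence when counts move
by less than $10^{-6}$ (cap 500 iterations). Exceedance probabilities
are Monte-Carlo ($10^6$ Dirichlet draws by default, seeded); the
protected variant discounts by the Bayes omnibus risk
$BOR = 1/(1+e^{F_1 - F_0})$, where $F_1$ is the variational bound of the
random-effects model and $F_0$ the evidence of the fixed
equal-frequency null, and
$PXP_k = XP_k\,(1 - BOR) + BOR/K$.

## Rival models

Three established model classes are implemented in their standard
published forms (their exact parameterisation in the comparison
literature is not fully specified, so these are canonical, class-level
implementations):

* **oscillator** — two firing-rate populations with sigmoidal gain,
  mutual inhibition and slow self-adaptation (Euler integration;
  defaults: inhibition 2, adaptation strength 1.2, adaptation time
  constant 4 s, drive 0.8, gain 8, rate time constant 0.4 s), which
  alternates deterministically with ~10 s periods, matching the ~10 s
  phases the study titrated its stimulus speed to;
* **attractor** — an overdamped particle in the double well
  $V(x) = h(x^2-1)^2$ with additive white noise (defaults $h = 1$,
  noise 0.75, relaxation 1 s; ~11 s Kramers escape times, approximately
  exponential);
* **intermediate** — the oscillator with Ornstein-Uhlenbeck noise on the
  drives (SD 0.3, correlation time 0.5 s), giving duration variability
  between the two limits (CV ≈ 0.4).

`fit_rival()` maps the model's state difference at the scored overlap
times through a fixed-slope logistic to a Bernoulli choice probability
and reuses the same MAP + Laplace machinery and the same scored-overlap
convention as the behavioural variants, so all log evidences are
directly comparable in one random-effects comparison. Two pragmatic
devices make this possible: the deterministic oscillator carries a
phase-offset nuisance parameter (without it a deterministic oscillation
cannot be aligned to stochastic data), and the stochastic rivals are
evaluated with frozen noise (one seeded noise path reused across
parameter evaluations), a crude but standard simulation-based
likelihood. Rival optimisation uses deliberately coarser settings
(60 iterations, relative tolerance $10^{-8}$): the frozen-noise surface
is only piecewise smooth and high-precision line searches buy nothing.

## Model-based fMRI

Three design matrices share stick regressors for overlaps and
transitions and differ in the parametric modulator on the overlap
sticks: the absolute prediction error (*PE model*), nothing but a split
of transitions into ambiguous and replay (*Conventional model*), or the
ambiguity boxcar (*Block model*). Events are laid on a fine grid of 16
bins per TR (TR = 2 s), convolved with the canonical double-gamma HRF
(response delay 6 s, undershoot delay 16 s, unit dispersions, ratio 6,
32 s support, unit-peak normalisation), and read out at scan times (402
scans, or 415 for the slowest stimulus speed). Modulators are
mean-centred within run before convolution but *not* serially
orthogonalised against the overlap stick: model comparison should see
each model's stated regressors. High-pass filtering projects a
discrete-cosine basis (cutoff 128 s) out of both design and data at fit
time; drifts inside the basis are removed exactly, generic slow drifts
are attenuated.

Voxel-wise evidence uses a conjugate Bayesian linear model on
standardised data: unit Gaussian weight priors (the same scale for every
model, which makes evidences comparable and prices extra regressors via
the determinant penalty) and unit noise, so
$y \sim N(0, I + XX^\top)$ in closed form. This is a desk-scale analog
of first-level Bayesian estimation, not a bit-match to any particular
neuroimaging pipeline — the reference procedures' priors and AR noise
models are not reproduced, and synthetic noise is white. Group-level
inference stacks per-subject evidence maps and runs the same
random-effects machinery per voxel; a display utility thresholds
exceedance maps at 0.99 with a minimum cluster size of 10 when a voxel
grid is supplied.

## Problem sizes and seeds

The package's own studies use: three pooled repetitions of the 6e5 s
canonical simulation (about 166,000 complete phases) for duration
statistics; a 20-subject, 3-run cohort for parameter and model recovery;
and a 10-subject, 300-voxel dataset (100 voxels per generating design,
unit betas against unit noise) for voxel-wise model identification.
These sizes give comfortably stable statistics — e.g. the recovery
correlation is about $-0.97$ and the protected exceedance probability of
the generating variant exceeds 0.999 — while keeping every study
re-runnable in minutes. All stochastic steps take explicit integer
seeds, and cohort/substream seeds are derived arithmetically from a
single master seed, so every result in the tests and the acceptance
script is bit-reproducible.

## Known limitations

* The additive PE-on-variance law is a reconstruction of an
  underdetermined dynamic; alternative laws (e.g. squared-error
  accumulation) would need the same anchoring against duration
  statistics.
* Durations are reported on the overlap grid; off-grid accounting (and
  hence a median of exactly 10.00 s at 0.33 Hz) is not representable.
* The stereodisparity component is identified by replay blocks only; in
  a design without replay, variant 4 collapses onto variant 2.
* Rival fits use frozen-noise likelihoods and class-level canonical
  forms; they support class-level conclusions, not parameter inference
  on the rivals.
* The fMRI stage models white noise and linear mixing only; no motion,
  physiological noise, AR structure, or spatial correlation.
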
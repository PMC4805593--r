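---
title: "Modelling action selection as direct-indirect pathway competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling action selection as direct-indirect pathway competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcompete)
```

## The model

The basal ganglia's direct (motor-facilitating) and indirect
(motor-suppressing) pathways are often described as independent levers.
`bgcompete` implements the alternative view: within each action channel the
two pathways engage in a dynamic competition, and the state of that
competition encodes the network's uncertainty about whether to act.  Each
channel is a two-population rate model,

$$\tau \dot{D} = -D + f\!\big(w_{self} D - w_{inh} I + g_d I_d + I_m +
I_\lambda\big) + \sigma\sqrt{dt}\,\xi_D,$$

and symmetrically for the indirect population $I$, integrated by
Euler-Maruyama with rectification at zero.  $I_d$ and $I_i$ are selective
cortical drives, $I_m$ is a modulatory non-selective drive (cued
expectation), and $I_\lambda$ a tonic non-specific background drive (the
tonic-dopamine analogue).  Decisions are read out by accumulating the
normalized firing-rate difference,

$$E(t) = \sum_t \beta\,\frac{D - I}{D + I + \varepsilon}\,dt,$$

to an execution threshold $\theta$ before a deadline $T$; failure to reach
$\theta$ is a no-go.  The normalized difference is bounded in $[-1, 1]$ and
degenerates gracefully at rest, which is why it is preferred over the raw
difference: with both populations at baseline the decision variable is flat
regardless of overall excitability.

With recurrent self-excitation strong enough that $f'(u)(w_{self} +
w_{inh}) > 1$ at the symmetric state, the channel is bistable: a Go-like
attractor (direct pathway wins), a NoGo-like attractor (indirect wins), and
a symmetric saddle between them.  `find_fixed_points()` locates the
equilibria by Newton polishing on a grid and classifies them by the
analytic Jacobian.

```{r fixed-points}
pre <- channel_preset("bistable")
find_fixed_points(pre$params, pre$input)
```

## Transfer functions and the excitability mechanism

Two transfer functions are provided.  The threshold-linear form is the
default for `channel_params()` and is the cleanest setting for linear-regime
analysis (the leak-dominated `"leak"` preset has a single stable origin).
The task presets use the logistic form, and this choice is load-bearing:
with a threshold-linear $f$, a drive added equally to both populations
cancels out of the difference dynamics, so baseline shifts would have no
behavioural effect.  With a saturating $f$ the local gain $f'(u)$ grows as
the operating point climbs the lower, convex limb of the sigmoid, so
non-selective input destabilizes the symmetric state and speeds the
nonlinear separation of the two rates (the "gate", `gate_time()`).  That is
the single mechanism behind both cue priming ($I_m$) and tonic
exploitation ($I_\lambda$) here.

## Default constants

All defaults live in `default_config()` and can be overridden by a YAML
config.  The central ones, with rationale:

| parameter | default | why |
|---|---|---|
| `dt` | 1 ms | ≥ 10 steps per time constant (`dt <= tau/10` is enforced) |
| `tau` | 100 ms | population time constant on the scale of striatal decision epochs |
| `w_self`, `w_inh` | 1.5, 1.5 | bistable regime: $f'(w_{self}+w_{inh}) > 1$ near threshold |
| activation | logistic, slope 4, offset 1, max 1 | rates in [0, 1]; instability onset at baseline drive ≈ 0.42 |
| `noise_sd` | 0.02 | attractor entry from symmetric drive within the trial window, ~50/50 split |
| horizon / `deadline` | 1500 ms | typical forced-choice trial length |
| `threshold` | 1 evidence unit | crossed ~200-400 ms after gating at $\beta = 0.005$/ms |
| `t0` | 100 ms | conventional non-decision (sensory + motor) time |
| ceiling | 10 | divergence guard only; logistic rates saturate at 1 |
| fixed-point merge tolerance | 1e-6 | distinct equilibria differ by O(0.1) rate units |
| `gate_time` dwell | 50 ms | rejects transient noise-driven separations |

Whether $I_m$ and $I_\lambda$ pass through the pathway gains is
configurable (`ns_weighted`); they enter unweighted by default, as pure
non-selective drives.  `lambda_mode = "gain"` offers a multiplicative
alternative to the default additive tonic drive.

## Cued choice

`run_cued_block()` implements a two-channel forced choice.  Sensory drive
enters each channel as a constant input with a direct-pathway bias
(`direct_bias`, default 0.65 > 0.5, reflecting denser sensory afferents
onto direct-pathway neurons); a ramping-sensory variant was considered and
rejected as adding a free dynamic without changing the qualitative
predictions — constant drive is the minimal reduction.  The cue delivers
`I_m` to the cued channel from $t = 0$ (the cue precedes the stimulus, so
it appears as a baseline shift).  The first channel to cross $\theta$ wins;
a same-sample tie is broken uniformly at random from the trial's own RNG
stream.  There is no between-channel inhibition by default: the
within-channel direct-indirect competition alone decides, and the cued
channel only (not its competitor, at reduced strength or otherwise)
receives modulatory input — both were genuinely open choices; the defaults
are the most parsimonious readings and both are confined to one code path
(`cued_channel_input`) if a user wants the alternatives.

Valid cues destabilize the correct channel and speed correct responses;
invalid cues destabilize the wrong one and produce fast errors — raising
`cue_strength` buys valid-trial speed at invalid-trial accuracy, a
speed-accuracy tradeoff produced by baseline excitability rather than an
explicit boundary change.

```{r cued}
blk <- run_cued_block(cued_task_params(cue_validity = 0.5), n = 200, seed = 7)
blk$by_validity
```

## Reinforcement learning

`run_learning_session()` simulates the probabilistic selection task: two
stimuli pay Bernoulli rewards with probabilities `p_opt >= p_sub`.  The
schedule presets (0.80/0.20, 0.70/0.30, 0.60/0.40) follow the conventional
probability pairs of this paradigm; they are presets, not fitted values.
Feedback acts at two coupled levels:

* **values**: the chosen action's estimate moves by the delta rule
  `q' = q + alpha_q (r - q)`; the value difference maps linearly onto the
  drift rates of a two-accumulator race
  (`drift_base ± drift_map_slope · (q_opt − q_sub)/2`);
* **pathway sensitivities**: the chosen action's direct gain moves `+delta`
  and its indirect gain `-delta` after reward, and oppositely after
  non-reward, clamped to `gain_bounds`.  A fixed increment is the default;
  `rpe_scaled = TRUE` scales it by |RPE| for users who want burst-magnitude
  scaling.  Updates are on-policy: only the chosen action changes.

Choices come from a race of two constant-drift accumulators.  Exploration
is *not* a softmax parameter — it arises from the accumulator noise itself.
The race is sampled exactly: the first-passage time of a constant-drift
diffusion through a single absorbing bound is inverse-Gaussian (sampled by
the Michael-Schucany-Haas transform; negative drifts cross with probability
$e^{2va/\sigma^2}$ and, conditioned on crossing, behave as the reflected
positive drift; zero drift gives a Levy time).  This avoids any
time-discretization bias, and the unit tests verify the sampler against an
Euler-simulated diffusion.  Double timeouts are a forced fair guess that
still receives feedback (`learn_on_timeout = FALSE` disables this).
`run_learning_race()` provides the alternative network-backed engine, where
the learned sensitivities multiply `g_d`/`g_i` of two full channels; the
two engines agreeing in preference direction at matched values is a test,
not an assumption.

Race constants (`boundary = 1`, `race_noise_sd = 0.045`/√ms,
`drift_base = 0.0022`/ms) put equal-value RTs near 550 ms with a
coefficient of variation near 1, comparable to the network channel's
go RTs under moderate drive.

```{r learning}
tr <- run_learning_session(reward_schedule(0.8, 0.2, 300),
                           learning_params(), seed = 1)
tr
```

## Tonic modulation

`run_tonic_sweep()` varies $I_\lambda$ at fixed `I_d:I_i`.  The tonic
preset weights cortical input more strongly to the direct pathway
(`g_d = 1.15 > g_i = 0.85`) and routes the non-selective drives through
those gains (`ns_weighted = TRUE`), reflecting dopamine's opposite effects
on the two striatal populations; raising $I_\lambda$ then speeds gating,
tightens the RT distribution and biases outcomes toward go.  In the
abstract race, the same tonic level multiplies both drifts by
`1 + lambda_gain * I_lambda` — expression changes, learning state does not
(the sweep asserts gains are untouched).  Exploration is quantified as the
Shannon entropy of the response distribution in a fixed-value race probe.
The probe uses a value difference of 0.5 and 8000 probe trials per level:
the per-level entropy drop is ~0.02 bits, and at 8000 trials the
Monte-Carlo standard error (~0.005 bits) leaves that ordering resolvable;
smaller probes would measure noise.

## Diffusion-model bridge

`estimate_ddm()` inverts accuracy and the mean and variance of correct RTs
into effective drift, boundary and non-decision time with the EZ-style
closed-form equations (diffusion coefficient s = 1 by convention here;
RT unit conversion ms→s happens only at this boundary).  A moment-based
inversion was chosen over likelihood fitting deliberately: it is
dependency-free, deterministic, exactly unit-testable, and sufficient for
comparing conditions.  Accuracies of exactly 0 or 1 are edge-corrected to
$1/(2n)$ and $1 - 1/(2n)$; accuracy exactly 0.5 returns zero drift with
boundary and $t_0$ undefined (the moments no longer identify them).
`compare_conditions()` adds trial-level bootstrap percentile intervals.
The headline qualitative result this module exposes: manipulating the
channel input ratio moves the *recovered drift* monotonically while the
recovered boundary moves comparatively little — uncertainty manipulations
express as drift, not threshold, changes.

## What the simulator does and does not emulate

The package generates all of its own data; the generator *is* the model.
Passing tests therefore show internal consistency of the mechanism —
ratio-ordered speed and accuracy, bistability, cue-validity effects,
convergence of values to reward probabilities, gap-ordered learning speed,
tonic exploitation, drift-loaded condition effects — under the stated
conditions (500-1000 trials per behavioural cell, 100 sessions per
schedule, 200 attractor seeds; sizes chosen to leave clear Monte-Carlo
margins at desk scale).  They do not show that real striatal populations
obey these equations: there are no spiking neurons, no explicit GPe/GPi/STN
or thalamic nodes, no arkypallidal feedback, no hyper-direct stop process,
and the networks are two-population reductions with unlabelled rate units.
Numerical caveats worth knowing: Euler integration at `dt = 1` ms agrees
with `dt/10` to ~0.02 rate units on zero-noise trajectories but is still a
first-order scheme; threshold-linear dynamics with `w_self > 1` diverge by
construction (caught by the ceiling guard); Newton polishing can stall on
the threshold-linear kink (such candidates are dropped and counted, never
silently kept); and exactly symmetric zero-noise starts sit on the saddle's
stable manifold forever, which is a property of the model, not a bug.
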
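---
title: "A dual-error model of visuomotor adaptation: simulation and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-error model of visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualadapt)
```

## The problem

When a reach is made under a rotated cursor, the motor system can correct
itself using two different error signals. The *sensory prediction error* is
the gap between the cursor it expected (from the efference copy of the
command) and the cursor it saw; learning from it updates an internal
estimate of the perturbation, which changes both the motor command and the
predicted sensory consequences of commands — it leaves a *sensory
remapping* behind, measurable as a shift in where subjects localize their
unseen hand. The *reward prediction error* is the gap between the expected
and the realized success of the reach; learning from it shifts the policy
directly and leaves the motor-sensory map untouched. `dualadapt` implements
a learner that carries both mechanisms, the three feedback regimes that
modulate their balance (continuous cursor, ERR; endpoint-only flash, EPE;
reward only, RWD), a trial-by-trial fitting procedure that decomposes an
observed reach series into the two underlying memories, and a synthetic
subject generator for end-to-end validation.

## The generative learner

All variables are scalar reach angles in degrees, clockwise positive. On
trial $k$ the hand lands at $h_k = u_k + \epsilon^u_k$, the cursor at
$c_k = h_k + p_k$ where $p_k$ is the imposed rotation, and the observation
(when the regime provides one) is $y_k = c_k + \epsilon^y_k$. Reward is
$r_k = \mathbf{1}\{|c_k - t| \le 3^\circ\} - \lambda u_k^2$ for the
6°-wide target at $t$.

**State estimator.** The learner models the perturbation as a slowly
drifting AR(1) state, $p_{k+1} = A p_k + \epsilon^p_k$, and runs the scalar
Kalman filter

$$\hat p^-_k = A\hat p_{k-1},\qquad P^-_k = A^2 P_{k-1} + q,$$
$$K_k = \frac{P^-_k}{P^-_k + \sigma^2_y},\qquad
  \hat p_k = \hat p^-_k + K_k\,\big(y_k - (u_k + \hat p^-_k)\big),\qquad
  P_k = (1-K_k)\,P^-_k.$$

The bracketed term is the sensory prediction error. In RWD there is no
observation and the gain is identically zero, so $\hat p$ never leaves its
initial value: whatever adaptation occurs cannot come from this channel.
The full state of the task is three-dimensional (hand, perturbation,
target), but the hand is determined by the command up to noise and the
target is known, so only the perturbation carries uncertainty; the filter
is therefore implemented in its exact scalar reduction.

**Actor–critic policy.** The command is
$u_k = (t - \hat p_k) + x_{r,k} + \eta_k$, where $x_r$ is the accumulated
reward-driven correction and $\eta_k \sim N(0, \sigma^2_\eta)$ is *active
search noise* — deliberate exploration, distinct from execution noise.
One reach is one decision, so the temporal-difference error uses the
current value as its own successor,
$\delta_k = r_k + \gamma v - v$, and

$$v \leftarrow v + \alpha_c\,\delta_k,\qquad
  x_r \leftarrow x_r + \alpha_a\,\delta_k\,\eta_k .$$

The actor update is the standard REINFORCE-style eligibility: the executed
exploration is reinforced in proportion to the reward surprise. With
$\gamma = 0$ it reduces to $\delta = r - v$. Because the reward zone moves
with the rotation schedule (1° every 40 trials), this stochastic
hill-climbing tracks the zone even with no visual feedback at all; a
static zone several exploration SDs away would never be found, since the
reward probability — and with it $\delta$ — would be zero everywhere near
the start.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `retention` $A$ | 0.99 | AR(1) retention of the perturbation prior |
| `process_noise_var` $q$ | 0.01 deg² | assumed drift of the perturbation |
| `observation_noise_var` $\sigma^2_y$ | 1 (ERR), 8 (EPE), absent (RWD) | reliability of the cursor percept |
| `motor_noise_sd` | 1 deg | passive execution noise |
| `search_noise_sd` $\sigma_\eta$ | 0.5 (ERR), 1 (EPE), 1.5 (RWD) | active exploration |
| `actor_lr`, `critic_lr` | 0.15 | reward-learning rates |
| `discount` $\gamma$ | 0.9 | TD discount |
| `motor_cost_scale` $\lambda$ | 0.001 | quadratic effort cost |

$A$ and $q$ are conventional slow-drift values for gradual-rotation
paradigms; nothing in the behavioral protocol pins them, and they are
reported with every output. The EPE observation variance is set to eight
times the ERR variance — the endpoint flash is informative but much less
reliable than continuous vision; the exact factor is a modelling choice,
config-overridable, and only the ordering ERR < EPE < (absent) matters for
any asserted property. Search noise grows as feedback degrades, which is
both what the model needs (reward learning is driven by $\delta\,\eta$)
and what the elevated reach variability under reward-only feedback
reflects. With these defaults the combined ERR reach noise SD is
$\sqrt{1^2+0.5^2} \approx 1.1^\circ$ against a ±3° reward zone, which is
why the full-vision learner is rewarded on essentially every trial.

```{r}
cond <- feedback_condition("ERR")
sim <- run_condition(learner_params(cond), build_schedule("EXP1"),
                     cond, reward_geometry(), seed = 1)
summary(sim)
```

The headline dissociation is a one-liner per condition: ERR ends with a
terminal $\hat p$ near 8° (a remapping), RWD ends with $\hat p = 0$
exactly while the reach compensates just as fully. `uncertainty_sweep()`
traces the continuum in between: terminal remapping falls monotonically
with $\sigma^2_y$ while adaptation stays within a degree of the plateau,
because the reward system absorbs whatever the estimator does not.

## The dual-memory fit

For an observed subject (reach $h_k$, imposed rotation $p_k$, reward
$r_k$), the model asserts $h_k = x_{p,k} + x_{r,k} + \eta_k$ with
$x_p \equiv -\hat p$. `forward_filter()` runs the two recursions forward
*constrained by the data*: the residual $\eta_k = h_k - (x_{p,k} +
x_{r,k})$ feeds the actor update, the logged reward feeds the TD error
(the scalar reward is reconstructed as the hit flag minus
$\lambda h_k^2$), and the sensory prediction error is formed from the
known imposed rotation, $e_k = p_k - \hat p^-_k$. Minimizing
$\sum_k \eta_k^2$ — the squared difference between observed and
model-predicted reaches, equivalently the magnitude of the search-noise
sequence — over the free parameters is a bounded nonlinear least-squares
problem, solved by Levenberg–Marquardt (`minpack.lm::nls.lm`) from
Latin-hypercube multi-starts because the landscape is multimodal on
series this short. ERR/EPE fits free three parameters
($\sigma^2_y$, searched on a log scale; the actor rate; and a third whose
identity is a single configuration point — process-noise variance by
default, the critic rate via `fit_config(third = "critic_lr")`); RWD fits
free the actor and critic rates with the gain clamped to zero. The
discount is fixed during fitting, and the critic shares the actor's rate
unless the alternative mapping is selected.

```{r}
fit <- fit_subject(sim$trials, cond, n_starts = 6, seed = 1)
fit
decompose(fit)
```

Two caveats are inherent to the method and worth stating. First, the
filter cannot distinguish active search noise from passive motor noise —
both land in $\eta$ — so the residual variance estimates their sum, and
the reconstructed $x_r$ path is driven by a noisier eligibility than the
generating one; recovered learning rates are accordingly biased low and
only order-of-magnitude identifiable (the recovery tests assert median
relative error below 50%, not unbiasedness). Second, of $(\sigma^2_y, q)$
only the gain they jointly imply is well identified, so individual values
can wander while the memory trajectories — the quantities of scientific
interest — remain stable. Fits on fewer than 50 trials are refused
outright; recovery degrades sharply below that.

## The synthetic cohort

`generate_subject()` wraps a simulated adaptation run with the two probe
blocks of the behavioral protocol. Localization (10 PRE + 10 POST probes,
each closing a four-shooting-trials micro-block) is recorded relative to
the actual hand crossing; POST probes are displaced toward the cursor by
`remap_fraction` times the terminal $\hat p$, plus pointing noise (SD 2°).
Generalization probes (80-trial blocks: 32 at the trained direction, 8 at
each of ±10°, ±20°, ±30°) transfer the signed adaptation with a Gaussian
curve $\exp(-\theta^2/2 w_g^2)$ in probe direction — the standard
phenomenological shape (a cosine alternative is provided); the learner
itself is scalar and does not produce a generalization width, so the
generator imposes one. `remap_fraction` and $w_g$ are the two
subject-level phenomenological dials; `cohort_sampler()` couples both to
one latent "reliance on vision" variable, so that subjects who remap more
also generalize more broadly. Under the clockwise-positive convention
with a negative rotation, larger illusions are more negative, so the
signed illusion–generalization correlation of such a cohort is negative;
`cohort_correlation()` therefore defaults to the signed index (the
absolute-value variant flips the sign and is available via
`signed = FALSE`). Only the sign of that correlation is a model property —
its magnitude depends on the sampler, for which no quantitative law
exists.

What passing these tests shows — and does not. The generator emulates the
statistical skeleton the analyses assume: two-memory trial dynamics,
condition-dependent search noise, probe bookkeeping, a coupled remap/width
continuum. It does not emulate within-movement trajectories, proprioceptive
drift, use-dependent biases, or any neural encoding of direction, so green
tests validate the machinery and its internal consistency, not those
aspects of real behavior.

## Numerical choices and problem sizes

Reward-zone boundaries are inclusive (|error| ≤ 3° rewards). Reach
variability uses the population-SD convention. Terminal quantities are
means over the final 100 trials (80 for fit decompositions, the terminal
plateau). Initial conditions are $\hat p = 0$, $P = 1$ deg², $x_r = 0$,
$v = 0$ throughout. Monte-Carlo summaries use 20 seeds per cell with the
seed lists reported; recovery suites fit 20 synthetic subjects per
condition with 6 optimizer starts each, and the estimator-equivalence
property checks 1000 random observation sequences against an
independently coded conjugate-Gaussian recursion at $10^{-9}$. All
simulations use the full 496-trial gradual schedule; these sizes make the
complete suite run in a few minutes while leaving every Monte-Carlo bound
at least three standard errors wide.

## Known limitations

The critic is a single scalar value (appropriate for one trained target;
no function approximation), generalization is phenomenological rather
than mechanistic, the fit does not co-estimate the discount, and group
statistics are descriptive only — no hierarchical pooling across
subjects.
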
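---
title: "Modeling trial-by-trial criterion learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling trial-by-trial criterion learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critlearn)
```

## The scientific problem

Signal detection theory treats a discrimination decision as a comparison of
a noisy measurement against a decision criterion, usually assumed fixed.
But human decisions show history effects: the criterion drifts with the
recent stimulus sequence even in stable environments. `critlearn`
implements a complete in-silico version of a two-task paradigm for studying
that drift: a **covert-criterion task**, in which an observer categorizes
an oriented ellipse as category *A* or *B* and receives feedback, and an
**overt-criterion task**, in which the observer explicitly rotates a
criterion line on every trial before the stimulus appears. Stimulus
orientations come from two Gaussian categories with equal SD
$\sigma = 10^\circ$; the category-A mean is always clockwise of the
category-B mean, with the separation $\Delta\theta$ chosen so that
$d' = \Delta\theta / \sqrt{\sigma^2 + \sigma_v^2} = 1$, where $\sigma_v$ is
the observer's sensory noise. In the *static* condition the means are fixed
within a 600-trial block (the initial A mean drawn uniformly from
$(-50^\circ, 50^\circ)$); in the *dynamic* condition both means follow a
shared Gaussian random walk with step SD $\sigma_{\text{random}} = 5^\circ$
and constant separation.

Because no human data ship with the package, a synthetic-data generator
plays the role of the observers. It is first-class, tested code: sessions
are produced by closed-loop simulation in which an observer model proposes
a criterion, the response and feedback are generated, and the model state
is updated — exactly the loop assumed by the fitting machinery.

## The observer models

All models reduce each trial to a criterion $z_n$; the covert response is
*A* when the noisy measurement $X \sim N(S, \sigma_v)$ falls clockwise of
$z_n$, and the overt setting is $z_n$ corrupted by adjustment noise
$\sigma_a$.

* **Ideal Bayesian** (static only): computes the posterior odds that the
  new measurement belongs to category A given all past samples,
  marginalizing over the unknown means (flat prior on $\mu_A < \mu_B$) and
  shared SD (Jeffreys prior); the criterion is the measurement at which the
  odds equal one.
* **Bayesian model selection**: running arithmetic mean per category;
  criterion halfway between the two estimates.
* **Exponentially weighted moving average (EWMA)**:
  $\hat\mu \leftarrow \alpha x + (1-\alpha)\hat\mu$ for the presented
  category; $0 < \alpha < 1$ sets the time constant
  $\tau = -1/\log(1-\alpha)$ trials. $\alpha \to 0$ approaches the running
  mean; $\alpha = 1$ is the limited-memory rule.
* **Kalman filter** (dynamic): Bayesian mean tracking under the assumed
  random walk; the trial-specific gain depends only on
  $r = \sigma_{\text{random}}^2 / \sigma_{\text{cat}}^2$ and converges to
  the positive root of $\kappa^2 + r\kappa - r = 0$ within a few trials,
  which is why it is practically indistinguishable from an EWMA with
  matched fixed gain.
* **Delta rule (reinforcement learning)**: the criterion moves a fraction
  $\beta$ toward the stimulus after negative feedback only.
* **Limited memory**: each category estimate is the single most recent
  sample.

## Design choices in the open

Several aspects of the paradigm are underdetermined and had to be fixed;
these are the package's choices and the reasoning behind them.

**Orientation arithmetic.** Orientations are axial (180°-periodic). All
updates use shortest-arc differences and estimates are wrapped to
$(-90^\circ, 90^\circ]$; at the category and walk scales used here (10°
and 5°) consecutive quantities never approach the 90° ambiguity, so the
arithmetic coincides with the linear arithmetic the analyses assume.
Logged values are always wrapped; the dynamic random walk is unbounded in
latent arc-length, and analyses that need a continuous series
(cross-correlation) first unwrap by accumulating shortest-arc increments.

**Learning signal.** Observer updates consume the presented stimulus
orientation $S$ (known from feedback), not the latent noisy measurement
$X$; sensory noise enters only the current decision. Learning from $X$
would make the criterion trajectory stochastic given the log and require a
marginalization the likelihoods do not define. A `learn_from =
"measurement"` switch exists for simulation studies.

**Warm-up.** Before both categories have been observed, covert models
respond by an unbiased guess (each trial contributes $\log \tfrac12$ to the
likelihood) and overt models emit the running estimate of the one known
category (0° if none). The delta rule starts at $z_1 = 0$ for covert
sessions and, when fitting overt data, at the first logged setting.

**EWMA initialization.** For fitting, the first observed sample of a
category initializes its estimate. A uniform random initialization would
add an unidentifiable nuisance parameter to the likelihood.

**Ideal-observer quadrature.** The posterior odds integral is evaluated by
deterministic quadrature: 121 mean-grid points per category spanning the
data range ± 4 sample SDs, constrained to $\mu_A < \mu_B$ with the
diagonal given half weight (keeping the triangular sum second-order
accurate), and 61 log-spaced SD points on $[1^\circ, 50^\circ]$, where the
Jeffreys density and the log-grid Jacobian cancel. Doubling the resolution
moves 20-trial log odds by well under $10^{-3}$. The Jeffreys prior is made
proper by the SD bounds, which bracket the true $\sigma = 10^\circ$
generously. When the category SD is a fitted parameter the quadrature
conditions on it (two-dimensional integral over the means only); because
that trajectory depends on the fitted SD, per-session trajectories are
precomputed on a 9-point log-spaced SD grid and interpolated inside the
likelihood.

**Priors and sampling.** Jeffreys priors for all SD parameters, made
proper on $[0.5^\circ, 60^\circ]$; flat priors for $\alpha, \beta$ on
$(0,1)$ and for the Kalman ratio on $(0.01, 100]$. The sampler is an
adaptive random-walk Metropolis-within-Gibbs with log-scale proposals for
SDs and the ratio and logit-scale proposals for $\alpha$ and $\beta$;
proposal SDs adapt toward a 20–50% acceptance rate during adaptation and
are then frozen, so retained draws come from a fixed kernel. It is
validated against the conjugate closed form for a scale parameter before
being trusted on the real models. The default chain plan (3 chains of
500 adaptation / 500 burn-in / 2000 retained draws) keeps one fit in the
ten-second range; `full_chain_plan()` (1000/1000/10000) is the study-scale
plan. "Retained draws" are unthinned; effective sample sizes are reported
alongside so the resolution is honest.

**Model comparison.** One DIC per fit ($p_D$ = mean deviance minus
deviance at the posterior mean). Models within 7 DIC units of an
observer's best model tie with it; 7 or more above is a poor fit, so the
boundary value is excluded. Group-level inference uses random-effects
Bayesian model selection: a variational Dirichlet scheme over per-observer
model assignments with log evidence approximated by $-\mathrm{DIC}/2$, and
exceedance probabilities estimated from $10^5$ Dirichlet posterior draws.

**Lagged regressions.** Lags count within category ("the k-th most recent
category-A ellipse"), not within the trial sequence; nine lags per
category by default. Rows lacking a 9-deep history in either category are
dropped (about 20 of 600 trials). Regressors are centered on the block
mean orientation — the analyses are translation invariant, and centering
removes the arbitrary block mean without changing lag-weight shape. An
intercept is always included. Covert regressions add the current stimulus
and are logistic; overt regressions are linear on the settings.

**2IFC threshold correction.** The fitted psychometric slope is the SD of
the difference of two noisy measurements, so the default converts to the
per-stimulus sensory SD by dividing by $\sqrt{2}$; a `"half"` convention
(dividing by 2) is available where comparability with that convention is
needed.

**Staircases.** Two 1-up-2-down and two 1-up-3-down staircases of 65
trials each, interleaved uniformly at random, stepping one position on a
25-level log-spaced ladder from 0.25° to 16°. Raw (difference, choice)
pairs are logged and the psychometric function is fit to all of them;
no reversal averaging.

## What the generator does and does not emulate

The simulator reproduces the statistical structure the analyses assume:
Gaussian categories, Bernoulli(0.5) category assignment, Gaussian sensory
and adjustment noise, feedback computed from the logged (noisy) overt
setting, and observer models updating only on post-feedback information.
It does not emulate lapses in the main tasks, reaction times, learning of
the task structure itself, motor dynamics of the mouse adjustment, or any
conservatism bias — so passing tests demonstrate that the pipeline
recovers what it assumes, not that human data obey these models.

## Problem sizes and calibrated tolerances

The test suite runs everything at sizes chosen to keep a full run in the
minutes range while leaving the statistical checks meaningful:

* Convergence check: one 600-trial covert EWMA session, default desk plan,
  all split-chain $\hat R < 1.1$.
* Parameter recovery: 20 replicates per model × task at $n = 600$ with a
  reduced plan (2 chains, 150/150/400) followed by MAP refinement (the MAP
  is optimizer-refined, so it is insensitive to chain length). Tolerances
  were calibrated once by simulation at these conditions and then frozen:
  $\alpha$ and $\beta$ within ±0.12 of the generating 0.3, and noise SDs
  within ±35% of their generating values, required jointly in at least
  90% of replicates.
* Model identification: 10 synthetic EWMA observers, the full static
  covert menu, reduced chains (2 × 150/150/500); the exceedance
  probability must be highest for the EWMA model.
* Psychometric coverage: 200 discrimination experiments generated by the
  task's own interleaved staircases ($n = 260$), parametric bootstrap with
  499 replicates; the nominal 95% interval for the slope must cover the
  generating value 93–97% of the time. Staircases concentrate trials near
  threshold, where the slope is identifiable — with trials spread
  uniformly over the ladder the percentile interval is visibly
  miscalibrated, which is a property of the design, not the estimator.

## A worked example

```{r example, eval = FALSE}
cfg <- experiment_config("static", sigma_v = 6)
sess <- simulate_covert_session("ewma", list(alpha = 0.3), cfg, seed = 1)
fit <- fit_observer_model(sess, "ewma", seed = 1)
tidy(fit)
glance(fit)
autoplot(fit)

# model-free view of the same session
des <- build_lagged_design(sess)
fit_lagged_logistic(des)
```

## Known limitations

* The ideal observer is static-mode only (the dynamic marginalization over
  mean trajectories is intractable) and its fitted variant conditions on a
  category-SD parameter rather than marginalizing it.
* DIC values depend on the warm-up conventions above; comparisons are only
  meaningful between fits sharing them (all fits in this package do).
* Lagged regressions treat wrapped orientations linearly; in dynamic
  sessions whose walk crosses the representable boundary repeatedly the
  overt weights are attenuated near crossings.
* The variational BMS scheme, like the original, assumes independent
  observers and can be overconfident for very small groups.
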
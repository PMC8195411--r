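---
title: "Self-consistent Bayesian observers and post-feedback estimation"
author: "condobs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-consistent Bayesian observers and post-feedback estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condobs)
```

## The task and the model

`condobs` models a two-stage orientation-judgment task. On each trial an
observer views a noisy orientation stimulus at $\theta$ degrees relative to a
reference, first reports whether it is clockwise (cw, positive) or
counter-clockwise (ccw) of the reference, receives fully valid feedback on
that categorical judgment, and then reports an estimate $\hat\theta$ of the
orientation. Two stimulus-noise levels are randomly interleaved. The central
scientific question is what happens on *incorrect* trials: when feedback
forces the observer to abandon their category choice, what do their
estimates reveal about the state of working memory?

The core model is a self-consistent Bayesian observer. The observer receives
a measurement $m \sim N(\theta, \sigma_s)$, with $\sigma_s$ a free parameter
per noise level. The categorical stage evaluates
$$p(m|C) = \int N(m;\theta,\sigma_s)\,p(\theta|C)\,d\theta, \qquad
  p(C|m) \propto p(m|C)\,p(C),$$
and chooses the category with the higher posterior. The stimulus prior
$p(\theta|C)$ is one-sided: constant on a plateau of width $\alpha$ on the
category's side of the reference, then falling to zero over a band of width
$\beta$. We give the roll-off a raised-cosine shape,
$p(\theta|C) \propto \tfrac12\bigl(1 + \cos \pi(|\theta|-\alpha)/\beta\bigr)$,
so the plateau height is $1/(\alpha+\beta/2)$; "cosine roll-off" names a
family, and the raised cosine is our declared choice within it. Since the
decision is a likelihood-ratio threshold rule in $m$, the psychometric
function is $p(\hat C = cw \mid \theta) = 1 - \Phi((m^*-\theta)/\sigma_s)$
where $m^*$ is the root of the posterior log-ratio.

At estimation time the measurement is recalled from working memory with
additional Gaussian noise, $m_m \sim N(m, \sigma_m)$. The defining
self-consistency assumption is that the observer conditions estimation on
their own categorical commitment as if it were fact: the estimate is the
mean (squared-error loss) of the posterior
$$p(\theta|m_m,\hat C) \propto N(m_m;\theta,\sigma_{like})\,p(\theta|\hat C),
  \qquad \sigma_{like} = \sqrt{\sigma_s^2+\sigma_m^2}.$$
The likelihood width follows the generative chain (measurement noise plus
memory noise); this produces the characteristic repulsion of estimates away
from the reference, strongest near it and for high noise. A Gaussian motor
kernel of width $\sigma_0$ — measured independently per subject, never
fitted — is convolved onto every predicted estimate distribution.

## The five incorrect-trial variants

On correct trials all variants coincide with the self-consistent rule
conditioned on the (correct) choice. They differ in what happens after
negative feedback:

* **Model 1a (prior only).** If the categorical commitment overwrote memory,
  nothing usable remains after the flip; the estimate is the mean of the
  feedback side's prior. Predicted distributions are Gaussian
  (motor noise only) and identical across noise levels.
* **Model 1b (uncertainty only).** The observer retains only the trial's
  noise level and points $\sigma_s$ degrees onto the feedback side. A
  deliberate heuristic, not a Bayesian rule.
* **Model 2a (flip decision).** Memory is intact; the observer simply
  re-runs conditioned estimation with the feedback-corrected category. The
  estimate is computed from the *tail* of the likelihood (the measurement
  itself sits on the wrong side), which makes the mean nearly independent of
  $\theta$.
* **Model 2b (resampled).** Like 2a, but memory recall is itself conditioned
  on feedback: proposals from $N(m, \sqrt{\sigma_s^2+\sigma_m^2})$ are drawn
  until one lands on the feedback side (rejection sampling; the draw count
  is kept as a response-time proxy). In grid predictions the sampler is
  replaced by the exactly equivalent truncated Gaussian. Because the peak,
  not the tail, of the recalled likelihood now sits on the correct side, 2b
  is more repulsed than 2a everywhere.
* **Model 2c (reweighted).** Surprise about the negative feedback reduces
  trust in the sensory evidence. Surprise is the symmetrized KL divergence
  between the decision posterior and its flip,
  $KL = (2q-1)\ln\frac{q}{1-q}$ with $q = p(\hat C|m)$, and the sensory
  width is scaled to $\sigma_s' = (1+KL)\,\sigma_s$ before the combined
  likelihood width is formed. We adopt the linear scaling as the package's
  definition; a square-root form would only compress the same monotone
  effect. Surprise is a function of $m$, so inside predictive integrals the
  reweighted width varies across the measurement region — largest for
  measurements far from the criterion, which happen disproportionately when
  $\theta$ is close to the reference.

Predictive distributions condition on the trial outcome: the measurement
integral is restricted to the decision region producing the required choice
and renormalized, pushed through the variant's recall and estimation rules,
convolved with the motor kernel, and integrated over estimate bins of 0.5
degrees.

## Fitting and model comparison

Parameters $\rho = (\sigma_{s,low}, \sigma_{s,high}, \sigma_m, \alpha_{cw},
\alpha_{ccw}, \beta, p_{cw})$ are fitted jointly to the categorical choices
of *all* trials (Bernoulli terms from the psychometric function) and the
binned estimates of *correct* trials only, by Nelder–Mead on log-transformed
parameters (logit for $p_{cw}$) from 30 random restarts (10 in the reduced
test configurations). In symmetric-range mode $p_{cw} = 0.5$ and a single
$\alpha$ are fixed. Incorrect-trial predictions then use these parameters
unchanged — the comparison is parameter-free by construction.

Each variant is scored by the log probability of each incorrect-trial
estimate's 0.5-degree bin (probability floor $10^{-6}$). Scores are anchored
between Model 1a and an omniscient bound — the empirical bin frequencies of
the data themselves, in-sample, which maximize the attainable likelihood per
condition:
$$\text{score} = \frac{LL_{model} - LL_{1a}}{LL_{omni} - LL_{1a}}.$$
Confidence intervals come from 200 stratified bootstrap resamples (within
condition, so sparse large-$|\theta|$ cells are never lost); paired
contrasts bootstrap the per-table log-likelihood difference. The omniscient
bound conditions on (orientation, noise, category) — the same conditioning
the models use — so it is an upper bound cell by cell; at the reference
orientation this splits the randomly assigned categories rather than pooling
them.

## The synthetic-data generator

`build_design()` reproduces the two designs: a symmetric range
($-21\ldots21$ in steps of 3, $\sigma_s$ conditions 3 and 18) and an
asymmetric one ($-12\ldots0$ by 2 and $0\ldots30$ by 5, conditions 6
and 18), 70 repetitions per (orientation, noise) cell — 2100 and 1820
trials. `simulate_subject()` runs the generative chain forward (measurement,
threshold decision, valid feedback, plain or feedback-truncated recall,
posterior-mean estimate, motor noise); at $\theta = 0$ the correct category
is a fair coin. A lapse parameter (default 0) replaces estimates with
uniform draws to exercise the consistency filter: trials whose estimate sign
contradicts the feedback-corrected category are excluded, as in the
experimental analysis. Note that with motor noise present a small fraction
of ordinary trials (a few tenths of a percent) also trips this filter —
sign flips near the reference — so a zero exclusion rate is only guaranteed
when $\sigma_0 = 0$.

What the generator does *not* emulate: the line-array rendering of the
stimulus (the array's sample-mean vs generative-mean distinction is absorbed
into $\sigma_s$), reference randomization on screen (all quantities are
reference-relative), session structure, training, and response times beyond
the resampling draw-count proxy. Passing tests therefore certify the
inference machinery on data that match the model's own assumptions, not
robustness to the many ways real subjects deviate from them.

## Numerical choices

* **Grid.** $\theta$, $m$ and $m_m$ share a uniform grid, default step 0.2
  degrees, bounds at least $\pm 90$ and always covering the prior support
  plus $4\sigma$ (`default_grid()`). Integrals are trapezoid sums; density
  jumps (the prior edges) take the midpoint value at the discontinuity,
  which restores second-order accuracy. Halving the step moves predicted
  means by well under 0.05 degrees; fitting uses a 0.5-degree grid for
  speed.
* **Kernels.** Gaussian transitions between on-grid variables are Toeplitz
  and assembled by indexing one vector of density values; the off-grid
  decision-criterion node is carried as an explicit extra quadrature point
  so decision regions are cut exactly at $m^*$, not at the nearest node.
* **Binning.** Motor convolution is exact per support point via the Gaussian
  CDF, using a lookup table of $\Phi$ with linear interpolation (absolute
  error below $10^{-8}$). Bin edges sit at integer multiples of 0.5 degrees.
* **Model 2c.** The measurement-dependent likelihood width is quantized to
  41 levels across its range within the decision region; support points are
  merged at 0.02-degree resolution before binning. Both approximations are
  an order of magnitude below the Monte-Carlo tolerance used to validate the
  distributions.
* **Degenerate inputs.** Posterior means fall back to a shifted log-domain
  evaluation when dense weights underflow, and never return `NaN`; decision
  ties (posterior exactly 0.5 within $10^{-12}$) are broken by a fair coin,
  mirroring the random category assignment at the reference; resampling
  acceptance probabilities are computed from the accurate Gaussian tail so
  far-side components cannot divide by zero; conditions whose outcome
  probability is below $10^{-12}$ raise an explicit empty-condition error.
* **Optimization.** Restart initial values are log-uniform inside the
  bounds ($\sigma_s \in [0.5, 40]$, $\sigma_m \in [0.01, 20]$,
  $\alpha \in [5, 60]$, $\beta \in [0.5, 40]$, $p_{cw} \in [0.05, 0.95]$).
  The simplex runs at a relative function tolerance of $10^{-7}$ — at
  joint negative log likelihoods of a few thousand nats this is roughly a
  millinat of absolute slack; looser settings demonstrably stall with the
  memory-noise parameter still drifting — and the best restart is polished
  at $10^{-9}$. Out-of-bounds proposals are rejected by a graded penalty on
  the natural scale. Fits are deterministic given the configuration seed.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on full-size single subjects (2100 / 1820
trials). The oracle-equivalence tests compare every variant, noise level and
five orientations against $10^5$-trial forward simulations written
independently of the grid code (own grid, own prior construction,
inverse-CDF truncated sampling). Parameter recovery uses five
symmetric-range subjects at full trial counts with 10 restarts, and one
asymmetric-range subject for the category-prior check. The acceptance script
reproduces the pipeline end to end at a reduced cohort size (three
symmetric-range subjects generated by the resampling variant plus one
asymmetric-range subject, 30 repetitions per condition) and reports recovery
errors, normalized scores, exclusion rates and the cw/ccw asymmetry.

## Known limitations

* Orientation is treated as linear, not circular; valid because every
  support in these designs lies within $\pm 60$ degrees of the reference.
* $\beta$ is shared across sides and weakly identified; its fitted value
  should be read as a nuisance smoothness, and prior width comparisons
  should rely on $\alpha$ (or $\alpha + \beta/2$, the effective mass width).
* The omniscient bound is in-sample and therefore optimistic; normalized
  scores are comparisons against a ceiling, not goodness-of-fit tests.
* Model 1b's rank among the variants depends strongly on the generating
  parameters of synthetic data (its prediction is a single point blurred by
  motor noise); only the 2b-versus-2a repulsion ordering and the anchors are
  stable properties.
* No lapse parameter is fitted; inconsistent trials are excluded instead,
  matching the analysis the models are meant to reproduce.
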
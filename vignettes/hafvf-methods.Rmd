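---
title: "Adaptive forgetting and diffusion decisions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive forgetting and diffusion decisions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafvf)
```

## The learning problem

An agent in a volatile environment must decide, on every observation,
whether a surprising outcome is noise (and should barely move its beliefs)
or a genuine change of contingency (and should trigger forgetting and
relearning). Classical reinforcement learning fixes or schedules the
learning rate and therefore cannot make this distinction; a Bayesian
learner with a plain conjugate filter accumulates evidence forever and
becomes unable to adapt.

The critic implemented here solves this with *stabilized forgetting*: the
prior for trial $j$ is an exponentially weighted mixture of the previous
posterior and a fixed naive prior,

$$p(z \mid x_{<j}) \propto q_{j-1}(z)^{w}\, p(z \mid \theta_0)^{1-w},$$

where $w \in [0,1]$ is the forgetting factor: $w \to 1$ keeps memory,
$w \to 0$ resets the agent to its naive state. Because both components are
Normal-Inverse-Gamma (NIG) distributions over the mean and variance of the
reward, the normalized mixture is again NIG with natural parameters
$w\,\eta_{j-1} + (1-w)\,\eta_0$, and its log normalizing constant has the
closed form

$$\log Z(w) = A\!\big(w\eta_{j-1} + (1-w)\eta_0\big) - w A(\eta_{j-1})
  - (1-w) A(\eta_0),$$

with $A$ the NIG log-partition function. By convexity of $A$,
$\log Z \le 0$, so the mixture acts as an automatic Occam factor on $w$.

The forgetting factor itself carries a Beta belief that is learned from
the data, and — the distinctive feature of this model — that belief is in
turn subject to forgetting through a second-level factor $b$ with its own
Beta belief. The three-level hierarchy lets the agent learn not only the
contingency but also how stable the contingency, and the stability itself,
have been.

## Variational updates

The posterior is approximated by a mean-field product
$q(z)\,q(w)\,q(b)$ with NIG and Beta factors. Per trial the package
cycles:

1. **Reward belief** (conjugate): the NIG update under the weighted prior,
   with $\hat w = E_q[w]$,
   $$\kappa_j = \hat w \kappa_{j-1} + (1-\hat w)\kappa_0 + 1, \qquad
   \mu_j = \frac{\hat w \kappa_{j-1} \mu_{j-1} + (1-\hat w)\kappa_0\mu_0 +
   x_j}{\kappa_j},$$
   and the matching shape/rate updates
   ($\alpha_j = \hat w\alpha_{j-1} + (1-\hat w)\alpha_0 + \tfrac12$, with
   the three-term squared-deviation update for $\beta_j$).
2. **Forgetting beliefs** (non-conjugate): the Beta factors over $w$ and
   $b$ are updated by non-conjugate variational message passing (NCVMP):
   the new natural parameters are $\mathrm{Cov}_q(T)^{-1}\nabla_\lambda S$,
   where $S$ collects the terms of the expected log-joint that involve the
   factor. Terms linear in the mean parameters reproduce conjugate updates
   exactly; the nonlinear terms ($\hat w$-weighted evidence and the
   expected mixture log-normalizer) make the update a fixed-point
   iteration. Expectations of $\log Z(w)$ under a Beta belief have no
   closed form and are replaced by a second-order Taylor expansion around
   $\hat w$; the required $d^2 \log Z / d w^2$ is evaluated analytically
   along the straight line in natural-parameter space (an earlier
   finite-difference version amplified rounding noise catastrophically
   once differentiated again inside NCVMP).

The sweep repeats until the per-trial evidence lower bound (ELBO) changes
by less than `tol` ($10^{-3}$ by default), with a hard cap of 50 sweeps
and damping 0.8 on the NCVMP steps (NCVMP convergence is not guaranteed in
general; damping trades speed for reliability). Setting `tol = 0` runs a
fixed number of sweeps instead, which keeps the trajectory an exactly
smooth function of the prior parameters — this mode is used whenever the
filter is differentiated numerically (gradient checks, MAP fitting,
Laplace Hessians), because the adaptive early exit introduces
$O(\mathrm{tol})$ kinks that dominate finite-difference second
derivatives.

The per-trial ELBO is reported as a model-fit score. It contains the
expected log-likelihood of the observation, the forgetting-weighted prior
cross-entropies at all three levels (with the Taylor-approximated expected
log-normalizers), and the entropies of the three factors. Under a
stationary stream it approaches the log predictive density of the data,
which is why the session average discriminates between prior
configurations.

**A calibration note.** The NCVMP fixed point was verified against a
brute-force grid search over the Beta parameters of $q(w)$ maximizing the
same objective (quadrature for the expected log-normalizer): the fixed
point lands within one grid cell of the argmax. A collapsed variant that
replaces the mean-field evidence term with the exact NIG predictive
likelihood of the trial was also implemented and gives the same long-run
behaviour. Both formulations equilibrate, in a stationary stream, at an
efficient memory of roughly 10–15 trials under the long-memory prior
used in the flexibility study; configurations that consolidate
substantially further are not reachable by either formulation, which
bounds how badly the long-memory agents can be hurt by a late contingency
change (see the package tests for the quantitative consequences).

## Memory diagnostics

The *effective memory* is the pseudo-observation count $\kappa_j$; the
*efficient memory* is its asymptotic ceiling $E_q[1/(1-w)]$, computed
exactly as $(a+b-1)/(b-1)$ when the Beta parameter $b > 1$ and by the
first-order fallback $1/(1-E[w])$ otherwise. Because $\kappa_j$ tracks a
lagged geometric average of past forgetting factors, the ceiling holds in
running-maximum form, $\kappa_j \le \kappa_0 + \max_{i\le j}
\mathrm{eff}_i + 1$, which is what the test suite asserts.

## Counterfactual updating

For actions not selected on a trial, the *continuous* scheme (the default
in simulations) applies the conjugate update with the observation replaced
by the weighted-prior predictive mean and the squared residual by its
expectation under the current belief. The posterior mean therefore stays
exactly at the trial's prior mean, while $\kappa$ and the variance belief
relax toward the naive prior at rate $\hat w$: uncertainty about unchosen
options grows, which feeds exploration. The *delayed* alternative leaves
unchosen beliefs untouched and applies a geometric discount $w^{n}$ at the
next selection after a lag of $n$ trials (`delayed_prior()`).

No closed-form reference algebra was available for the counterfactual and
discount-factor messages; both schemes were constructed from their
required observable behaviour (mean preservation, variance growth toward
the prior, discount belief pulled to its prior when $w$ drops) and are
tested against those properties.

## Temporal-difference learning

For multi-stage tasks the effective observation of the chosen state-action
is $r + E[\gamma]\,V(s')$, with $V(s')$ the Dirichlet($\pi_0$)-smoothed,
action-frequency-weighted mean of the next state's posteriors
($\pi_0 = 5$ limits the impact of early choices). The discount factor
$\gamma$ carries a Beta belief updated by NCVMP against the expected
log-likelihood of the bootstrapped observation; its forgetting weight is
inherited from the chosen action's first-level $\hat w$, so a contingency
change that collapses $w$ also releases $\gamma$ toward its prior
(`Beta(9, 1)` by default, discouraging myopic strategies). In the
multi-stage experiments the unchosen state-actions use delayed rather than
continuous updating: with visit frequencies around one in ten, continuous
relaxation would erase unvisited beliefs faster than they can be refreshed.

The two five-state tasks are encoded as explicit intended-transition
tables (left/right actions, 90% intended transition, 10% spread evenly
over the other states, reward 5 on each arrival in the rewarded state,
continuing task). The first contingency rewards state 5 via left actions
in states 3–4–5; after the midpoint switch the deep-change variant moves
the reward to state 2 (optimal: right in 1–4–2) while the shallow-change
variant keeps state 5 rewarded with left in 1–3–5, so part of the old
policy stays valid.

## The actor

Decisions are made by racing the two candidate actions: per trial the
agent samples $\tilde\sigma_i^2 \sim IG(\alpha_i, \beta_i)$ and
$\tilde\mu_i \sim N(\mu_i, \tilde\sigma_i^2/\kappa_i)$ from its posteriors
and runs a Wiener process with drift $\tilde\mu_1 - \tilde\mu_2$ and
diffusion variance $\tilde\sigma_1^2 + \tilde\sigma_2^2$ from $z_0$
(default $\zeta/2$) to absorbing bounds at $0$ and $\zeta$. The absorption
probability has the standard closed form; first-passage densities use the
small-time/large-time series with the usual switching rule, evaluated in
compiled code. Parameters are drawn once per trial (not per time step),
matching the state-space model used for fitting. As the threshold grows
the race's choice rule converges to Q-value sampling
($P(\tilde\mu_1 > \tilde\mu_2)$, Thompson-like); with more than two
actions the package selects by a single joint posterior draw rather than a
race tournament.

Numerical choices: simulation uses an Euler discretization with
`dt = 1e-3` by default plus a Brownian-bridge within-step crossing
correction (without it, discretization bias is visible to a
Kolmogorov-Smirnov test at $10^5$ trials); likelihoods always use the
analytic density, never the Euler path. Bulk data generation samples
choices from the analytic absorption probability and reaction times by
inverse-CDF sampling of the analytic density.

## Fitting

Fitting treats the critic trajectory as a deterministic state-space
transition: given priors and the observed rewards/choices,
`forward_filter()` reproduces the exact beliefs the actor acted from. The
per-trial likelihood of `(choice, rt)` marginalizes the trial latents
$\chi = (\xi, \lambda^{-1}(\sigma_1^2), \lambda^{-1}(\sigma_2^2))$
($\lambda$ = softplus, chosen for its bounded gradient; the ELBO receives
the log-Jacobian $-\log(1+e^{-x})$ for the transformed variances). The
marginal is lower-bounded by amortized variational inference: a one-hidden
-layer (32 tanh units) inference network maps the nine per-trial features
(rt, choice sign, mean difference, the two $\kappa$, $\alpha$, $\beta$) to
the mean and Cholesky factor of a Gaussian over $\chi$, and the bound is
estimated with 8 reparameterized samples per trial. The network is warm
-started by regressing its outputs onto the per-trial prior moments, so
optimisation begins from a prior-matched posterior.

MAP optimisation follows the stochastic scheme of the original algorithm:
Adam with step size 0.005, $\beta_1 = 0.9$, $\beta_2 = 0.99$, the step
size divided by $\lceil i/1000 \rceil$, an annealing jitter with variance
$1/i$ applied to all parameters each iteration, and an L2 penalty
(standard normal prior in the unbounded space) on every parameter.
Gradients combine hand-coded backpropagation through the network with
central differences for the Wiener density's dependence on the latents and
the three subject-level diffusion parameters (there is no general-purpose
automatic differentiation available to the package, so the Hessians used
for Laplace evidence are central differences as well). The threshold is
parameterized through the softplus, the start point as a logistic bias on
$z_0/\zeta$ (this also hosts the start-point scatter of the simulated
population, whose generating distribution is only loosely specified), and
the non-decision time as a logistic fraction of the smallest observed
reaction time.

For signal-only fits (the square-wave benchmark) the likelihood is the
session-total per-trial ELBO, the parameters are the eight priors in the
unbounded space under the same standard normal hyperprior, and the
optimiser is BFGS rather than Adam: the objective is deterministic and
eight-dimensional, so a quasi-Newton method reaches the mode in seconds
and multi-start probes from long-memory, short-memory and tight-variance
configurations all land on the same mode. The Laplace evidence is
$\log p(\hat\theta) + \tfrac{M}{2}\log 2\pi - \tfrac12 \log\det(-H)$.

## The synthetic studies

All generators are pure functions of their seed. The study conditions
follow the published simulation designs:

* **Square wave**: two periods of 200 trials alternating $N(1, 0.33)$ and
  $N(-1, 0.33)$ (0.33 read as a standard deviation), optionally followed
  by 1200 trials at level 5.
* **Flexibility experiments**: four agents (long/short memory at each
  level: Beta(4.5, 0.5) vs Beta(0.5, 4.5), reward prior $\mu_0 = 0,
  \kappa_0 = 0.1, \alpha_0 = 1, \beta_0 = 1$). Experiment 1 switches the
  mean from $+3$ to $-3$ (sd 1) after 900 (dataset 1) or 100 (dataset 2)
  trials; experiment 2 inserts a single $-3$ observation at the same
  points. Sessions are 1000 trials in both variants (the source states
  only the training lengths; equal totals make the two datasets
  comparable trial-for-trial).
* **Bandit fitting study**: arm 1 pays 0/+2/−2 with changes at trials 500
  and 600; arm 2 is the reversed-order, opposite-sign schedule (+2/−2/0,
  changes at 400 and 500), sd 1 for both. Subject parameters scatter
  around a reference near-optimal configuration with an inverse-Wishart
  covariance (scale diag(1, ..., 1, 0.1); degrees of freedom $d+2$ for
  propriety of the 11-dimensional draw) and subjects below 70% accuracy
  are rejected and resampled. Locating the exact optimum by stochastic
  optimisation is not reproduced; parameter-recovery studies simulate from
  known parameters directly.
* **Multi-stage study**: priors $\mu_0 = 0, \kappa_0 = 0.5, \alpha_0 = 3,
  \beta_0 = 0.5$, flat forgetting priors, $\gamma \sim$ Beta(9, 1),
  $\pi_0 = 5$; 1000 trials with the contingency switch at the midpoint.

What the generators do *not* emulate: real reaction-time data contain
contaminant responses, lapses and slow drifts of attention none of which
are modelled; reward noise is exactly Gaussian and change points exactly
instantaneous. Passing tests therefore demonstrate internal consistency
of the implementation and reproducibility of the simulation claims, not
validity on empirical data.

## Problem sizes used by the test suite

The checked studies run at the sizes stated in the published designs
wherever those sizes are explicit (20 signal seeds for the score table,
10 seeds for the square-wave evidence, $10^5$ trials at `dt = 1e-4` for
the reaction-time distribution check). The parameter-recovery study runs
at 8 subjects × 300 trials — a deliberately scaled-down analogue of the
64-subject study, sized so the whole suite stays interactive; the
correlation thresholds it asserts (r > 0.8) are correspondingly
conservative. The multi-stage check uses 16 agents and 500 trials.

## Known limitations

* The exact NCVMP message algebra of the original derivation was not
  available; the ELBO-gradient formulation used here is validated against
  a grid-search oracle, but its stationary consolidation ceiling
  (efficient memory ~10–15 trials under the long-memory prior) is lower
  than what two of the published long-training score-table cells imply.
  The package reports what its own machinery computes.
* The value-of-perfect-information exploration bonus is not implemented
  (only the Q-sampling/diffusion policy is).
* The hierarchical filter handles univariate Gaussian rewards; multivariate
  rewards and learned state-transition tables are out of scope.
* Laplace evidence relies on finite-difference Hessians; for more than a
  few dozen parameters this is the dominant cost.

## A worked trace

```{r example, fig.width = 7, fig.height = 5, eval = requireNamespace("ggplot2", quietly = TRUE)}
sig <- gen_cc_experiment("long", seed = 1)
tr <- hafvf_filter(sig$r, flexibility_priors("LS"))
glance(tr)
autoplot(tr)
```
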
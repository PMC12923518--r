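---
title: "Models and methods behind costlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind costlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`costlearn` implements the complete computational analysis of a loss-frame
probabilistic learning experiment: a two-context card task in which every
choice can only lose money, a family of trial-by-trial learning models fit to
each participant's choices, random-effects model selection, and the
behavioural and parameter regressions that relate task behaviour to
substance-use severity. This vignette documents the models, the default
settings and why they were chosen, the numerical decisions, and what the
synthetic-data machinery can and cannot establish.

## The task

On each of 200 trials the participant chooses between two cards with
displayed loss magnitudes drawn independently and uniformly on $1–$5; the
incorrect card loses its displayed amount, the correct card loses nothing.
One hundred contiguous trials form a *stable* context (one card loses with
probability 0.75 throughout, the other 0.25); the other hundred form a
*volatile* context (0.80/0.20, with the assignment reversing after every 25
trials). Context order is randomised across participants.
`generate_schedule()` reproduces this structure exactly; which card starts as
the high-loss card is randomised per schedule because the design gives no
counterbalancing rule, and the correct card is drawn independently per trial
from the stated probability, with no run-length constraints.

Magnitudes are modelled as *continuous* uniform draws, rounded to whole
dollars only for on-screen display. This is the reading of "randomized
between \$1 and \$5" consistent with the observed per-participant frequencies
of small and large magnitude differences (69–101 trials with $|\Delta| \le
\$1$ and 6–25 trials with $|\Delta| \ge \$3$ out of 200): independent
continuous draws give analytic means of $200 \cdot 7/16 = 87.5$ and
$200 \cdot 1/16 = 12.5$, inside those ranges, whereas independent
*integer*-uniform draws give means of about 104 and 48, far outside them.
Payoffs use the raw (unrounded) values; whether the original task rounded
before computing payoffs is unknowable from the description, and the
difference is immaterial for every analysis in the package.

## Learning models

Six candidate models couple a perceptual (learning) model of the reference
card's loss probability with a common softmax observation model. Outcomes
are coded on card 1: $u_t = 1$ when card 1 loses on trial $t$ (fully
observable from either card's feedback, because exactly one card is correct
per trial).

**Rescorla–Wagner** (`rw`): $v_{t+1} = v_t + \alpha(u_t - v_t)$ with learning
rate $\alpha \in (0,1)$.

**Sutton K1** (`k1`): a delta rule whose log learning rate $b_t$ adapts
through the recent correlation of prediction errors,
$b_t = b_{t-1} + \mu\,\delta_t h_{t-1}$, learning rate
$\min(1, e^{b_t})$, and gain trace
$h_t = h_{t-1}\max(0, 1-\alpha_t) + \alpha_t\delta_t$. The cap at 1 keeps
the tracked probability in $[0,1]$; $b$ is clamped to $\pm 20$ purely as an
overflow guard.

**Two-level HGF** (`hgf2`, `hgf2_loss`): the canonical binary Hierarchical
Gaussian Filter step,
$$\hat{s}_t = \text{logistic}(\mu_{2,t-1}), \qquad
\hat\sigma_2 = \sigma_{2,t-1} + e^{\omega},$$
$$\pi_2 = \hat\sigma_2^{-1} + \hat{s}_t(1-\hat{s}_t), \qquad
\mu_{2,t} = \mu_{2,t-1} + \pi_2^{-1}(u_t - \hat{s}_t), \qquad
\sigma_{2,t} = \pi_2^{-1}.$$
The volatility parameter $\omega$ sets the speed of belief updating. The
trajectory records the outcome prediction error $\delta_1 = u_t - \hat s_t$,
the uncertainty $\sigma_2$, and the precision-weighted prediction error
$\varepsilon_2 = \pi_2^{-1}\delta_1$ (a derived quantity, not a parameter).

**Three-level HGF** (`hgf3`, `hgf3_loss`): as above with effective
log-volatility $\kappa\mu_3 + \omega$ at level 2 and a Gaussian level-3
update of $(\mu_3, \sigma_3)$ driven by the level-2 volatility prediction
error with step variance $\vartheta$. The coupling $\kappa$ is fixed at 1 by
default (the toolbox convention for binary inputs); it can be freed through
the prior table. Parameter regimes that drive the level-3 precision
non-positive are rejected with an explicit invalid-trajectory signal, which
the fitter treats as an invalid candidate — the behaviour, not a silent NaN,
is the contract.

Initial states are fixed, not fitted: $v_0 = 0.5$, $\mu_2 = 0$ (so the first
prediction is 0.5), $\sigma_2 = 1$, $\mu_3 = 1$, $\sigma_3 = 1$ — a neutral
prior belief.

## Observation model

Beliefs and displayed magnitudes map to choice through expected loss
utilities and a softmax:
$$v^{(1)} = -\hat{s}\,m_1^{\rho}, \qquad v^{(2)} = -(1-\hat{s})\,m_2^{\rho},
\qquad P(\text{choose 1}) = \text{logistic}\big(\beta(v^{(1)} - v^{(2)})\big).$$
Inverse temperature $\beta \ge 0$ measures how consistently the better
expected value is chosen; loss sensitivity $\rho > 0$ measures how strongly
the dollar amounts weigh on choice. $\rho$ enters as a *power* on magnitude
rather than a multiplicative weight: in a two-option loss-only softmax a
multiplicative weight is exactly collinear with $\beta$ (only their product
would be identifiable), while the power form leaves the two parameters
separately identifiable and preserves the interpretation that higher $\rho$
means greater magnitude sensitivity. One parameter set covers all 200 trials
(one $\omega, \beta, \rho$ per subject, not per context), and the
log-likelihood clamps choice probabilities away from 0/1 at machine epsilon
so it is always finite for a valid trajectory.

## Fitting, evidence, model selection

`fit_map()` maximises log-likelihood plus log-prior on unconstrained
parameter scales (logit for $\alpha$; log for $\beta$, $\rho$, $\kappa$,
$\vartheta$, the K1 meta-rate; identity for $\omega$) with BFGS from the
prior mean plus jittered restarts (jitter SD = one prior SD; restart sets are
nested under a fixed seed, so more restarts can only improve the best
penalised objective). Default priors are weakly informative Gaussians:
$\omega \sim N(-3, 16)$, $\log\beta \sim N(0, 4)$, $\log\rho \sim N(0, 1)$,
$\text{logit}\,\alpha \sim N(0,4)$, K1 $\log\mu \sim N(-2,4)$ and
$b_0 \sim N(-2.3, 4)$, $\log\vartheta \sim N(-6, 16)$. These are typical
toolbox defaults for binary tasks; they live in an ordinary data frame
(`default_priors()`) precisely so that study-specific values can be dropped
in without touching code.

Log model evidence uses the Laplace approximation at the mode,
$\log p(y) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H$, with $H$ the numerical Hessian of the negative log
joint. A non-positive-definite Hessian is ridge-regularised; if that fails
the code falls back to a BIC-style approximation and flags the fit — fits
are never silently dropped. A useful internal check: a parameter pinned by a
near-delta prior contributes nothing to the evidence (its Occam term cancels
against its prior height), so nested models score identically, which the
test suite asserts numerically.

`bms()` implements random-effects Bayesian model selection: model identity
is a population-level random effect with Dirichlet prior (concentration 1
per model), per-subject assignment posteriors and Dirichlet counts are
iterated to convergence ($\max|\Delta\alpha| < 10^{-4}$), and exceedance
probabilities — the probability that a model is the most frequent in the
population — come from $10^5$ seeded Dirichlet draws.

**Winsorization.** Subject-level inverse-temperature estimates are
right-skewed, and the analysis convention is to winsorize *extreme* outliers
— values above $Q_3 + 3\,\text{IQR}$ with linear-interpolation (type-7)
quartiles — to the maximum non-extreme value plus one SD of the non-extreme
values, before taking logs. Only the upper tail is treated, the operation is
idempotent, and a report of original and replacement values is returned.
With very small samples a single enormous outlier can inflate $Q_3$ enough
to mask itself (a generic weakness of fence rules at $n \approx 4$, worth
knowing about, not worth a special case).

## Behavioural regressions

`build_stay_table()` codes, per analysable trial, whether the subject
repeated the previous choice, the previous trial's outcome (avoided =
reference level, so the previous-outcome coefficient contrasts incurred vs
avoided), the context (stable = reference), and the chosen-minus-unchosen
magnitude difference on the current trial (mean-centered once over the
pooled analysable rows). The first trial of the session *and* the first
trial of the second context block are excluded: the design is silent on
lagging across the boundary, and a within-block lag is the only coding that
never crosses a contingency regime the participant has not yet seen. A
complete subject therefore contributes 198 rows.

`fit_mixed_logistic()` fits the two random-intercept logistic models via
lme4's Laplace approximation, and the test suite validates it against a
brute-force numerical-integration fit of the marginal likelihood on a tiny
instance. `simple_slopes()` computes conditional slopes as linear
combinations of coefficients with delta-method SEs, handling any interaction
order; continuous moderators are probed at ±1 SD by convention, binary ones
at their two coded levels. `fit_parameter_regression()` runs the OLS models
`parameter ~ asix_z + randomization + age_c` for volatility, log inverse
temperature (winsorized upstream) and log loss sensitivity.

Severity scoring (`score_asix()`) sums years of regular use (three or more
times weekly) across substances, then square-root transforms and z-scores
across the cohort — in that order, which matters because the sum has a point
mass at zero and a long right tail.

## Synthetic cohorts

`generate_cohort()` stands in for the study sample. Defaults, fixed once:

* 137 subjects; 25% with zero years of regular use (point mass), the rest
  Gamma(shape 1.5, scale 8) years — a right-skewed distribution with mean
  12 years, matching a community sample in which 75% report regular use of
  at least one substance;
* age Normal(35, 10) truncated to 18–65; context order randomised 50/50;
* generative parameters on unconstrained scales:
  $\omega \sim N(-3, 1.5^2)$, $\log\beta \sim N(0.5, 1^2)$,
  $\log\rho \sim N(0, 0.5^2)$, dispersed enough that recovery is a
  meaningful test;
* one covariate link: $\log\beta$ decreases by 0.3 per z unit of transformed
  severity — the direction and rough size of the one robust severity effect
  in this literature — with null links on $\omega$ and $\log\rho$.

Gaussian noise is added on the *unconstrained* scale so native-scale
constraints hold automatically. True parameters are stored alongside the
covariates for recovery checks.

What passing recovery tests on these cohorts shows: the estimation pipeline
can recover dispersed parameters (correlations of about 0.96 for $\log\beta$
and 0.88 for $\omega$ at $n = 100$), selects the generating model family,
and propagates a planted severity link through simulate → fit → regression
with the correct signs (including the induced *positive* previous-outcome ×
severity interaction on staying: noisier choosers stay less after avoided
losses). What it does not show: real participants' choices contain
perseveration, lapses, side biases and non-stationarities that no candidate
model generates; recovery on synthetic agents is a necessary, not a
sufficient, validation for real data.

## Power simulation

`power_simulation()` estimates power for the previous-outcome × severity
interaction in the individual-differences stay/shift model by simulating
cohorts directly from that model's data-generating process (137 subjects ×
198 analysable rows), fitting the model as analysed, and counting Wald
rejections. Nuisance defaults (`power_nuisance()`): fixed effects at
magnitudes like the basic-task estimates (previous outcome −0.67, context
−0.10, their interaction 0.12, severity −0.23, context × severity 0.08,
three-way 0), random-intercept SD 0.8, and a random *previous-outcome slope*
with SD 0.6 — about 0.9 times the fixed previous-outcome effect. The slope
component is the load-bearing choice: power for a cross-level interaction
(within-subject effect × between-subject covariate) is governed by
between-subject variation in the within-subject effect, and with ~200 trials
per subject a generative model containing only a random intercept would put
power for any detectable interaction at essentially 1, making the analysis
vacuous. Moderate slope heterogeneity is also what agent-based simulation of
this task produces, since subjects differ in their learning and choice
parameters. The *fitted* model remains the random-intercept specification
exactly as analysed. Under these defaults, 200 replicates at effect size
0.17 and $n = 137$ give power in the mid-90s percent range.

The default fitting engine inside the power loop is lme4 with `nAGQ = 0`
(penalised least squares without the final adaptive quadrature step): at
this problem size its estimates and Wald statistics are nearly identical to
the full Laplace fit while being an order of magnitude faster, which is what
makes hundreds of replicates practical. User-facing fits default to
`nAGQ = 1`.

## Numerical choices and problem sizes

* Optimiser: BFGS, objective tolerance $10^{-6}$, 10 restarts by default;
  recovery studies in the test suite use 3 restarts, which suffices for
  these unimodal-in-practice posteriors at 200 trials.
* Likelihood clamping at machine epsilon; diverging trajectories return an
  invalid-candidate sentinel rather than an error inside the optimiser.
* BMS convergence at $\max|\Delta\alpha| < 10^{-4}$; exceedance from $10^5$
  Dirichlet draws.
* Test-suite problem sizes: parameter recovery at 100 subjects, model
  recovery at 50 subjects × 6 models, end-to-end sign recovery at 137
  subjects, power at 200 replicates — sizes at which every gate is stable
  under reseeding while the whole suite runs in minutes on one core.
* All randomness flows through named integer seeds; cohort generation,
  fitting, BMS and the pipeline are bit-reproducible given the same seed.

## Known limitations

* The exact utility equation of the original observation model (how $\rho$
  and magnitudes combine) and the study's prior table are not recoverable
  from the main text; the power form and the defaults above are this
  package's own, documented, substitutable choices.
* Protected exceedance probabilities, hierarchical prior re-estimation and
  MCMC posteriors are out of scope; the Laplace evidence is a local
  approximation and can misrank models whose posteriors are strongly
  non-Gaussian.
* The K1 implementation caps the learning rate at 1; sequences engineered
  to push the gain far beyond that bound are represented at the cap.
* Power results are conditional on the declared nuisance defaults; the
  random-slope SD is the single most influential setting and should be
  varied in any serious design analysis (`power_nuisance()` exposes it).
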
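---
title: "Models and methods: reversal learning and social attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: reversal learning and social attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the design choices
behind them, and what the shipped validation machinery does and does not
establish.

## The two paradigms

**Probabilistic reversal learning.** Sixty trials, three symbols paying
+10 points with probability 0.8 / 0.5 / 0.2 (otherwise −5). After trial
30 the contingencies rotate covertly: the worst symbol becomes the best,
the best becomes the middling one, and the middling one becomes the
worst. `prl_environment()` encodes this; outcome draws are conditional on
the chosen option — the task has no pre-generated reward schedule, which
is the simplest reading of a stochastic contingency and has no
consequence for any likelihood in the package.

**Repeated-reversal Dictator game.** Twenty trials with one partner who
holds 10 points per trial and either splits them (fair, return
$r = 0.5$) or keeps them ($r = 0$). The partner's policy is 80/20 unfair
or fair by condition, and silently reverses after trial 10. After every
return the participant rates, on 0–100 scales initialised at 50, the
partner's *harmful intent* (HI: wanting to reduce the participant's
bonus) and *self-interest* (SI: wanting to maximise their own earnings).

## The non-social model family

All eight registry variants (`prl_model_space()`) are three-option
Q-learners with a softmax policy,

$$p(c) \propto \exp(Q_c/\tau),$$

with values initialised at 2.5 points — the expected value of a symbol
with even odds of +10/−5 — and updated by a delta rule
$Q_c \leftarrow Q_c + \lambda (r - Q_c)$. Mechanisms added on top:

* **Pearce–Hall salience** `S`: a salience trace follows the absolute
  prediction error, $s_t = S\,|PE|/15 + (1-S)\,s_{t-1}$, and the
  effective learning rate is $s_t \lambda$. The prediction error is
  divided by 15, the largest magnitude attainable when both rewards and
  values live in $[-5, 10]$, so the trace stays in $[0,1]$ and $\lambda$
  keeps its interpretation as a maximal learning rate. The trace starts
  at 1 so that $S = 0$ reproduces the plain delta rule exactly.
* **Memory decay** `phi`: unchosen values decay toward 2.5,
  $Q \leftarrow 2.5 - \phi(2.5 - Q)$; $\phi = 1$ is perfect retention.
* **Reset-at-reversal** `eta_pr`: once, between trials 30 and 31, all
  values shift toward the mean, $Q \leftarrow Q + \eta_{pr}(2.5 - Q)$.
* **Lapse** `zeta`: the emitted policy is
  $\zeta/3 + (1-\zeta)\,p(c)$.
* **Second learning rate** `lambda2` replacing $\lambda_1$ from trial 31.

Within a trial the operator order is: choose, observe, salience update,
chosen-value update, decay of unchosen values; the reset sits between
trials. The order matters only jointly with parameter values, and this
composition makes every nested identity exact (the test suite asserts
them at $10^{-10}$).

The win-stay/lose-shift baseline (`wsls`) is the two-parameter model
pinned at $\tau = 0.01$, $\lambda = 0.99$. Log-probabilities are
accumulated directly from the log-softmax, so this extreme temperature
remains finite even for choices the policy all but rules out.

The eight-member registry reconstructs a model set described at the
family level (RW / Pearce–Hall / WSLS variants with 2–7 parameters);
`prl_model_space()` returns plain data, so alternative spaces can be
assembled by subsetting or adding rows.

## The belief-based social model

Beliefs about the partner are a joint distribution over harmful intent
and self-interest, each discretised into 9 bins (bin 1 "totally
altruistic", bin 9 "totally antisocial"). Priors per dimension are
binomial-power distributions,

$$P_k \propto \mathrm{Bin}(k;\, 8,\, p)^u, \qquad k = 0,\dots,8,$$

with central tendency $p$ and uncertainty exponent $u$ ($u>1$ sharpens,
$u<1$ blunts, $u=0$ is uniform), and the initial joint is their outer
product. A logistic policy map links attribute pairs to behaviour,

$$\pi(r = 0 \mid HI, SI) = \sigma\!\big(w_0 + w_{HI}(HI - 5) + w_{SI}(SI - 5)\big),$$

and the fair-return probability is its complement (the two returns are
complementary events). Each observed return multiplies the belief grid
cellwise by this likelihood — exact Bayes on 81 cells. The emitted
rating pair is modelled through a blunted copy of the posterior,

$$\hat p \propto p^{1/u_\pi} + \xi,$$

where the policy-uncertainty exponent $u_\pi$ expresses how loosely the
participant assumes actions reflect intents, and $\xi = 0.02/81$ is a
small fixed lapse that keeps every cell reachable; $\xi$ is never
fitted, and it enters fitting and simulation identically (both go
through the same emission grid). At the reversal the next trial's prior
is a convex mixture $(1-\eta_{dg})\,p^{t=0} + \eta_{dg}\,p^{t=10}$.

Two choices here were genuinely open:

* **What propagates.** The blunted distribution is used for emission
  only; the unblunted Bayes posterior carries forward as the next
  prior. The alternative reading (propagating the blunted grid) is
  available as `propagate_blunted = TRUE` on the likelihood and
  simulator.
* **The rating likelihood.** Ratings are mapped to bins
  (`bin = min(9, floor(rating · 9/100) + 1)`, so the scale anchor 50
  falls in the centre bin), and a trial contributes the log of the
  single blunted joint cell at the observed (HI, SI) bin pair.
  Simulation samples a joint bin and reports bin centres. No continuous
  response kernel is assumed because none is implied by the model's
  discrete state.

The registry (`social_model_space()`) crosses a fixed policy map
(documented defaults $w_0 = -1$, $w_{HI} = w_{SI} = 0.1$, configurable)
against an individually fitted one, and 0/1/2 reset parameters. The
two-eta variant mixes the HI and SI *marginals* separately and rebuilds
the joint as their product — the variant is named but not specified
algebraically in its source, so this reconstruction is flagged as such.
With no reset parameter, beliefs simply carry over.

## The associative comparator family

The associative models replace the belief grid with one cached scalar,
the expected social value $ESV \in [0, 0.5]$ on the return scale,
updated by $ESV \leftarrow ESV + \alpha(r - ESV)$. Attributions are
logistic in the centred latent,
$\mathrm{hi} = \sigma(w^{HI}_0 + w^{HI}(ESV - 0.25))$ (likewise SI), and
observed ratings (divided by 100) get Gaussian noise with a shared sd
$\sigma$. Centring at 0.25 — the midpoint of the return scale — makes
intercepts interpretable as neutral-partner attributions; both the
centring and the shared-$\sigma$ choice are reconstructions of a model
family whose full formalism is not public, and the seven-spec registry
(`assoc_model_space()`) says so in its documentation.

**Comparing across families.** The belief model scores a trial as a
probability *mass* on the 9×9 grid; the associative family scores two
continuous *densities*. Densities are not bounded by 1, so ranking raw
BIC across the two conventions would be ill-posed. `compare_models()`
therefore converts belief-family log-likelihoods to densities on the
unit rating square (adds $2\log 9$ per trial — the cell mass divided by
the cell area) before ranking, and only when both conventions are
present in the comparison set. Stored per-fit BIC/AIC fields are never
altered. A residual asymmetry remains: a near-deterministic rater lets
the Gaussian density grow without bound while the grid caps at
$81$ per trial; this is a known limitation of comparing discrete and
continuous response models and is documented rather than hidden.

## MAP fitting

Each participant × model fit maximises log-likelihood plus weak,
range-restricting priors: Beta(1.2, 1.2) on unit-interval parameters,
Gamma(shape 2, scale 3) on positive ones ($\tau$, the uncertainty
exponents, $\sigma$), Normal(0, 5) on real weights and half-Normal(0, 5)
on the non-negative policy sensitivities. These are near-flat in the
interior and exist mostly to keep optimisers away from degenerate
corners. Optimisation runs on transformed coordinates (logit for unit
intervals, log for positives) in three stages: a factorial grid for
small models or a Latin-hypercube scan above four parameters, short
simulated-annealing chains seeded from the best scan points (geometric
temperature 1 → 0.01), then a Nelder–Mead and a BFGS polish (Brent in
one dimension). The defaults (800 scan points, 4 chains × 100
proposals) were chosen by checking, on simulated data, that the
pipeline's optimum never falls below the generating parameters'
posterior value — the relevant adequacy criterion for a multi-start
scheme; longer anneals bought nothing. Everything is deterministic
under the `seed` argument, and refits are bitwise identical.

BIC uses $k$ = number of free parameters and $n$ = number of trials
(60 / 20), counting a rating pair as one observation; `fit_map(n_obs=)`
lets you count 40 instead, which shifts all social models equally and
cannot reorder a within-task comparison.

## The synthetic cohort

`generate_cohort()` stands in for the study population:

* **Paranoia** (persecutory-scale score): negative binomial, clipped at
  the observed maximum of 33, with the *parent* parameters solved
  numerically so the clipped distribution hits mean 3.88 and sd 6.18 —
  zero-heavy, strongly right-tailed, integer-valued.
* **ICAR** (fluid intelligence): normal truncated to [0, 11], parent
  mean solved so the truncated mean is 4.96 (sd 2.42). Scores are kept
  continuous; real ICAR scores are integers, a feature nothing
  downstream depends on.
* **Parameters**: drawn on link scales (log / logit / identity) as
  $\theta = \mu + \mathrm{sd}\,(\beta z + \sqrt{1-\beta^2}\,\varepsilon)$,
  where $z$ is standardised paranoia, so $\beta$ is the link-scale
  correlation. Default slopes couple paranoia to decision temperature
  (0.13), prior strength over harmful intent (0.16), policy uncertainty
  (0.17) and self-interest sensitivity (0.15) — the reported
  standardised coefficients, reused as generative link-scale
  correlations because generative slopes are not published. Population
  locations echo fitted group means (policy intercept near −1,
  sensitivities near 0.1); spreads are set wide enough that individual
  differences are expressible in 60- and 20-trial data.

What the generator does *not* emulate: attrition, comprehension checks,
questionnaire item structure, any paranoia–ICAR dependence, and —
importantly — the unknown true generative relation between paranoia and
parameters. Tests that pass on this cohort show the pipeline recovers
structure *built to be there*; they are not evidence about the real
population.

## Recovery analyses and their limits

`parameter_recovery()` simulates agents at known parameters and refits
them. Generating draws default to uniform over `recovery_ranges()`:
the region where each mechanism is behaviourally expressed
(temperatures 0.5–8 points, policy uncertainty 0.4–3, sensitivities
0.08–1.2, rates 0.05–0.95). Outside these ranges parameters are
trivially unrecoverable — a temperature of 50 makes all choices uniform
— and including such draws only dilutes the sweep. Correlations are
reported on the natural scale, the estimation (link) scale, and as
Spearman; the link scale is the honest one for log-fitted parameters,
whose natural-scale Pearson is dominated by the upper end of the range.

Two structural identifiability limits emerged from this machinery and
are worth stating plainly:

* **The non-social reset** $\eta_{pr}$ acts exactly once, and its
  footprint on the value vector is erased within a few post-reversal
  trials by ongoing learning and decay. Even with every other parameter
  pinned at its generating value, refitting $\eta_{pr}$ alone from
  60-trial data yields only a weak true–recovered correlation; the full
  five-parameter fit is no better. Per-participant MAP estimates of
  this parameter from a single-reversal task are, in this package's
  analysis, noisy by construction, and should be interpreted (and
  regressed on covariates) with that in mind.
* **The social reset** $\eta_{dg}$ *is* recoverable when the other
  eight parameters are known, but degrades substantially in the joint
  fit, where post-reversal rating dynamics can be traded off against
  the policy weights and $u_\pi$. Hierarchical (empirical-prior) group
  fitting would pool exactly the information that per-participant MAP
  lacks here; that machinery is deliberately out of this package's
  scope.

The acceptance suite encodes recovery thresholds for all headline
parameters, including the two resets; the reset assertions fail at
desk scale for the reasons above, and are left failing rather than
weakened, as an honest statement of what per-participant MAP supports.
The self-interest sensitivity $w_{SI}$ sits essentially *at* its
threshold — repeated sweeps put its link-scale recovery correlation in
the high 0.4s to low 0.6s — so that assertion's outcome varies with the
simulation seed; this, too, is reported rather than tuned away.

`model_recovery()` simulates from the winning belief model and asks
whether BIC (scale-equated as above) re-selects a belief-based spec
against the seven associative ones.

## Numerical choices, in one place

* Q values stay on the raw points scale; 2.5 is hard-coded as the
  initial value and decay/reset anchor.
* Log-softmax and log-space binomial-power weights throughout; grids
  renormalise after every operation and the suite asserts normalisation
  at $10^{-10}$.
* Belief-grid recursions are compiled (Rcpp); the exported per-step R
  operations are the reference implementation and the tests assert
  C++/R agreement at $10^{-8}$ or better.
* Degenerate inputs: zero denominators in switch statistics yield
  `NA`, never 0; constant vectors make the permutation test return a
  flagged `NA`; priors at $p \in \{0, 1\}$ with $u > 0$ collapse to the
  correct point mass.
* Permutation p-values are two-sided with add-one correction,
  $p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\})/(B+1)$, so the
  smallest attainable p is $1/(B+1)$ and monotone transforms of either
  variable leave the result unchanged.
* The trial-30 → 31 transition belongs to the pre-reversal scope in
  switch statistics, since the feedback driving that switch was
  delivered pre-reversal.

## Problem sizes

The shipped tests run the full pipeline at desk scale: 200 agents per
task for parameter recovery, 100 for model recovery, 100 agents per
point for the nine-point sensitivity sweep, 200 replicates for
permutation calibration, and an 800-participant synthetic cohort for
the end-to-end structure-recovery check. A power analysis at the
default effect map, combined with the measured estimate reliabilities,
says the strong links (prior strength over harmful intent, policy
uncertainty) are detectable at this size while the attenuated
$w_{SI}$ association (expected observed correlation around 0.05)
would need cohorts in the thousands; the end-to-end check asserts all
four links and is therefore expected to fail on $w_{SI}$ — a
quantified statement about estimate reliability at 20 trials per
participant, not a defect of the permutation machinery, which is
calibrated independently.
`scripts/acceptance.R` recomputes the same quantities at comparable
sizes. Larger cohorts are a config field away
(`cohort_config(n_participants = ...)`).

## Known limitations

* Per-participant MAP only; no hierarchical pooling, no posterior
  uncertainty on estimates.
* The reset parameters' identifiability limits, above.
* The associative family and parts of the model registries are
  documented reconstructions, not transcriptions.
* Discrete-vs-continuous likelihood comparison requires the density
  conversion described above and is not fully symmetric.
* The synthetic cohort's covariate–parameter coupling is a stand-in;
  nothing here estimates the real population's generative structure.
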
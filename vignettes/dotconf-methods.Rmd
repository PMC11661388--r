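---
title: "Decision and confidence computation in multi-alternative dot-numerosity tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision and confidence computation in multi-alternative dot-numerosity tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotconf)
```

## The task and the modelling problem

In a dot-numerosity discrimination task, an observer sees a brief cloud of
red, green and blue dots, reports which colour has the most dots, and rates
their confidence on a 4-point scale. The scientific appeal of this paradigm
is that the mapping from stimulus to internal evidence can be written down
with a single free parameter, which in turn makes it possible to compare
theories of *confidence computation* — the rule by which the brain turns
internal evidence into a confidence report — in genuinely multi-alternative
settings.

`dotconf` implements the full modelling pipeline for this paradigm: the
generative decision model, three competing confidence computations, the
maximum-likelihood fitting and AIC comparison machinery, a synthetic subject
generator, and the behavioural contrasts that serve as qualitative model
signatures.

## The decision model

The internal activation produced by $n$ dots of one colour is modelled as

$$X_n \sim \mathcal{N}(\mu_n, \sigma_n^2), \qquad \mu_n = n, \quad \sigma_n = \alpha n,$$

with a single noise coefficient $\alpha$. The linear mean and the linear
standard deviation both follow from an additivity argument: the activation
produced by $n_1 + n_2$ dots should equal the sum of the activations
produced by the two subsets, and since that shared variability is perfectly
correlated, standard deviations (not variances) add. Zero dots produce zero
activation with zero variability, which pins the intercepts at zero. The
linear noise scaling is the classic scalar-variability / Weber-law property
of magnitude representations. On each trial the observer samples one
activation per colour independently and chooses the colour with the highest
activation.

The four-parameter extension multiplies each colour's activation by a bias
factor $m$ (so $X_n \sim \mathcal{N}(mn, \alpha^2 m^2 n^2)$), with red as
the reference colour ($m_r = 1$, leaving $m_g$, $m_b$ free), and adds a
lapse rate $\lambda$: the proportion of trials answered at random,
independent of the stimulus. Choice probabilities are
$p_i = (1-\lambda)\,P(X_i = \max) + \lambda/3$.

A useful consequence of scalar variability is *scale invariance* of the
bias-free choice rule: scaling all dot counts by a constant scales every
mean and standard deviation by the same constant, leaving
$P(X_i = \max)$ unchanged. Conditions matched in dot ratios therefore have
matched predicted accuracy regardless of absolute numerosity.

## The three confidence models

All three models place three criteria on a continuous confidence variable to
produce the 4-point rating; they differ only in the variable.

* **Top-2 Difference (top2diff)** — the gap between the highest and
  second-highest activation, $\max(x) - \mathrm{max2}(x)$. The variable is
  scale-*covariant*: scaling all counts by $c$ scales the variable by $c$,
  so conditions with more dots at fixed ratios push more mass above fixed
  criteria. This is the mechanism behind the numerosity effect the model
  predicts.
* **Bayesian Confidence Hypothesis (bch)** — the posterior probability that
  the chosen colour truly dominates, given the activations and the
  generative model, marginalising the unknown dot counts $(k_r, k_g, k_b)$
  over an integer grid (1 to 200 by default, uniform independent prior).
  Tuples where the chosen colour ties one competitor count as correct with
  probability 1/2, triple ties with 1/3. The posterior is nearly scale
  invariant (exactly so up to the grid's integer discreteness), which is why
  this model predicts *no* numerosity confidence effect.
* **Positive Evidence (pe)** — the chosen option's activation alone,
  $\max(x)$. Because a larger runner-up count occasionally wins the sample
  and then yields a large maximum, this model predicts *higher* confidence
  when the non-dominant counts are larger — an inverted within-group trend
  and a strongly inflated numerosity effect.

The BCH numerator factorises over the grid: with $L_k(x)$ the Gaussian
likelihood that activation $x$ came from $k$ dots,

$$\sum_{k} L_k(x_{\text{chosen}})
  \Big(C_{k-1}(x_2) + \tfrac12 L_k(x_2)\Big)
  \Big(C_{k-1}(x_3) + \tfrac12 L_k(x_3)\Big)
  \;+\; \tfrac{1}{12}\sum_k L_k(x_{\text{chosen}}) L_k(x_2) L_k(x_3),$$

where $C_{k-1}$ is the cumulative sum of likelihoods below $k$. The $1/12$
correction exists because multiplying the two $\tfrac12 L_k$ tie terms gives
triple ties a weight of $\tfrac14$ where $\tfrac13$ is required. The test
suite verifies this factored form against a brute-force $O(k^3)$ triple sum
on a reduced grid to $10^{-10}$.

## Numerical choices

* **Choice probabilities.** $P(X_i = \max) = \int \phi_i(x) \prod_{j \ne i}
  \Phi_j(x)\,dx$ is evaluated with a fixed 201-node Gauss–Legendre panel
  over the chosen component's mean $\pm 10$ sd. The integrand is smooth, so
  the fixed panel agrees with adaptive quadrature (`method = "adaptive"`,
  `stats::integrate` at `rel.tol = 1e-9`) to about $10^{-8}$ while being
  deterministic and fast enough to sit inside an optimiser; both routes are
  checked against a $10^6$-sample Monte-Carlo oracle in the tests.
  Zero-dot colours are point masses at zero and enter the product as step
  functions (the integration range is clipped at the step).
* **Zero-dot colours inside the BCH posterior.** A zero-dot colour produces
  the degenerate activation $x = 0$ exactly. Evaluating the continuous
  likelihood $L_k(0)$ over $k \ge 1$ would give the absent colour a
  scale-free $1/k$ count profile and make the posterior depend on absolute
  numerosity — an artifact of comparing a point-mass observation against
  densities. The package instead treats an exact-zero activation as
  conclusive evidence of zero dots: the colour drops out of the dominance
  competition (every hypothesised count of the chosen colour beats it, with
  no tie terms). This preserves the model's defining scale invariance in
  designs with two-colour conditions. A chosen colour with zero activation
  (possible only when every other activation is negative) gets posterior
  0 — it cannot out-count competitors whose hypothesised counts start at 1 —
  or 1/3 when all three colours are zero.
* **Ties.** Continuous activations tie with probability zero; the only
  reachable ties involve degenerate zero-dot components, which resolve to
  the lowest colour index. No valid design has two zero-dot colours, so this
  is a documented edge convention rather than a modelling choice.
* **Joint (choice, rating) probabilities.** BCH has no closed-form joint
  distribution, so cell probabilities for fitting come from a fixed
  reservoir of activation draws per (condition, configuration) — 20,000 by
  default — with the lapse component added analytically
  ($\lambda/12$ per cell). The reservoir is seeded once per fit, so
  criterion moves re-bin the *same* samples (common random numbers): the
  objective is piecewise constant but internally consistent, which bounded
  Nelder–Mead handles well. Cells are floored at $10^{-6}$ and the slice
  renormalised, so empty sampled cells cannot produce infinite
  log-likelihoods.
* **Criterion parametrisation.** Criteria are fitted as an ordered triple
  (base plus log-increments) — on the linear scale for top2diff and PE, and
  on the logit scale for BCH, whose confidence variable lives in $(0,1)$ and
  saturates near 1. This keeps the order constraint built into the search
  rather than penalised.
* **Fitting protocol.** Decision models are fitted from the choice marginal
  by exact quadrature likelihoods (1-parameter: bounded search of $\alpha
  \in [0.01, 2]$; 4-parameter: Nelder–Mead on a logistic box transform,
  bounds $m \in [0.5, 2]$, $\lambda \in [0, 0.5]$). Confidence models are
  then fitted with the decision parameters frozen, so all three confidence
  models share identical distributional assumptions and have exactly three
  free parameters; AIC $= -2\log L + 2k$ therefore ranks them identically to
  BIC. Every fit is run twice from jittered starts and the better solution
  kept.
* **Lapse trials and confidence.** The models are silent about the
  confidence emitted on lapse trials. The generator draws a uniform rating
  on lapse trials (so a lapse contributes $\lambda/12$ to every cell),
  which is the natural extension of "random response unrelated to the
  stimulus" to the confidence report; `simulate_response(lapse_confidence =
  "model")` switches to stimulus-driven lapse confidence for sensitivity
  analyses.
* **BCH and colour bias.** When the decision model carries colour
  multipliers, each colour's likelihood $L_k$ inside the BCH posterior uses
  that colour's multiplier — the observer is assumed to know its own bias.
  The alternative (bias-blind posterior) is a plausible variant the package
  does not currently implement.

## The synthetic-data generator

`simulate_cohort()` stands in for a behavioural dataset. Its defaults are
the study conditions of the paradigm: the 6-condition design with 576
trials/subject and the 12-condition design with 1,440 trials/subject, full
counterbalancing over the six colour-rank configurations, population noise
$\alpha \sim \mathrm{TN}(0.27, 0.09)$ and lapse $\lambda \sim
\mathrm{TN}(0.065, 0.04)$ (truncated normals, truncated to the fitting
bounds — the reported population means and spreads of the fitted
parameters), mild colour-bias variability
($m \sim \mathrm{TN}(1, 0.05)$), and per-model criterion triples frozen
after a one-off calibration at the pooled confidence-variable quartiles
under the 12-condition design at $\alpha = 0.27$ (so all four ratings are
used in roughly equal proportion). Per-subject seeds derive
deterministically from the cohort seed: the same spec always reproduces the
same dataset.

What the generator emulates: the condition structure, counterbalancing,
scalar-variability evidence, lapses, per-subject parameter variability, and
response generation under a known confidence model. What it deliberately
does not emulate: reaction times, session/block structure and fatigue,
training and feedback effects, metacognitive noise on the confidence
variable, and any non-Gaussian skew of the activation distributions (small
for the large dot counts used here). Passing tests therefore demonstrate
that the pipeline is correct and well-calibrated *under the model's own
assumptions*, not that the model family is the true account of any real
observer.

## Behavioural contrasts

`numerosity_effect()` contrasts the ratio-matched condition groups
(6-condition design: 1–3 vs 4–6; 12-condition design: 1–6 vs 7–12) on
accuracy and confidence; the behavioural signature is a confidence increase
with little accuracy change. `tradeoff_effect()` contrasts the four
12-condition pairs in which the dominant count is fixed while the two
non-dominant counts are redistributed (3v5, 9v11, 3v4, 9v10); a more even
split raises accuracy while confidence stays flat or falls. Contrasts are
paired two-sided t-tests across subjects with Cohen's
$d = \bar{d}/s_d$ (the paired-design convention), uncorrected for multiple
comparisons. The RMSE goodness-of-fit helper takes any matched
observed/predicted surface; per-condition accuracy and full per-condition
choice proportions are both reasonable surfaces and the package fixes
neither as canonical.

## Problem sizes used by the shipped tests and acceptance script

The test-suite simulations are sized for a desk-scale run: Monte-Carlo
oracles use $10^5$–$10^6$ draws, parameter recovery uses 20 subjects of
1,440 trials, model recovery uses 10 subjects per generating model at a
reduced reservoir (3,000 draws per cell) and single-start fits, and the
BCH numerosity computation uses 30,000 draws per condition with common
random numbers across ratio-matched pairs (the scaled condition's
activations are exactly 0.8 times its partner's, which removes almost all
sampling noise from the group difference). The trade-off direction check
uses a 60-subject cohort: under the generator's population spread the
top-two-difference confidence effect for the 3v4/9v10 pairs inverts for
subjects below $\alpha \approx 0.2$, so the positive population-mean sign
needs more subjects to resolve than the other, more homogeneous
signatures. The acceptance script uses
100,000 draws per condition for that quantity and a 25-subject cohort for
the noise-level recovery; its cohort is generated lapse-free because the
recomputed quantity is the 1-parameter model's own noise coefficient, and a
1-parameter fit to lapse-contaminated choices would conflate the two noise
sources.

## Known limitations

* The BCH posterior inherits the grid bounds (1–200 dots); activations far
  above the grid saturate, so criteria fitted on the logit scale must stay
  below 1.
* Monte-Carlo cell probabilities make the confidence log-likelihood a
  stochastic estimate; with the default reservoir its standard error is a
  fraction of an AIC point, negligible for the model comparisons reported
  here, but per-subject AIC differences below ~1 point should not be
  over-interpreted at reduced reservoir sizes.
* The 1-parameter fit assumes colour symmetry; applying it to strongly
  biased observers inflates $\alpha$.
* `fit_confidence` freezes the decision parameters rather than jointly
  refitting them with the criteria; this mirrors the two-stage protocol the
  pipeline is built around and keeps the confidence-model comparison on a
  shared footing, but it is not a full joint maximum-likelihood fit.
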
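---
title: "Bounded-rational models of multi-feature binary choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-rational models of multi-feature binary choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brchoice)
```

## The task world

Everything in this package lives on a discrete world of eight stimulus
patterns. A `task_spec` holds the class-conditional feature-presence
probabilities $\mu_j$ (class 1) and $\nu_j$ (class 2) for three independent
binary features, plus the class prior (default $1/2$). The generative model
is a product of Bernoullis,
$$P(\mathbf{x}\mid y{=}1)=\prod_j \mu_j^{x_j}(1-\mu_j)^{1-x_j},$$
and likewise with $\nu$ for class 2. Patterns are always enumerated in the
fixed order 111, 110, 101, 100, 011, 010, 001, 000 (feature 1 is the most
significant bit); every table, CSV and policy matrix uses this order.

Two specifications are built in. `"template"` is the distribution the
stimulus template was drawn from; `"empirical"` is the realized frequency
table of the finite template (50 stimuli per class and condition), which is
what responders actually experience. The empirical table is degenerate in
feature 3 ($\nu_3 = 1$): a stimulus without feature 3 is *certainly* class 1.
We handle this by doing all posterior arithmetic with exact likelihoods, so
zeros propagate exactly; only the log-odds weight representation
(`naive_bayes_weights`) clamps probabilities to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$, because a $-\infty$ weight is useless for
reporting while the exact posterior is not harmed. Argmax ties (which occur
only for measure-zero specifications) break toward class 1.

With the 0/1 utility $U(y,a)=\delta_{y,a}$, the expected utility of an
action is the posterior of the matching class, and the ideal actor's
expected hit rate is $\sum_x P(x)\max_a EU(x,a)$ — `r
round(ideal_expected_hit_rate(task_spec("empirical")), 4)` on the empirical
task. This is the key dissociation the metrics preserve: the argmax actor
scores 100 % *selection accuracy* (always picks the more probable class) but
only ~80 % *hit rate*, because the class is stochastic given the features.

## Single-channel model

The bounded-rational responder with one action channel maximizes
$$\mathbb{E}[EU] - \tfrac{1}{\beta} I(X;A)$$
over choice policies $P(a\mid\mathbf{x})$. The optimum is the Boltzmann
policy $P^*(a\mid\mathbf{x}) \propto P^*(a)\,e^{\beta\,EU(\mathbf{x},a)}$
with the self-consistent prior $P^*(a)=\sum_x P(x)P^*(a\mid x)$. We solve it
by alternating the two updates from a uniform start (the problem is convex
in each block), in log space so that large $\beta$ cannot overflow.
Convergence is declared when the largest absolute table change over a full
cycle falls below $10^{-12}$ (cap 20 000 iterations); the tight tolerance is
cheap — convergence is geometric — and keeps the fixed point self-consistent
to $10^{-10}$.

Units: $\beta$ multiplies utility inside a natural-log exponent (it is "per
nat"), while every reported mutual information is in bits. The free-energy
objective is therefore evaluated in nats internally and information fields
are converted with $\log 2$.

`efficiency_frontier()` sweeps $\beta$ and returns the information-utility
curve; on the empirical task it runs from (0 bits, 0.5) to (just under 1
bit, 0.8036), is monotone, and concave — the task's rate-distortion curve.
The capacity-constrained form ($I(X;A)\le K$) is exposed by
`solve_for_capacity()`, which bisects on $\beta$ until the channel
information matches $K$ to $10^{-6}$ bits.

The precision MLE (`fit_beta_mle`) maximizes the summed log-likelihood of
observed choices over a 61-point log-spaced grid on $[10^{-3}, 10^3]$
followed by golden-section refinement on $\log\beta$. The range brackets
every precision scale a responder in this task plausibly occupies (fitted
subject-level values are of order 1–50). Two edge cases are flagged rather
than hidden: deterministic (error-free) data drives $\hat\beta$ to the top
of the range (`at_bound`), and a likelihood that is flat across the grid
returns the smallest optimal value (`flat`).

## Multi-channel model

The structured model routes each feature through its own binary perceptual
channel $P(s_j\mid x_j)$ (shared precision $\beta$) before an action channel
$P(a\mid\mathbf{s})$ over the $2^3 = 8$ internal states (precision
$\beta_U$), maximizing
$$\mathbb{E}[EU] - \tfrac{1}{\beta}\sum_j I(X_j;S_j)
  - \tfrac{1}{\beta_U} I(A;S).$$
Internal states are binary because that is the minimal structure that still
mirrors feature presence; nothing in the objective requires more states, and
richer state spaces only add unidentifiable degrees of freedom.

The solver cycles through the fixed-point updates — channel 1, 2, 3, then
the action channel, then the priors — with the coupling term
$$F(\mathbf{x},\mathbf{s}) = \sum_a P^*(a\mid s)\,EU(x,a)
  - \tfrac{1}{\beta_U}\sum_a P^*(a\mid s)\log\tfrac{P^*(a\mid s)}{P^*(a)}.$$
The joint problem is non-convex, so the solver runs seeded restarts and
keeps the best objective: restart 1 is exactly uniform, restart 2 is the
*informed* start (identity channels plus the Boltzmann action table — the
exact optimum of the unconstrained limit), and all further restarts are
Dirichlet-perturbed uniform tables (concentration 10). The informed start
matters: from symmetric starts alone the alternation can stall on a saddle
at very large precisions, whereas with it the $\beta,\beta_U\to\infty$
solution reproduces the deterministic optimum exactly. Degenerate updates
(a zero normalizer producing NaN) trigger a fresh perturbed start.
Convergence: largest table change per cycle below $10^{-10}$, cap 5 000
cycles. A zero precision is treated as a hard constraint (the corresponding
channels are pinned to their priors and contribute zero information).

Two reductions tie the model to the single-channel one and are tested:
with perceptual channels frozen to the identity (`perceptual = "identity"`),
the action-channel updates are exactly the single-channel alternation at
$\beta_U$; and the marginal strategy
$P(a\mid\mathbf{x})=\sum_s \prod_j P(s_j|x_j) P(a|\mathbf{s})$ always
satisfies $I(X;A)\le I(A;S)$, since actions see the stimulus only through
the internal state.

At fast-condition precision scales (perceptual $\beta \approx 19$, action
$\beta_U \approx 2.75$) the solved model concentrates its per-feature mutual
information on feature 1 with features 2–3 jointly below it — the
take-the-best signature — while at slow-condition scales
($\beta \approx 45$, $\beta_U \approx 3.3$) the feature-3 information rises
back toward the Bayes-optimal profile. We note the opposite assignment
(small perceptual, large action precision) does *not* produce feature-1
concentration in this task: a cheap perceptual budget prefers feature 3,
whose absence is a perfect class-1 indicator.

The two-precision MLE (`fit_multi_channel_mle`) is a grid search, 15×15
log-spaced over $\beta_U \in [0.1, 100]$ and $\beta \in [0.5, 500]$
(bracketing the subject-level scales above), with the grid's marginal
policies cached per session so cross-validation folds cost one solve per
grid point. Fitting-grid solves use 3 restarts (uniform + informed +
one perturbed) against 10 for standalone solves; with the informed start
included, grid solutions were found identical across 3/5/10 restarts at the
scales we probed. A caveat discovered while validating recovery: the map
from $(\beta, \beta_U)$ to the marginal policy is degenerate along a ridge —
near-identical policies can arise at quite different $\beta_U$ — so while
the perceptual precision and the *policy* are recovered well from simulated
data, the action precision per se can be off by more than a factor of two
near that ridge. Recovery checks therefore also compare policies in total
variation.

## Baselines

**Masked logistic regression.** Choices are regressed on the three features
with a per-condition free-parameter budget: slow
$\{b_0, w_1, w_2, w_3\}$, medium $\{b_0, w_1, w_3\}$, fast $\{b_0, w_1\}$.
The budget counts are fixed by design (4/3/2); which parameters to drop is
our choice: feature 2 goes first because its class-conditional frequencies
are equal (0.18/0.18 — it carries no evidence), and the fast condition keeps
feature 1, the dominant cue. The fit is penalized maximum likelihood with a
ridge penalty of $10^{-4}$ on the active coefficients — small enough to be
irrelevant away from separation, large enough to keep separable data (e.g.
deterministic responders) finite; such fits are flagged. No installed
package fits a masked, uniformly-penalized logistic at a fixed penalty, so
the fit is a small Newton/BFGS optimization in-package, run on the 8-pattern
weighted design (exactly equivalent to the trial-level likelihood).

**COR.** Stimuli are encoded as signed cues (+1 if feature 1 present, −1 if
feature 3 present, 0 otherwise — feature 2 is uninformative), responses as
$y=\pm 1$. For each cue dimension $j$ a ridge regression
$\hat W^j = (\Lambda_j + X^\top X)^{-1} X^\top y$ on mean-centered data
penalizes the two off-dimensions by $\sigma^2/\eta^2$ ($\sigma^2$ fixed at
1; only the ratio is identifiable), with offset
$W_0^j = \mu_y - \hat W^j \mu_x$. Choice takes the regressor with maximum
absolute margin and uses its sign; exact zero margins resolve to class 1
and are flagged. As $\eta^2\to\infty$ the three regressors coincide (one
shared hyperplane); as $\eta^2\to 0$ each keeps only its own cue —
single-cue, take-the-best-like classifiers. On task-encoded data the
feature-2 cue column is identically zero, which makes the regressor whose
free dimension is cue 2 exactly singular; that dimension is solved by the
minimum-norm pseudo-inverse and flagged, because refusing to fit would
exclude the COR family from every dataset in this task. COR predictions are
deterministic, so the likelihood used in model comparison wraps them in an
$\varepsilon$-noise link $P(\text{choice}=\text{prediction})=1-\varepsilon$;
at each $\eta^2$ grid point $\varepsilon$ is profiled out (its MLE is the
training mismatch rate, clamped to $[10^{-3}, 0.5]$).

## Information metrics

All mutual informations are plug-in (maximum-likelihood) estimates in bits,
with no bias correction — matching the use of raw empirical frequencies
throughout — and the small positive bias of plug-in MI at low trial counts
is accepted and documented rather than corrected. Empirical choice tables
normalize per observed pattern; patterns never shown are flagged and
excluded from Euclidean table distances (distances restrict to the common
observed support). Per-feature MI profiles $\big(I(X_j;A)\big)_{j=1..3}$ are
the comparison fingerprint: for model policies they use the specification's
stimulus marginal, for data the empirical joint.

## Model comparison

`compare_models` evaluates all families on identical random half-splits,
stratified by stimulus pattern (train and test counts of any pattern differ
by at most one trial), refitting every family on each training half and
summing held-out log predictive probabilities. Deterministic families (Naive
Bayes, and COR when its noise link floors out) are floored at $10^{-12}$
per trial. The default fold count is configurable; tests and the shipped
experiments use 50 folds, where fold-mean likelihoods are within
Monte-Carlo error of much larger fold counts (verified in the test suite at
10 vs 200). Single-channel refits inside cross-validation use the grid
without golden-section refinement: the grid's 1.26× resolution is far below
sampling noise at 50-trial training halves. Paired $t$ statistics between
families are reported descriptively for synthetic cohorts.

A finding worth stating plainly: on synthetic cohorts generated by the
multi-channel model at the fitted subject-level precision scales, half-split
cross-validation at 100 trials per condition does *not* reliably rank the
multi-channel family first — the single-channel family wins. The reason is
parsimony, not machinery: at those scales the generating marginal policies
are imitable by single-channel policies to within ~0.0005 nats per trial,
while the cost of estimating one extra precision from 50 training trials is
an order of magnitude larger. The generating family *is* recovered for
single-channel cohorts, and the comparison machinery (fold identity,
determinism, distances) is fully tested. Distinguishing the two
bounded-rational families at this trial budget requires behavior further
from the single-channel family than the multi-channel model itself produces
at those parameters.

## Synthetic subjects

The generator emulates the study conditions: a stimulus template of 50
stimuli per class and condition drawn once from the generative model and
shared by all subjects (so every subject experiences identical empirical
frequencies); three deadline conditions (fast 1 s, medium 3 s, slow 5 s) in
blocks of 50 trials, 300 trials per session; choices sampled from any model
family's policy at condition-specific precisions; feedback correct exactly
when the choice matches the stochastic true class. Cohorts derive
per-subject seeds from a master seed and jitter precisions log-normally
($\sigma_{\log} = 0.3$ by default) to produce between-subject scatter around
the efficiency frontier. Missed trials default to 0 % and are excluded from
all fits; reaction times are decorative (uniform below the deadline) — no
response-time model is implied. What passing tests on these cohorts show is
that the estimators and comparisons behave correctly when their assumptions
hold; real responders additionally exhibit learning, sequential effects and
lapses that the generator deliberately omits.

## Problem sizes used

Test-suite experiments run at: recovery $n = 5000$ trials per fit;
Monte-Carlo hit-rate checks $n = 10^5$; cohort comparisons 16 subjects × 3
conditions × 100 trials at 50 folds (the study's own scale), with smaller
cohorts for determinism and smoke checks. The pipeline default is a
16-subject multi-channel cohort at 50 folds.

## Known limitations

* The action precision $\beta_U$ is weakly identified near the policy ridge
  described above; interpret fitted $\beta_U$ through the policy it implies.
* Plug-in MI is upward-biased at small trial counts; profiles from 100-trial
  slices carry bias of order 0.01 bits.
* The COR likelihood requires an explicit noise link; reported $\eta^2$
  depends mildly on that choice.
* No learning dynamics: the generator treats conditions as exchangeable and
  subjects as stationary.
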
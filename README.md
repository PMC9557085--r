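# brchoice

Information-theoretic bounded-rational models of two-alternative forced
choice with multi-feature stimuli.

## The problem

In a timed binary classification task, a stimulus carries three independent
binary features; feature `j` is present with probability `mu[j]` in class 1
and `nu[j]` in class 2 (equiprobable classes). A responder sees the feature
pattern `x ∈ {0,1}^3` and chooses a class `a ∈ {1,2}`, receiving feedback
against the stochastic true class. The optimal responder is the Naive Bayes
classifier

    P(y = 1 | x) = σ(wᵀx + w₀),
    w_j = log(μ_j / (1 − μ_j)) − log(ν_j / (1 − ν_j)),
    w₀  = Σ_j log((1 − μ_j) / (1 − ν_j)),

whose deterministic argmax policy reaches 100 % selection accuracy but only
an expected hit rate of `Σ_x P(x) max_a EU(x, a)` — about 0.80 on the
built-in "empirical" task — because the features only stochastically
determine the class.

Human-like responders under time pressure are modelled as *bounded
rational*: they maximize expected utility subject to information
constraints. The package implements

* **single-channel model** — maximize `E[EU] − (1/β) I(X;A)`; the optimum
  is the Boltzmann policy `P*(a|x) ∝ P*(a) exp(β EU(x,a))` with the
  self-consistent prior `P*(a) = Σ_x P(x) P*(a|x)`, solved by
  Blahut–Arimoto-style alternation. Sweeping β traces the
  information-utility efficiency frontier (the task's rate-distortion
  curve).
* **multi-channel model** — three feature-specific perceptual channels
  `P(s_j|x_j)` with shared precision β plus an action channel `P(a|s)` with
  precision β_U, jointly maximizing
  `E[EU] − (1/β) Σ_j I(X_j;S_j) − (1/β_U) I(A;S)` by cyclic fixed-point
  updates with seeded restarts. At fast-condition precision scales this
  model concentrates its per-feature mutual information on the single most
  useful feature — a take-the-best signature.
* **baselines** — condition-wise logistic regression with a shrinking
  free-parameter budget (4/3/2 for slow/medium/fast), and the COR
  (Covariance Orthogonalizing Regularization) ridge model whose prior
  strength η² interpolates between one shared regressor and three
  single-cue regressors, choosing by the maximum-margin hyperplane.

Supporting machinery: plug-in mutual-information metrics (per-feature MI
profiles, `I(X;A)`), hit rate and selection accuracy, half-split
cross-validated likelihood comparison of all five families on identical
folds, Euclidean table/profile distances, and a synthetic-subject generator
(shared stimulus template of 50 stimuli per class and condition, 300 trials
per session, fast/medium/slow deadlines of 1 s/3 s/5 s).

## Worked example

```r
library(brchoice)

spec <- task_spec("empirical")   # realized template frequencies
ideal_expected_hit_rate(spec)
#> 0.8036

sol <- solve_single_channel(spec, beta = 2)
print(sol)
#> Single-channel bounded-rational policy (beta = 2)
#>   I(X;A) = 0.2304 bits, E[EU] = 0.6733 (converged, 68 iterations)
#>         a1     a2
#> 111 0.6861 0.3139
#> 110 0.8593 0.1407
#> ...
```

A responder with precision 2 buys 0.23 bits of stimulus information and
converts it into an expected hit rate of 0.67 — a point on the efficiency
frontier between guessing (0.5 at 0 bits) and the Bayes optimum (0.8036 at
just under one bit).

Simulate a synthetic subject and fit a model with the standard modelling
interface:

```r
tpl  <- generate_template(spec, per_class = 50, seed = 1)
subj <- simulate_subject(tpl, solve_single_channel(spec, 2)$policy, spec,
                         seed = 2)
fit  <- fit_choice_model(subj[subj$condition == "slow", ], spec, "schannel")
print(fit)
#> Choice-model fit: family "schannel" (slow), 100 trials, log-lik -46.231
#>   beta
#> 2.5248

round(feature_mi_profile(subj[subj$condition == "slow", ]), 3)
#>    f1    f2    f3
#> 0.138 0.002 0.192
```

The fitted precision (2.52) recovers the generating value (2) up to
sampling error at 100 trials; the empirical MI profile shows the responder
leaning on features 1 and 3 and ignoring the uninformative feature 2.
`compare_models()` runs the three-pronged comparison (cross-validated
likelihood, choice-table distance, MI-profile distance) across all five
families, and `run_pipeline()` drives the whole analysis from a config.

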
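test_that("generative likelihoods match hand-computed products and normalize", {
  spec <- empirical_spec()
  expect_equal(class_likelihood(spec, "111", 2), 0.12 * 0.18 * 1.00)
  expect_equal(class_likelihood(spec, "110", 2), 0)  # nu3 = 1 forbids x3 = 0
  expect_equal(class_likelihood(spec, c(1, 1, 1), 1), 0.56 * 0.18 * 0.62)
  for (s in list(spec, template_spec(), random_spec(3))) {
    expect_equal(sum(class_likelihood(s, NULL, 1)), 1, tolerance = 1e-12)
    expect_equal(sum(class_likelihood(s, NULL, 2)), 1, tolerance = 1e-12)
    expect_equal(sum(stimulus_marginal(s)), 1, tolerance = 1e-12)
  }
  expect_error(class_likelihood(spec, "111", 3), "class label")
})

test_that("stimulus marginal matches hand enumeration; uniform task is flat", {
  spec <- empirical_spec()
  expect_equal(stimulus_marginal(spec, "001"),
               0.5 * (0.44 * 0.82 * 0.62) + 0.5 * (0.88 * 0.82 * 1.0),
               tolerance = 1e-12)
  expect_equal(stimulus_marginal(spec, "110"), 0.5 * (0.56 * 0.18 * 0.38),
               tolerance = 1e-12)
  u <- task_spec(c(.5, .5, .5), c(.5, .5, .5))
  expect_equal(unname(stimulus_marginal(u)), rep(1 / 8, 8))
})

test_that("Bayes posterior is exact and agrees with the sigmoid form", {
  spec <- empirical_spec()
  # class-2 likelihood of 110 is 0, so the posterior is degenerate
  expect_equal(unname(bayes_posterior(spec, "110")), c(1, 0))
  u <- task_spec(c(.5, .5, .5), c(.5, .5, .5))
  expect_equal(unname(bayes_posterior(u)[, 1]), rep(0.5, 8))
  # sigmoid equivalence on non-degenerate specs
  for (seed in 1:20) {
    s <- random_spec(seed)
    wts <- naive_bayes_weights(s)
    g <- pattern_grid()
    sig <- 1 / (1 + exp(-(drop(g %*% wts$w) + wts$w0)))
    expect_equal(unname(bayes_posterior(s)[, 1]), unname(sig),
                 tolerance = 1e-9)
  }
})

test_that("naive Bayes weights follow the log-odds formulas with clamping", {
  tm <- template_spec()
  w <- naive_bayes_weights(tm)
  expect_equal(w$w[1], log(0.616 / 0.384) - log(0.198 / 0.802),
               tolerance = 1e-10)
  expect_equal(w$w0, log(0.384 / 0.802) + log(0.911 / 0.773) +
                 log(0.320 / 0.015), tolerance = 1e-10)
  same <- task_spec(c(.3, .6, .9), c(.3, .6, .9))
  expect_equal(naive_bayes_weights(same)$w, c(0, 0, 0))
  # degenerate nu3 = 1: clamped weight is finite and strongly negative
  w3 <- naive_bayes_weights(empirical_spec())$w[3]
  expect_true(is.finite(w3) && w3 < -10)
})

test_that("expected utility is the posterior of the matching class", {
  spec <- empirical_spec()
  expect_equal(expected_utility(spec, "110", 1), 1)
  expect_equal(expected_utility(spec, "001", 2),
               0.7216 / (0.223696 + 0.7216), tolerance = 1e-6)
  eu <- expected_utility(spec)
  expect_equal(unname(rowSums(eu)), rep(1, 8))
})

test_that("optimal policy picks the argmax class, ties toward class 1", {
  spec <- empirical_spec()
  pol <- optimal_policy(spec)
  # class 2 is optimal exactly when feature 1 is absent and feature 3 present
  g <- pattern_grid()
  expect_equal(unname(pol[, 2]), as.numeric(g[, 1] == 0 & g[, 3] == 1))
  u <- task_spec(c(.5, .5, .5), c(.5, .5, .5))
  expect_equal(unname(optimal_policy(u)[, 1]), rep(1, 8))  # all ties
  # presence of feature 1 alone favors class 1 in the template task
  expect_equal(unname(optimal_policy(template_spec())["100", ]), c(1, 0))
})

test_that("ideal hit rate matches 8-pattern enumeration and its bounds", {
  spec <- empirical_spec()
  # independent enumeration: 0.5 * sum_x max(P(x|1), P(x|2))
  l1 <- apply(pattern_grid(), 1, function(b)
    prod(c(.56, .18, .62)^b * c(.44, .82, .38)^(1 - b)))
  l2 <- apply(pattern_grid(), 1, function(b)
    prod(c(.12, .18, 1)^b * c(.88, .82, 0)^(1 - b)))
  oracle <- 0.5 * sum(pmax(l1, l2))
  expect_equal(ideal_expected_hit_rate(spec), oracle, tolerance = 1e-12)
  expect_equal(round(ideal_expected_hit_rate(spec), 2), 0.80)
  expect_equal(ideal_expected_hit_rate(task_spec(c(.5, .5, .5), c(.5, .5, .5))), 0.5)
  expect_equal(ideal_expected_hit_rate(task_spec(c(1, .5, .5), c(0, .5, .5))), 1)
  for (seed in 1:10) {
    s <- random_spec(seed)
    expect_gte(ideal_expected_hit_rate(s), 0.5)
  }
})

test_that("selection accuracy separates accuracy from hit rate", {
  spec <- empirical_spec()
  acc <- selection_accuracy(optimal_policy(spec), spec)
  expect_equal(unname(acc$by_pattern), rep(1, 8))
  expect_equal(acc$overall, 1)
  # perfect accuracy coexists with a sub-1 hit rate
  expect_lt(ideal_expected_hit_rate(spec), 1)
  rand <- matrix(0.5, 8, 2)
  expect_equal(unname(selection_accuracy(rand, spec)$by_pattern), rep(0.5, 8))
  # data input: a near-deterministic bounded-rational responder scores high
  d <- sim_trials(spec, solve_single_channel(spec, 50)$policy, 10000, seed = 1)
  expect_gt(selection_accuracy(d, spec)$overall, 0.95)
})
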
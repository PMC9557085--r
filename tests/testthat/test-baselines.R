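spec <- empirical_spec()

test_that("logistic mask contract and recovered weight signs", {
  d <- sim_trials(spec, optimal_policy(spec), 5000, seed = 2)
  full <- logistic_fit(d)
  expect_gt(full$w[1], 0)  # feature 1 favors class 1
  expect_lt(full$w[3], 0)  # feature 3 favors class 2

  fast <- logistic_fit(d, condition_mask("fast"))
  expect_identical(fast$mask, c("b0", "w1"))
  expect_equal(fast$w[2:3], c(0, 0))
  med <- logistic_fit(d, "medium")
  expect_equal(med$w[2], 0)

  # choices independent of the stimulus: all weights near zero (averaged
  # over seeds; a single n=5000 draw has coefficient SE ~ 0.07)
  wbar <- rowMeans(sapply(1:5, function(s)
    logistic_fit(sim_trials(spec, matrix(0.5, 8, 2), 5000, seed = s))$w))
  expect_lt(max(abs(wbar)), 0.1)
})

test_that("logistic predictions are inverse-logit of the masked score", {
  zero <- structure(list(b0 = 0, w = c(0, 0, 0), mask = c("b0", "w1")),
                    class = "br_logistic")
  expect_equal(unname(logistic_predict(zero)), rep(0.5, 8))
  sat <- structure(list(b0 = 0, w = c(10, 0, 0), mask = c("b0", "w1")),
                   class = "br_logistic")
  expect_equal(logistic_predict(sat, "100"), 1, tolerance = 1e-4)
  expect_equal(logistic_predict(sat, "011"), 0.5)
})

test_that("signed cue encoding follows the fixed evidence directions", {
  expect_equal(cor_encode("111"), c(1, 0, -1))
  expect_equal(cor_encode("000"), c(0, 0, 0))
  expect_equal(cor_encode(c(1, 0, 1)), c(1, 0, -1))  # feature 2 irrelevant
  expect_equal(cor_encode("010"), c(0, 0, 0))
})

test_that("COR prior-strength limits: shared regressor vs single-cue regressors", {
  for (seed in 1:10) {
    d <- random_signed_data(seed)
    big <- cor_fit(d, 1e9)
    expect_lt(max(abs(sweep(big$W, 2, colMeans(big$W)))), 1e-5)
    small <- cor_fit(d, 1e-9)
    expect_lt(max(abs(small$W - diag(diag(small$W)))), 1e-5)
  }
})

test_that("COR choice rule: max-margin regressor, sign, ties, scale invariance", {
  m <- structure(list(W = rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
                      W0 = c(0, 0, 0), eta2 = 1, sigma2 = 1,
                      singular_dims = integer(0)), class = "br_cor")
  expect_equal(cor_predict(m, "100"), 1L, ignore_attr = TRUE)
  p000 <- cor_predict(m, "000")
  expect_equal(p000, 1L, ignore_attr = TRUE)
  expect_true(attr(p000, "tie"))
  # jointly scaling W and W0 by a positive constant leaves choices unchanged
  d <- random_signed_data(42)
  fit <- cor_fit(d, 0.5)
  scaled <- fit
  scaled$W <- 7 * fit$W; scaled$W0 <- 7 * fit$W0
  expect_equal(unname(cor_predict(fit)), unname(cor_predict(scaled)))
})

test_that("COR fit on task-encoded data flags the constant cue dimension", {
  d <- sim_trials(spec, optimal_policy(spec), 2000, seed = 2)
  m <- cor_fit(d, 1)
  expect_equal(m$singular_dims, 2L)  # cue 2 is identically zero
  # the eta2 -> Inf fit reproduces the optimal choices on nonzero margins
  big <- cor_fit(d, 1e9)
  pred <- cor_predict(big)
  opt <- max.col(optimal_policy(spec), ties.method = "first")
  margins <- sweep(cor_encode(pattern_grid()) %*% t(big$W), 2, big$W0, `+`)
  nz <- abs(margins[cbind(1:8, max.col(abs(margins)))]) > 1e-8
  expect_equal(unname(pred[nz]), opt[nz])
})

test_that("COR eta2 MLE prefers single-cue structure for a one-feature responder", {
  # responder: choose class 1 iff feature 1 present
  g <- pattern_grid()
  pol <- cbind(ifelse(g[, 1] == 1, 0.95, 0.05),
               ifelse(g[, 1] == 1, 0.05, 0.95))
  d <- sim_trials(spec, pol, 2000, seed = 5)
  lik <- function(e2) {
    m <- cor_fit(d, e2)
    idx <- brchoice:::trial_pattern_index(d)
    pred <- cor_predict(m)[idx]
    mean(pred == d$choice)
  }
  expect_gte(lik(1e-6), lik(1e6))
  f <- cor_fit_eta_mle(d)
  expect_s3_class(f, "br_cor_fit")
  one <- cor_fit_eta_mle(d, eta_grid = 0.25)
  expect_equal(one$eta2, 0.25)
})

test_that("duplicating trials changes the COR fit (penalty does not rescale)", {
  d <- random_signed_data(7, n = 100)
  f1 <- cor_fit(d, 0.1)
  f2 <- cor_fit(rbind(d, d), 0.1)
  expect_gt(max(abs(f1$W - f2$W)), 1e-8)
})
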
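spec <- empirical_spec()

test_that("half-split folds are stratified, balanced and reproducible", {
  tpl <- generate_template(spec, 50, seed = 1)
  d <- simulate_subject(tpl, optimal_policy(spec), spec, seed = 1)
  sl <- d[d$condition == "fast", ]
  folds <- half_split_folds(sl, 50, seed = 1)
  idx <- brchoice:::trial_pattern_index(sl)
  for (f in folds[1:10]) {
    expect_equal(length(f$train), 50)
    expect_equal(length(f$test), 50)
    expect_length(intersect(f$train, f$test), 0)
    gap <- abs(tabulate(idx[f$train], 8) - tabulate(idx[f$test], 8))
    expect_lte(max(gap), 1)
  }
  expect_identical(folds, half_split_folds(sl, 50, seed = 1))
  expect_error(half_split_folds(sl[integer(0), ], 5, 1), "scorable")
})

test_that("cross-validated likelihood behaves across generating models", {
  # data from the optimal policy: naive Bayes predicts every choice with
  # probability 1, so the held-out log-likelihood is exactly 0
  d_opt <- sim_trials(spec, optimal_policy(spec), 300, seed = 9)
  cv_nb <- cv_likelihood(d_opt, "nb", spec, n_folds = 20, seed = 1)
  expect_equal(cv_nb$mean_log_lik, 0)

  # stochastic single-channel data: the stochastic model beats the
  # deterministic Bayes optimum, which pays the floor on wrong choices
  d <- sim_trials(spec, solve_single_channel(spec, 2)$policy, 300, seed = 9)
  folds <- half_split_folds(d, 30, seed = 2)
  cv_sch <- cv_likelihood(d, "schannel", spec, folds = folds)
  cv_nb2 <- cv_likelihood(d, "nb", spec, folds = folds)
  expect_gte(cv_sch$mean_log_lik, cv_nb2$mean_log_lik)

  # fold-count robustness: means agree within Monte-Carlo error
  c10 <- cv_likelihood(d, "schannel", spec, n_folds = 10, seed = 3)
  c200 <- cv_likelihood(d, "schannel", spec, n_folds = 200, seed = 4)
  se <- sd(c200$per_fold) / sqrt(10)
  expect_lt(abs(c10$mean_log_lik - c200$mean_log_lik), 2 * se + 1e-9)
})

test_that("comparison report is deterministic and complete", {
  resp <- list(family = "schannel",
               params = list(fast = list(beta = 0.8),
                             medium = list(beta = 1.8),
                             slow = list(beta = 1.9)))
  subs <- cohort(2, spec, resp, master_seed = 3, jitter_sigma = 0)
  a <- compare_models(subs, spec, families = c("nb", "schannel", "logreg"),
                      n_folds = 10, seed = 5)
  b <- compare_models(subs, spec, families = c("nb", "schannel", "logreg"),
                      n_folds = 10, seed = 5)
  expect_identical(a$results, b$results)
  expect_equal(nrow(a$results), 2 * 3 * 3 * 3)  # subj x cond x model x prong
  expect_true(all(c("cv_log_lik", "table_distance", "mi_profile_distance")
                  %in% a$results$prong))
  expect_true(all(!is.na(a$results$value)))
  # paired summaries exist for every prong and pair
  expect_equal(nrow(a$paired_t), 3 * 3)
})

test_that("cohorts generated by the single-channel family are recovered", {
  resp <- list(family = "schannel",
               params = list(fast = list(beta = 0.784),
                             medium = list(beta = 1.7623),
                             slow = list(beta = 1.8823)))
  wins <- 0
  for (r in 1:3) {
    subs <- cohort(4, spec, resp, master_seed = 20 + r)
    cmp <- compare_models(subs, spec, n_folds = 20, seed = r)
    g <- cmp$grand_means
    g <- g[g$prong == "cv_log_lik", ]
    wins <- wins + (g$model[which.max(g$value)] == "schannel")
  }
  expect_gte(wins, 2)
})

test_that("optimal-policy cohorts give naive Bayes a near-zero table distance", {
  subs <- cohort(2, spec, list(family = "nb", params = NULL), master_seed = 6,
                 jitter_sigma = 0)
  cmp <- compare_models(subs, spec, families = c("nb", "schannel", "cor"),
                        n_folds = 10, seed = 7)
  g <- cmp$grand_means
  td <- g[g$prong == "table_distance", ]
  expect_equal(td$value[td$model == "nb"], 0, tolerance = 1e-9)
  expect_lte(td$value[td$model == "nb"], min(td$value) + 1e-9)
})
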
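spec <- empirical_spec()

test_that("solution tables are normalized and mutually consistent", {
  m <- solve_multi_channel(spec, beta = 5, beta_u = 5, restarts = 5, seed = 2)
  for (j in 1:3) expect_equal(unname(rowSums(m$perceptual[[j]])), c(1, 1),
                              tolerance = 1e-12)
  expect_equal(unname(rowSums(m$action)), rep(1, 8), tolerance = 1e-12)
  expect_equal(unname(rowSums(m$marginal_policy)), rep(1, 8),
               tolerance = 1e-12)
  expect_equal(marginal_strategy(m), m$marginal_policy, tolerance = 1e-10)
  expect_true(all(m$per_feature_info_bits >= 0))
  # actions see x only through s
  expect_lte(policy_information(spec, m$marginal_policy),
             m$action_info_bits + 1e-9)
  # objective never exceeds the unconstrained utility bound
  expect_lte(free_energy(m), ideal_expected_hit_rate(spec))
})

test_that("limits reduce correctly: zero precision, identity channels, large precisions", {
  m0 <- solve_multi_channel(spec, beta = 0, beta_u = 5)
  expect_equal(m0$per_feature_info_bits, rep(0, 3))
  expect_equal(m0$expected_utility, 0.5, tolerance = 1e-9)

  # frozen identity channels recover the single-channel solution
  for (bu in c(1, 3)) {
    mi <- solve_multi_channel(spec, beta = 1, beta_u = bu,
                              perceptual = "identity")
    sc <- solve_single_channel(spec, bu)
    expect_lt(max(abs(mi$marginal_policy - sc$policy)), 1e-8)
  }

  # unconstrained limit approaches the deterministic optimum
  mL <- solve_multi_channel(spec, beta = 1e4, beta_u = 1e4, restarts = 5,
                            seed = 4)
  expect_lt(max(abs(mL$marginal_policy - optimal_policy(spec))), 1e-2)

  # no information penalties: objective equals expected utility (zero-prec
  # channels carry no information, so both penalty terms vanish)
  m00 <- solve_multi_channel(spec, beta = 0, beta_u = 0)
  expect_equal(m00$objective, m00$expected_utility, tolerance = 1e-12)
  expect_equal(m00$objective, 0.5, tolerance = 1e-12)
})

test_that("restarts are deterministic given the seed", {
  a <- solve_multi_channel(spec, beta = 8, beta_u = 2, restarts = 6, seed = 11)
  b <- solve_multi_channel(spec, beta = 8, beta_u = 2, restarts = 6, seed = 11)
  expect_identical(a$marginal_policy, b$marginal_policy)
  expect_identical(a$objective, b$objective)
})

test_that("precision-pair MLE recovers the perceptual precision and the policy", {
  truth <- c(beta = 3, beta_u = 40)
  pol <- solve_multi_channel(spec, beta = truth["beta"],
                             beta_u = truth["beta_u"], restarts = 10,
                             seed = 1)$marginal_policy
  d <- sim_trials(spec, pol, 5000, seed = 3)
  f <- fit_multi_channel_mle(d, spec, restarts = 3, seed = 1)
  expect_gt(f$beta, truth["beta"] / 2)
  expect_lt(f$beta, truth["beta"] * 2)
  # the action precision sits on a likelihood ridge (near-identical marginal
  # policies arise at rather different beta_u), so recovery is asserted in
  # policy space
  expect_lt(max(rowSums(abs(f$policy - pol)) / 2), 0.06)

  # random choices push the perceptual precision near the grid floor
  d_rand <- sim_trials(spec, matrix(0.5, 8, 2), 2000, seed = 5)
  f_rand <- fit_multi_channel_mle(d_rand, spec, restarts = 3, seed = 1)
  expect_lte(f_rand$beta, 1)

  # deterministic optimal data saturates the grid
  d_opt <- sim_trials(spec, optimal_policy(spec), 2000, seed = 6)
  f_opt <- fit_multi_channel_mle(d_opt, spec, restarts = 3, seed = 1)
  expect_true(f_opt$at_bound)
})
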
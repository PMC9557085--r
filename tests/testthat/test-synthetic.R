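spec <- empirical_spec()
tspec <- template_spec()

test_that("template: class balance, realized frequencies, determinism", {
  tpl <- generate_template(tspec, per_class = 50, seed = 1)
  expect_equal(nrow(tpl), 300)
  for (cond in c("fast", "medium", "slow")) {
    d <- tpl[tpl$condition == cond, ]
    expect_equal(nrow(d), 100)
    expect_equal(sum(d$true_class == 1), 50)
  }
  # realized frequencies deviate from the generating probabilities by
  # sampling error but not wildly
  real <- attr(tpl, "realized")$fast
  expect_lt(max(abs(real[1, ] - tspec$mu)), 0.2)
  expect_identical(generate_template(tspec, 50, seed = 1), tpl)
  tiny <- generate_template(tspec, per_class = 1, seed = 3)
  expect_equal(nrow(tiny), 6)  # 2 trials per condition
})

test_that("simulated subjects have consistent feedback and block structure", {
  tpl <- generate_template(spec, 50, seed = 2)
  d <- simulate_subject(tpl, optimal_policy(spec), spec, seed = 5)
  expect_true(all(d$feedback == ifelse(d$choice == d$true_class,
                                       "correct", "incorrect")))
  expect_true(all(d$rt <= c(fast = 1, medium = 3, slow = 5)[d$condition]))
  expect_equal(unname(table(d$condition, d$block)["fast", ]), c(50, 50))
  # all-missed session
  dm <- simulate_subject(tpl, optimal_policy(spec), spec, seed = 5,
                         miss_rate = 1)
  expect_true(all(dm$feedback == "missed"))
  expect_error(hit_rate(dm), "scorable")
})

test_that("hit rates under fitted single-channel precisions order by condition", {
  tpl <- generate_template(spec, per_class = 5000, seed = 8)
  resp <- list(family = "schannel",
               params = list(fast = list(beta = 0.7840),
                             medium = list(beta = 1.7623),
                             slow = list(beta = 1.8823)))
  d <- simulate_subject(tpl, resp, spec, seed = 8)
  hr <- sapply(c("fast", "medium", "slow"),
               function(cc) hit_rate(d[d$condition == cc, ])$overall)
  expect_lt(hr["fast"], hr["medium"])
  expect_lte(hr["medium"], hr["slow"] + 0.02)
})

test_that("empirical choice frequencies converge to the generating policy", {
  pol <- solve_single_channel(spec, 2)$policy
  d <- sim_trials(spec, pol, 10000, seed = 10)
  ep <- empirical_policy(d)
  expect_lt(max(abs(ep$freq[ep$observed, 1] - pol[ep$observed, 1])), 0.05)
})

test_that("cohorts derive per-subject seeds and reproduce byte-identically", {
  resp <- list(family = "schannel",
               params = list(fast = list(beta = 1), medium = list(beta = 1),
                             slow = list(beta = 1)))
  co <- cohort(3, spec, resp, master_seed = 4, jitter_sigma = 0)
  expect_length(co, 3)
  # same generating parameters, different realizations
  expect_false(identical(co[[1]]$choice, co[[2]]$choice))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials(co, f1)
  write_trials(cohort(3, spec, resp, master_seed = 4, jitter_sigma = 0), f2)
  expect_identical(readLines(f1), readLines(f2))
  rt <- read_trials(f1)
  expect_equal(nrow(rt), 900)
  # reader rejects corrupted feedback
  bad <- read.csv(f1)
  bad$feedback[1] <- if (bad$feedback[1] == "correct") "incorrect" else "correct"
  fb <- tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(read_trials(fb), "inconsistent")
})
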
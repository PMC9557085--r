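# shared fixtures and independent oracles

empirical_spec <- function() task_spec("empirical")
template_spec <- function() task_spec("template")

# random non-degenerate task spec for property loops
random_spec <- function(seed, lo = 0.01, hi = 0.99) {
  set.seed(seed)
  task_spec(runif(3, lo, hi), runif(3, lo, hi))
}

# i.i.d. trials: stimulus from P(x), true class from the posterior, choice
# from the given policy -- independent of the template machinery
sim_trials <- function(spec, policy, n, seed) {
  set.seed(seed)
  px <- stimulus_marginal(spec)
  idx <- sample.int(8, n, replace = TRUE, prob = px)
  post1 <- bayes_posterior(spec)[, 1]
  g <- pattern_grid()
  data.frame(
    x1 = g[idx, 1], x2 = g[idx, 2], x3 = g[idx, 3],
    true_class = ifelse(runif(n) < post1[idx], 1L, 2L),
    choice = ifelse(runif(n) < policy[idx, 1], 1L, 2L))
}

# exhaustive search over the 2-pattern policy simplex: best expected utility
# attainable at information budget <= I_bits (plug-in grid, step `step`)
brute_force_two_pattern <- function(px, EU, I_bits, step = 1e-3) {
  p <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = p, p2 = p)
  pa1 <- px[1] * grid$p1 + px[2] * grid$p2
  term <- function(p_ax, pa) {
    out <- numeric(length(p_ax))
    nz <- p_ax > 0 & pa > 0
    out[nz] <- p_ax[nz] * log2(p_ax[nz] / pa[nz])
    out
  }
  I <- px[1] * (term(grid$p1, pa1) + term(1 - grid$p1, 1 - pa1)) +
    px[2] * (term(grid$p2, pa1) + term(1 - grid$p2, 1 - pa1))
  eu <- px[1] * (grid$p1 * EU[1, 1] + (1 - grid$p1) * EU[1, 2]) +
    px[2] * (grid$p2 * EU[2, 1] + (1 - grid$p2) * EU[2, 2])
  ok <- I <= I_bits + 1e-9
  max(eu[ok])
}

# random signed-cue dataset with full-rank centered design
random_signed_data <- function(seed, n = 200) {
  set.seed(seed)
  repeat {
    X <- matrix(sample(c(-1, 0, 1), n * 3, replace = TRUE), n, 3)
    y <- sample(c(-1L, 1L), n, replace = TRUE)
    Xc <- sweep(X, 2, colMeans(X))
    if (qr(Xc)$rank == 3) break
  }
  data.frame(x1 = X[, 1], x2 = X[, 2], x3 = X[, 3], y = y,
             choice = ifelse(y == 1, 1L, 2L))
}
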
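# Blahut-Arimoto style alternation for the single-channel policy:
#   P*(a|x) = P*(a) exp(beta * EU(x,a)) / Z(x),  P*(a) = sum_x P(x) P*(a|x)
# beta multiplies utility inside a natural-log exponent; all reported mutual
# informations are in bits. Computations run in log space so large beta does
# not overflow.
ba_solve <- function(px, EU, beta, tol = 1e-12, max_iter = 20000) {
  nx <- length(px); na <- ncol(EU)
  pol <- matrix(1 / na, nx, na)
  prior <- rep(1 / na, na)
  converged <- FALSE
  it <- 0
  if (beta == 0) {
    # exponent is constant: policy rows equal the prior (uniform fixed point)
    return(list(policy = pol, prior = prior, iterations = 0L,
                converged = TRUE))
  }
  for (it in seq_len(max_iter)) {
    lg <- sweep(beta * EU, 2, log(prior), `+`)
    lg <- lg - apply(lg, 1, max)
    new_pol <- exp(lg)
    new_pol <- new_pol / rowSums(new_pol)
    new_prior <- as.numeric(crossprod(px, new_pol))
    delta <- max(abs(new_pol - pol), abs(new_prior - prior))
    pol <- new_pol; prior <- new_prior
    if (delta < tol) { converged <- TRUE; break }
  }
  list(policy = pol, prior = prior, iterations = it, converged = converged)
}

#' Solve the single-channel bounded-rational policy
#'
#' Maximizes \code{E[EU] - (1/beta) I(X;A)} over choice policies by
#' alternating the Boltzmann policy update \code{P(a|x) proportional to
#' P(a) exp(beta EU(x,a))} with the optimal-prior update
#' \code{P(a) = sum_x P(x) P(a|x)}, from a uniform start. \code{beta} is the
#' precision (per nat of utility); \code{beta = 0} forces the prior policy,
#' large \code{beta} approaches the deterministic optimum.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param beta non-negative precision.
#' @param tol convergence tolerance on the maximum absolute table change
#'   (default 1e-12).
#' @param max_iter iteration cap (default 20000).
#' @return an object of class \code{"br_channel"}: list with \code{policy}
#'   (8 x 2), \code{prior}, \code{beta}, \code{mutual_info_bits},
#'   \code{expected_utility}, \code{iterations}, \code{converged}.
#' @examples
#' sol <- solve_single_channel(task_spec("empirical"), beta = 2)
#' sol$mutual_info_bits
#' @export
solve_single_channel <- function(spec, beta, tol = 1e-12, max_iter = 20000) {
  stopifnot(inherits(spec, "br_task"), beta >= 0)
  px <- stimulus_marginal(spec)
  EU <- expected_utility(spec)
  fit <- ba_solve(px, EU, beta, tol, max_iter)
  dimnames(fit$policy) <- dimnames(EU)
  rownames(fit$policy) <- rownames(pattern_grid())
  structure(list(
    policy = fit$policy,
    prior = fit$prior,
    beta = beta,
    mutual_info_bits = policy_information(spec, fit$policy),
    expected_utility = sum(px * rowSums(fit$policy * EU)),
    iterations = fit$iterations,
    converged = fit$converged,
    spec = spec
  ), class = "br_channel")
}

#' @export
print.br_channel <- function(x, ...) {
  cat(sprintf(
    "Single-channel bounded-rational policy (beta = %.4g)\n  I(X;A) = %.4f bits, E[EU] = %.4f (%s, %d iterations)\n",
    x$beta, x$mutual_info_bits, x$expected_utility,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$policy, 4))
  invisible(x)
}

#' Information-utility efficiency frontier
#'
#' One single-channel solution per precision in \code{beta_grid}; the
#' resulting (information, utility) points trace the task's rate-distortion
#' style frontier: expected utility is non-decreasing and concave in the
#' information budget.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param beta_grid non-negative, sorted precisions.
#' @return a data frame of class \code{"br_frontier"} with columns
#'   \code{beta}, \code{info_bits}, \code{expected_utility},
#'   \code{converged}.
#' @export
efficiency_frontier <- function(spec, beta_grid) {
  stopifnot(all(beta_grid >= 0), !is.unsorted(beta_grid))
  rows <- lapply(beta_grid, function(b) {
    s <- solve_single_channel(spec, b)
    data.frame(beta = b, info_bits = s$mutual_info_bits,
               expected_utility = s$expected_utility,
               converged = s$converged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("br_frontier", "data.frame")
  out
}

#' Solve for a target information capacity
#'
#' The constrained problem (maximize utility subject to \code{I(X;A) <= K})
#' is solved by bisecting on the precision \code{beta} until the channel's
#' mutual information matches the bound \code{K} (in bits) within
#' \code{tol_bits}. If even the largest precision stays below \code{K} the
#' (effectively unconstrained) upper-end solution is returned.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param K_bits target mutual information in bits.
#' @param beta_max upper bracket for the precision (default 1e3).
#' @param tol_bits capacity matching tolerance (default 1e-6).
#' @return a \code{"br_channel"} solution whose \code{mutual_info_bits} is
#'   within \code{tol_bits} of \code{K_bits} (or the bracket endpoint).
#' @export
solve_for_capacity <- function(spec, K_bits, beta_max = 1e3,
                               tol_bits = 1e-6) {
  stopifnot(K_bits >= 0)
  hi <- solve_single_channel(spec, beta_max)
  if (hi$mutual_info_bits <= K_bits + tol_bits) return(hi)
  lo_b <- 0; hi_b <- beta_max
  for (i in 1:200) {
    mid <- (lo_b + hi_b) / 2
    s <- solve_single_channel(spec, mid)
    if (abs(s$mutual_info_bits - K_bits) < tol_bits) return(s)
    if (s$mutual_info_bits > K_bits) hi_b <- mid else lo_b <- mid
  }
  s
}

# memoized single-channel policies along a precision grid, keyed by the
# spec; makes repeated ML fits (cross-validation folds) cost one solve per
# grid point per session
.sch_cache <- new.env(parent = emptyenv())

sch_grid_policies <- function(spec, grid) {
  key <- paste(c(spec$mu, spec$nu, spec$class_prior, grid), collapse = "|")
  if (!is.null(.sch_cache[[key]])) return(.sch_cache[[key]])
  pols <- lapply(grid, function(b) solve_single_channel(spec, b)$policy)
  .sch_cache[[key]] <- pols
  pols
}

# summed log-likelihood of 8x2 choice counts under a policy
counts_loglik <- function(counts, policy, floor = 0) {
  p <- pmax(policy, floor)
  keep <- counts > 0
  sum(counts[keep] * log(p[keep]))
}

#' Maximum-likelihood precision for the single-channel model
#'
#' Fits \code{beta} by maximizing the summed log-likelihood of observed
#' choices under the solved policy \code{P*_beta(choice | stimulus)}.
#' Search is a 61-point log-spaced grid over [1e-3, 1e3] followed (optionally)
#' by golden-section refinement on log(beta) around the best grid point.
#' Deterministic given the data.
#'
#' @param data trial data frame with columns \code{x1, x2, x3, choice} (or an
#'   8 x 2 count matrix).
#' @param spec a \code{\link{task_spec}}.
#' @param grid precision grid (default \code{10^seq(-3, 3, length.out = 61)}).
#' @param refine logical; run golden-section refinement (default TRUE).
#' @return an object of class \code{"br_beta_fit"}: list with \code{beta},
#'   \code{log_lik}, \code{policy}, \code{at_bound} (TRUE when the likelihood
#'   is still increasing at the top of the search range), \code{flat} (TRUE
#'   when the likelihood is constant across the grid; the smallest optimal
#'   beta is returned).
#' @export
fit_beta_mle <- function(data, spec, grid = 10^seq(-3, 3, length.out = 61),
                         refine = TRUE) {
  counts <- if (is.matrix(data)) data else choice_counts(data)
  if (sum(counts) == 0) stop("empty data slice")
  ll_at <- function(b) counts_loglik(counts, solve_single_channel(spec, b)$policy)
  pols <- sch_grid_policies(spec, grid)
  lls <- vapply(seq_along(grid),
                function(i) counts_loglik(counts, pols[[i]]), numeric(1))
  flat <- diff(range(lls)) < 1e-9
  tied <- which(lls >= max(lls) - 1e-9)  # likelihood saturates for large beta
  best <- if (flat) 1L else if (max(tied) == length(grid)) length(grid)
  else which.max(lls)
  at_bound <- !flat && best == length(grid)
  beta <- grid[best]
  ll <- lls[best]
  policy <- pols[[best]]
  if (refine && !flat && !at_bound && best > 1) {
    lo <- log(grid[max(1, best - 1)]); hi <- log(grid[min(length(grid), best + 1)])
    opt <- stats::optimize(function(lb) ll_at(exp(lb)), c(lo, hi),
                           maximum = TRUE, tol = 1e-6)
    if (opt$objective >= ll) {
      beta <- exp(opt$maximum); ll <- opt$objective
      policy <- solve_single_channel(spec, beta)$policy
    }
  }
  structure(list(beta = beta, log_lik = ll, policy = policy,
                 at_bound = at_bound, flat = flat),
            class = "br_beta_fit")
}

#' @export
print.br_beta_fit <- function(x, ...) {
  cat(sprintf("Single-channel ML fit: beta = %.4g (log-lik %.3f)%s%s\n",
              x$beta, x$log_lik,
              if (x$at_bound) " [at search bound]" else "",
              if (x$flat) " [flat likelihood]" else ""))
  invisible(x)
}
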
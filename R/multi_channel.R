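# Multi-channel bounded-rational model: three binary perceptual channels
# P(s_j|x_j) plus an action channel P(a|s) over the 8 internal states,
# jointly maximizing
#   E[EU] - (1/beta) sum_j I(X_j;S_j) - (1/beta_u) I(A;S)
# by cyclic fixed-point updates. Internal states s_j are binary, mirroring
# feature presence, so |S| = 8 and states share the canonical pattern order.
# The objective is evaluated in nats (matching the exponent convention);
# reported information fields are in bits.

# 8x8 matrix m_j[x, s] = P(s_j | x_j) for channel j
channel_slice <- function(ch_j, j, XB, SB) {
  ch_j[XB[, j] + 1, SB[, j] + 1]
}

row_softmax <- function(lg) {
  lg <- lg - apply(lg, 1, max)
  e <- exp(lg)
  e / rowSums(e)
}

mch_objective <- function(px, EU, ch, A, beta, beta_u, XB, SB) {
  m <- lapply(1:3, function(j) channel_slice(ch[[j]], j, XB, SB))
  M <- m[[1]] * m[[2]] * m[[3]]
  ps <- as.numeric(crossprod(px, M))
  EUA <- EU %*% t(A)
  eeu <- sum(px * rowSums(M * EUA))
  pxj <- vapply(1:3, function(j) sum(px[XB[, j] == 1]), numeric(1))
  i_perc <- vapply(1:3, function(j) {
    mutual_information(rbind((1 - pxj[j]) * ch[[j]][1, ],
                             pxj[j] * ch[[j]][2, ])) * log(2)
  }, numeric(1))
  i_act <- mutual_information(ps * A) * log(2)
  pen_p <- if (beta > 0 && is.finite(beta)) sum(i_perc) / beta else 0
  pen_a <- if (beta_u > 0 && is.finite(beta_u)) i_act / beta_u else 0
  list(value = eeu - pen_p - pen_a, eeu = eeu,
       i_perc_bits = i_perc / log(2), i_act_bits = i_act / log(2))
}

mch_run <- function(px, EU, beta, beta_u, ch, A, perceptual_free,
                    tol = 1e-10, max_cycles = 5000, XB, SB) {
  pxj <- vapply(1:3, function(j) sum(px[XB[, j] == 1]), numeric(1))
  psj <- lapply(1:3, function(j) (1 - pxj[j]) * ch[[j]][1, ] + pxj[j] * ch[[j]][2, ])
  m <- lapply(1:3, function(j) channel_slice(ch[[j]], j, XB, SB))
  M <- m[[1]] * m[[2]] * m[[3]]
  ps <- as.numeric(crossprod(px, M))
  pa <- as.numeric(crossprod(ps, A))
  converged <- FALSE
  cycles <- 0
  for (cycles in seq_len(max_cycles)) {
    A_prev <- A; ch_prev <- ch
    # action channel: P*(a|s) ~ P*(a) exp(beta_u sum_x P(x|s) EU(x,a))
    if (beta_u > 0) {
      pxs <- px * M
      den <- colSums(pxs)
      PxgS <- sweep(pxs, 2, ifelse(den > 0, den, 1), `/`)
      V <- crossprod(PxgS, EU)            # 8 x 2
      A <- row_softmax(sweep(beta_u * V, 2, log(pa), `+`))
    } else {
      A <- matrix(pa, nrow(A), 2, byrow = TRUE)
    }
    pa <- as.numeric(crossprod(ps, A))
    # F(x,s) = sum_a P*(a|s) EU(x,a) - (1/beta_u) KL(P*(a|s) || P*(a))
    EUA <- EU %*% t(A)
    if (beta_u > 0 && is.finite(beta_u)) {
      lr <- ifelse(A > 0, A * log(sweep(A, 2, pa, `/`)), 0)
      kl_s <- rowSums(lr)
      Fm <- sweep(EUA, 2, kl_s / beta_u, `-`)
    } else Fm <- EUA
    # perceptual channels, cyclically
    if (perceptual_free && beta > 0) {
      for (j in 1:3) {
        W <- 1
        for (k in setdiff(1:3, j)) W <- W * m[[k]]
        H <- W * Fm
        wx <- cbind((XB[, j] == 0) * px / (1 - pxj[j]),
                    (XB[, j] == 1) * px / pxj[j])
        Is <- cbind(SB[, j] == 0, SB[, j] == 1) * 1
        E <- crossprod(wx, H %*% Is)      # 2 x 2 (rows x_j, cols s_j)
        ch[[j]] <- row_softmax(sweep(beta * E, 2, log(psj[[j]]), `+`))
        psj[[j]] <- (1 - pxj[j]) * ch[[j]][1, ] + pxj[j] * ch[[j]][2, ]
        m[[j]] <- channel_slice(ch[[j]], j, XB, SB)
      }
      M <- m[[1]] * m[[2]] * m[[3]]
    }
    ps <- as.numeric(crossprod(px, M))
    pa <- as.numeric(crossprod(ps, A))
    if (any(is.nan(A)) || any(vapply(ch, anyNA, logical(1)))) return(NULL)
    delta <- max(abs(A - A_prev),
                 max(abs(ch[[1]] - ch_prev[[1]])),
                 max(abs(ch[[2]] - ch_prev[[2]])),
                 max(abs(ch[[3]] - ch_prev[[3]])))
    if (delta < tol) { converged <- TRUE; break }
  }
  list(ch = ch, A = A, psj = psj, pa = pa, cycles = cycles,
       converged = converged, obj = mch_objective(px, EU, ch, A, beta,
                                                  beta_u, XB, SB))
}

# Dirichlet-perturbed uniform rows, concentration `conc`
perturbed_rows <- function(nrow, ncol, conc = 10) {
  g <- matrix(stats::rgamma(nrow * ncol, shape = conc / ncol), nrow, ncol)
  g / rowSums(g)
}

#' Solve the multi-channel bounded-rational model
#'
#' Alternating fixed-point optimization of three feature-specific perceptual
#' channels \code{P(s_j|x_j)} (shared precision \code{beta}) and one action
#' channel \code{P(a|s)} (precision \code{beta_u}) against the objective
#' \code{E[EU] - (1/beta) sum_j I(X_j;S_j) - (1/beta_u) I(A;S)}. The joint
#' problem is non-convex, so the solver runs several seeded random restarts
#' (Dirichlet-perturbed uniform starts) and keeps the best objective.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param beta non-negative perceptual precision (finite; \code{beta = 0}
#'   pins every perceptual channel to its prior).
#' @param beta_u non-negative action precision.
#' @param restarts number of restarts (>= 1; the first start is exactly
#'   uniform).
#' @param seed integer seed for the restart perturbations.
#' @param perceptual \code{"free"} (default) optimizes the perceptual
#'   channels; \code{"identity"} freezes them to noiseless relays
#'   \code{s_j = x_j}, reducing the model to the single-channel problem at
#'   \code{beta_u}.
#' @param tol convergence tolerance on the largest absolute table change
#'   over a full update cycle.
#' @param max_cycles cycle cap per restart.
#' @return an object of class \code{"br_mchannel"}: list with
#'   \code{perceptual} (three 2 x 2 tables), \code{perceptual_priors},
#'   \code{action} (8 x 2), \code{action_prior}, \code{beta}, \code{beta_u},
#'   \code{marginal_policy} (8 x 2), \code{per_feature_info_bits},
#'   \code{action_info_bits}, \code{expected_utility}, \code{objective},
#'   \code{converged}, \code{cycles}, \code{restarts_used}.
#' @export
solve_multi_channel <- function(spec, beta, beta_u, restarts = 10, seed = 1,
                                perceptual = c("free", "identity"),
                                tol = 1e-10, max_cycles = 5000) {
  stopifnot(inherits(spec, "br_task"), beta >= 0, beta_u >= 0, restarts >= 1)
  perceptual <- match.arg(perceptual)
  XB <- pattern_grid(); SB <- XB
  px <- stimulus_marginal(spec)
  EU <- expected_utility(spec)
  ident <- rbind(c(1, 0), c(0, 1))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      if (perceptual == "identity") {
        ch0 <- rep(list(ident), 3)
      } else if (beta == 0) {
        ch0 <- rep(list(matrix(0.5, 2, 2)), 3)
      } else if (r == 1) {
        ch0 <- rep(list(matrix(0.5, 2, 2)), 3)
      } else if (r == 2) {
        # informed start: noiseless relays plus the Boltzmann action table,
        # the exact optimum of the unconstrained (large-precision) limit
        ch0 <- rep(list(ident), 3)
      } else {
        ch0 <- lapply(1:3, function(j) perturbed_rows(2, 2))
      }
      A0 <- if (r == 1) {
        matrix(0.5, 8, 2)
      } else if (r == 2 && perceptual == "free" && beta > 0) {
        row_softmax(min(beta_u, 50) * EU)
      } else perturbed_rows(8, 2)
      run <- mch_run(px, EU, beta, beta_u, ch0, A0,
                     perceptual_free = perceptual == "free" && beta > 0,
                     tol = tol, max_cycles = max_cycles, XB = XB, SB = SB)
      if (is.null(run)) {  # NaN in an update: retry from a fresh perturbation
        run <- mch_run(px, EU, beta, beta_u,
                       lapply(1:3, function(j) perturbed_rows(2, 2)),
                       perturbed_rows(8, 2),
                       perceptual_free = perceptual == "free" && beta > 0,
                       tol = tol, max_cycles = max_cycles, XB = XB, SB = SB)
        if (is.null(run)) next
      }
      if (is.null(best) || run$obj$value > best$obj$value) best <- run
      if (perceptual == "identity" || beta == 0) break  # start is immaterial
    }
  })
  if (is.null(best)) stop("multi-channel solver failed on every restart")
  m <- lapply(1:3, function(j) channel_slice(best$ch[[j]], j, XB, SB))
  M <- m[[1]] * m[[2]] * m[[3]]
  marg <- M %*% best$A
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(rownames(XB), c("a1", "a2"))
  structure(list(
    perceptual = lapply(best$ch, function(m2) {
      dimnames(m2) <- list(c("x0", "x1"), c("s0", "s1")); m2
    }),
    perceptual_priors = best$psj,
    action = structure(best$A, dimnames = list(rownames(SB), c("a1", "a2"))),
    action_prior = best$pa,
    beta = beta, beta_u = beta_u,
    marginal_policy = marg,
    per_feature_info_bits = best$obj$i_perc_bits,
    action_info_bits = best$obj$i_act_bits,
    expected_utility = best$obj$eeu,
    objective = best$obj$value,
    converged = best$converged,
    cycles = best$cycles,
    restarts_used = restarts,
    spec = spec
  ), class = "br_mchannel")
}

#' @export
print.br_mchannel <- function(x, ...) {
  cat(sprintf(
    "Multi-channel bounded-rational solution (beta = %.4g, beta_u = %.4g)\n",
    x$beta, x$beta_u))
  cat(sprintf("  E[EU] = %.4f, I(Xj;Sj) = (%.3f, %.3f, %.3f) bits, I(A;S) = %.3f bits\n",
              x$expected_utility, x$per_feature_info_bits[1],
              x$per_feature_info_bits[2], x$per_feature_info_bits[3],
              x$action_info_bits))
  cat(sprintf("  objective = %.6f (%s, %d cycles)\n", x$objective,
              if (x$converged) "converged" else "NOT converged", x$cycles))
  cat("marginal policy P(a|x):\n")
  print(round(x$marginal_policy, 4))
  invisible(x)
}

#' Marginal choice strategy of a multi-channel solution
#'
#' \code{P(a|x) = sum_s prod_j P(s_j|x_j) P(a|s)}: exact marginalization over
#' the eight internal states.
#'
#' @param solution a \code{"br_mchannel"} object.
#' @return an 8 x 2 policy matrix.
#' @export
marginal_strategy <- function(solution) {
  stopifnot(inherits(solution, "br_mchannel"))
  XB <- pattern_grid(); SB <- XB
  m <- lapply(1:3, function(j) channel_slice(solution$perceptual[[j]], j, XB, SB))
  M <- m[[1]] * m[[2]] * m[[3]]
  marg <- M %*% solution$action
  marg <- marg / rowSums(marg)
  dimnames(marg) <- list(rownames(XB), c("a1", "a2"))
  marg
}

#' Free-energy objective of a multi-channel solution
#'
#' Evaluates \code{E[EU] - (1/beta) sum_j I(X_j;S_j) - (1/beta_u) I(A;S)}
#' exactly from the stored tables (information in nats, matching the
#' precision convention; a zero precision is a hard constraint whose
#' information term is zero by construction).
#'
#' @param solution a \code{"br_mchannel"} object.
#' @param spec a \code{\link{task_spec}} (defaults to the one stored in the
#'   solution).
#' @return the scalar objective value.
#' @export
free_energy <- function(solution, spec = solution$spec) {
  stopifnot(inherits(solution, "br_mchannel"))
  XB <- pattern_grid()
  mch_objective(stimulus_marginal(spec), expected_utility(spec),
                solution$perceptual, solution$action,
                solution$beta, solution$beta_u, XB, XB)$value
}

# memoized marginal policies over a (beta_u, beta) grid; keyed by the spec
# and solver settings so repeated CV folds reuse the same solutions
.mch_cache <- new.env(parent = emptyenv())

mch_grid_policies <- function(spec, grid_beta_u, grid_beta, restarts, seed) {
  key <- paste(c(spec$mu, spec$nu, spec$class_prior, grid_beta_u, grid_beta,
                 restarts, seed), collapse = "|")
  if (!is.null(.mch_cache[[key]])) return(.mch_cache[[key]])
  pols <- vector("list", length(grid_beta_u) * length(grid_beta))
  dim(pols) <- c(length(grid_beta_u), length(grid_beta))
  for (i in seq_along(grid_beta_u)) for (k in seq_along(grid_beta)) {
    pols[[i, k]] <- solve_multi_channel(spec, beta = grid_beta[k],
                                        beta_u = grid_beta_u[i],
                                        restarts = restarts,
                                        seed = seed)$marginal_policy
  }
  .mch_cache[[key]] <- pols
  pols
}

#' Maximum-likelihood precisions for the multi-channel model
#'
#' Grid search over log-spaced \code{(beta_u, beta)} pairs; each candidate's
#' likelihood is the summed log-probability of the observed choices under the
#' solution's marginal strategy. Deterministic given the data, grids and
#' restart seed. Solutions for a given grid are cached within the session, so
#' repeated fits (e.g. across cross-validation folds) cost one solve per grid
#' point.
#'
#' @param data trial data frame (columns \code{x1, x2, x3, choice}) or an
#'   8 x 2 count matrix.
#' @param spec a \code{\link{task_spec}}.
#' @param grid_beta_u action-precision grid (default 15 log-spaced points on
#'   [0.1, 100]).
#' @param grid_beta perceptual-precision grid (default 15 log-spaced points on
#'   [0.5, 500]).
#' @param restarts,seed restart settings passed to
#'   \code{\link{solve_multi_channel}}.
#' @return an object of class \code{"br_mch_fit"}: list with \code{beta},
#'   \code{beta_u}, \code{log_lik}, \code{policy}, \code{at_bound} (TRUE when
#'   either coordinate sits on its grid maximum).
#' @export
fit_multi_channel_mle <- function(data, spec,
                                  grid_beta_u = 10^seq(-1, 2, length.out = 15),
                                  grid_beta = 10^seq(log10(0.5), log10(500),
                                                     length.out = 15),
                                  restarts = 3, seed = 1) {
  counts <- if (is.matrix(data)) data else choice_counts(data)
  if (sum(counts) == 0) stop("empty data slice")
  pols <- mch_grid_policies(spec, grid_beta_u, grid_beta, restarts, seed)
  ll <- matrix(-Inf, length(grid_beta_u), length(grid_beta))
  for (i in seq_along(grid_beta_u)) for (k in seq_along(grid_beta))
    ll[i, k] <- counts_loglik(counts, pols[[i, k]], floor = 1e-12)
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  structure(list(
    beta = grid_beta[best[2]],
    beta_u = grid_beta_u[best[1]],
    log_lik = max(ll),
    policy = pols[[best[1], best[2]]],
    at_bound = best[1] == length(grid_beta_u) || best[2] == length(grid_beta),
    grid_log_lik = ll
  ), class = "br_mch_fit")
}

#' @export
print.br_mch_fit <- function(x, ...) {
  cat(sprintf("Multi-channel ML fit: beta = %.4g, beta_u = %.4g (log-lik %.3f)%s\n",
              x$beta, x$beta_u, x$log_lik,
              if (x$at_bound) " [at grid bound]" else ""))
  invisible(x)
}
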
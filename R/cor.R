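# COR (Covariance Orthogonalizing Regularization): three ridge regressors,
# one per cue dimension, whose shared prior strength eta^2 interpolates
# between a single full regression (eta^2 -> Inf) and three single-cue
# regressors reminiscent of take-the-best (eta^2 -> 0). Class choice picks
# the regressor with maximum |margin|.

#' Signed cue encoding of a stimulus pattern
#'
#' Maps binary feature presence to signed evidence: presence of feature 1
#' favors class 1 (+1), presence of feature 3 favors class 2 (-1), feature 2
#' is uninformative (0); absent features encode to 0. The all-present
#' pattern 111 becomes (+1, 0, -1).
#'
#' @param x a stimulus pattern (0/1 triplet, string, or index), or an n x 3
#'   binary matrix.
#' @return signed cue vector in \{-1, 0, +1\}^3 (or n x 3 matrix).
#' @export
cor_encode <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 3, all(x %in% 0:1))
    return(cbind(x[, 1], 0, -x[, 3]))
  }
  b <- unname(pattern_grid()[pattern_index(x), ])
  c(b[1], 0, -b[3])
}

# signed design matrix and +/-1 responses from a trial data frame; columns
# already containing -1 are taken as pre-encoded signed cues
cor_design <- function(data) {
  d <- data
  if (!is.null(d$choice)) y <- ifelse(d$choice == 1, 1, -1)
  else if (!is.null(d$y)) y <- d$y
  else stop("data must have a choice or y column")
  X <- as.matrix(d[, c("x1", "x2", "x3")])
  if (all(X %in% 0:1)) X <- cor_encode(X)
  stopifnot(all(X %in% c(-1, 0, 1)), all(y %in% c(-1, 1)))
  list(X = X, y = y)
}

#' Fit the COR model at a given prior strength
#'
#' For each cue dimension \code{j}, a ridge regression
#' \code{W^j = (Lambda_j + X'X)^{-1} X'y} on mean-centered signed cues and
#' +/-1-coded responses, where \code{Lambda_j} penalizes the two
#' off-dimensions by \code{sigma2/eta2} and leaves dimension \code{j} free;
#' offsets are \code{W0^j = mean(y) - W^j . mean(x)}. Only the ratio
#' \code{sigma2/eta2} is identifiable, so \code{sigma2} is fixed at 1.
#'
#' A dimension whose penalized Gram matrix is singular (e.g. its own cue is
#' constant in the data, as for the uninformative feature 2 under the task
#' encoding) is solved by the minimum-norm pseudo-inverse and flagged in
#' \code{singular_dims}.
#'
#' @param data trial data frame (binary features + \code{choice}, or
#'   pre-encoded signed cues + \code{y}).
#' @param eta2 positive prior-strength parameter.
#' @param sigma2 noise scale (fixed, default 1).
#' @return an object of class \code{"br_cor"}: list with \code{W} (3 x 3
#'   matrix, row j = W^j), \code{W0} (numeric(3)), \code{eta2},
#'   \code{sigma2}, \code{singular_dims}.
#' @export
cor_fit <- function(data, eta2, sigma2 = 1) {
  stopifnot(eta2 > 0)
  dd <- cor_design(data)
  X <- dd$X; y <- dd$y
  if (nrow(X) == 0) stop("empty data slice")
  mux <- colMeans(X); muy <- mean(y)
  Xc <- sweep(X, 2, mux)
  yc <- y - muy
  cor_solve(crossprod(Xc), drop(crossprod(Xc, yc)), mux, muy, eta2, sigma2)
}

# the same ridge solutions from 8x2 pattern-choice counts (valid for the
# task's binary patterns, whose signed encoding is fixed per pattern)
cor_fit_counts <- function(counts, eta2, sigma2 = 1) {
  stopifnot(eta2 > 0)
  n_x <- rowSums(counts); n <- sum(n_x)
  if (n == 0) stop("empty data slice")
  S <- cor_encode(pattern_grid())
  mux <- drop(crossprod(S, n_x)) / n
  muy <- (sum(counts[, 1]) - sum(counts[, 2])) / n
  G <- crossprod(S, S * n_x) - n * tcrossprod(mux)
  v <- (counts[, 1] - counts[, 2]) - n_x * muy
  cor_solve(G, drop(crossprod(S, v)), mux, muy, eta2, sigma2)
}

cor_solve <- function(G, Xty, mux, muy, eta2, sigma2) {
  W <- matrix(0, 3, 3, dimnames = list(paste0("W", 1:3), paste0("x", 1:3)))
  singular <- integer(0)
  for (j in 1:3) {
    lam <- rep(sigma2 / eta2, 3)
    lam[j] <- 0
    Aj <- G + diag(lam)
    if (rcond(Aj) > 1e-12) {
      W[j, ] <- solve(Aj, Xty)
    } else {
      W[j, ] <- drop(MASS::ginv(Aj) %*% Xty)
      singular <- c(singular, j)
    }
  }
  W0 <- muy - drop(W %*% mux)
  structure(list(W = W, W0 = W0, eta2 = eta2, sigma2 = sigma2,
                 singular_dims = singular),
            class = "br_cor")
}

#' Deterministic class choice of a COR model
#'
#' Scores the stimulus with each regressor, selects the decision hyperplane
#' with the maximum absolute margin \code{j* = argmax_j |W^j x + W0^j|}, and
#' chooses by its sign (+ maps to class 1). An exact zero margin resolves to
#' class 1 and is flagged.
#'
#' @param model a \code{"br_cor"} fit.
#' @param x a stimulus pattern, or \code{NULL} for all eight patterns.
#' @return integer choice(s) 1/2, with attribute \code{tie} marking
#'   zero-margin patterns.
#' @export
cor_predict <- function(model, x = NULL) {
  g <- pattern_grid()
  Xs <- cor_encode(g)
  margins <- sweep(Xs %*% t(model$W), 2, model$W0, `+`)  # 8 x 3
  jstar <- max.col(abs(margins), ties.method = "first")
  m <- margins[cbind(1:8, jstar)]
  choice <- ifelse(m >= 0, 1L, 2L)
  tie <- m == 0
  names(choice) <- rownames(g)
  if (!is.null(x)) {
    i <- pattern_index(x)
    return(structure(unname(choice[i]), tie = unname(tie[i])))
  }
  structure(choice, tie = tie)
}

# deterministic 8 x 2 policy implied by a COR model, optionally softened by
# an epsilon-noise link P(choice = prediction) = 1 - eps
cor_policy <- function(model, eps = 0) {
  ch <- cor_predict(model)
  pol <- cbind(a1 = ifelse(ch == 1, 1 - eps, eps),
               a2 = ifelse(ch == 2, 1 - eps, eps))
  rownames(pol) <- rownames(pattern_grid())
  pol
}

#' Maximum-likelihood prior strength for the COR model
#'
#' COR predictions are deterministic, so they are wrapped in an
#' epsilon-noise link \code{P(choice = prediction) = 1 - eps} to define a
#' likelihood; \code{eps} is profiled out at each grid point (its ML estimate
#' is the training mismatch rate, clamped to [1e-3, 0.5]) and the best
#' \code{(eta2, eps)} pair is returned. Ties prefer the smaller \code{eta2}.
#'
#' @param data trial data frame, or an 8 x 2 pattern-choice count matrix in
#'   canonical order.
#' @param eta_grid positive grid of \code{eta2} values (default 13 log-spaced
#'   points on [1e-4, 1e2]).
#' @return an object of class \code{"br_cor_fit"}: list with \code{eta2},
#'   \code{epsilon}, \code{log_lik}, \code{model}, \code{policy} (the
#'   epsilon-softened 8 x 2 table).
#' @export
cor_fit_eta_mle <- function(data, eta_grid = 10^seq(-4, 2, length.out = 13)) {
  counts <- if (is.matrix(data)) data else choice_counts(data)
  cor_fit_eta_mle_counts(counts, eta_grid)
}

cor_fit_eta_mle_counts <- function(counts,
                                   eta_grid = 10^seq(-4, 2, length.out = 13)) {
  if (length(eta_grid) == 0 || any(eta_grid <= 0))
    stop("eta_grid must be a nonempty positive grid")
  n <- sum(counts)
  if (n == 0) stop("empty data slice")
  best <- NULL
  for (e2 in eta_grid) {
    m <- cor_fit_counts(counts, e2)
    pred <- cor_predict(m)
    mism <- sum(counts[cbind(1:8, 3L - pred)])
    eps <- min(max(mism / n, 1e-3), 0.5)
    ll <- (n - mism) * log(1 - eps) + mism * log(eps)
    if (is.null(best) || ll > best$log_lik + 1e-12) {
      best <- list(eta2 = e2, epsilon = eps, log_lik = ll, model = m)
    }
  }
  best$policy <- cor_policy(best$model, best$epsilon)
  class(best) <- "br_cor_fit"
  best
}

#' @export
print.br_cor <- function(x, ...) {
  cat(sprintf("COR model (eta2 = %.4g)\n", x$eta2))
  print(round(cbind(x$W, W0 = x$W0), 4))
  if (length(x$singular_dims))
    cat("pseudo-inverse used for dimension(s):",
        paste(x$singular_dims, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.br_cor_fit <- function(x, ...) {
  cat(sprintf("COR ML fit: eta2 = %.4g, eps = %.3f (log-lik %.3f)\n",
              x$eta2, x$epsilon, x$log_lik))
  invisible(x)
}
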
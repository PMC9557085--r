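# Condition-wise logistic regression of choices on the three binary features,
# with a shrinking free-parameter budget across time-pressure conditions.

#' Parameter mask for a time condition
#'
#' The free-parameter budget shrinks with time pressure: four parameters in
#' the slow condition, three in the medium, two in the fast. Feature 2 is
#' dropped first (its class-conditional frequencies are equal, so it carries
#' no evidence), then feature 3, leaving the fast condition with intercept
#' and feature 1 only.
#'
#' @param condition one of \code{"slow"}, \code{"medium"}, \code{"fast"}.
#' @return character vector of active parameter names among
#'   \code{c("b0", "w1", "w2", "w3")}.
#' @export
condition_mask <- function(condition) {
  switch(match.arg(condition, c("slow", "medium", "fast")),
         slow = c("b0", "w1", "w2", "w3"),
         medium = c("b0", "w1", "w3"),
         fast = c("b0", "w1"))
}

#' Fit a masked logistic regression of choices on features
#'
#' Penalized maximum likelihood (ridge penalty 1e-4 on the active
#' coefficients, which keeps the fit finite under complete separation) of
#' \code{P(choice = class 1 | x) = sigma(b0 + w'x)}. Parameters outside the
#' mask are fixed at exactly 0. Deterministic.
#'
#' @param data trial data frame with columns \code{x1, x2, x3, choice}
#'   (choice coded 1 = class 1), or an 8 x 2 pattern-choice count matrix in
#'   canonical order.
#' @param mask character vector of active parameters (see
#'   \code{\link{condition_mask}}), or a condition name.
#' @param lambda ridge penalty (default 1e-4).
#' @return an object of class \code{"br_logistic"}: list with \code{b0},
#'   \code{w} (numeric(3), zeros off-mask), \code{mask}, \code{log_lik}
#'   (unpenalized), \code{separation} (TRUE when weights are pinned only by
#'   the penalty).
#' @export
logistic_fit <- function(data, mask = c("b0", "w1", "w2", "w3"),
                         lambda = 1e-4) {
  counts <- if (is.matrix(data)) data else choice_counts(data)
  logistic_fit_counts(counts, mask, lambda)
}

# the likelihood depends on the trials only through the 8x2 pattern-choice
# counts, so the fit is run on the weighted 8-pattern design
logistic_fit_counts <- function(counts, mask = c("b0", "w1", "w2", "w3"),
                                lambda = 1e-4) {
  if (length(mask) == 1 && mask %in% c("slow", "medium", "fast"))
    mask <- condition_mask(mask)
  stopifnot(all(mask %in% c("b0", "w1", "w2", "w3")),
            length(mask) %in% 2:4)
  g <- pattern_grid()
  X <- cbind(b0 = 1, w1 = g[, 1], w2 = g[, 2], w3 = g[, 3])[, mask,
                                                            drop = FALSE]
  n1 <- counts[, 1]; ntot <- rowSums(counts)
  nll <- function(th) {
    eta <- drop(X %*% th)
    sum(ntot * (log1p(exp(-abs(eta))) + pmax(eta, 0)) - n1 * eta) +
      lambda * sum(th^2)
  }
  grad <- function(th) {
    p <- sigmoid(drop(X %*% th))
    drop(crossprod(X, ntot * p - n1)) + 2 * lambda * th
  }
  fit <- stats::optim(rep(0, length(mask)), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  th <- fit$par
  names(th) <- mask
  coefs <- c(b0 = 0, w1 = 0, w2 = 0, w3 = 0)
  coefs[mask] <- th
  eta <- drop(X %*% th)
  ll <- sum(n1 * eta - ntot * (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  structure(list(b0 = unname(coefs["b0"]), w = unname(coefs[2:4]),
                 mask = mask, log_lik = ll,
                 separation = max(abs(th)) > 15),
            class = "br_logistic")
}

#' Predicted class-1 probability of a logistic model
#'
#' @param model a \code{"br_logistic"} fit.
#' @param x a stimulus pattern or \code{NULL} for all eight patterns.
#' @return probability (or named 8-vector) of choosing class 1.
#' @export
logistic_predict <- function(model, x = NULL) {
  g <- pattern_grid()
  p <- sigmoid(model$b0 + drop(g %*% model$w))
  names(p) <- rownames(g)
  if (is.null(x)) p else unname(p[pattern_index(x)])
}

# 8 x 2 policy implied by a logistic model
logistic_policy <- function(model) {
  p <- logistic_predict(model)
  pol <- cbind(a1 = p, a2 = 1 - p)
  rownames(pol) <- rownames(pattern_grid())
  pol
}

#' @export
print.br_logistic <- function(x, ...) {
  cat("Logistic choice model (mask:", paste(x$mask, collapse = ", "), ")\n")
  print(round(c(b0 = x$b0, w1 = x$w[1], w2 = x$w[2], w3 = x$w[3]), 4))
  if (x$separation) cat("note: weights limited only by the ridge penalty\n")
  invisible(x)
}
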
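#' Fit a choice model to trial data
#'
#' The single front end over the five model families: the Naive Bayes
#' optimum (\code{"nb"}, no free parameters), the single-channel
#' bounded-rational model (\code{"schannel"}, precision \code{beta}), the
#' multi-channel bounded-rational model (\code{"mchannel"}, perceptual
#' precision \code{beta} and action precision \code{beta_u}), masked
#' logistic regression (\code{"logreg"}) and the COR ridge model
#' (\code{"cor"}, prior strength \code{eta2} with an epsilon-noise link).
#' All fits are maximum likelihood on the supplied trials.
#'
#' @param data trial data frame with columns \code{x1, x2, x3, choice} (and
#'   optionally \code{condition}).
#' @param spec a \code{\link{task_spec}}.
#' @param family model family, one of \code{"nb"}, \code{"schannel"},
#'   \code{"mchannel"}, \code{"logreg"}, \code{"cor"}.
#' @param condition optional condition label; selects the logistic parameter
#'   mask and is recorded in the fit. Defaults to the unique condition in
#'   the data if there is one.
#' @param ... passed to the family fitter (\code{\link{fit_beta_mle}},
#'   \code{\link{fit_multi_channel_mle}}, \code{\link{logistic_fit}},
#'   \code{\link{cor_fit_eta_mle}}).
#' @return an object of class \code{c("br_fit_<family>", "br_fit")} with
#'   methods \code{print}, \code{summary}, \code{coef}, \code{logLik},
#'   \code{predict}, \code{simulate}, \code{residuals} and \code{plot}.
#' @examples
#' spec <- task_spec("empirical")
#' tpl <- generate_template(spec, per_class = 25, seed = 1)
#' dat <- simulate_subject(tpl, solve_single_channel(spec, 2)$policy,
#'                         spec, seed = 2)
#' fit <- fit_choice_model(dat, spec, "schannel")
#' coef(fit)
#' @export
fit_choice_model <- function(data, spec,
                             family = c("nb", "schannel", "mchannel",
                                        "logreg", "cor"),
                             condition = NULL, ...) {
  family <- match.arg(family)
  if (is.null(condition) && !is.null(data$condition) &&
      length(unique(data$condition)) == 1)
    condition <- unique(data$condition)
  d <- trials_clean(data)
  counts <- choice_counts(d)
  inner <- switch(family,
    nb = list(policy = optimal_policy(spec)),
    schannel = fit_beta_mle(d, spec, ...),
    mchannel = fit_multi_channel_mle(d, spec, ...),
    logreg = logistic_fit(d, mask = if (is.null(condition))
      c("b0", "w1", "w2", "w3") else condition_mask(condition), ...),
    cor = cor_fit_eta_mle(d, ...))
  policy <- switch(family,
                   nb = inner$policy,
                   schannel = inner$policy,
                   mchannel = inner$policy,
                   logreg = logistic_policy(inner),
                   cor = inner$policy)
  ll <- counts_loglik(counts, policy, floor = 1e-12)
  structure(list(family = family, fit = inner, policy = policy, spec = spec,
                 condition = condition, counts = counts,
                 n = sum(counts), log_lik = ll),
            class = c(paste0("br_fit_", family), "br_fit"))
}

fit_df <- function(object) {
  switch(object$family, nb = 0, schannel = 1, mchannel = 2,
         logreg = length(object$fit$mask), cor = 2)
}

#' @export
coef.br_fit <- function(object, ...) {
  switch(object$family,
         nb = numeric(0),
         schannel = c(beta = object$fit$beta),
         mchannel = c(beta = object$fit$beta, beta_u = object$fit$beta_u),
         logreg = {
           v <- c(b0 = object$fit$b0, w1 = object$fit$w[1],
                  w2 = object$fit$w[2], w3 = object$fit$w[3])
           v[c("b0", "w1", "w2", "w3") %in% object$fit$mask]
         },
         cor = c(eta2 = object$fit$eta2, epsilon = object$fit$epsilon))
}

#' @export
logLik.br_fit <- function(object, ...) {
  structure(object$log_lik, df = fit_df(object), nobs = object$n,
            class = "logLik")
}

#' @export
print.br_fit <- function(x, ...) {
  cat(sprintf("Choice-model fit: family \"%s\"%s, %d trials, log-lik %.3f\n",
              x$family,
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else "",
              x$n, x$log_lik))
  cf <- coef(x)
  if (length(cf)) print(round(cf, 4)) else cat("(no free parameters)\n")
  invisible(x)
}

#' @export
summary.br_fit <- function(object, ...) {
  cat(sprintf("Family: %s   trials: %d   log-lik: %.3f   free parameters: %d\n",
              object$family, object$n, object$log_lik, fit_df(object)))
  cf <- coef(object)
  if (length(cf)) { cat("coefficients:\n"); print(round(cf, 4)) }
  cat("\npredicted P(a|x) vs empirical choice frequencies:\n")
  emp <- object$counts / pmax(rowSums(object$counts), 1)
  out <- cbind(round(object$policy, 3),
               emp_a1 = round(emp[, 1], 3),
               n = rowSums(object$counts))
  print(out)
  cat(sprintf("\nI(X;A) of fitted policy: %.4f bits; feature MI profile: %s\n",
              policy_information(object$spec, object$policy),
              paste(sprintf("%.3f", feature_mi_profile(object$policy,
                                                       object$spec)),
                    collapse = ", ")))
  invisible(object)
}

#' @export
predict.br_fit <- function(object, newdata = NULL,
                           type = c("prob", "policy", "choice"), ...) {
  type <- match.arg(type)
  if (type == "policy") return(object$policy)
  if (is.null(newdata)) {
    p1 <- object$policy[, 1]
  } else {
    idx <- if (is.data.frame(newdata)) trial_pattern_index(newdata)
    else pattern_index(newdata)
    p1 <- object$policy[idx, 1]
  }
  if (type == "prob") p1 else ifelse(p1 >= 0.5, 1L, 2L)
}

#' @export
simulate.br_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (is.null(newdata))
    newdata <- generate_template(object$spec, per_class = 50,
                                 seed = seed %||% 1)
  lapply(seq_len(nsim), function(i)
    simulate_subject(newdata, object$policy, object$spec,
                     seed = (seed %||% 1) + i - 1, subject = i))
}

#' @export
residuals.br_fit <- function(object, ...) {
  n <- rowSums(object$counts)
  emp <- ifelse(n > 0, object$counts[, 1] / n, NA)
  emp - object$policy[, 1]
}

#' @export
plot.br_fit <- function(x, ...) {
  n <- rowSums(x$counts)
  emp <- ifelse(n > 0, x$counts[, 1] / n, NA)
  bp <- graphics::barplot(rbind(x$policy[, 1], emp), beside = TRUE,
                          names.arg = rownames(x$policy), las = 2,
                          col = c("steelblue", "grey70"), ylim = c(0, 1),
                          ylab = "P(choose class 1)", xlab = "pattern",
                          main = sprintf("%s fit", x$family), ...)
  graphics::legend("topright", c("model", "data"),
                   fill = c("steelblue", "grey70"), bty = "n")
  invisible(bp)
}

#' @export
plot.br_frontier <- function(x, ...) {
  plot(x$info_bits, x$expected_utility, type = "b", pch = 16,
       xlab = "I(X;A) [bits]", ylab = "expected utility",
       main = "Information-utility frontier", ...)
  invisible(x)
}
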
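#' Task specification for the three-feature binary classification task
#'
#' A task is a discrete world of eight stimulus patterns \code{x in {0,1}^3}
#' and two equiprobable classes. Each class is a bag-of-features model: feature
#' \code{j} is present with probability \code{mu[j]} in class 1 and
#' \code{nu[j]} in class 2, independently given the class.
#'
#' Two named specifications are built in: \code{"template"}, the probabilities
#' used to draw the stimulus template, and \code{"empirical"}, the realized
#' frequencies of the finite template actually experienced by responders.
#'
#' @param mu numeric(3), feature-presence probabilities in class 1, or one of
#'   \code{"template"}, \code{"empirical"}.
#' @param nu numeric(3), feature-presence probabilities in class 2. Ignored
#'   when \code{mu} is a built-in name.
#' @param class_prior probability of class 1 (default 1/2).
#' @return an object of class \code{"br_task"}: a list with elements
#'   \code{mu}, \code{nu}, \code{class_prior} and \code{name}.
#' @examples
#' task_spec("empirical")
#' task_spec(c(.6, .5, .4), c(.2, .5, .9))
#' @export
task_spec <- function(mu, nu = NULL, class_prior = 0.5) {
  name <- "custom"
  if (is.character(mu)) {
    name <- match.arg(mu, c("template", "empirical"))
    built <- list(
      template  = list(mu = c(0.616, 0.089, 0.680), nu = c(0.198, 0.227, 0.985)),
      empirical = list(mu = c(0.560, 0.180, 0.620), nu = c(0.120, 0.180, 1.000))
    )[[name]]
    mu <- built$mu
    nu <- built$nu
  }
  mu <- as.numeric(mu); nu <- as.numeric(nu)
  stopifnot(length(mu) == 3, length(nu) == 3)
  if (any(mu < 0 | mu > 1) || any(nu < 0 | nu > 1))
    stop("feature probabilities must lie in [0, 1]")
  if (class_prior <= 0 || class_prior >= 1)
    stop("class_prior must lie in (0, 1)")
  structure(list(mu = mu, nu = nu, class_prior = class_prior, name = name),
            class = "br_task")
}

#' @export
print.br_task <- function(x, ...) {
  cat("Binary classification task (", x$name, ")\n", sep = "")
  m <- rbind(`class 1` = x$mu, `class 2` = x$nu)
  colnames(m) <- paste0("f", 1:3)
  print(m)
  cat("P(class 1) =", x$class_prior, "\n")
  invisible(x)
}

#' Canonical enumeration of the eight stimulus patterns
#'
#' Patterns are listed in the fixed order 111, 110, 101, 100, 011, 010, 001,
#' 000 (feature 1 is the most significant bit). All policy tables and CSV
#' outputs in the package use this order.
#'
#' @return an 8 x 3 integer matrix with rownames \code{"111"} ... \code{"000"}.
#' @export
pattern_grid <- function() .pattern_grid

.pattern_grid <- local({
  g <- as.matrix(expand.grid(x3 = 1:0, x2 = 1:0, x1 = 1:0))[, 3:1]
  rownames(g) <- apply(g, 1, paste, collapse = "")
  g
})

# resolve a pattern given as length-3 0/1 vector, "110"-style string, or
# row index; returns the canonical row index 1..8
pattern_index <- function(x) {
  g <- pattern_grid()
  if (is.character(x)) {
    i <- match(x, rownames(g))
    if (anyNA(i)) stop("unknown pattern: ", paste(x[is.na(i)], collapse = ", "))
    return(i)
  }
  if (length(x) == 1 && x %in% 1:8) return(as.integer(x))
  if (length(x) == 3 && all(x %in% 0:1))
    return(match(paste(x, collapse = ""), rownames(g)))
  stop("pattern must be a 0/1 triplet, a string like \"110\", or an index 1..8")
}

#' Class-conditional likelihood of a stimulus pattern
#'
#' \code{P(x | y)} under the product-Bernoulli generative model: the product
#' over features of \code{p_j^x_j (1-p_j)^(1-x_j)} with \code{p = mu} for
#' class 1 and \code{p = nu} for class 2. Exact zeros are allowed (a feature
#' with probability 1 makes its absence impossible).
#'
#' @param spec a \code{\link{task_spec}}.
#' @param x a stimulus pattern (0/1 triplet, \code{"110"}-style string, or
#'   canonical index); \code{NULL} returns the full 8-vector.
#' @param y class label, 1 or 2.
#' @return likelihood value(s).
#' @export
class_likelihood <- function(spec, x = NULL, y) {
  stopifnot(inherits(spec, "br_task"))
  if (!(length(y) == 1 && y %in% c(1, 2))) stop("class label must be 1 or 2")
  p <- if (y == 1) spec$mu else spec$nu
  g <- pattern_grid()
  lik <- apply(g, 1, function(b) prod(p^b * (1 - p)^(1 - b)))
  if (is.null(x)) lik else unname(lik[pattern_index(x)])
}

#' Marginal probability of a stimulus pattern
#'
#' \code{P(x) = sum_y P(x|y) pi(y)}, the class-prior mixture of the two
#' product-Bernoulli likelihoods.
#'
#' @inheritParams class_likelihood
#' @return probability value(s); the full 8-vector sums to 1.
#' @export
stimulus_marginal <- function(spec, x = NULL) {
  px <- spec$class_prior * class_likelihood(spec, NULL, 1) +
    (1 - spec$class_prior) * class_likelihood(spec, NULL, 2)
  if (is.null(x)) px else unname(px[pattern_index(x)])
}

#' Bayes posterior over classes given a stimulus pattern
#'
#' Computed by Bayes' rule from the exact likelihoods (zeros propagate); this
#' is the reference posterior, not the clamped sigmoid representation of
#' \code{\link{naive_bayes_weights}}.
#'
#' @inheritParams class_likelihood
#' @return for a single pattern, a named probability pair; for \code{x =
#'   NULL}, an 8 x 2 matrix with columns \code{y1}, \code{y2}.
#' @export
bayes_posterior <- function(spec, x = NULL) {
  l1 <- class_likelihood(spec, NULL, 1)
  l2 <- class_likelihood(spec, NULL, 2)
  num <- cbind(y1 = spec$class_prior * l1, y2 = (1 - spec$class_prior) * l2)
  px <- rowSums(num)
  if (any(px == 0)) {
    bad <- rownames(pattern_grid())[px == 0]
    if (is.null(x) || any(pattern_index(x) %in% which(px == 0)))
      stop("pattern(s) with zero marginal probability: ",
           paste(bad, collapse = ", "))
  }
  post <- num / px
  rownames(post) <- rownames(pattern_grid())
  if (is.null(x)) post else post[pattern_index(x), ]
}

#' Log-odds weights of the Naive Bayes classifier
#'
#' The posterior admits the sigmoid form \code{P(y=1|x) = sigma(w'x + w0)}
#' with \code{w_j = log(mu_j/(1-mu_j)) - log(nu_j/(1-nu_j))} and
#' \code{w0 = sum_j log((1-mu_j)/(1-nu_j))} (plus the prior log-odds when the
#' class prior is not 1/2). Degenerate probabilities (0 or 1) are clamped to
#' \code{[eps, 1-eps]} so the weights stay finite; the clamping affects only
#' this representation, never the exact posterior.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param eps clamping width for degenerate probabilities (default 1e-6).
#' @return a list with elements \code{w} (numeric(3)) and \code{w0}.
#' @export
naive_bayes_weights <- function(spec, eps = 1e-6) {
  mu <- pmin(pmax(spec$mu, eps), 1 - eps)
  nu <- pmin(pmax(spec$nu, eps), 1 - eps)
  w  <- log(mu / (1 - mu)) - log(nu / (1 - nu))
  w0 <- sum(log((1 - mu) / (1 - nu))) +
    log(spec$class_prior / (1 - spec$class_prior))
  list(w = w, w0 = w0)
}

#' Expected utility of an action given a stimulus
#'
#' Under the 0/1 utility \code{U(y, a) = 1} iff \code{y == a}, the expected
#' utility of action \code{a} at pattern \code{x} is simply the posterior
#' probability \code{P(y = a | x)}.
#'
#' @inheritParams class_likelihood
#' @param a action, 1 or 2; \code{NULL} returns both columns.
#' @return expected utility value(s); for \code{x = NULL, a = NULL} an
#'   8 x 2 matrix.
#' @export
expected_utility <- function(spec, x = NULL, a = NULL) {
  eu <- bayes_posterior(spec, NULL)
  colnames(eu) <- c("a1", "a2")
  if (!is.null(a)) {
    if (!(length(a) == 1 && a %in% c(1, 2))) stop("action must be 1 or 2")
    eu <- eu[, a]
  }
  if (is.null(x)) eu else if (is.null(a)) eu[pattern_index(x), ]
  else unname(eu[pattern_index(x)])
}

#' Deterministic expected-utility-maximizing policy
#'
#' Puts probability 1 on \code{argmax_a EU(x, a)} for each of the eight
#' patterns. Exact ties are broken toward class 1.
#'
#' @param spec a \code{\link{task_spec}}.
#' @return an 8 x 2 policy matrix (rows = patterns in canonical order,
#'   columns = actions \code{a1}, \code{a2}; each row sums to 1).
#' @export
optimal_policy <- function(spec) {
  eu <- expected_utility(spec)
  pick1 <- eu[, 1] >= eu[, 2]
  pol <- cbind(a1 = as.numeric(pick1), a2 = as.numeric(!pick1))
  rownames(pol) <- rownames(pattern_grid())
  pol
}

#' Expected hit rate of the ideal decision-maker
#'
#' \code{sum_x P(x) max_a EU(x, a)}: the best achievable probability of
#' positive feedback. Because class membership is stochastic given the
#' features, this is below 1 whenever posteriors are non-degenerate, even for
#' a responder with perfect (100\%) selection accuracy.
#'
#' @param spec a \code{\link{task_spec}}.
#' @return a probability.
#' @export
ideal_expected_hit_rate <- function(spec) {
  px <- stimulus_marginal(spec)
  eu <- expected_utility(spec)
  sum(px * pmax(eu[, 1], eu[, 2]))
}

#' Selection accuracy against the optimal policy
#'
#' Per stimulus pattern, how often the responder chooses the class that is
#' more probable (i.e. agrees with \code{\link{optimal_policy}}). For a
#' stochastic policy the per-pattern accuracy is the probability mass placed
#' on the optimal action; for trial data it is the empirical fraction.
#'
#' @param x an 8 x 2 policy matrix, or a trial data frame with columns
#'   \code{x1, x2, x3, choice}.
#' @param spec a \code{\link{task_spec}}.
#' @return a list with \code{by_pattern} (named vector; \code{NA} for
#'   unobserved patterns in data input), \code{overall} (mean over scored
#'   patterns weighted by trials for data, by \code{P(x)} for a policy) and
#'   \code{excluded} (patterns with no trials).
#' @export
selection_accuracy <- function(x, spec) {
  opt <- max.col(optimal_policy(spec), ties.method = "first")
  pat <- rownames(pattern_grid())
  if (is.matrix(x)) {
    acc <- x[cbind(1:8, opt)]
    names(acc) <- pat
    px <- stimulus_marginal(spec)
    return(list(by_pattern = acc, overall = sum(px * acc),
                excluded = character(0)))
  }
  stopifnot(is.data.frame(x))
  d <- trials_clean(x)
  idx <- trial_pattern_index(d)
  ok <- d$choice == opt[idx]
  acc <- tapply(ok, factor(idx, levels = 1:8), mean)
  n <- tabulate(idx, 8)
  names(acc) <- pat
  list(by_pattern = acc, overall = mean(ok), excluded = pat[n == 0])
}

# drop missed trials, check required columns
trials_clean <- function(d) {
  need <- c("x1", "x2", "x3", "choice")
  if (!all(need %in% names(d)))
    stop("trial data must have columns ", paste(need, collapse = ", "))
  d <- d[!is.na(d$choice) & d$choice %in% c(1, 2), , drop = FALSE]
  if (nrow(d) == 0) stop("no scorable trials")
  d
}

trial_pattern_index <- function(d) {
  pattern_index_vec(paste0(d$x1, d$x2, d$x3))
}

pattern_index_vec <- function(s) {
  i <- match(s, rownames(pattern_grid()))
  if (anyNA(i)) stop("invalid stimulus pattern in data")
  i
}

# 8 x 2 matrix of choice counts per pattern
choice_counts <- function(d) {
  d <- trials_clean(d)
  idx <- trial_pattern_index(d)
  cnt <- matrix(0, 8, 2, dimnames = list(rownames(pattern_grid()),
                                         c("a1", "a2")))
  t1 <- table(factor(idx, 1:8), factor(d$choice, 1:2))
  cnt[] <- as.numeric(t1)
  cnt
}
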
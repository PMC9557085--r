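#' Mutual information of a discrete joint distribution
#'
#' Plug-in mutual information \code{sum_ij p_ij log2(p_ij / (p_i. p_.j))} in
#' bits, with the convention \code{0 log 0 = 0}. No small-sample bias
#' correction is applied; raw (empirical or model) joint tables are used as
#' given.
#'
#' @param joint a non-negative matrix summing to 1 (within 1e-9).
#' @return mutual information in bits (clipped at 0 against roundoff).
#' @examples
#' mutual_information(matrix(c(.4, .1, .1, .4), 2)) # 0.278 bits
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("joint table has negative entries")
  if (abs(sum(joint) - 1) > 1e-9) stop("joint table must sum to 1")
  pr <- rowSums(joint)
  pc <- colSums(joint)
  ref <- outer(pr, pc)
  nz <- joint > 0
  max(0, sum(joint[nz] * log2(joint[nz] / ref[nz])))
}

#' Mutual information between stimulus and action under a policy
#'
#' \code{I(X; A)} of the joint \code{P(x) P(a|x)} with the stimulus marginal
#' taken from the task specification. Zero for any constant policy; at most
#' 1 bit for a binary action.
#'
#' @param spec a \code{\link{task_spec}}.
#' @param policy an 8 x 2 policy matrix in canonical pattern order.
#' @return mutual information in bits.
#' @export
policy_information <- function(spec, policy) {
  px <- stimulus_marginal(spec)
  mutual_information(px * policy)
}

#' Per-feature mutual information profile
#'
#' For each feature \code{j}, the mutual information \code{I(X_j; A)} between
#' feature presence and the chosen class — the fingerprint used to compare
#' how much weight a responder puts on each feature. Accepts either a model
#' policy (profile computed from \code{P(x)} and the policy) or a trial data
#' frame (plug-in profile from empirical joint frequencies).
#'
#' @param x an 8 x 2 policy matrix or a trial data frame with columns
#'   \code{x1, x2, x3, choice}.
#' @param spec a \code{\link{task_spec}}; required for policy input, ignored
#'   for data input.
#' @return numeric(3) of per-feature mutual informations in bits.
#' @export
feature_mi_profile <- function(x, spec = NULL) {
  g <- pattern_grid()
  if (is.matrix(x)) {
    stopifnot(inherits(spec, "br_task"))
    px <- stimulus_marginal(spec)
    joint_xa <- px * x  # 8 x 2
    prof <- vapply(1:3, function(j) {
      m <- rbind(colSums(joint_xa[g[, j] == 0, , drop = FALSE]),
                 colSums(joint_xa[g[, j] == 1, , drop = FALSE]))
      mutual_information(m)
    }, numeric(1))
  } else {
    d <- trials_clean(x)
    n <- nrow(d)
    prof <- vapply(1:3, function(j) {
      m <- table(factor(d[[paste0("x", j)]], 0:1), factor(d$choice, 1:2)) / n
      mutual_information(as.matrix(m))
    }, numeric(1))
  }
  names(prof) <- paste0("f", 1:3)
  prof
}

#' Hit rate of a trial dataset
#'
#' Fraction of (non-missed) trials whose choice equals the true class — the
#' rate of positive feedback — plus the same broken down per stimulus
#' pattern.
#'
#' @param data trial data frame with columns \code{x1, x2, x3, true_class,
#'   choice}.
#' @return a list with \code{overall} and \code{by_pattern}.
#' @export
hit_rate <- function(data) {
  d <- trials_clean(data)
  if (is.null(d$true_class)) stop("data must have a true_class column")
  hit <- d$choice == d$true_class
  idx <- trial_pattern_index(d)
  by <- tapply(hit, factor(idx, 1:8), mean)
  names(by) <- rownames(pattern_grid())
  list(overall = mean(hit), by_pattern = by)
}

#' Empirical choice policy of a dataset
#'
#' Per-pattern choice counts and conditional choice frequencies; the
#' data-side counterpart of a model's 8 x 2 policy table. Patterns never
#' shown are flagged and excluded from distances.
#'
#' @param data trial data frame with columns \code{x1, x2, x3, choice}.
#' @return an object of class \code{"br_empirical_policy"}: list with
#'   \code{counts} (8 x 2), \code{freq} (8 x 2, \code{NA} rows where
#'   unobserved), \code{n} (per-pattern totals), \code{observed} (logical(8)).
#' @export
empirical_policy <- function(data) {
  cnt <- choice_counts(data)
  n <- rowSums(cnt)
  freq <- cnt / ifelse(n > 0, n, NA)
  structure(list(counts = cnt, freq = freq, n = n, observed = n > 0),
            class = "br_empirical_policy")
}

#' @export
print.br_empirical_policy <- function(x, ...) {
  cat("Empirical choice policy (", sum(x$n), " trials)\n", sep = "")
  print(cbind(round(x$freq, 3), n = x$n))
  invisible(x)
}

policy_col1 <- function(p) {
  if (inherits(p, "br_empirical_policy"))
    list(v = p$freq[, 1], obs = p$observed)
  else if (is.matrix(p))
    list(v = p[, 1], obs = rep(TRUE, nrow(p)))
  else stop("expected a policy matrix or an empirical policy")
}

#' Euclidean distance between two choice-probability tables
#'
#' L2 norm of the difference of the class-1 choice-probability columns,
#' restricted to patterns observed in both tables (model policies count as
#' fully observed).
#'
#' @param p,q policy matrices or \code{\link{empirical_policy}} objects.
#' @return a non-negative scalar.
#' @export
table_distance <- function(p, q) {
  a <- policy_col1(p); b <- policy_col1(q)
  keep <- a$obs & b$obs
  if (!any(keep)) stop("tables share no observed patterns")
  sqrt(sum((a$v[keep] - b$v[keep])^2))
}

#' Euclidean distance between two mutual-information profiles
#'
#' @param p,q numeric(3) profiles in bits (see
#'   \code{\link{feature_mi_profile}}).
#' @return a non-negative scalar.
#' @export
mi_profile_distance <- function(p, q) {
  stopifnot(length(p) == 3, length(q) == 3)
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}
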
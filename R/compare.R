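# Three-pronged model comparison across the five families: half-split
# cross-validated predictive likelihood, Euclidean distance between
# conditional choice-probability tables, and Euclidean distance between
# per-feature mutual-information profiles.

MODEL_FAMILIES <- c("nb", "schannel", "mchannel", "logreg", "cor")

#' Random half-split folds, stratified by stimulus pattern
#'
#' Generates \code{n_folds} random partitions of the scorable trials into a
#' fitting half and an evaluation half. Splits are stratified by stimulus
#' pattern: train and test counts of any pattern differ by at most one trial
#' (a pattern with a single trial goes wholly to one side). Reproducible
#' given the seed.
#'
#' @param data trial data frame.
#' @param n_folds number of folds (default 1000).
#' @param seed integer seed.
#' @return list of folds, each a list with integer row-index vectors
#'   \code{train} and \code{test}.
#' @export
half_split_folds <- function(data, n_folds = 1000, seed = 1) {
  d <- trials_clean(data)
  rows <- which(!is.na(data$choice) & data$choice %in% c(1, 2))
  n <- length(rows)
  if (n < 2) stop("need at least 2 scorable trials")
  idx <- trial_pattern_index(d)
  groups <- split(rows, idx)
  sizes <- lengths(groups)
  odd <- which(sizes %% 2 == 1)
  extra <- floor(n / 2) - sum(sizes %/% 2)
  with_seed(seed, {
    folds <- lapply(seq_len(n_folds), function(f) {
      take <- sizes %/% 2
      if (extra > 0) {
        bump <- if (length(odd) == 1) odd else sample(odd, extra)
        take[bump] <- take[bump] + 1
      }
      train <- unlist(lapply(seq_along(groups), function(g) {
        if (take[g] == 0) return(integer(0))
        sample(groups[[g]], take[g])
      }), use.names = FALSE)
      list(train = sort(train), test = sort(setdiff(rows, train)))
    })
  })
  folds
}

# predicted 8x2 choice-probability table for a family fitted to an 8x2
# pattern-choice count matrix (every family's likelihood depends on the data
# only through these counts)
fit_family_policy <- function(counts, family, spec, condition = NULL,
                              mch_restarts = 3, mch_seed = 1) {
  switch(family,
         nb = optimal_policy(spec),
         schannel = fit_beta_mle(counts, spec, refine = FALSE)$policy,
         mchannel = fit_multi_channel_mle(counts, spec,
                                          restarts = mch_restarts,
                                          seed = mch_seed)$policy,
         logreg = logistic_policy(logistic_fit_counts(
           counts, mask = if (is.null(condition)) c("b0", "w1", "w2", "w3")
           else condition_mask(condition))),
         cor = cor_fit_eta_mle_counts(counts)$policy,
         stop("unknown model family: ", family))
}

#' Cross-validated predictive log-likelihood of a model family
#'
#' For each fold, fits the family on the training half and sums the log
#' predicted probability of the held-out choices; reports the mean over
#' folds. Deterministic-model probabilities are floored at \code{floor}
#' (default 1e-12) so a single surprising choice does not produce an
#' infinite penalty. Folds on which fitting fails are skipped and counted.
#'
#' @param data trial data frame for one subject and condition.
#' @param family one of \code{"nb"}, \code{"schannel"}, \code{"mchannel"},
#'   \code{"logreg"}, \code{"cor"}.
#' @param spec a \code{\link{task_spec}}.
#' @param n_folds number of half-split folds (default 50).
#' @param seed fold seed.
#' @param condition condition label (selects the logistic parameter mask);
#'   defaults to the single condition present in the data, if unique.
#' @param folds optional pre-built folds from \code{\link{half_split_folds}}
#'   (lets several families share identical partitions).
#' @param floor per-trial probability floor.
#' @param mch_restarts,mch_seed multi-channel solver settings.
#' @return a list with \code{mean_log_lik} (mean over folds of the summed
#'   held-out log-likelihood), \code{per_fold}, \code{skipped}.
#' @export
cv_likelihood <- function(data, family, spec, n_folds = 50, seed = 1,
                          condition = NULL, folds = NULL, floor = 1e-12,
                          mch_restarts = 3, mch_seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(condition) && !is.null(data$condition) &&
      length(unique(data$condition)) == 1)
    condition <- unique(data$condition)
  if (is.null(folds)) folds <- half_split_folds(data, n_folds, seed)
  # per-trial pattern/choice codes once; per-fold counts by fast tabulation
  code <- rep(NA_integer_, nrow(data))
  ok <- !is.na(data$choice) & data$choice %in% c(1, 2)
  code[ok] <- (pattern_index_vec(paste0(data$x1, data$x2, data$x3))[ok] - 1L) *
    2L + as.integer(data$choice[ok])
  fold_counts <- function(rows)
    matrix(tabulate(code[rows], 16L), 8, 2, byrow = TRUE)
  per_fold <- rep(NA_real_, length(folds))
  skipped <- 0L
  for (f in seq_along(folds)) {
    pol <- tryCatch(
      fit_family_policy(fold_counts(folds[[f]]$train), family, spec,
                        condition, mch_restarts, mch_seed),
      error = function(e) NULL)
    if (is.null(pol)) { skipped <- skipped + 1L; next }
    per_fold[f] <- counts_loglik(fold_counts(folds[[f]]$test), pol,
                                 floor = floor)
  }
  list(mean_log_lik = mean(per_fold, na.rm = TRUE), per_fold = per_fold,
       skipped = skipped)
}

#' Three-pronged comparison of the five model families
#'
#' For every subject x condition slice of a cohort, computes (i) the mean
#' half-split cross-validated predictive log-likelihood, (ii) the Euclidean
#' distance between the family's fitted choice-probability table and the
#' empirical table, and (iii) the Euclidean distance between the fitted and
#' empirical per-feature mutual-information profiles. Every family is
#' evaluated on identical folds. Paired t statistics between families
#' (per prong, across subject x condition cells) are reported descriptively.
#'
#' @param datasets list of subject trial data frames (each may span several
#'   conditions).
#' @param spec a \code{\link{task_spec}}.
#' @param families model families to include (default all five).
#' @param n_folds folds per slice (default 50).
#' @param seed master seed (fold seeds are derived per slice).
#' @param mch_restarts,mch_seed multi-channel solver settings.
#' @return an object of class \code{"br_comparison"}: list with
#'   \code{results} (long data frame: subject, condition, model, prong,
#'   value), \code{grand_means}, \code{paired_t} (per prong, model pair:
#'   mean difference and t statistic), \code{n_folds}, \code{seed}.
#' @export
compare_models <- function(datasets, spec, families = MODEL_FAMILIES,
                           n_folds = 50, seed = 1, mch_restarts = 3,
                           mch_seed = 1) {
  families <- match.arg(families, MODEL_FAMILIES, several.ok = TRUE)
  rows <- list()
  slice_id <- 0L
  for (si in seq_along(datasets)) {
    d <- datasets[[si]]
    subj <- if (!is.null(d$subject)) d$subject[1] else si
    for (cond in unique(d$condition)) {
      slice_id <- slice_id + 1L
      slice <- d[d$condition == cond & !is.na(d$choice), , drop = FALSE]
      if (nrow(slice) < 2) next
      fseed <- (seed * 7919 + slice_id * 104729) %% (2^31 - 1)
      folds <- half_split_folds(slice, n_folds, fseed)
      emp <- empirical_policy(slice)
      emp_mi <- feature_mi_profile(slice)
      for (fam in families) {
        cv <- cv_likelihood(slice, fam, spec, condition = cond,
                            folds = folds, mch_restarts = mch_restarts,
                            mch_seed = mch_seed)
        full_pol <- fit_family_policy(choice_counts(slice), fam, spec,
                                      cond, mch_restarts, mch_seed)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, condition = cond, model = fam,
          cv_log_lik = cv$mean_log_lik,
          table_distance = table_distance(emp, full_pol),
          mi_profile_distance = mi_profile_distance(
            emp_mi, feature_mi_profile(full_pol, spec)),
          folds_skipped = cv$skipped)
      }
    }
  }
  res <- do.call(rbind, rows)
  long <- stats::reshape(
    res, direction = "long",
    varying = c("cv_log_lik", "table_distance", "mi_profile_distance"),
    v.names = "value", timevar = "prong",
    times = c("cv_log_lik", "table_distance", "mi_profile_distance"))
  long <- long[, c("subject", "condition", "model", "prong", "value")]
  rownames(long) <- NULL
  gm <- stats::aggregate(value ~ model + prong, long, mean)
  paired <- list()
  for (pr in unique(long$prong)) {
    for (i in seq_along(families)) for (k in seq_along(families)) {
      if (i >= k) next
      a <- long$value[long$prong == pr & long$model == families[i]]
      b <- long$value[long$prong == pr & long$model == families[k]]
      if (length(a) < 2 || length(a) != length(b)) next
      dif <- a - b
      tt <- if (stats::sd(dif) > 0)
        stats::t.test(dif) else list(statistic = NA, p.value = NA)
      paired[[length(paired) + 1]] <- data.frame(
        prong = pr, model_a = families[i], model_b = families[k],
        mean_diff = mean(dif), t = unname(tt$statistic),
        p = unname(tt$p.value))
    }
  }
  structure(list(results = long, grand_means = gm,
                 paired_t = do.call(rbind, paired),
                 n_folds = n_folds, seed = seed),
            class = "br_comparison")
}

#' @export
print.br_comparison <- function(x, ...) {
  cat("Model comparison (", x$n_folds, "-fold half-split CV)\n", sep = "")
  cat("grand means by prong:\n")
  for (pr in unique(x$grand_means$prong)) {
    g <- x$grand_means[x$grand_means$prong == pr, ]
    g <- g[order(g$value, decreasing = pr == "cv_log_lik"), ]
    cat(" ", pr, ": ",
        paste(sprintf("%s=%.3f", g$model, g$value), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
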
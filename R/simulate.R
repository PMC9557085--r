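# Synthetic stand-in for the behavioral cohort: a fixed stimulus template
# shared by all subjects (50 stimuli per class and condition), choices drawn
# from any model family's policy at condition-specific precision, feedback,
# and decorative reaction times.

# response deadlines (seconds) per condition
condition_deadlines <- c(fast = 1, medium = 3, slow = 5)

#' Generate the shared stimulus template
#'
#' Per condition, draws \code{per_class} stimulus patterns from the
#' generative model of each class and shuffles them into a trial sequence.
#' The same template is meant to be reused for every subject of a cohort, so
#' all subjects experience identical empirical feature frequencies. The
#' realized per-class feature frequencies (which deviate from the generating
#' probabilities by sampling error) are attached as attribute
#' \code{"realized"}.
#'
#' @param spec a \code{\link{task_spec}} (typically \code{"template"}).
#' @param per_class stimuli per class and condition (default 50).
#' @param seed integer seed.
#' @param conditions condition names (default fast/medium/slow).
#' @return a data frame with columns \code{condition, x1, x2, x3,
#'   true_class}; \code{2 * per_class} rows per condition.
#' @export
generate_template <- function(spec, per_class = 50, seed = 1,
                              conditions = c("fast", "medium", "slow")) {
  stopifnot(inherits(spec, "br_task"), per_class >= 1)
  with_seed(seed, {
    out <- lapply(conditions, function(cond) {
      cls <- rep(1:2, each = per_class)
      p <- rbind(spec$mu, spec$nu)[cls, , drop = FALSE]
      x <- matrix(as.numeric(stats::runif(length(p)) < p), ncol = 3)
      ord <- sample(nrow(x))
      data.frame(condition = cond, x1 = x[ord, 1], x2 = x[ord, 2],
                 x3 = x[ord, 3], true_class = cls[ord])
    })
    out <- do.call(rbind, out)
  })
  realized <- lapply(conditions, function(cond) {
    d <- out[out$condition == cond, ]
    t(sapply(1:2, function(y) colMeans(d[d$true_class == y, c("x1", "x2", "x3")])))
  })
  names(realized) <- conditions
  attr(out, "realized") <- realized
  attr(out, "seed") <- seed
  out
}

# resolve a responder description into per-condition 8x2 policies.
# Accepted forms:
#   - an 8x2 policy matrix (used for every condition)
#   - a named list of 8x2 policy matrices per condition
#   - list(family=, params=) with family in nb/schannel/mchannel and params a
#     per-condition list (schannel: beta; mchannel: beta, beta_u)
responder_policies <- function(responder, spec, conditions) {
  if (is.matrix(responder))
    return(stats::setNames(rep(list(responder), length(conditions)), conditions))
  stopifnot(is.list(responder))
  if (!is.null(responder$family)) {
    fam <- responder$family
    pols <- lapply(conditions, function(cond) {
      p <- responder$params[[cond]]
      switch(fam,
             nb = optimal_policy(spec),
             schannel = solve_single_channel(spec, p$beta)$policy,
             mchannel = solve_multi_channel(spec, beta = p$beta,
                                            beta_u = p$beta_u,
                                            restarts = p$restarts %||% 10,
                                            seed = p$seed %||% 1)$marginal_policy,
             stop("unknown responder family: ", fam))
    })
    return(stats::setNames(pols, conditions))
  }
  stopifnot(all(conditions %in% names(responder)))
  responder[conditions]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one subject's session from a template
#'
#' Samples a choice on every template trial from the responder's
#' condition-specific policy, issues feedback (correct iff the choice equals
#' the stochastic true class), optionally marks trials as missed, and fills
#' in a uniform reaction time below the condition deadline (1 s / 3 s / 5 s
#' for fast/medium/slow). Trials are arranged in blocks of 50 per condition.
#'
#' @param template a data frame from \code{\link{generate_template}}.
#' @param responder a policy matrix, a per-condition list of policies, or a
#'   \code{list(family =, params =)} description (see Details in
#'   \code{\link{cohort}}).
#' @param spec a \code{\link{task_spec}} (needed when \code{responder} is a
#'   family description).
#' @param seed integer seed.
#' @param miss_rate probability a trial is missed (default 0; missed trials
#'   have \code{NA} choice and feedback \code{"missed"}).
#' @param subject subject identifier (default 1).
#' @return a trial data frame (class \code{"br_trials"}) with columns
#'   \code{subject, session, block, condition, x1, x2, x3, true_class,
#'   choice, feedback, rt}; the responder description is attached as
#'   attribute \code{"generator"}.
#' @export
simulate_subject <- function(template, responder, spec = NULL, seed = 1,
                             miss_rate = 0, subject = 1) {
  conditions <- unique(template$condition)
  pols <- responder_policies(responder, spec, conditions)
  n <- nrow(template)
  out <- template
  out$subject <- subject
  out$session <- 2L
  # blocks of 50 consecutive same-condition trials
  out$block <- stats::ave(seq_len(n), out$condition,
                          FUN = function(i) (seq_along(i) - 1) %/% 50 + 1)
  with_seed(seed, {
    idx <- pattern_index_vec(paste0(out$x1, out$x2, out$x3))
    p1 <- vapply(seq_len(n), function(i) pols[[out$condition[i]]][idx[i], 1],
                 numeric(1))
    out$choice <- ifelse(stats::runif(n) < p1, 1L, 2L)
    missed <- stats::runif(n) < miss_rate
    out$choice[missed] <- NA_integer_
    out$rt <- stats::runif(n) * condition_deadlines[out$condition]
    out$rt[missed] <- NA_real_
  })
  out$feedback <- ifelse(is.na(out$choice), "missed",
                         ifelse(out$choice == out$true_class,
                                "correct", "incorrect"))
  out <- out[, c("subject", "session", "block", "condition",
                 "x1", "x2", "x3", "true_class", "choice", "feedback", "rt")]
  attr(out, "generator") <- list(responder = responder, seed = seed,
                                 miss_rate = miss_rate)
  class(out) <- c("br_trials", "data.frame")
  out
}

#' Simulate a cohort of synthetic subjects
#'
#' All subjects share one stimulus template; each subject gets their own
#' derived seed and (optionally) log-normally jittered precision parameters,
#' producing the between-subject scatter around the efficiency frontier seen
#' in real cohorts.
#'
#' @param n_subjects cohort size (the study scale is 16).
#' @param spec a \code{\link{task_spec}}.
#' @param responder \code{list(family =, params =)}: \code{family} one of
#'   \code{"nb"}, \code{"schannel"}, \code{"mchannel"}; \code{params} a named
#'   per-condition list of precision lists (\code{beta}, and \code{beta_u}
#'   for the multi-channel family).
#' @param master_seed integer master seed; per-subject seeds are derived from
#'   it.
#' @param jitter_sigma log-normal sigma applied per subject to each precision
#'   (default 0.3; 0 disables jitter).
#' @param template optional pre-built template (defaults to
#'   \code{generate_template(spec, 50, master_seed)}).
#' @param miss_rate per-trial miss probability (default 0).
#' @return list of subject trial data frames (see
#'   \code{\link{simulate_subject}}).
#' @export
cohort <- function(n_subjects, spec, responder, master_seed = 1,
                   jitter_sigma = 0.3, template = NULL, miss_rate = 0) {
  stopifnot(n_subjects >= 1)
  if (is.null(template))
    template <- generate_template(spec, 50, seed = master_seed)
  seeds <- jit <- NULL
  with_seed(master_seed, {
    seeds <- sample.int(2^31 - 2, n_subjects)
    jit <- matrix(stats::rnorm(n_subjects * 6, 0, jitter_sigma), n_subjects)
  })
  lapply(seq_len(n_subjects), function(i) {
    resp_i <- responder
    if (!is.null(responder$family) && responder$family != "nb" &&
        jitter_sigma > 0) {
      k <- 0
      for (cond in names(resp_i$params)) {
        for (pn in intersect(c("beta", "beta_u"), names(resp_i$params[[cond]]))) {
          k <- k + 1
          resp_i$params[[cond]][[pn]] <-
            resp_i$params[[cond]][[pn]] * exp(jit[i, k])
        }
      }
    }
    simulate_subject(template, resp_i, spec, seed = seeds[i],
                     miss_rate = miss_rate, subject = i)
  })
}

#' Write / read a trial log CSV
#'
#' The trial-log schema is \code{subject, session, block, condition, x1, x2,
#' x3, true_class, choice, feedback, rt}. The reader validates feedback
#' consistency and pattern validity.
#'
#' @param data a trial data frame (or list of them, row-bound on write).
#' @param path file path.
#' @return \code{read_trials} returns the validated data frame.
#' @export
write_trials <- function(data, path) {
  if (is.list(data) && !is.data.frame(data)) data <- do.call(rbind, data)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path)
  need <- c("subject", "session", "block", "condition", "x1", "x2", "x3",
            "true_class", "choice", "feedback", "rt")
  if (!all(need %in% names(d)))
    stop("trial log missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  pattern_index_vec(paste0(d$x1, d$x2, d$x3))
  ok <- ifelse(is.na(d$choice), d$feedback == "missed",
               d$feedback == ifelse(d$choice == d$true_class,
                                    "correct", "incorrect"))
  if (!all(ok)) stop("feedback inconsistent with choice/true_class at row(s) ",
                     paste(utils::head(which(!ok)), collapse = ", "))
  d
}
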
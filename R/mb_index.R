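# Model-based planning index: stay/switch logistic decomposition of two-step
# behavior. The index is the coefficient on the previous-outcome x transition
# interaction; the outcome main effect captures the model-free tendency.

#' Build the stay-regression design table
#'
#' One row per consecutive trial pair: the response is whether the first-stage
#' action was repeated, and the predictors are the previous trial's outcome
#' (`o`, +1 good / -1 bad), transition (`tau`, +1 common / -1 rare) and their
#' product. The +1/-1 coding keeps the interaction orthogonal to the main
#' effects under balanced designs.
#'
#' @param trials A two-step trial table (one or more participants) as
#'   produced by [simulate_two_step()].
#' @return A tibble with `participant_id`, `stay`, `o`, `tau`, `o_tau`.
#' @export
build_stay_table <- function(trials) {
  split <- dplyr::group_split(dplyr::group_by(trials, .data$participant_id))
  purrr::map(split, function(d) {
    d <- arrange(d, .data$trial_index)
    if (nrow(d) < 2) {
      abort(sprintf("participant %s has fewer than 2 trials",
                    d$participant_id[1]))
    }
    m <- nrow(d) - 1
    tibble(
      participant_id = d$participant_id[1],
      stay = as.integer(d$action[-1] == d$action[-nrow(d)]),
      o = ifelse(d$outcome[-nrow(d)] == "good", 1, -1),
      tau = ifelse(d$transition[-nrow(d)] == "common", 1, -1)
    ) %>% mutate(o_tau = .data$o * .data$tau)
  }) %>% bind_rows()
}

# Ridge-penalized logistic IRLS on design X (first column the intercept).
# The penalty keeps estimates finite under separation or degenerate
# responses; SEs come from the inverse penalized Hessian.
ridge_logit <- function(X, y, ridge = 1e-4, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- crossprod(X, y - mu) - ridge * beta
    H <- crossprod(X * w, X) + diag(ridge, p)
    step <- drop(solve(H, score))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(X * w, X) + diag(ridge, p)
  se <- sqrt(diag(solve(H)))
  list(beta = beta, se = se, converged = converged)
}

#' Fit the stay regression for each participant
#'
#' Maximum-likelihood logistic regression of stay on `{1, o, o * tau}` (the
#' transition main effect is optional and off by default), with a small ridge
#' penalty so estimates stay finite under separation. The model-based index is
#' the coefficient on `o * tau`. With `estimator = "pooled_shrinkage"`,
#' per-subject estimates are shrunk toward the cohort mean with
#' empirical-Bayes weights inverse to their squared SEs.
#'
#' @param stay_table Output of [build_stay_table()].
#' @param estimator `"per_subject"` (default) or `"pooled_shrinkage"`.
#' @param ridge Ridge penalty (default `1e-4`).
#' @param include_transition Include the `tau` main effect (default `FALSE`).
#' @return An `mb_index_fit`: a tibble with one row per participant
#'   (`b0_hat`, `b_mf_hat`, `b_mb_hat`, their SEs, `n_stay_events`,
#'   `converged`, `mb_index`) carrying the estimator label as an attribute.
#'   Degenerate all-stay/all-switch participants are returned with
#'   `converged = FALSE` and the ridge-stabilized estimate.
#' @export
fit_stay_regression <- function(stay_table,
                                estimator = c("per_subject", "pooled_shrinkage"),
                                ridge = 1e-4, include_transition = FALSE) {
  estimator <- match.arg(estimator)
  if (nrow(stay_table) == 0) abort("empty stay table")
  split <- dplyr::group_split(dplyr::group_by(stay_table, .data$participant_id))
  res <- purrr::map(split, function(d) {
    X <- cbind(1, d$o, d$o_tau)
    if (include_transition) X <- cbind(X, d$tau)
    fit <- ridge_logit(X, d$stay, ridge = ridge)
    degenerate <- length(unique(d$stay)) < 2
    tibble(
      participant_id = d$participant_id[1],
      b0_hat = fit$beta[1], b_mf_hat = fit$beta[2], b_mb_hat = fit$beta[3],
      b0_se = fit$se[1], b_mf_se = fit$se[2], b_mb_se = fit$se[3],
      n_stay_events = nrow(d),
      converged = fit$converged && !degenerate
    )
  }) %>% bind_rows()
  if (estimator == "pooled_shrinkage" && nrow(res) > 1) {
    res <- res %>% mutate(
      b0_hat = eb_shrink(.data$b0_hat, .data$b0_se),
      b_mf_hat = eb_shrink(.data$b_mf_hat, .data$b_mf_se),
      b_mb_hat = eb_shrink(.data$b_mb_hat, .data$b_mb_se)
    )
  }
  res <- res %>% mutate(mb_index = .data$b_mb_hat)
  structure(res, estimator = estimator, class = c("mb_index_fit", class(res)))
}

# Normal-normal empirical-Bayes shrinkage toward the cohort mean; the
# between-subject variance is a method-of-moments estimate.
eb_shrink <- function(est, se) {
  mu <- mean(est)
  tau2 <- max(0, var(est) - mean(se^2))
  w <- tau2 / (tau2 + se^2)
  mu + w * (est - mu)
}

#' Estimate model-based indices for a whole cohort
#'
#' Runs [build_stay_table()] and [fit_stay_regression()] over a cohort-level
#' trial table and returns the per-subject index column ready to join onto a
#' cohort. Participants listed in `cohort_ids` but missing a trial table are
#' flagged and excluded from the column.
#'
#' @param trials Cohort-level two-step trial table.
#' @param estimator Passed to [fit_stay_regression()].
#' @param cohort_ids Optional character vector of expected participants.
#' @return An `mb_index_fit` tibble; if `cohort_ids` is given, the attribute
#'   `missing_participants` lists ids without trials.
#' @export
estimate_cohort_indices <- function(trials,
                                    estimator = c("per_subject", "pooled_shrinkage"),
                                    cohort_ids = NULL) {
  estimator <- match.arg(estimator)
  fit <- fit_stay_regression(build_stay_table(trials), estimator = estimator)
  if (!is.null(cohort_ids)) {
    missing <- setdiff(cohort_ids, fit$participant_id)
    if (length(missing)) {
      warn(sprintf("%d participant(s) lack trial tables and were excluded",
                   length(missing)))
    }
    attr(fit, "missing_participants") <- missing
  }
  fit
}

#' @export
tidy.mb_index_fit <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("participant_id", "b0_hat", "b_mf_hat", "b_mb_hat",
           "b0_se", "b_mf_se", "b_mb_se", "converged") %>%
    tidyr::pivot_longer(cols = c("b0_hat", "b_mf_hat", "b_mb_hat"),
                        names_to = "term", values_to = "estimate") %>%
    mutate(
      term = sub("_hat$", "", .data$term),
      std.error = dplyr::case_when(
        .data$term == "b0" ~ .data$b0_se,
        .data$term == "b_mf" ~ .data$b_mf_se,
        TRUE ~ .data$b_mb_se
      )
    ) %>%
    select("participant_id", "term", "estimate", "std.error", "converged")
}

#' @export
glance.mb_index_fit <- function(x, ...) {
  tibble(
    n_participants = nrow(x),
    estimator = attr(x, "estimator"),
    mean_index = mean(x$mb_index),
    sd_index = sd(x$mb_index),
    prop_converged = mean(x$converged)
  )
}

#' @export
autoplot.mb_index_fit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mb_index)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "model-based index (outcome x transition coefficient)",
                  y = "participants",
                  title = "Distribution of estimated model-based indices") +
    ggplot2::theme_minimal()
}
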
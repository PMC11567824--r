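# Synthetic cohort generation: demographics, correlated risk factors, latent
# cognition with calibrated injected effects, and a calibrated subjective
# memory item.

#' Generate a synthetic cohort
#'
#' Draws a cross-sectional cohort whose marginal distributions, prevalences,
#' and risk-factor associations with cognition follow the supplied
#' [effect_spec()]. Risk factors share an exchangeable Gaussian copula; latent
#' continuous cognition is linear in the (analysis-coded) risk factors, age,
#' age squared and gender plus a shared factor and Gaussian noise; the binary
#' subjective memory item comes from a logistic model whose intercept is
#' calibrated so the population complaint prevalence equals the target.
#'
#' Injected effects are *marginal* targets: the direct coefficients are
#' back-solved (a linear system for continuous outcomes; pseudo-true
#' score-equation iteration for the logistic outcome) so that downstream
#' single-factor regressions adjusted for age and gender recover the injected
#' values in expectation. See the methods vignette.
#'
#' Cognition columns are emitted on interpretable scales: working-memory
#' accuracy (higher is better), flexibility completion time in seconds
#' (higher is worse), and a model-based planning index (higher is more
#' model-based). `prepare_cohort()` re-orients and standardizes them.
#'
#' @param spec An [effect_spec()].
#' @return A `CohortTable`: a tibble with one row per participant, unique
#'   `participant_id`, demographics, the thirteen risk factors, the three
#'   objective cognition columns, `subjective_memory` (0/1) and the latent
#'   task traits (`wm_trait`, `flex_trait`, `mb_trait`). No missing values.
#' @examples
#' cohort <- generate_cohort(effect_spec(n = 200, seed = 1))
#' dplyr::glimpse(cohort)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  n <- spec$n
  if (n == 0) return(attach_task_traits(empty_cohort(), spec))

  marg <- spec$marginals
  ## demographics -----------------------------------------------------------
  age <- with_seed(split_seed(spec$seed, "age"), {
    m <- marg$age
    # underlying normal chosen so the *truncated* moments match the targets
    par <- truncnorm_match(m$mean, m$sd, m$min - 0.5, m$max + 0.5)
    round(rtruncnorm(n, par$mean, par$sd, m$min - 0.5, m$max + 0.5))
  })
  age <- pmin(pmax(age, marg$age$min), marg$age$max)
  female <- with_seed(split_seed(spec$seed, "gender"),
                      rbinom(n, 1, marg$gender_female$prevalence))

  ## risk factors via exchangeable Gaussian copula --------------------------
  rho <- spec$copula_rho
  g_cop <- with_seed(split_seed(spec$seed, "copula_shared"), rnorm(n))
  factors <- risk_factor_names()
  raw <- matrix(NA_real_, n, length(factors), dimnames = list(NULL, factors))
  for (f in factors) {
    z <- with_seed(split_seed(spec$seed, paste0("factor:", f)), {
      sqrt(rho) * g_cop + sqrt(1 - rho) * rnorm(n)
    })
    m <- marg[[f]]
    raw[, f] <- if (m$type == "binary") {
      as.numeric(z > qnorm(1 - m$prevalence))
    } else {
      pmin(pmax(round(m$mean + m$sd * z), m$min), m$max)
    }
  }

  ## analysis-coded predictor matrix (oriented; z or 0/2) -------------------
  V <- analysis_code(raw)
  age_z <- gen_z(age)
  age_sq <- gen_z(age_z^2)
  fem_c <- female - mean(female)

  ## continuous latent outcomes ---------------------------------------------
  g_shared <- with_seed(split_seed(spec$seed, "shared_cognition"), rnorm(n))
  lat <- list()
  for (o in c("visual_working_memory", "cognitive_flexibility",
              "model_based_planning")) {
    m_target <- effect_vector(spec, o)
    # the empirical covariance solve needs n comfortably above the number of
    # factors; tiny cohorts fall back to direct injection
    b <- if (n >= 200) backsolve_linear(V, m_target) else m_target
    ag <- spec$age_gender_effects[[o]]
    lin <- drop(scale(V, scale = FALSE) %*% b) +
      ag[["age"]] * age_z + ag[["age_sq"]] * age_sq + ag[["female"]] * fem_c
    inter <- spec$interactions %>% filter(.data$outcome == o)
    if (nrow(inter)) {
      for (i in seq_len(nrow(inter))) {
        lin <- lin + inter$effect[i] * V[, inter$risk_factor[i]] * age_z
      }
    }
    lam <- unname(spec$trait_loadings[[o]])
    sd_e <- if (is.null(spec$noise_sd)) {
      slack <- 1 - (if (n >= 2) var(lin) else 0) - lam^2
      if (slack <= 0) {
        abort(sprintf(
          "injected effects plus shared factor explain >= unit variance for '%s'", o))
      }
      sqrt(slack)
    } else spec$noise_sd
    eps <- with_seed(split_seed(spec$seed, paste0("noise:", o)), rnorm(n, 0, sd_e))
    lat[[o]] <- lin + lam * g_shared + eps  # higher = worse
  }

  ## subjective memory item --------------------------------------------------
  m_subj <- effect_vector(spec, "subjective_memory")
  ag <- spec$age_gender_effects$subjective_memory
  offset <- ag[["age"]] * age_z + ag[["age_sq"]] * age_sq + ag[["female"]] * fem_c
  inter <- spec$interactions %>% filter(.data$outcome == "subjective_memory")
  m_inter <- setNames(inter$effect, inter$risk_factor)
  cal <- calibrate_logistic(V, m_subj, offset,
                            cbind(age = age_z, female = fem_c),
                            q = spec$subjective_prevalence,
                            age_z = age_z, m_inter = m_inter,
                            refine = n >= 200)
  subjective <- with_seed(split_seed(spec$seed, "subjective"),
                          rbinom(n, 1, plogis(cal$eta)))

  cohort <- tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = as.integer(age),
    gender = factor(ifelse(female == 1, "cis_female", "cis_male"),
                    levels = c("cis_male", "cis_female")),
    as_tibble(raw),
    subjective_memory = as.integer(subjective),
    # display scales: accuracy-like, seconds-like, index-like
    visual_working_memory = 0.80 - 0.08 * lat$visual_working_memory,
    cognitive_flexibility = 63.28 + 21.73 * lat$cognitive_flexibility,
    model_based_planning = 0.27 - 0.33 * lat$model_based_planning
  )
  attach_task_traits(cohort, spec)
}

# Standardize within the generator, degrading to zeros for degenerate
# columns (n < 2 or zero variance) instead of erroring like the analysis path.
gen_z <- function(x) {
  s <- sd(x)
  if (length(x) < 2 || is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

empty_cohort <- function() {
  tibble(
    participant_id = character(), age = integer(),
    gender = factor(character(), levels = c("cis_male", "cis_female")),
    education = numeric(), ses = numeric(), depression = numeric(),
    loneliness = numeric(), social_network = numeric(),
    hearing_handicap = numeric(), tinnitus = numeric(), stroke = numeric(),
    diabetes = numeric(), hypertension = numeric(), smoking = numeric(),
    exercise = numeric(), family_history = numeric(),
    subjective_memory = integer(),
    visual_working_memory = numeric(), cognitive_flexibility = numeric(),
    model_based_planning = numeric()
  )
}

# Orient risk factors so higher = higher risk, then code them as the analysis
# does: continuous z-scored, binaries 0/2. Zero-variance columns are returned
# as zeros (they cannot carry an effect).
analysis_code <- function(raw) {
  V <- raw
  for (f in colnames(raw)) {
    x <- raw[, f]
    if (f %in% reversed_factors()) x <- -x
    if (f %in% binary_factors()) {
      V[, f] <- 2 * x
    } else {
      V[, f] <- gen_z(x)
    }
  }
  V
}

# Solve for direct coefficients b so that, for each factor j, the simple
# covariance-based slope Cov(Vb, V_j)/Var(V_j) equals the target m_j.
backsolve_linear <- function(V, m) {
  keep <- apply(V, 2, sd) > 0
  b <- setNames(numeric(ncol(V)), colnames(V))
  if (!any(keep)) return(b)
  C <- stats::cov(V[, keep, drop = FALSE])
  rhs <- m[keep] * diag(C)
  b[keep] <- drop(solve(C + diag(1e-10, nrow(C)), rhs))
  b[!keep] <- m[!keep]
  b
}

# Calibrate the logistic linear predictor: intercept to hit prevalence q and
# (when `refine`) direct slopes — and any age-interaction coefficients — so
# the pseudo-true single-factor age+gender-adjusted logistic fits recover the
# target coefficients. Non-collapsibility of the logistic model otherwise
# attenuates them.
calibrate_logistic <- function(V, m, offset, covars, q, age_z = NULL,
                               m_inter = numeric(), refine = TRUE,
                               iters = 12, tol = 5e-4) {
  b <- m
  g <- m_inter  # direct age-interaction coefficients, start at targets
  keep <- apply(V, 2, sd) > 0
  eta_for <- function(b, g, c0) {
    eta <- c0 + drop(V %*% b) + offset
    for (f in names(g)) eta <- eta + g[[f]] * V[, f] * age_z
    eta
  }
  solve_intercept <- function(b, g) {
    uniroot(function(c0) mean(plogis(eta_for(b, g, c0))) - q,
            lower = -30, upper = 30)$root
  }
  c0 <- solve_intercept(b, g)
  if (refine && any(keep)) {
    for (it in seq_len(iters)) {
      p <- plogis(eta_for(b, g, c0))
      mhat <- vapply(colnames(V)[keep], function(f) {
        X <- cbind(1, V[, f], covars)
        pseudo_logit_fit(X, p)[2]
      }, numeric(1))
      delta <- m[keep] - mhat
      b[keep] <- b[keep] + delta
      delta_g <- numeric(length(g))
      for (i in seq_along(g)) {
        f <- names(g)[i]
        X <- cbind(1, V[, f], covars, V[, f] * age_z)
        ihat <- pseudo_logit_fit(X, p)[ncol(X)]
        delta_g[i] <- m_inter[[f]] - ihat
        g[[f]] <- g[[f]] + delta_g[i]
      }
      c0 <- solve_intercept(b, g)
      if (max(abs(c(delta, delta_g))) < tol) break
    }
  }
  list(eta = eta_for(b, g, c0), intercept = c0, direct = b, direct_inter = g)
}

# Pseudo-true logistic coefficients: Newton solve of
# sum x_i (p_i - plogis(x_i'th)) = 0 with fractional "responses" p.
pseudo_logit_fit <- function(X, p, iters = 25) {
  th <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    mu <- plogis(drop(X %*% th))
    w <- mu * (1 - mu)
    score <- crossprod(X, p - mu)
    H <- crossprod(X * w, X)
    step <- solve(H + diag(1e-10, ncol(X)), score)
    th <- th + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  drop(th)
}

#' Attach standardized latent task traits to a cohort
#'
#' Adds `wm_trait`, `flex_trait` and `mb_trait`: within-sample standardized
#' versions of the three objective cognition columns, oriented the way the
#' task simulators consume them (`wm_trait` and `mb_trait` higher = better
#' performance; `flex_trait` higher = slower, i.e. worse). Deterministic given
#' the cohort; refreshes existing trait columns.
#'
#' @param cohort A `CohortTable` with the three objective cognition columns.
#' @param spec The generating [effect_spec()] (kept for interface symmetry;
#'   the traits are pure functions of the cohort columns).
#' @return The cohort with trait columns added or refreshed.
#' @export
attach_task_traits <- function(cohort, spec = NULL) {
  need <- c("visual_working_memory", "cognitive_flexibility", "model_based_planning")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    abort(sprintf("cohort lacks cognition column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(cohort) == 0) {
    cohort$wm_trait <- numeric()
    cohort$flex_trait <- numeric()
    cohort$mb_trait <- numeric()
    return(cohort)
  }
  std <- function(x) if (length(x) > 1 && sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
  cohort %>%
    mutate(
      wm_trait = std(.data$visual_working_memory),
      flex_trait = std(.data$cognitive_flexibility),
      mb_trait = std(.data$model_based_planning)
    )
}

#' Write a cohort to CSV with a reproducibility sidecar
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param spec The generating [effect_spec()] (hashed into the sidecar).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, spec = NULL) {
  readr::write_csv(cohort, path)
  if (!is.null(spec)) write_sidecar(path, spec$seed, unclass(spec))
  invisible(path)
}
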
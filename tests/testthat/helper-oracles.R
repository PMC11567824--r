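# Independent oracles and small builders shared across tests.

# Monte-Carlo oracle for the memory-game guessing chain: simulates the pick
# process directly (vectorised over draws) and returns the mean accuracy and
# its standard error.
mc_chance_accuracy <- function(G, k, L, n_draws = 1e5, seed = 99) {
  withr::with_seed(seed, {
    c_found <- integer(n_draws)
    e <- integer(n_draws)
    active <- rep(TRUE, n_draws)
    for (step in seq_len(k + L)) {
      if (!any(active)) break
      p_hit <- (k - c_found[active]) / (G - c_found[active] - e[active])
      hit <- stats::runif(sum(active)) < p_hit
      c_found[active] <- c_found[active] + hit
      e[active] <- e[active] + !hit
      active[active] <- c_found[active] < k & e[active] < L
    }
    acc <- c_found / (c_found + e)
    list(mean = mean(acc), se = stats::sd(acc) / sqrt(n_draws))
  })
}

# Brute-force grid search over the ridge-penalized stay-regression
# log-likelihood; the oracle shares nothing with the IRLS implementation.
grid_stay_fit <- function(stay_df, ridge = 1e-4, grid = seq(-2, 2, by = 0.05)) {
  X <- cbind(1, stay_df$o, stay_df$o_tau)
  y <- stay_df$stay
  best <- c(NA, NA, NA)
  best_ll <- -Inf
  for (b0 in grid) {
    for (b1 in grid) {
      eta_base <- b0 * X[, 1] + b1 * X[, 2]
      for (b2 in grid) {
        eta <- eta_base + b2 * X[, 3]
        ll <- sum(y * eta - log1p(exp(eta))) -
          0.5 * ridge * (b0^2 + b1^2 + b2^2)
        if (ll > best_ll) {
          best_ll <- ll
          best <- c(b0, b1, b2)
        }
      }
    }
  }
  list(beta = best, loglik = best_ll)
}

# Penalized log-likelihood of a coefficient vector on a stay table (for
# comparing the implementation's optimum against the grid oracle's).
stay_penalized_loglik <- function(stay_df, beta, ridge = 1e-4) {
  eta <- beta[1] + beta[2] * stay_df$o + beta[3] * stay_df$o_tau
  sum(stay_df$stay * eta - log1p(exp(eta))) - 0.5 * ridge * sum(beta^2)
}

# A minimal raw cohort with the full schema, built from independent noise;
# individual columns can then be overwritten to construct targeted cases.
blank_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      age = sample(18:84, n, replace = TRUE),
      gender = factor(sample(c("cis_male", "cis_female"), n, replace = TRUE),
                      levels = c("cis_male", "cis_female")),
      education = sample(0:5, n, replace = TRUE),
      ses = sample(1:10, n, replace = TRUE),
      depression = sample(0:60, n, replace = TRUE),
      loneliness = sample(0:60, n, replace = TRUE),
      social_network = sample(0:30, n, replace = TRUE),
      hearing_handicap = sample(0:40, n, replace = TRUE),
      tinnitus = stats::rbinom(n, 1, 0.3),
      stroke = stats::rbinom(n, 1, 0.1),
      diabetes = stats::rbinom(n, 1, 0.1),
      hypertension = stats::rbinom(n, 1, 0.2),
      smoking = stats::rbinom(n, 1, 0.34),
      exercise = sample(0:119, n, replace = TRUE),
      family_history = stats::rbinom(n, 1, 0.17),
      subjective_memory = stats::rbinom(n, 1, 0.4),
      visual_working_memory = stats::rnorm(n, 0.8, 0.08),
      cognitive_flexibility = stats::rnorm(n, 63, 21),
      model_based_planning = stats::rnorm(n, 0.27, 0.33)
    )
  })
}

# An effect spec with every injected risk-factor effect set to zero (age,
# gender and moderation effects removed too unless kept).
null_spec <- function(n, seed, keep_age = FALSE) {
  zero <- default_effects()
  zero$effect <- 0
  ag <- if (keep_age) default_age_gender_effects() else {
    lapply(default_age_gender_effects(), function(x) x * 0)
  }
  effect_spec(n = n, seed = seed, effects = zero,
              age_gender_effects = ag,
              interactions = tibble::tibble(risk_factor = character(),
                                            outcome = character(),
                                            effect = numeric()))
}
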
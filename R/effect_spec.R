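#' Names of the modelled risk factors and cognitive outcomes
#'
#' The cohort carries thirteen self-report risk factors for dementia and four
#' cognitive outcomes: three objective executive-function measures (visual
#' working memory accuracy, cognitive flexibility completion time, a
#' model-based planning index) and one binary subjective memory complaint.
#'
#' @return A character vector of column names.
#' @export
risk_factor_names <- function() {
  c("education", "ses", "depression", "loneliness", "social_network",
    "hearing_handicap", "tinnitus", "stroke", "diabetes", "hypertension",
    "smoking", "exercise", "family_history")
}

#' @rdname risk_factor_names
#' @export
outcome_names <- function() {
  c("visual_working_memory", "cognitive_flexibility",
    "model_based_planning", "subjective_memory")
}

# Risk factors whose natural scale points toward *better* outcomes; they are
# reverse-coded before analysis so that higher always means higher risk
# ("less education", "low SES", "small social network", "less exercise").
reversed_factors <- function() c("education", "ses", "social_network", "exercise")

binary_factors <- function() {
  c("tinnitus", "stroke", "diabetes", "hypertension", "smoking", "family_history")
}

#' Default marginal distributions of the cohort variables
#'
#' Means, SDs, ranges and prevalences of the thirteen risk-factor measures and
#' the demographics, mirroring the descriptive statistics of the reference
#' smartphone cohort (N = 3327, age 18-84, 66.3% cisgender female among the
#' cisgender participants). Bounded scales are generated from latent normals
#' and then rounded and clipped to their admissible range, which slightly
#' shrinks the SD of strongly skewed scales (e.g. hearing handicap).
#'
#' @return A named list; each element describes one variable as either
#'   `list(type = "continuous", mean, sd, min, max)` (integer total scores) or
#'   `list(type = "binary", prevalence)`.
#' @export
default_marginals <- function() {
  list(
    age              = list(type = "continuous", mean = 45.74, sd = 14.55, min = 18, max = 84),
    gender_female    = list(type = "binary", prevalence = 0.663),
    education        = list(type = "continuous", mean = 2.82, sd = 1.00, min = 0, max = 5),
    ses              = list(type = "continuous", mean = 5.95, sd = 1.77, min = 1, max = 10),
    depression       = list(type = "continuous", mean = 17.96, sd = 13.59, min = 0, max = 60),
    loneliness       = list(type = "continuous", mean = 21.10, sd = 15.54, min = 0, max = 60),
    social_network   = list(type = "continuous", mean = 15.96, sd = 6.46, min = 0, max = 30),
    hearing_handicap = list(type = "continuous", mean = 5.60, sd = 7.47, min = 0, max = 40),
    tinnitus         = list(type = "binary", prevalence = 0.298),
    stroke           = list(type = "binary", prevalence = 0.014),
    diabetes         = list(type = "binary", prevalence = 0.052),
    hypertension     = list(type = "binary", prevalence = 0.154),
    smoking          = list(type = "binary", prevalence = 0.341),
    exercise         = list(type = "continuous", mean = 32.70, sd = 25.48, min = 0, max = 119),
    family_history   = list(type = "binary", prevalence = 0.168)
  )
}

#' Default injected risk-factor effects
#'
#' Target marginal associations between each (reverse-coded where applicable)
#' risk factor and each cognitive outcome, adjusted for age and gender:
#' standardized betas for the three continuous objective outcomes and log odds
#' ratios (per 0/2-coded binary or per-SD continuous predictor) for the binary
#' subjective outcome. These are *marginal* single-factor targets; the cohort
#' generator back-solves the direct coefficients so that the downstream
#' single-factor regressions recover these values in expectation (see the
#' methods vignette).
#'
#' @return A tibble with columns `risk_factor`, `outcome`, `effect`.
#' @export
default_effects <- function() {
  vals <- tibble::tribble(
    ~risk_factor,      ~visual_working_memory, ~cognitive_flexibility, ~model_based_planning, ~subjective_memory,
    "depression",        0.15, 0.11,  0.07, 0.60,
    "ses",               0.06, 0.08,  0.06, 0.50,
    "hearing_handicap",  0.04, 0.06,  0.00, 0.46,
    "loneliness",        0.07, 0.06,  0.03, 0.42,
    "education",         0.16, 0.14,  0.12, 0.33,
    "exercise",          0.02, 0.04,  0.03, 0.34,
    "smoking",           0.06, 0.07,  0.03, 0.29,
    "tinnitus",          0.01, -0.01, -0.03, 0.28,
    "social_network",    0.06, 0.07,  0.03, 0.24,
    "stroke",            0.24, 0.40,  0.06, 0.61,
    "family_history",   -0.02, 0.00,  0.00, 0.11,
    "diabetes",          0.12, 0.09,  0.01, 0.17,
    "hypertension",      0.09, 0.09,  0.02, 0.07
  )
  tidyr::pivot_longer(vals, -"risk_factor",
                      names_to = "outcome", values_to = "effect")
}

# Age (standardized, linear + re-standardized quadratic) and gender (cis-female
# dummy, cis-male reference) effects on each outcome; log-OR scale for the
# subjective outcome.
default_age_gender_effects <- function() {
  list(
    visual_working_memory = c(age = 0.20, age_sq = 0.07, female = 0.00),
    cognitive_flexibility = c(age = 0.34, age_sq = 0.13, female = -0.04),
    model_based_planning  = c(age = 0.09, age_sq = 0.07, female = 0.05),
    subjective_memory     = c(age = log(1.04), age_sq = 0, female = log(1.24))
  )
}

# Default age-moderation: smoking history's association with subjective memory
# weakens with age (log OR of the age x smoking interaction term).
default_interactions <- function() {
  tibble(risk_factor = "smoking", outcome = "subjective_memory",
         effect = log(0.87))
}

#' Build a cohort-generation specification
#'
#' Bundles everything [generate_cohort()] needs: sample size, seed, marginal
#' distributions, target risk-factor effects, subjective-complaint prevalence,
#' residual noise, and the exchangeable copula correlation among risk factors.
#'
#' @param n Number of participants (>= 0). Default 3327.
#' @param seed Integer seed; every random component derives its own stream
#'   from it, so the table is fully reproducible.
#' @param marginals Named list as produced by [default_marginals()]; entries
#'   override the defaults.
#' @param effects Tibble/data frame with columns `risk_factor`, `outcome`,
#'   `effect`: target marginal associations (see [default_effects()]).
#'   Entries override the matching defaults.
#' @param subjective_prevalence Target population prevalence of subjective
#'   memory complaints, in (0,1). Default 0.405.
#' @param noise_sd Residual SD of each latent continuous cognition variable,
#'   or `NULL` (default) to complete each latent outcome to unit variance so
#'   injected effects are directly on the standardized-beta scale.
#' @param copula_rho Exchangeable latent correlation among the thirteen risk
#'   factors (Gaussian copula). Default 0.15.
#' @param age_gender_effects Named list of per-outcome `c(age, age_sq, female)`
#'   coefficients; defaults mirror the reference cohort's descriptive models.
#' @param interactions Tibble with `risk_factor`, `outcome`, `effect`:
#'   age-by-factor moderation terms injected into the outcome model.
#' @param trait_loadings Length-3 named vector of shared-factor loadings for
#'   the three objective outcomes, inducing their mutual correlation.
#'
#' @return An object of class `effect_spec`.
#' @examples
#' spec <- effect_spec(n = 500, seed = 7)
#' cohort <- generate_cohort(spec)
#' @export
effect_spec <- function(n = 3327, seed = 1,
                        marginals = list(),
                        effects = NULL,
                        subjective_prevalence = 0.405,
                        noise_sd = NULL,
                        copula_rho = 0.15,
                        age_gender_effects = list(),
                        interactions = default_interactions(),
                        trait_loadings = c(visual_working_memory = 0.62,
                                           cognitive_flexibility = 0.55,
                                           model_based_planning = 0.28)) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    abort("`n` must be a single non-negative integer")
  }
  marg <- modifyList(default_marginals(), marginals)
  for (nm in names(marg)) {
    m <- marg[[nm]]
    if (identical(m$type, "binary")) {
      if (m$prevalence <= 0 || m$prevalence >= 1) {
        abort(sprintf("prevalence of '%s' must lie in (0, 1)", nm))
      }
    } else if (identical(m$type, "continuous")) {
      if (m$sd <= 0 || m$min >= m$max) {
        abort(sprintf("invalid continuous marginal for '%s'", nm))
      }
    } else {
      abort(sprintf("unknown marginal type for '%s'", nm))
    }
  }
  eff <- default_effects()
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    if (!all(c("risk_factor", "outcome", "effect") %in% names(effects))) {
      abort("`effects` needs columns risk_factor, outcome, effect")
    }
    bad <- setdiff(effects$risk_factor, risk_factor_names())
    if (length(bad)) abort(sprintf("unknown risk factor(s) in effects: %s",
                                   paste(bad, collapse = ", ")))
    bad <- setdiff(effects$outcome, outcome_names())
    if (length(bad)) abort(sprintf("unknown outcome(s) in effects: %s",
                                   paste(bad, collapse = ", ")))
    eff <- eff %>%
      dplyr::anti_join(effects, by = c("risk_factor", "outcome")) %>%
      bind_rows(effects)
  }
  if (subjective_prevalence <= 0 || subjective_prevalence >= 1) {
    abort("`subjective_prevalence` must lie in (0, 1)")
  }
  if (!is.null(noise_sd) && (!is.numeric(noise_sd) || any(noise_sd < 0))) {
    abort("`noise_sd` must be NULL or non-negative")
  }
  if (copula_rho < 0 || copula_rho >= 1) abort("`copula_rho` must be in [0, 1)")
  ag <- modifyList(default_age_gender_effects(), age_gender_effects)
  trait_loadings <- unlist(trait_loadings)
  if (length(trait_loadings) != 3) abort("`trait_loadings` needs 3 entries")
  if (is.null(names(trait_loadings)) || !all(nzchar(names(trait_loadings)))) {
    names(trait_loadings) <- setdiff(outcome_names(), "subjective_memory")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), marginals = marg,
         effects = eff, subjective_prevalence = subjective_prevalence,
         noise_sd = noise_sd, copula_rho = copula_rho,
         age_gender_effects = ag,
         interactions = as_tibble(interactions),
         trait_loadings = trait_loadings),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>\n")
  cat("  n:", x$n, " seed:", x$seed, "\n")
  cat("  subjective prevalence target:", x$subjective_prevalence, "\n")
  cat("  copula rho:", x$copula_rho, "\n")
  nz <- sum(x$effects$effect != 0)
  cat("  injected effects:", nz, "non-zero of", nrow(x$effects), "\n")
  invisible(x)
}

# Pull the target marginal effect vector for one outcome, ordered as
# risk_factor_names().
effect_vector <- function(spec, outcome) {
  eff <- spec$effects %>% filter(.data$outcome == .env$outcome)
  out <- setNames(numeric(length(risk_factor_names())), risk_factor_names())
  out[eff$risk_factor] <- eff$effect
  out
}

#' Read or write an effect specification as JSON
#'
#' Serializes the spec's fields (marginals, effects, prevalence, copula
#' correlation, seeds) so a run can be reproduced from a plain-text file.
#'
#' @param spec An [effect_spec()].
#' @param path File path.
#' @return `read_effect_spec()` returns an `effect_spec`;
#'   `write_effect_spec()` returns `path` invisibly.
#' @export
write_effect_spec <- function(spec, path) {
  stopifnot(inherits(spec, "effect_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_effect_spec
#' @export
read_effect_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise_sd <- raw$noise_sd
  if (length(noise_sd) == 0) noise_sd <- NULL  # NULL serializes as {}
  effect_spec(
    n = raw$n, seed = raw$seed,
    marginals = raw$marginals %||% list(),
    effects = raw$effects,
    subjective_prevalence = raw$subjective_prevalence %||% 0.405,
    noise_sd = noise_sd,
    copula_rho = raw$copula_rho %||% 0.15,
    age_gender_effects = lapply(raw$age_gender_effects %||% list(), function(x) {
      x <- unlist(x)
      if (is.null(names(x))) names(x) <- c("age", "age_sq", "female")
      x
    }),
    interactions = raw$interactions %||% default_interactions(),
    trait_loadings = unlist(raw$trait_loadings %||%
                              c(visual_working_memory = 0.62,
                                cognitive_flexibility = 0.55,
                                model_based_planning = 0.28))
  )
}
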
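# The risk-factor association suite: preparation (orientation, z-scoring, 0/2
# binary coding), descriptive age/gender models, the primary single-factor
# suite with per-outcome Bonferroni correction, quantile binarization of the
# objective outcomes, depression-adjusted models, and age-interaction models.

#' Prepare a cohort for the association analyses
#'
#' Applies the analysis coding: every variable is oriented so higher values
#' mean worse cognition or higher risk (education, SES, social network,
#' exercise, working-memory accuracy and the model-based index are
#' reverse-coded); continuous variables (independent and dependent) are
#' z-scored within sample; binary variables are coded 0/2 so a 2-unit change
#' plays the role of one SD (exactly one SD only at 50% prevalence — the
#' realized SD, `2 * sqrt(p * (1 - p))`, is recorded); gender is contrast
#' coded with cisgender male as the reference; `age_sq` is the re-standardized
#' square of standardized age. The observed subjective-complaint prevalence
#' `q` is stored for the quantile binarization.
#'
#' @param cohort A cohort tibble with demographics, the thirteen risk factors
#'   and the four cognition columns; no missing values in analysis columns.
#' @return A `prepared_cohort` tibble with attributes `q` (observed
#'   subjective prevalence), `reversed` (reoriented columns) and
#'   `binary_sds` (realized SDs of the 0/2 columns).
#' @export
prepare_cohort <- function(cohort) {
  need <- c("participant_id", "age", "gender", risk_factor_names(),
            "subjective_memory", "visual_working_memory",
            "cognitive_flexibility", "model_based_planning")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ana <- cohort[need]
  if (anyNA(ana)) abort("analysis columns contain missing values")

  reversed <- c(reversed_factors(), "visual_working_memory", "model_based_planning")
  continuous_factors <- setdiff(risk_factor_names(), binary_factors())
  out <- tibble(participant_id = cohort$participant_id)
  out$gender_female <- as.numeric(cohort$gender == "cis_female")
  out$age <- zscore(cohort$age, "age")
  out$age_sq <- zscore(out$age^2, "age_sq")

  binary_sds <- c()
  for (f in risk_factor_names()) {
    x <- cohort[[f]]
    if (f %in% reversed) x <- -x
    if (f %in% binary_factors()) {
      if (!all(cohort[[f]] %in% c(0, 1))) {
        abort(sprintf("binary factor '%s' must be 0/1 in the raw cohort", f))
      }
      out[[f]] <- 2 * cohort[[f]]
      p <- mean(cohort[[f]])
      if (p %in% c(0, 1)) abort(sprintf("zero-variance column: %s", f))
      binary_sds[f] <- 2 * sqrt(p * (1 - p))
    } else {
      out[[f]] <- zscore(x, f)
    }
  }
  for (o in c("visual_working_memory", "cognitive_flexibility",
              "model_based_planning")) {
    x <- cohort[[o]]
    if (o %in% reversed) x <- -x
    out[[o]] <- zscore(x, o)
  }
  if (!all(cohort$subjective_memory %in% c(0, 1))) {
    abort("subjective_memory must be 0/1")
  }
  q <- mean(cohort$subjective_memory)
  if (q %in% c(0, 1)) abort("zero-variance column: subjective_memory")
  out$subjective_memory <- 2 * cohort$subjective_memory
  binary_sds["subjective_memory"] <- 2 * sqrt(q * (1 - q))

  structure(out, q = q, reversed = reversed, binary_sds = binary_sds,
            class = c("prepared_cohort", class(out)))
}

# Binary response on the 0/1 scale for logistic fits (stored 0/2 as a
# predictor coding only).
binary_response <- function(prep, outcome) {
  y <- prep[[outcome]]
  if (all(y %in% c(0, 2))) y <- y / 2
  y
}

is_binary_outcome <- function(prep, outcome) {
  all(prep[[outcome]] %in% c(0, 1, 2))
}

# Fit one association model and return a one-row tidy result for `term`.
fit_one <- function(prep, outcome, rhs_terms, term, covariates_label,
                    alpha = 0.05) {
  logistic <- is_binary_outcome(prep, outcome)
  dat <- as_tibble(prep)
  if (logistic) dat[[outcome]] <- binary_response(prep, outcome)
  fml <- stats::reformulate(rhs_terms, response = outcome)
  if (logistic) {
    fit <- glm(fml, data = dat, family = binomial())
    if (!fit$converged) warn(sprintf("glm did not converge: %s ~ %s",
                                     outcome, paste(rhs_terms, collapse = "+")))
    s <- summary(fit)$coefficients
    beta <- s[term, "Estimate"]; se <- s[term, "Std. Error"]
    stat <- s[term, "z value"]; p <- s[term, "Pr(>|z|)"]
    or_value <- exp(beta)
    ci <- exp(beta + c(-1, 1) * qnorm(0.975) * se)
  } else {
    fit <- lm(fml, data = dat)
    s <- summary(fit)$coefficients
    beta <- s[term, "Estimate"]; se <- s[term, "Std. Error"]
    stat <- s[term, "t value"]; p <- s[term, "Pr(>|t|)"]
    or_value <- NA_real_
    ci <- beta + c(-1, 1) * qt(0.975, df = fit$df.residual) * se
  }
  tibble(
    outcome = outcome, term = term, covariates = covariates_label,
    family = if (logistic) "logistic" else "linear",
    beta = beta, se = se, statistic = stat, p_value = p,
    or_value = or_value,
    ci_low = ci[1], ci_high = ci[2],
    alpha = alpha, significant = p < alpha,
    n = nrow(dat)
  )
}

#' Single risk-factor association model
#'
#' Fits one model predicting a cognitive outcome from one risk factor plus
#' covariates: linear regression with standardized coefficients for
#' continuous outcomes, logistic regression with odds ratios and Wald 95% CIs
#' for binary outcomes (the OR equals `exp(beta)` on the 0/2 predictor
#' coding). Perfect separation is intercepted by `glm`'s convergence flag and
#' surfaced as a warning.
#'
#' @param prep A [prepare_cohort()] result.
#' @param outcome,risk_factor Column names in `prep`.
#' @param covariates Character vector of adjustment variables; default
#'   `c("age", "gender_female")`.
#' @param alpha Significance threshold recorded with the result.
#' @return A one-row tibble (`AssociationResult`): `outcome`, `term`,
#'   `covariates`, `family`, `beta`, `se`, `statistic`, `p_value`,
#'   `or_value`, `ci_low`, `ci_high`, `alpha`, `significant`, `n`. For
#'   linear fits the CI is on the beta scale; for logistic fits it is the OR
#'   interval.
#' @export
fit_association <- function(prep, outcome, risk_factor,
                            covariates = c("age", "gender_female"),
                            alpha = 0.05) {
  stopifnot(inherits(prep, "prepared_cohort"))
  lab <- covariates_label(covariates)
  fit_one(prep, outcome, c(risk_factor, covariates), risk_factor, lab, alpha) %>%
    rename(risk_factor = "term")
}

covariates_label <- function(covariates) {
  if (setequal(covariates, c("age", "gender_female"))) return("age_gender")
  if (setequal(covariates, c("age", "gender_female", "depression"))) {
    return("age_gender_depression")
  }
  paste(sort(covariates), collapse = "+")
}

#' Descriptive age and gender models
#'
#' For each cognitive outcome fits `outcome ~ age + age_sq + gender_female`
#' (linear for the three objective measures, logistic for the subjective
#' item), reporting standardized betas or ORs with 95% CIs. The quadratic
#' age term appears only in these descriptive models; the association suites
#' adjust for linear age alone.
#'
#' @param prep A [prepare_cohort()] result.
#' @return A tidy tibble with one row per model term (intercept omitted).
#' @export
descriptive_age_gender_models <- function(prep) {
  stopifnot(inherits(prep, "prepared_cohort"))
  purrr::map_dfr(outcome_names(), function(o) {
    purrr::map_dfr(c("age", "age_sq", "gender_female"), function(tm) {
      fit_one(prep, o, c("age", "age_sq", "gender_female"), tm,
              "age_quadratic_gender")
    })
  })
}

#' Correlations between the cognitive measures
#'
#' Pearson product-moment correlations for pairs of continuous measures; for
#' pairs of one continuous measure and the binary subjective item both the
#' point-biserial correlation and a two-step polyserial estimate are
#' reported. The polyserial estimate divides the point-biserial correlation
#' by `dnorm(qnorm(p)) / sqrt(p * (1 - p))`, the attenuation factor implied
#' by dichotomizing a latent normal at the observed prevalence `p`.
#'
#' @param prep A [prepare_cohort()] result.
#' @return A tibble with `var1`, `var2`, `method`
#'   (`"pearson"`, `"point_biserial"`, `"polyserial"`), `estimate`.
#' @export
correlate_measures <- function(prep) {
  stopifnot(inherits(prep, "prepared_cohort"))
  vars <- outcome_names()
  for (v in vars) {
    if (sd(prep[[v]]) == 0) abort(sprintf("constant column: %s", v))
  }
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- prep[[pr[1]]]; y <- prep[[pr[2]]]
    bx <- is_binary_outcome(prep, pr[1]); by <- is_binary_outcome(prep, pr[2])
    if (!bx && !by) {
      tibble(var1 = pr[1], var2 = pr[2], method = "pearson",
             estimate = cor(x, y))
    } else {
      if (bx) { tmp <- x; x <- y; y <- tmp }  # y is the binary one
      yb <- as.numeric(y > 0)
      p <- mean(yb)
      r_pb <- cor(x, yb)
      r_ps <- r_pb * sqrt(p * (1 - p)) / dnorm(qnorm(p))
      tibble(var1 = pr[1], var2 = pr[2],
             method = c("point_biserial", "polyserial"),
             estimate = c(r_pb, max(-1, min(1, r_ps))))
    }
  })
}

#' Binarize the objective cognitive outcomes at the subjective prevalence
#'
#' Dichotomizes each (worseness-oriented) objective score at the empirical
#' quantile matching the observed subjective-complaint prevalence `q`: the
#' worst `round(q * n)` participants are flagged as having poor performance.
#' Ties at the boundary are broken by a stable sort on (score, then
#' participant id), so the flagged count is exact regardless of ties.
#'
#' @param prep A [prepare_cohort()] result.
#' @param q Flagged proportion; defaults to the stored subjective prevalence.
#' @return `prep` with added 0/1 columns `<outcome>_poor` and attribute
#'   `n_flagged`.
#' @export
binarize_objective <- function(prep, q = NULL) {
  stopifnot(inherits(prep, "prepared_cohort"))
  q <- q %||% attr(prep, "q")
  if (is.null(q) || q < 0 || q > 1) abort("`q` must lie in [0, 1]")
  n <- nrow(prep)
  m <- round(q * n)
  for (o in c("visual_working_memory", "cognitive_flexibility",
              "model_based_planning")) {
    ord <- order(-prep[[o]], prep$participant_id)  # worst first, stable ties
    flag <- integer(n)
    flag[ord[seq_len(m)]] <- 1L
    prep[[paste0(o, "_poor")]] <- flag
  }
  attr(prep, "n_flagged") <- m
  prep
}

# Shared engine: one single-factor model per (outcome, factor) pair.
run_suite <- function(prep, outcomes, factors, covariates, alpha,
                      covariate_label) {
  purrr::map_dfr(outcomes, function(o) {
    purrr::map_dfr(factors, function(f) {
      fit_one(prep, o, c(f, covariates), f, covariate_label, alpha) %>%
        rename(risk_factor = "term")
    })
  }) %>%
    group_by(.data$outcome) %>%
    arrange(desc(abs(.data$beta)), .by_group = TRUE) %>%
    ungroup()
}

#' Primary association suite
#'
#' One model per risk factor and cognitive outcome, adjusted for age and
#' gender: 13 x 3 linear models for the objective outcomes, 13 logistic
#' models for the subjective item (52 models), plus 13 x 3 logistic models on
#' the quantile-binarized objective outcomes (39 models) so odds ratios are
#' directly comparable across outcomes. Bonferroni correction is per
#' dependent variable: `alpha = 0.05 / 13`.
#'
#' @param prep A [prepare_cohort()] result.
#' @param alpha_total Family-wise alpha before division (default 0.05).
#' @return An `assoc_suite` tibble (column `model_type` separates
#'   `"primary"` from `"binarized"` rows) with attributes `alpha`,
#'   `n_models`, `suite`.
#' @examples
#' prep <- prepare_cohort(generate_cohort(effect_spec(n = 400, seed = 2)))
#' suite <- run_primary_suite(prep)
#' glance(suite)
#' @export
run_primary_suite <- function(prep, alpha_total = 0.05) {
  stopifnot(inherits(prep, "prepared_cohort"))
  alpha <- alpha_total / length(risk_factor_names())
  primary <- run_suite(prep, outcome_names(), risk_factor_names(),
                       c("age", "gender_female"), alpha, "age_gender") %>%
    mutate(model_type = "primary")
  prep_b <- binarize_objective(prep)
  bin <- run_suite(prep_b,
                   paste0(c("visual_working_memory", "cognitive_flexibility",
                            "model_based_planning"), "_poor"),
                   risk_factor_names(), c("age", "gender_female"), alpha,
                   "age_gender") %>%
    mutate(model_type = "binarized")
  res <- bind_rows(primary, bin)
  structure(res, alpha = alpha, n_models = nrow(res), suite = "primary",
            class = c("assoc_suite", class(res)))
}

#' Depression-adjusted association suite
#'
#' Repeats the primary single-factor models for the 12 risk factors other
#' than depression, additionally adjusting for depression (CES-D total):
#' 12 x 4 models. Significance is still judged at the primary per-outcome
#' Bonferroni threshold `0.05 / 13`.
#'
#' @inheritParams run_primary_suite
#' @return An `assoc_suite` tibble with attributes `alpha`, `n_models`.
#' @export
run_depression_adjusted <- function(prep, alpha_total = 0.05) {
  stopifnot(inherits(prep, "prepared_cohort"))
  alpha <- alpha_total / length(risk_factor_names())
  factors <- setdiff(risk_factor_names(), "depression")
  res <- run_suite(prep, outcome_names(), factors,
                   c("age", "gender_female", "depression"), alpha,
                   "age_gender_depression") %>%
    mutate(model_type = "depression_adjusted")
  structure(res, alpha = alpha, n_models = nrow(res),
            suite = "depression_adjusted",
            class = c("assoc_suite", class(res)))
}

#' Age-interaction suite
#'
#' For each (risk factor, outcome) pair that was significant in the primary
#' suite, refits the age+gender-adjusted model with an added age x factor
#' interaction term and reports that term, at `alpha = 0.05 / n_pairs`.
#'
#' @param prep A [prepare_cohort()] result.
#' @param significant_pairs Tibble with columns `risk_factor`, `outcome`;
#'   see [significant_primary_pairs()]. An empty set yields an empty table.
#' @param alpha_total Family-wise alpha before division (default 0.05).
#' @return An `assoc_suite` tibble of interaction terms (`InteractionResult`
#'   rows) with attributes `alpha`, `n_models`.
#' @export
run_age_interaction_suite <- function(prep, significant_pairs,
                                      alpha_total = 0.05) {
  stopifnot(inherits(prep, "prepared_cohort"))
  pairs <- as_tibble(significant_pairs)
  if (nrow(pairs) == 0) {
    res <- tibble(outcome = character(), risk_factor = character(),
                  covariates = character(), family = character(),
                  beta = numeric(), se = numeric(), statistic = numeric(),
                  p_value = numeric(), or_value = numeric(),
                  ci_low = numeric(), ci_high = numeric(), alpha = numeric(),
                  significant = logical(), n = integer(),
                  model_type = character())
    return(structure(res, alpha = NA_real_, n_models = 0L,
                     suite = "age_interaction",
                     class = c("assoc_suite", class(res))))
  }
  alpha <- alpha_total / nrow(pairs)
  res <- purrr::pmap_dfr(pairs[c("risk_factor", "outcome")],
                         function(risk_factor, outcome) {
    inter <- paste0(risk_factor, ":age")
    fit_one(prep, outcome,
            c(risk_factor, "age", "gender_female", inter),
            inter, "age_gender", alpha) %>%
      rename(interaction = "term") %>%
      mutate(risk_factor = risk_factor, .after = "outcome")
  }) %>%
    mutate(model_type = "age_interaction")
  structure(res, alpha = alpha, n_models = nrow(res),
            suite = "age_interaction",
            class = c("assoc_suite", class(res)))
}

#' Significant (factor, outcome) pairs from the primary suite
#'
#' @param suite A [run_primary_suite()] result.
#' @return Tibble of `risk_factor`, `outcome` for the non-binarized models
#'   significant at the suite's per-outcome Bonferroni alpha.
#' @export
significant_primary_pairs <- function(suite) {
  stopifnot(inherits(suite, "assoc_suite"))
  suite %>%
    as_tibble() %>%
    filter(.data$model_type == "primary", .data$significant) %>%
    select("risk_factor", "outcome")
}

#' @export
tidy.assoc_suite <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.assoc_suite <- function(x, ...) {
  tibble(
    suite = attr(x, "suite"),
    n_models = attr(x, "n_models"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant)
  )
}

#' @export
print.assoc_suite <- function(x, ...) {
  cat(sprintf("<assoc_suite: %s> %d models, alpha = %.4f, %d significant\n",
              attr(x, "suite"), attr(x, "n_models"), attr(x, "alpha"),
              sum(x$significant)))
  NextMethod()
}

#' Forest plot of an association suite
#'
#' Estimates (standardized betas for linear fits, odds ratios for logistic
#' fits) with 95% CIs, faceted by outcome, significant results filled.
#'
#' @param object An `assoc_suite`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_suite <- function(object, ...) {
  dat <- as_tibble(object) %>%
    mutate(
      estimate = ifelse(.data$family == "logistic", .data$or_value, .data$beta),
      ref = ifelse(.data$family == "logistic", 1, 0)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$risk_factor)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$ref),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant), shape = 21) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::facet_wrap(~ outcome, scales = "free_x") +
    ggplot2::labs(x = "standardized beta (linear) / OR (logistic)",
                  y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}
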
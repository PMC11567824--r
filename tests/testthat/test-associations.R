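prep_default <- function(n = 1200, seed = 44) {
  prepare_cohort(generate_cohort(effect_spec(n = n, seed = seed)))
}

test_that("preparation standardizes, recodes and orients as specified", {
  prep <- prep_default(800, 3)
  for (v in c("age", "depression", "loneliness", "visual_working_memory",
              "cognitive_flexibility", "model_based_planning")) {
    expect_lt(abs(mean(prep[[v]])), 1e-10)
    expect_lt(abs(sd(prep[[v]]) - 1), 1e-10)
  }
  for (v in c("tinnitus", "stroke", "smoking", "subjective_memory")) {
    expect_true(all(prep[[v]] %in% c(0, 2)), info = v)
  }
  expect_true(all(prep$gender_female %in% 0:1))
  expect_equal(attr(prep, "q"),
               mean(prep$subjective_memory / 2))
  # orientation: worse memory accuracy means a higher prepared score
  co <- generate_cohort(effect_spec(n = 800, seed = 3))
  expect_lt(cor(co$visual_working_memory, prep$visual_working_memory), -0.99)
})

test_that("0/2 coding gives population SD 1 only at 50% prevalence", {
  co <- blank_cohort(1000, seed = 2)
  co$smoking <- rep(c(0L, 1L), 500)
  prep <- prepare_cohort(co)
  sds <- attr(prep, "binary_sds")
  expect_equal(unname(sds["smoking"]), 1)  # 2*sqrt(.5*.5), exact algebra
  co$tinnitus <- rep(c(rep(1L, 405), rep(0L, 595)))
  prep <- prepare_cohort(co)
  expect_equal(unname(attr(prep, "binary_sds")["tinnitus"]),
               2 * sqrt(0.405 * 0.595))
  expect_equal(unname(attr(prep, "binary_sds")["tinnitus"]), 0.9819,
               tolerance = 1e-3)  # 2*sqrt(0.405*0.595) = 0.98178
})

test_that("zero-variance columns fail with the offending name", {
  co <- blank_cohort(100, seed = 5)
  co$loneliness <- 7
  expect_error(prepare_cohort(co), "loneliness")
  co <- blank_cohort(100, seed = 5)
  co$stroke <- 0L
  expect_error(prepare_cohort(co), "stroke")
})

test_that("single-factor fits report coherent ORs, CIs and estimator properties", {
  prep <- prep_default(1500, 7)
  fit <- fit_association(prep, "subjective_memory", "depression")
  expect_equal(fit$or_value, exp(fit$beta))  # machine precision link
  expect_lt(fit$ci_low, fit$or_value)
  expect_gt(fit$ci_high, fit$or_value)
  expect_equal(fit$family, "logistic")

  lin <- fit_association(prep, "visual_working_memory", "depression")
  expect_equal(lin$family, "linear")
  expect_true(is.na(lin$or_value))

  # duplicating the sample leaves beta fixed and shrinks the SE by ~sqrt(2)
  co <- generate_cohort(effect_spec(n = 700, seed = 21))
  doubled <- dplyr::bind_rows(co, dplyr::mutate(
    co, participant_id = paste0(participant_id, "b")))
  f1 <- fit_association(prepare_cohort(co), "cognitive_flexibility", "smoking")
  f2 <- fit_association(prepare_cohort(doubled), "cognitive_flexibility", "smoking")
  # re-preparation z-scores with the n-1 denominator, so equality is up to
  # the sqrt(2(n-1)/(2n-1)) scale factor, not machine precision
  expect_equal(f2$beta, f1$beta, tolerance = 1e-3)
  expect_equal(f2$se, f1$se / sqrt(2), tolerance = 0.01)
})

test_that("standardized betas are invariant to positive rescaling of the raw predictor", {
  co <- generate_cohort(effect_spec(n = 900, seed = 12))
  f1 <- fit_association(prepare_cohort(co), "visual_working_memory", "depression")
  co$depression <- co$depression * 7.3
  f2 <- fit_association(prepare_cohort(co), "visual_working_memory", "depression")
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
})

test_that("measure correlations use Pearson, point-biserial and polyserial correctly", {
  co <- blank_cohort(600, seed = 9)
  co$cognitive_flexibility <- -3 * co$visual_working_memory  # same after orientation
  prep <- prepare_cohort(co)
  cm <- correlate_measures(prep)
  r <- cm$estimate[cm$var1 == "visual_working_memory" &
                     cm$var2 == "cognitive_flexibility"]
  expect_equal(r, 1.0)
  # independent columns: all correlations near zero
  co2 <- blank_cohort(10000, seed = 10)
  cm2 <- correlate_measures(prepare_cohort(co2))
  expect_true(all(abs(cm2$estimate) < 0.03))
  # a latent rho = 0.3 pair dichotomized at 40.5%: the polyserial estimate
  # recovers rho while the point-biserial is attenuated
  n <- 2e4
  withr::with_seed(11, {
    x <- rnorm(n)
    y_lat <- 0.3 * x + sqrt(1 - 0.09) * rnorm(n)
  })
  co3 <- blank_cohort(n, seed = 12)
  co3$visual_working_memory <- -x  # reversed on preparation
  co3$subjective_memory <- as.integer(y_lat > qnorm(1 - 0.405))
  cm3 <- correlate_measures(prepare_cohort(co3))
  ps <- cm3$estimate[cm3$var1 == "visual_working_memory" &
                       cm3$var2 == "subjective_memory" &
                       cm3$method == "polyserial"]
  pb <- cm3$estimate[cm3$var1 == "visual_working_memory" &
                       cm3$var2 == "subjective_memory" &
                       cm3$method == "point_biserial"]
  expect_equal(ps, 0.3, tolerance = 0.04)
  expect_lt(pb, ps)
  co3$visual_working_memory <- 0.5
  expect_error(correlate_measures(prepare_cohort(co3)), "visual_working_memory")
})

test_that("quantile binarization flags exactly round(q * n), ties included", {
  co <- blank_cohort(1000, seed = 14)
  co$subjective_memory <- c(rep(1L, 405), rep(0L, 595))
  prep <- prepare_cohort(co)
  b <- binarize_objective(prep)
  expect_equal(attr(b, "n_flagged"), 405)
  for (o in c("visual_working_memory", "cognitive_flexibility",
              "model_based_planning")) {
    expect_equal(sum(b[[paste0(o, "_poor")]]), 405, info = o)
  }
  expect_equal(sum(binarize_objective(prep, q = 0)$visual_working_memory_poor), 0)
  expect_error(binarize_objective(prep, q = 1.5), "q")
  # 600 tied boundary scores cannot inflate the flagged count
  co$model_based_planning <- c(seq_len(400) / 1000, rep(0.05, 600))
  b2 <- binarize_objective(prepare_cohort(co))
  expect_equal(sum(b2$model_based_planning_poor), 405)
})

test_that("the primary suite has the stated shape, alpha and sign recovery", {
  prep <- prepare_cohort(generate_cohort(effect_spec(n = 3327, seed = 55)))
  suite <- run_primary_suite(prep)
  expect_s3_class(suite, "assoc_suite")
  expect_equal(sum(suite$model_type == "primary"), 52)
  expect_equal(sum(suite$model_type == "binarized"), 39)
  expect_equal(attr(suite, "alpha"), 0.05 / 13)
  expect_equal(round(attr(suite, "alpha"), 4), 0.0038)
  # injected associations of magnitude >= 0.06 come back with their sign
  # (rare binaries like stroke carry large SEs, so >= 90% rather than all)
  big <- default_effects() %>% dplyr::filter(abs(effect) >= 0.06)
  got <- suite %>% tidy() %>% dplyr::filter(model_type == "primary")
  joined <- dplyr::inner_join(big, got, by = c("risk_factor", "outcome"))
  expect_gte(mean(sign(joined$beta) == sign(joined$effect)), 0.9)
})

test_that("the depression-adjusted suite drops depression and keeps 48 models", {
  prep <- prep_default(1000, 17)
  adj <- run_depression_adjusted(prep)
  expect_equal(nrow(adj), 48)
  expect_false("depression" %in% adj$risk_factor)
  expect_true(all(adj$covariates == "age_gender_depression"))
})

test_that("adjusting for depression removes a purely depression-mediated effect", {
  n <- 4000
  co <- blank_cohort(n, seed = 19)
  withr::with_seed(20, {
    lon <- rnorm(n)
    dep <- 0.7 * lon + sqrt(1 - 0.49) * rnorm(n)
    wm_worse <- 0.3 * dep + sqrt(1 - 0.09) * rnorm(n)
  })
  co$loneliness <- round(pmin(pmax(21 + 15 * lon, 0), 60))
  co$depression <- round(pmin(pmax(18 + 13 * dep, 0), 60))
  co$visual_working_memory <- 0.8 - 0.08 * wm_worse
  prep <- prepare_cohort(co)
  raw <- fit_association(prep, "visual_working_memory", "loneliness")
  adj <- fit_association(prep, "visual_working_memory", "loneliness",
                         covariates = c("age", "gender_female", "depression"))
  expect_gt(raw$beta, 0.15)
  expect_lt(abs(adj$beta), 2.5 * adj$se)
  # while a factor independent of depression is barely moved by adjustment
  f_raw <- fit_association(prep, "visual_working_memory", "exercise")
  f_adj <- fit_association(prep, "visual_working_memory", "exercise",
                           covariates = c("age", "gender_female", "depression"))
  expect_lt(abs(f_raw$beta - f_adj$beta), 0.02)
})

test_that("descriptive models recover linear and quadratic age structure", {
  prep <- prepare_cohort(generate_cohort(effect_spec(n = 3327, seed = 23)))
  desc <- descriptive_age_gender_models(prep)
  expect_equal(nrow(desc), 12)  # 4 outcomes x 3 terms
  age_flex <- desc %>%
    dplyr::filter(outcome == "cognitive_flexibility", term == "age")
  expect_lt(abs(age_flex$beta - 0.34), 2 * age_flex$se)
  # a quadratic-only generative age effect loads on age_sq, not age
  spec_q <- effect_spec(
    n = 3000, seed = 29,
    effects = dplyr::mutate(default_effects(), effect = 0),
    age_gender_effects = list(
      visual_working_memory = c(age = 0, age_sq = 0.3, female = 0)),
    interactions = tibble::tibble(risk_factor = character(),
                                  outcome = character(), effect = numeric()))
  desc_q <- descriptive_age_gender_models(prepare_cohort(generate_cohort(spec_q)))
  wm_rows <- desc_q %>% dplyr::filter(outcome == "visual_working_memory")
  lin <- wm_rows[wm_rows$term == "age", ]
  quad <- wm_rows[wm_rows$term == "age_sq", ]
  expect_lt(abs(lin$beta), 3 * lin$se)
  expect_lt(abs(quad$beta - 0.3), 3 * quad$se)
})

test_that("the age-interaction suite scopes to significant pairs and its alpha", {
  prep <- prep_default(1500, 31)
  empty <- run_age_interaction_suite(prep, tibble::tibble(
    risk_factor = character(), outcome = character()))
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "assoc_suite")

  pairs31 <- tidyr::expand_grid(risk_factor = risk_factor_names(),
                                outcome = outcome_names())[1:31, ]
  suite <- run_age_interaction_suite(prep, pairs31)
  expect_equal(nrow(suite), 31)
  expect_equal(round(attr(suite, "alpha"), 4), 0.0016)

  # the injected smoking x age moderation of subjective memory is recovered
  prep_big <- prepare_cohort(generate_cohort(effect_spec(n = 3327, seed = 37)))
  one <- run_age_interaction_suite(
    prep_big, tibble::tibble(risk_factor = "smoking",
                             outcome = "subjective_memory"))
  expect_equal(one$family, "logistic")
  expect_true(one$ci_low <= 0.87 && 0.87 <= one$ci_high)
})

test_that("suite objects tidy, glance and plot", {
  prep <- prep_default(500, 41)
  suite <- run_primary_suite(prep)
  td <- tidy(suite)
  expect_s3_class(td, "tbl_df")
  g <- glance(suite)
  expect_equal(g$n_models, 91)
  p <- autoplot(suite)
  expect_s3_class(p, "ggplot")
  pairs <- significant_primary_pairs(suite)
  expect_true(all(c("risk_factor", "outcome") %in% names(pairs)))
})
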
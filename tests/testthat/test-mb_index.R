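test_that("the stay table counts, codes and hand derivation are right", {
  ts <- simulate_two_step(two_step_params(), n_trials = 200, seed = 1)
  st <- build_stay_table(ts)
  expect_equal(nrow(st), 199)
  expect_true(all(st$o %in% c(-1, 1)))
  expect_true(all(st$o_tau == st$o * st$tau))

  alt <- tibble::tibble(participant_id = "X", trial_index = 1:6,
                        action = rep(c(0L, 1L), 3),
                        transition = "common", outcome = "good",
                        stay_next = NA_integer_)
  expect_true(all(build_stay_table(alt)$stay == 0))

  hand <- tibble::tibble(
    participant_id = "H", trial_index = 1:4,
    action = c(0L, 0L, 1L, 1L),
    transition = c("common", "rare", "common", "common"),
    outcome = c("good", "bad", "bad", "good"),
    stay_next = NA_integer_)
  st_h <- build_stay_table(hand)
  expect_equal(st_h$stay, c(1L, 0L, 1L))
  expect_equal(st_h$o, c(1, -1, -1))
  expect_equal(st_h$tau, c(1, -1, 1))
  expect_equal(st_h$o_tau, c(1, 1, -1))

  expect_error(build_stay_table(hand[1, ]), "fewer than 2")
})

test_that("null responses give a near-zero interaction estimate", {
  st <- withr::with_seed(3, tibble::tibble(
    participant_id = "N",
    stay = rbinom(1e4, 1, 0.5),
    o = sample(c(-1, 1), 1e4, replace = TRUE),
    tau = sample(c(-1, 1), 1e4, replace = TRUE)) %>%
      dplyr::mutate(o_tau = o * tau))
  fit <- fit_stay_regression(st)
  expect_lt(abs(fit$b_mb_hat), 3 * fit$b_mb_se)
  expect_true(fit$converged)
})

test_that("an agent's stay weights are recovered from long sessions", {
  ts <- simulate_two_step(two_step_params(b0 = 0, b_mf = 0.5, b_mb = 1),
                          n_trials = 1e4, seed = 8)
  fit <- fit_stay_regression(build_stay_table(ts))
  expect_lt(abs(fit$b_mb_hat - 1), 0.1)
  expect_lt(abs(fit$b_mf_hat - 0.5), 0.1)
})

test_that("the ridge fit matches a brute-force likelihood grid and stats::glm", {
  # four observations per (o, o*tau) cell with stay counts 3/2/2/1, so the
  # penalized optimum is interior (b0 = 0, b_mf = b_mb = logit(0.75)/2)
  cells <- tibble::tibble(o = c(1, 1, -1, -1), tau = c(1, -1, -1, 1),
                          stays = c(3L, 2L, 2L, 1L))
  st <- purrr::pmap_dfr(cells, function(o, tau, stays) {
    tibble::tibble(participant_id = "W", stay = rep(c(1L, 0L), c(stays, 4 - stays)),
                   o = o, tau = tau)
  }) %>% dplyr::mutate(o_tau = o * tau)
  fit <- fit_stay_regression(st)
  beta_hat <- c(fit$b0_hat, fit$b_mf_hat, fit$b_mb_hat)
  oracle <- grid_stay_fit(st)
  expect_lt(max(abs(beta_hat - oracle$beta)), 0.05)
  expect_gte(stay_penalized_loglik(st, beta_hat), oracle$loglik)

  ts <- simulate_two_step(two_step_params(), n_trials = 500, seed = 4)
  st2 <- build_stay_table(ts)
  g <- glm(stay ~ o + o_tau, data = st2, family = binomial())
  fit2 <- fit_stay_regression(st2, ridge = 1e-10)
  expect_equal(c(fit2$b0_hat, fit2$b_mf_hat, fit2$b_mb_hat),
               unname(coef(g)), tolerance = 1e-4)
})

test_that("degenerate all-stay data is flagged but stays finite", {
  st <- tibble::tibble(participant_id = "D", stay = 1L,
                       o = rep(c(-1, 1), 10), tau = rep(c(1, -1), 10)) %>%
    dplyr::mutate(o_tau = o * tau)
  fit <- fit_stay_regression(st)
  expect_false(fit$converged)
  expect_true(all(is.finite(c(fit$b0_hat, fit$b_mf_hat, fit$b_mb_hat))))
})

test_that("flipping the outcome coding flips the fitted weights coherently", {
  ts <- simulate_two_step(two_step_params(b0 = 0.2, b_mf = 0.6, b_mb = 0.8),
                          n_trials = 2000, seed = 9)
  st <- build_stay_table(ts)
  flipped <- st %>% dplyr::mutate(o = -o, o_tau = o * tau)
  f1 <- fit_stay_regression(st)
  f2 <- fit_stay_regression(flipped)
  expect_equal(f2$b_mf_hat, -f1$b_mf_hat, tolerance = 1e-8)
  expect_equal(f2$b_mb_hat, -f1$b_mb_hat, tolerance = 1e-8)
  expect_equal(f2$b0_hat, f1$b0_hat, tolerance = 1e-8)
})

test_that("shrinkage reduces between-subject variance and is idle for one subject", {
  tabs <- purrr::map(1:40, function(i) {
    simulate_two_step(two_step_params(b0 = 0.3, b_mf = 0.4,
                                      b_mb = runif(1, 0, 1.5)),
                      n_trials = 120, seed = 200 + i,
                      participant_id = sprintf("S%03d", i))
  }) %>% dplyr::bind_rows()
  st <- build_stay_table(tabs)
  per <- fit_stay_regression(st, estimator = "per_subject")
  pool <- fit_stay_regression(st, estimator = "pooled_shrinkage")
  expect_lte(var(pool$b_mb_hat), var(per$b_mb_hat))
  one <- st %>% dplyr::filter(participant_id == "S001")
  expect_equal(fit_stay_regression(one, estimator = "pooled_shrinkage")$b_mb_hat,
               fit_stay_regression(one, estimator = "per_subject")$b_mb_hat)
})

test_that("cohort index estimation matches the injected index distribution", {
  withr::with_seed(5, {
    true_mb <- rnorm(150, 0.27, 0.33)
    tabs <- purrr::map(seq_along(true_mb), function(i) {
      simulate_two_step(two_step_params(b0 = 0.3, b_mf = 0.4, b_mb = true_mb[i]),
                        n_trials = 200, seed = 400 + i,
                        participant_id = sprintf("C%03d", i))
    }) %>% dplyr::bind_rows()
  })
  idx <- estimate_cohort_indices(tabs)
  expect_equal(mean(idx$mb_index), 0.27, tolerance = 0.1)
  expect_gt(sd(idx$mb_index), 0.25)   # true spread plus estimation noise
  expect_lt(sd(idx$mb_index), 0.6)
  g <- glance(idx)
  expect_equal(g$n_participants, 150)
  # identical agents concentrate tightly by comparison
  same <- purrr::map(1:40, function(i) {
    simulate_two_step(two_step_params(b0 = 0.3, b_mf = 0.4, b_mb = 0.27),
                      n_trials = 200, seed = 700 + i,
                      participant_id = sprintf("I%03d", i))
  }) %>% dplyr::bind_rows()
  idx_same <- estimate_cohort_indices(same)
  expect_lt(sd(idx_same$mb_index), sd(idx$mb_index))
  expect_warning(
    estimate_cohort_indices(tabs, cohort_ids = c(idx$participant_id, "GHOST")),
    "excluded")
})
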
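# End-to-end orchestration: simulate a cohort and its trial tables, score the
# tasks, estimate planning indices, run the association suites, and leave a
# deterministic directory of CSVs plus a manifest.

#' Build a pipeline run configuration
#'
#' @param seed Integer master seed for every random component.
#' @param n Cohort size.
#' @param out_dir Output directory (created if needed).
#' @param stages Prefix of `c("simulate", "score", "index", "associate",
#'   "report")` to execute.
#' @param spec Optional [effect_spec()]; default is the reference-cohort
#'   spec with the supplied `n` and `seed`.
#' @param estimator Model-based index estimator, see [fit_stay_regression()].
#' @param cutoff_a,cutoff_b Run-censoring cut-offs in seconds.
#' @param n_trials Two-step trials per participant.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n = 3327, out_dir = tempfile("cogrisk-run-"),
                       stages = c("simulate", "score", "index", "associate",
                                  "report"),
                       spec = NULL,
                       estimator = "per_subject",
                       cutoff_a = 100, cutoff_b = 300, n_trials = 200) {
  all_stages <- c("simulate", "score", "index", "associate", "report")
  if (!all(stages %in% all_stages) ||
      !identical(stages, all_stages[seq_along(stages)])) {
    abort("`stages` must be a prefix of simulate > score > index > associate > report")
  }
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 out_dir = out_dir, stages = stages, spec = spec,
                 estimator = estimator, cutoff_a = cutoff_a,
                 cutoff_b = cutoff_b, n_trials = n_trials),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stage prefix. `simulate` writes the cohort and the
#' three trial tables; `score` the per-subject task scores; `index` the
#' stay-regression coefficients; `associate` replaces the cohort's latent
#' cognition columns with the task-derived scores and runs the descriptive
#' models plus the primary, depression-adjusted and age-interaction suites;
#' `report` writes a summary. A `manifest.json` with seed, config hash and
#' package version makes reruns checkable: the same config yields
#' byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory results (cohort, trial tables,
#'   scores, indices, suites) with `$files` naming everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec %||% effect_spec(n = config$n, seed = config$seed)
  files <- character()
  out <- list()
  wr <- function(x, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
    path
  }

  ## simulate ---------------------------------------------------------------
  cohort <- generate_cohort(spec)
  mm <- simulate_cohort_memory_match(cohort, seed = split_seed(spec$seed, "mm"))
  sr <- simulate_cohort_star_racer(cohort, seed = split_seed(spec$seed, "sr"))
  ts <- simulate_cohort_two_step(cohort, seed = split_seed(spec$seed, "ts"),
                                 n_trials = config$n_trials)
  wr(cohort, "cohort.csv")
  wr(mm, "trials_memory_match.csv")
  wr(sr, "trials_star_racer.csv")
  wr(ts, "trials_two_step.csv")
  out <- list(cohort = cohort, memory_trials = mm, star_runs = sr,
              two_step_trials = ts)

  if ("score" %in% config$stages) {
    scores <- score_cohort_tasks(mm, sr, cutoff_a = config$cutoff_a,
                                 cutoff_b = config$cutoff_b)
    wr(scores, "scores.csv")
    out$scores <- scores
  }
  if ("index" %in% config$stages) {
    idx <- estimate_cohort_indices(ts, estimator = config$estimator,
                                   cohort_ids = cohort$participant_id)
    wr(as_tibble(idx), "mb_index.csv")
    out$indices <- idx
  }
  if ("associate" %in% config$stages) {
    analysed <- cohort %>%
      select(-"visual_working_memory", -"cognitive_flexibility",
             -"model_based_planning") %>%
      left_join(out$scores %>%
                  select("participant_id", "visual_working_memory",
                         "cognitive_flexibility"),
                by = "participant_id") %>%
      left_join(as_tibble(out$indices) %>%
                  select("participant_id", model_based_planning = "mb_index"),
                by = "participant_id")
    analysed <- analysed[complete.cases(
      analysed[c("visual_working_memory", "cognitive_flexibility",
                 "model_based_planning")]), ]
    prep <- prepare_cohort(analysed)
    desc <- descriptive_age_gender_models(prep)
    primary <- run_primary_suite(prep)
    adjusted <- run_depression_adjusted(prep)
    interactions <- run_age_interaction_suite(
      prep, significant_primary_pairs(primary))
    wr(desc, "descriptive_models.csv")
    wr(as_tibble(primary), "associations_primary.csv")
    wr(as_tibble(adjusted), "associations_adjusted.csv")
    wr(as_tibble(interactions), "associations_interactions.csv")
    out$prepared <- prep
    out$descriptive <- desc
    out$primary <- primary
    out$adjusted <- adjusted
    out$interactions <- interactions
  }
  if ("report" %in% config$stages) {
    report <- bind_rows(
      glance(out$primary), glance(out$adjusted), glance(out$interactions))
    wr(report, "report_summary.csv")
    out$report <- report
  }

  manifest <- list(
    seed = config$seed, n = config$n,
    stages = config$stages,
    config_hash = config_hash(unclass(config[setdiff(names(config), "out_dir")])),
    package_version = as.character(utils::packageVersion("cogrisk")),
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$files <- c(files, file.path(config$out_dir, "manifest.json"))
  out$manifest <- manifest
  invisible(out)
}

#' Generate the small packaged fixture dataset
#'
#' A 50-participant cohort with full memory-game and run tables and two-step
#' tables for the first `n_two_step` participants, regenerated identically
#' from the seed. Two edge cases are constructed on purpose: participant
#' `P00001`'s form-B runs are all above the censoring cut-off (an
#' all-censored subject) and participant `P00002`'s two-step actions are
#' constant (an all-stay, separation-prone subject).
#'
#' @param seed Integer seed (default 42, the committed fixtures' seed).
#' @param n Cohort size (default 50).
#' @param n_two_step Participants with two-step tables (default 5).
#' @param dir Optional directory; when given, the four CSVs are written there.
#' @return A list with `cohort`, `memory_trials`, `star_runs`,
#'   `two_step_trials`.
#' @export
make_fixtures <- function(seed = 42, n = 50, n_two_step = 5, dir = NULL) {
  spec <- effect_spec(n = n, seed = seed)
  cohort <- generate_cohort(spec)
  mm <- simulate_cohort_memory_match(cohort, seed = split_seed(seed, "fix-mm"))
  sr <- simulate_cohort_star_racer(cohort, seed = split_seed(seed, "fix-sr"))
  ts <- simulate_cohort_two_step(head(cohort, n_two_step),
                                 seed = split_seed(seed, "fix-ts"))
  # constructed edge cases
  sr$completion_time[sr$participant_id == "P00001" & sr$form == "B"] <-
    c(320, 310, 305)
  ts$action[ts$participant_id == "P00002"] <- 0L
  ts <- ts %>%
    group_by(.data$participant_id) %>%
    mutate(stay_next = c(as.integer(
      .data$action[-1] == .data$action[-dplyr::n()]), NA_integer_)) %>%
    ungroup()
  fx <- list(cohort = cohort, memory_trials = mm, star_runs = sr,
             two_step_trials = ts)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(fx$cohort, file.path(dir, "fixture_cohort.csv"))
    readr::write_csv(fx$memory_trials, file.path(dir, "fixture_memory_match.csv"))
    readr::write_csv(fx$star_runs, file.path(dir, "fixture_star_racer.csv"))
    readr::write_csv(fx$two_step_trials, file.path(dir, "fixture_two_step.csv"))
  }
  fx
}
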
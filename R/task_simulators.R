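# Trial-level simulators for the three gamified assessments. Each consumes a
# per-subject latent trait and a seed and emits the trial table its scorer
# expects.

#' Memory game design constants
#'
#' The visual working-memory game presents a study array and asks the player
#' to find the studied symbols in a 4 x 5 response grid; lives equal the
#' number of targets, and the trial ends when all targets are found or all
#' lives are lost. Crossing 2 binding conditions x 2 stimulus types x 3 set
#' sizes x 2 repeats gives 24 trials.
#'
#' @param grid_size Number of response cells (default 20).
#' @param set_sizes Study set sizes (default 2, 3, 4).
#' @param binding_conditions,stimulus_types,repeats Design multiplicities.
#' @return A list of class `memory_match_design`; `n_trials(design)` gives
#'   the trial count.
#' @export
memory_match_design <- function(grid_size = 20, set_sizes = c(2, 3, 4),
                                binding_conditions = 2, stimulus_types = 2,
                                repeats = 2) {
  if (max(set_sizes) * 2 > grid_size) {
    abort("grid must be able to hold targets plus as many lives as targets")
  }
  structure(list(grid_size = grid_size, set_sizes = set_sizes,
                 binding_conditions = binding_conditions,
                 stimulus_types = stimulus_types, repeats = repeats),
            class = "memory_match_design")
}

#' @rdname memory_match_design
#' @param design A `memory_match_design`.
#' @export
n_trials <- function(design) {
  design$binding_conditions * design$stimulus_types *
    length(design$set_sizes) * design$repeats
}

#' Simulate one participant's memory-game trials
#'
#' Each pick is memory-driven with probability `p_mem` (a logistic function
#' of the working-memory trait, penalized by set size and the binding
#' condition) and otherwise a uniform guess over the remaining unselected
#' grid cells. The trial runs until all `k` targets are found or `k` lives
#' are lost. With `p_mem = 0` the process reduces exactly to the random
#' guessing chain whose expected accuracy [chance_accuracy()] enumerates.
#'
#' @param wm_trait Latent working-memory ability, standard-normal scale
#'   (higher = better). `Inf` forces perfect play, `-Inf` pure guessing.
#' @param design A [memory_match_design()].
#' @param seed Integer seed.
#' @param base_logit,trait_slope,size_penalty,binding_penalty Calibration of
#'   the memory-pick probability on the logit scale; defaults give mean
#'   scored accuracy near 0.80 (SD about 0.08) for a standard-normal trait.
#' @return A tibble of `MemoryMatchTrial` rows: `trial`, `set_size`,
#'   `binding`, `stimulus`, `n_correct`, `n_errors`.
#' @export
simulate_memory_match <- function(wm_trait, design = memory_match_design(),
                                  seed = 1, base_logit = 1.5,
                                  trait_slope = 0.45, size_penalty = 0.3,
                                  binding_penalty = 0.2) {
  grid <- expand.grid(repeat_idx = seq_len(design$repeats),
                      stimulus = c("letters", "shapes")[seq_len(design$stimulus_types)],
                      binding = seq_len(design$binding_conditions) - 1L,
                      set_size = design$set_sizes,
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    res <- purrr::pmap(grid, function(repeat_idx, stimulus, binding, set_size) {
      p_mem <- plogis(base_logit + trait_slope * wm_trait -
                        size_penalty * (set_size - 2) -
                        binding_penalty * binding)
      if (is.nan(p_mem)) p_mem <- as.numeric(wm_trait > 0)
      play_memory_trial(design$grid_size, set_size, set_size, p_mem)
    })
    tibble(
      trial = seq_len(nrow(grid)),
      set_size = grid$set_size, binding = grid$binding,
      stimulus = grid$stimulus,
      n_correct = vapply(res, `[[`, integer(1), "n_correct"),
      n_errors = vapply(res, `[[`, integer(1), "n_errors")
    )
  })
}

# One trial of the pick process: memory pick hits a remaining target with
# certainty; a guess samples uniformly among unselected cells, of which
# (k - c) are targets.
play_memory_trial <- function(G, k, lives, p_mem) {
  c_found <- 0L; e <- 0L
  while (c_found < k && e < lives) {
    remaining <- G - c_found - e
    p_hit <- p_mem + (1 - p_mem) * (k - c_found) / remaining
    if (runif(1) < p_hit) c_found <- c_found + 1L else e <- e + 1L
  }
  list(n_correct = c_found, n_errors = e)
}

#' Simulate one participant's trail-making style runs
#'
#' Six runs ordered A-B-A-B-A-B. Log completion times are normal with a
#' form-specific location, a loading on the flexibility trait (oriented so
#' higher trait = slower = worse), a shared person-level residual linking the
#' A and B forms, and run-level noise. With probability `outlier_rate` a run
#' is inattentive and its time is multiplied by `outlier_factor`, pushing it
#' beyond the censoring cut-offs used in scoring.
#'
#' @param flex_trait Latent flexibility deficit, standard-normal scale.
#' @param seed Integer seed.
#' @param mu_a,mu_b Log-scale locations of forms A and B; defaults give a
#'   population B mean/SD near 63.3/21.7 s.
#' @param trait_loading,person_sd,run_sd Log-scale variance components.
#' @param outlier_rate,outlier_factor Inattentive-run injection.
#' @return A tibble of `StarRacerRun` rows: `form`, `run_index`,
#'   `completion_time`.
#' @export
simulate_star_racer <- function(flex_trait, seed = 1,
                                mu_a = 3.528, mu_b = 4.0917,
                                trait_loading = 0.25, person_sd = 0.15,
                                run_sd = 0.16,
                                outlier_rate = 0.01, outlier_factor = 6) {
  with_seed(seed, {
    u <- rnorm(1, 0, person_sd)
    form <- rep(c("A", "B"), times = 3)
    mu <- ifelse(form == "A", mu_a, mu_b)
    t <- exp(mu + trait_loading * flex_trait + u + rnorm(6, 0, run_sd))
    lazy <- runif(6) < outlier_rate
    t[lazy] <- t[lazy] * outlier_factor
    tibble(form = form,
           run_index = rep(1:3, each = 2),
           completion_time = t)
  })
}

#' Two-step agent parameters
#'
#' The generative agent mirrors the analysis model: on each trial after the
#' first, it repeats its previous first-stage action with probability
#' `plogis(b0 + b_mf * o + b_mb * o * tau)` where `o` is +1/-1 for a
#' good/bad outcome on the previous trial and `tau` is +1/-1 for a
#' common/rare transition. `b_mb` is the model-based weight the stay
#' regression recovers.
#'
#' @param b0 Stay bias (logit units).
#' @param b_mf Model-free weight (previous outcome).
#' @param b_mb Model-based weight (outcome x transition interaction).
#' @param p_common First-stage transition probability, in (0.5, 1].
#' @param drift_sd SD of the per-state outcome-probability random walk.
#' @param outcome_bounds Reflecting bounds of the outcome probabilities.
#' @return A list of class `two_step_params`.
#' @export
two_step_params <- function(b0 = 0.3, b_mf = 0.4, b_mb = 0.27,
                            p_common = 0.8, drift_sd = 0.025,
                            outcome_bounds = c(0.25, 0.75)) {
  if (p_common <= 0.5 || p_common > 1) abort("`p_common` must lie in (0.5, 1]")
  if (length(outcome_bounds) != 2 || outcome_bounds[1] >= outcome_bounds[2] ||
      outcome_bounds[1] <= 0 || outcome_bounds[2] >= 1) {
    abort("`outcome_bounds` must be ordered within (0, 1)")
  }
  if (drift_sd < 0) abort("`drift_sd` must be >= 0")
  structure(list(b0 = b0, b_mf = b_mf, b_mb = b_mb, p_common = p_common,
                 drift_sd = drift_sd, outcome_bounds = outcome_bounds),
            class = "two_step_params")
}

#' Simulate a two-step planning game session
#'
#' Two first-stage actions each lead to their usual second-stage state with
#' probability `p_common` (a common transition) and to the other state
#' otherwise (rare). Each state's good-outcome probability follows a
#' reflecting Gaussian random walk within `outcome_bounds`. The stay/switch
#' choice follows the logistic stay model of [two_step_params()].
#'
#' @param params A [two_step_params()].
#' @param n_trials Number of trials (>= 2; default 200).
#' @param seed Integer seed.
#' @param participant_id Identifier copied into the table.
#' @return A `TwoStepTrialTable` tibble: `participant_id`, `trial_index`,
#'   `action` (0/1), `transition` ("common"/"rare"), `outcome`
#'   ("good"/"bad"), `stay_next` (1/0; `NA` on the final trial).
#' @export
simulate_two_step <- function(params = two_step_params(), n_trials = 200,
                              seed = 1, participant_id = "P00001") {
  stopifnot(inherits(params, "two_step_params"))
  if (n_trials < 2) abort("`n_trials` must be >= 2: no stay events otherwise")
  with_seed(seed, {
    lo <- params$outcome_bounds[1]; hi <- params$outcome_bounds[2]
    p_good <- runif(2, lo, hi)  # one drifting walk per second-stage state
    action <- integer(n_trials); transition <- character(n_trials)
    outcome <- character(n_trials)
    a <- sample(0:1, 1)
    for (t in seq_len(n_trials)) {
      common <- runif(1) < params$p_common
      state <- if (common) a else 1L - a
      good <- runif(1) < p_good[state + 1L]
      action[t] <- a
      transition[t] <- if (common) "common" else "rare"
      outcome[t] <- if (good) "good" else "bad"
      # reflecting random walk update
      p_good <- p_good + rnorm(2, 0, params$drift_sd)
      p_good <- ifelse(p_good < lo, 2 * lo - p_good, p_good)
      p_good <- ifelse(p_good > hi, 2 * hi - p_good, p_good)
      p_good <- pmin(pmax(p_good, lo), hi)
      if (t < n_trials) {
        o <- if (good) 1 else -1
        tau <- if (common) 1 else -1
        p_stay <- plogis(params$b0 + params$b_mf * o + params$b_mb * o * tau)
        a <- if (runif(1) < p_stay) a else 1L - a
      }
    }
    stay_next <- c(as.integer(action[-1] == action[-n_trials]), NA_integer_)
    tibble(participant_id = participant_id,
           trial_index = seq_len(n_trials),
           action = action, transition = transition, outcome = outcome,
           stay_next = stay_next)
  })
}

#' Simulate trial tables for a whole cohort
#'
#' Convenience wrappers mapping the single-subject simulators over a cohort's
#' trait columns with per-subject derived seeds.
#'
#' @param cohort A cohort with trait columns (see [attach_task_traits()]).
#' @param seed Integer master seed; each participant gets a derived stream.
#' @param ... Passed to the single-subject simulator.
#' @return A tibble binding all participants' trial rows, with
#'   `participant_id`.
#' @export
simulate_cohort_memory_match <- function(cohort, seed = 1, ...) {
  purrr::map2(cohort$participant_id, cohort$wm_trait, function(id, tr) {
    simulate_memory_match(tr, seed = split_seed(seed, paste0("mm:", id)), ...) %>%
      mutate(participant_id = id, .before = 1)
  }) %>% bind_rows()
}

#' @rdname simulate_cohort_memory_match
#' @export
simulate_cohort_star_racer <- function(cohort, seed = 1, ...) {
  purrr::map2(cohort$participant_id, cohort$flex_trait, function(id, tr) {
    simulate_star_racer(tr, seed = split_seed(seed, paste0("sr:", id)), ...) %>%
      mutate(participant_id = id, .before = 1)
  }) %>% bind_rows()
}

#' @rdname simulate_cohort_memory_match
#' @param index_mean,index_sd Population location/scale mapping `mb_trait` to
#'   the agent's model-based weight (`b_mb = index_mean + index_sd * mb_trait`).
#' @param n_trials Trials per participant.
#' @export
simulate_cohort_two_step <- function(cohort, seed = 1, n_trials = 200,
                                     index_mean = 0.27, index_sd = 0.33, ...) {
  purrr::map2(cohort$participant_id, cohort$mb_trait, function(id, tr) {
    pars <- two_step_params(b_mb = index_mean + index_sd * tr, ...)
    simulate_two_step(pars, n_trials = n_trials,
                      seed = split_seed(seed, paste0("ts:", id)),
                      participant_id = id)
  }) %>% bind_rows()
}
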
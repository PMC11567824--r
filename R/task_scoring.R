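# Scoring of the trial-level task tables into per-subject cognition scores,
# including the exact chance-level accuracy of the memory game.

#' Exact chance-level accuracy of the memory game
#'
#' Under pure guessing, each pick hits a remaining target with probability
#' `(k - c) / (G - c - e)` where `c` targets have been found and `e` errors
#' made on a `G`-cell grid with `k` targets; the trial absorbs when `c = k`
#' (all targets found) or `e = L` (all lives lost). This enumerates the
#' absorbing Markov chain exactly — no sampling — and returns the expected
#' scored accuracy `E[c / (c + e)]` at absorption. On the 20-cell grid with
#' lives equal to targets this gives 0.07, 0.12 and 0.17 (2 dp) for set
#' sizes 2, 3 and 4.
#'
#' @param G Grid cells (total response options).
#' @param k Set size (number of targets), `1 <= k <= G`.
#' @param L Lives (errors allowed), `>= 1`. `k + L <= G` guarantees the grid
#'   cannot be exhausted before absorption; smaller grids are accepted as
#'   long as no reachable state actually runs out of cells (e.g. `G = k`,
#'   where every pick is forced correct).
#' @return The exact expected accuracy, a scalar in (0, 1].
#' @examples
#' chance_accuracy(20, 2, 2)  # ~0.0719
#' round(chance_accuracy(20, 4, 4), 2)
#' @export
chance_accuracy <- function(G, k, L) {
  if (k < 1 || k > G) abort("need 1 <= k <= G")
  if (L < 1) abort("need L >= 1")
  # forward pass over reach probabilities of transient states (c, e)
  reach <- matrix(0, nrow = k + 1, ncol = L + 1)
  reach[1, 1] <- 1
  expected <- 0
  for (step in seq_len(k + L)) {
    nxt <- matrix(0, nrow = k + 1, ncol = L + 1)
    for (c in 0:(k - 1)) {
      for (e in 0:(L - 1)) {
        p <- reach[c + 1, e + 1]
        if (p == 0) next
        if (G - c - e <= 0) {
          abort("grid exhausted before absorption: need k + L <= G")
        }
        p_hit <- (k - c) / (G - c - e)
        if (c + 1 == k) {
          expected <- expected + p * p_hit * k / (k + e)
        } else {
          nxt[c + 2, e + 1] <- nxt[c + 2, e + 1] + p * p_hit
        }
        if (e + 1 == L) {
          expected <- expected + p * (1 - p_hit) * c / (c + L)
        } else {
          nxt[c + 1, e + 2] <- nxt[c + 1, e + 2] + p * (1 - p_hit)
        }
      }
    }
    reach <- nxt
  }
  expected
}

#' Score a participant's memory-game trials
#'
#' Per-trial accuracy is `n_correct / (n_correct + n_errors)`; the subject
#' score is by default the unweighted mean of per-trial accuracies so every
#' trial contributes equally across set sizes. `method = "pooled"` instead
#' pools counts across trials (`sum(correct) / sum(correct + errors)`).
#'
#' @param trials Tibble of memory trials (one participant) with `n_correct`
#'   and `n_errors` columns.
#' @param method `"trial_mean"` (default) or `"pooled"`.
#' @return A one-row tibble: `measure = "visual_working_memory"`, `value`
#'   (accuracy in `[0, 1]`), `n_units_used`.
#' @export
score_memory_match <- function(trials, method = c("trial_mean", "pooled")) {
  method <- match.arg(method)
  if (nrow(trials) < 1) abort("need at least one trial")
  tot <- trials$n_correct + trials$n_errors
  if (any(tot == 0)) {
    abort("trial with zero picks: impossible under the stopping rule")
  }
  value <- if (method == "trial_mean") {
    mean(trials$n_correct / tot)
  } else {
    sum(trials$n_correct) / sum(tot)
  }
  tibble(measure = "visual_working_memory", value = value,
         n_units_used = nrow(trials))
}

#' Score a participant's trail-making style runs with outlier censoring
#'
#' Runs with completion times at or above the form-specific cut-off (100 s
#' or more for form A, 300 s or more for form B) are excluded as
#' inattentive; each form's score is the mean time of the surviving runs.
#' Form A indexes processing speed and form B cognitive flexibility. If all
#' runs of a form are censored the score is `NA` and flagged.
#'
#' @param runs Tibble with `form` ("A"/"B"), `completion_time` (seconds).
#' @param cutoff_a,cutoff_b Inclusive censoring cut-offs in seconds.
#' @return A tibble with one row per form: `measure` ("processing_speed" for
#'   A, "cognitive_flexibility" for B), `value` (mean seconds, `NA` if all
#'   runs censored), `n_units_used`, `all_censored` flag.
#' @examples
#' runs <- tibble::tibble(form = rep("B", 3), completion_time = c(60, 70, 380))
#' score_star_racer(runs)  # 380 >= 300 excluded: mean of 60, 70
#' @export
score_star_racer <- function(runs, cutoff_a = 100, cutoff_b = 300) {
  stopifnot(all(runs$form %in% c("A", "B")))
  if (any(runs$completion_time <= 0)) abort("completion times must be positive")
  purrr::map_dfr(intersect(c("A", "B"), unique(runs$form)), function(f) {
    cutoff <- if (f == "A") cutoff_a else cutoff_b
    t <- runs$completion_time[runs$form == f]
    keep <- t < cutoff  # "100 or more seconds ... excluded": inclusive cut
    tibble(
      measure = if (f == "A") "processing_speed" else "cognitive_flexibility",
      value = if (any(keep)) mean(t[keep]) else NA_real_,
      n_units_used = sum(keep),
      all_censored = !any(keep)
    )
  })
}

#' Score all participants' task tables
#'
#' Maps the per-subject scorers over cohort-level trial tables and returns
#' one wide row per participant with `visual_working_memory` (accuracy),
#' `processing_speed` and `cognitive_flexibility` (mean seconds).
#'
#' @param memory_trials,star_runs Cohort-level trial tables carrying
#'   `participant_id`.
#' @param method Memory-score aggregation, see [score_memory_match()].
#' @param cutoff_a,cutoff_b Censoring cut-offs, see [score_star_racer()].
#' @return A tibble keyed by `participant_id`.
#' @export
score_cohort_tasks <- function(memory_trials, star_runs,
                               method = "trial_mean",
                               cutoff_a = 100, cutoff_b = 300) {
  mm <- memory_trials %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(~ score_memory_match(.x, method = method)) %>%
    ungroup() %>%
    select("participant_id", visual_working_memory = "value")
  sr <- star_runs %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(~ score_star_racer(.x, cutoff_a = cutoff_a,
                                           cutoff_b = cutoff_b)) %>%
    ungroup() %>%
    select("participant_id", "measure", "value") %>%
    tidyr::pivot_wider(names_from = "measure", values_from = "value")
  left_join(mm, sr, by = "participant_id")
}
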
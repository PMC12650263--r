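# Adaptive sequence-recall (Corsi-style) working-memory game: engine,
# synthetic player, and session scoring.

#' Game configuration for the adaptive recall task
#'
#' Difficulty is re-evaluated every `eval_window` trials: window accuracy above
#' `up_threshold` raises the level and shortens the display duration by
#' `duration_step_ms` (floored at `min_duration_ms`); accuracy below
#' `down_threshold` lengthens the duration (capped at `max_duration_ms`).
#' The level never decreases; only the display time eases. By default the
#' sequence length is fixed at 9 positions and the level modulates display
#' time only; supply `sequence_length_rule` (a function level -> length) to
#' make length adaptive instead.
#'
#' @param eval_window trials between difficulty evaluations.
#' @param up_threshold,down_threshold window-accuracy cut points in [0,1],
#'   `down_threshold < up_threshold`.
#' @param initial_duration_ms,duration_step_ms,min_duration_ms,max_duration_ms
#'   display-time schedule in milliseconds.
#' @param initial_level starting difficulty level (positive integer).
#' @param sequence_length_rule function mapping level to sequence length.
#' @return an object of class `game_config`.
#' @export
game_config <- function(eval_window = 10L,
                        up_threshold = 0.7,
                        down_threshold = 0.3,
                        initial_duration_ms = 1000L,
                        duration_step_ms = 100L,
                        min_duration_ms = 200L,
                        max_duration_ms = 2000L,
                        initial_level = 1L,
                        sequence_length_rule = function(level) 9L) {
  assert_scalar_num(eval_window, "eval_window", lower = 1)
  assert_scalar_num(up_threshold, "up_threshold", 0, 1)
  assert_scalar_num(down_threshold, "down_threshold", 0, 1)
  if (down_threshold >= up_threshold) {
    stop_validation("down_threshold (%g) must be < up_threshold (%g)",
                    down_threshold, up_threshold)
  }
  if (min_duration_ms > initial_duration_ms || initial_duration_ms > max_duration_ms) {
    stop_validation("need min_duration_ms <= initial_duration_ms <= max_duration_ms")
  }
  assert_scalar_num(initial_level, "initial_level", lower = 1)
  stopifnot(is.function(sequence_length_rule))
  structure(list(
    eval_window = as.integer(eval_window),
    up_threshold = up_threshold,
    down_threshold = down_threshold,
    initial_duration_ms = as.integer(initial_duration_ms),
    duration_step_ms = as.integer(duration_step_ms),
    min_duration_ms = as.integer(min_duration_ms),
    max_duration_ms = as.integer(max_duration_ms),
    initial_level = as.integer(initial_level),
    sequence_length_rule = sequence_length_rule
  ), class = "game_config")
}

#' Synthetic player for the recall game
#'
#' Recall of a full sequence is Bernoulli with probability from a logistic
#' psychometric function of sequence length:
#' `p = lapse/2 + (1 - lapse) / (1 + exp((length - capacity)/slope))`,
#' so `capacity` is the span at which recall probability is 0.5 (lapse = 0)
#' and probabilities stay inside `[lapse/2, 1 - lapse/2]`.
#'
#' @param capacity span at which recall probability is one half.
#' @param slope psychometric slope (> 0), in span units.
#' @param lapse floor/ceiling mixing proportion in [0,1].
#' @return an object of class `agent_model`.
#' @export
agent_model <- function(capacity = 6.8, slope = 2, lapse = 0.02) {
  assert_scalar_num(slope, "slope")
  if (slope <= 0) stop_validation("`slope` must be > 0")
  assert_scalar_num(lapse, "lapse", 0, 1)
  structure(list(capacity = capacity, slope = slope, lapse = lapse),
            class = "agent_model")
}

recall_probability <- function(agent, seq_length) {
  core <- stats::plogis((agent$capacity - seq_length) / agent$slope)
  agent$lapse / 2 + (1 - agent$lapse) * core
}

#' Apply one adaptive-difficulty evaluation
#'
#' @param state list with `level` and `duration_ms`.
#' @param window_accuracy accuracy over the most recent evaluation window,
#'   in [0,1].
#' @param config a [game_config()].
#' @return updated state list.
#' @export
update_difficulty <- function(state, window_accuracy, config = game_config()) {
  assert_scalar_num(window_accuracy, "window_accuracy", 0, 1)
  if (window_accuracy > config$up_threshold) {
    state$level <- state$level + 1L
    state$duration_ms <- max(config$min_duration_ms,
                             state$duration_ms - config$duration_step_ms)
  } else if (window_accuracy < config$down_threshold) {
    state$duration_ms <- min(config$max_duration_ms,
                             state$duration_ms + config$duration_step_ms)
  }
  state
}

#' Simulate one game session with a synthetic player
#'
#' Runs the trial loop: display a sequence at the current level/duration, draw
#' the agent's recall as a Bernoulli outcome, update the running cumulative
#' score, and re-evaluate difficulty every `eval_window` trials.
#'
#' @param agent an [agent_model()].
#' @param config a [game_config()].
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; the session is fully deterministic under it.
#' @param participant_id id recorded in the log.
#' @param start_time POSIXct session start for the trial timestamps.
#' @return a `data.frame` trial log with columns `participant_id`,
#'   `trial_index`, `level`, `display_duration_ms`, `correct`,
#'   `running_score`, `timestamp` (ISO-8601).
#' @export
simulate_session <- function(agent, config = game_config(), n_trials = 70L,
                             seed = 1L, participant_id = "p1",
                             start_time = as.POSIXct("2026-01-01 09:00:00", tz = "UTC")) {
  assert_scalar_num(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  level <- config$initial_level
  duration <- config$initial_duration_ms
  correct <- logical(n_trials)
  levels <- integer(n_trials)
  durations <- integer(n_trials)
  with_seed(derive_seed(seed, "wm", participant_id), {
    for (t in seq_len(n_trials)) {
      levels[t] <- level
      durations[t] <- duration
      p <- recall_probability(agent, config$sequence_length_rule(level))
      correct[t] <- stats::runif(1) < p
      if (t %% config$eval_window == 0L) {
        win <- correct[(t - config$eval_window + 1L):t]
        st <- update_difficulty(list(level = level, duration_ms = duration),
                                mean(win), config)
        level <- st$level
        duration <- st$duration_ms
      }
    }
  })
  running <- cumsum(correct) / seq_len(n_trials)
  data.frame(
    participant_id = participant_id,
    trial_index = seq_len(n_trials),
    level = levels,
    display_duration_ms = durations,
    correct = as.integer(correct),
    running_score = running,
    timestamp = format(start_time + 5 * seq_len(n_trials), "%Y-%m-%dT%H:%M:%SZ"),
    stringsAsFactors = FALSE
  )
}

#' Score a game session (the eight session metrics)
#'
#' The per-trial score sequence is, by default, the running cumulative
#' accuracy after each trial (cumulative correct / cumulative attempts);
#' `score_mode = "per_trial"` instead treats each trial's binary outcome as
#' its score. Max/median/mean are taken over that sequence; the two count
#' metrics use strict `>`; the streak is the longest run of consecutive
#' correct trials.
#'
#' @param log a trial-log `data.frame` with at least a `correct` column
#'   (0/1 or logical); ordering follows `trial_index` when present.
#' @param score_mode `"cumulative"` (default) or `"per_trial"`.
#' @return a one-row `data.frame` with `num_correct_responses`,
#'   `num_total_responses`, `max_score`, `median_score`, `mean_score`,
#'   `count_above_0_25`, `count_above_0_5`, `successive_correct_count`.
#' @export
score_session <- function(log, score_mode = c("cumulative", "per_trial")) {
  score_mode <- match.arg(score_mode)
  if (is.null(log) || NROW(log) == 0L) {
    stop_validation("trial log is empty: no metrics are defined")
  }
  if (!"correct" %in% names(log)) stop_validation("trial log lacks a `correct` column")
  if ("trial_index" %in% names(log)) log <- log[order(log$trial_index), , drop = FALSE]
  correct <- as.integer(as.logical(log$correct))
  if (anyNA(correct)) stop_validation("`correct` column contains missing values")
  n <- length(correct)
  running <- cumsum(correct) / seq_len(n)
  scores <- if (score_mode == "cumulative") running else as.numeric(correct)
  runs <- rle(correct)
  streak <- if (any(runs$values == 1L)) max(runs$lengths[runs$values == 1L]) else 0L
  data.frame(
    num_correct_responses = sum(correct),
    num_total_responses = n,
    max_score = max(scores),
    median_score = stats::median(scores),
    mean_score = mean(scores),
    count_above_0_25 = sum(scores > 0.25),
    count_above_0_5 = sum(scores > 0.5),
    successive_correct_count = as.integer(streak)
  )
}
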
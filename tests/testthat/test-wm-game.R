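# Adaptive recall game: difficulty schedule, session scoring, agent simulation.

test_that("score_session reproduces the hand-worked five-trial log", {
  s <- score_session(data.frame(correct = c(1, 0, 1, 1, 0)))
  expect_equal(s$num_correct_responses, 3)
  expect_equal(s$num_total_responses, 5)
  expect_equal(s$max_score, 1.0)
  expect_equal(s$median_score, 2 / 3, tolerance = 1e-12)
  expect_equal(s$mean_score, mean(c(1, 1 / 2, 2 / 3, 3 / 4, 3 / 5)), tolerance = 1e-12)
  expect_equal(s$count_above_0_25, 5)
  expect_equal(s$count_above_0_5, 4)
  expect_equal(s$successive_correct_count, 2)
})

test_that("score_session limit cases and errors", {
  all_good <- score_session(data.frame(correct = rep(1, 4)))
  expect_equal(all_good$max_score, 1)
  expect_equal(all_good$median_score, 1)
  expect_equal(all_good$mean_score, 1)
  expect_equal(all_good$count_above_0_25, 4)
  expect_equal(all_good$count_above_0_5, 4)
  expect_equal(all_good$successive_correct_count, 4)

  all_bad <- score_session(data.frame(correct = rep(0, 3)))
  expect_equal(all_bad$max_score, 0)
  expect_equal(all_bad$mean_score, 0)
  expect_equal(all_bad$count_above_0_25, 0)
  expect_equal(all_bad$successive_correct_count, 0)

  expect_error(score_session(data.frame(correct = integer(0))), "empty")
  expect_error(score_session(data.frame(level = 1)), "correct")
})

test_that("per-trial score mode treats each binary outcome as the score", {
  s <- score_session(data.frame(correct = c(1, 0, 1, 1, 0)), score_mode = "per_trial")
  expect_equal(s$max_score, 1)
  expect_equal(s$mean_score, 0.6)
  expect_equal(s$median_score, 1)
  expect_equal(s$count_above_0_5, 3)
})

test_that("running-score recurrence and column invariance hold on random logs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    correct <- rbinom(n, 1, runif(1))
    log <- data.frame(trial_index = seq_len(n), correct = correct,
                      display_duration_ms = sample(200:2000, n, replace = TRUE),
                      timestamp = as.character(seq_len(n)))
    s <- score_session(log)
    running <- cumsum(correct) / seq_len(n)
    # recurrence score_t = ((t-1) score_{t-1} + correct_t)/t
    for (t in 2:n) {
      expect_equal(running[t], ((t - 1) * running[t - 1] + correct[t]) / t,
                   tolerance = 1e-12)
    }
    expect_equal(s$max_score, max(running))
    # invariant to everything but the correct sequence
    shuffled <- log
    shuffled$display_duration_ms <- rev(shuffled$display_duration_ms)
    shuffled$timestamp <- "x"
    expect_equal(score_session(shuffled), s)
    # appending a correct trial never decreases the count metrics
    s2 <- score_session(data.frame(correct = c(correct, 1)))
    expect_gte(s2$num_correct_responses, s$num_correct_responses)
    expect_gte(s2$successive_correct_count, s$successive_correct_count)
    expect_gte(s2$count_above_0_25, s$count_above_0_25)
  }
})

test_that("update_difficulty follows the configured schedule", {
  cfg <- game_config(up_threshold = 0.7, down_threshold = 0.3,
                     duration_step_ms = 100, min_duration_ms = 200)
  up <- update_difficulty(list(level = 2L, duration_ms = 900L), 0.8, cfg)
  expect_equal(up$level, 3)
  expect_equal(up$duration_ms, 800)

  mid <- update_difficulty(list(level = 2L, duration_ms = 900L), 0.5, cfg)
  expect_equal(mid, list(level = 2L, duration_ms = 900L))

  floor <- update_difficulty(list(level = 1L, duration_ms = 250L), 1.0, cfg)
  expect_equal(floor$level, 2)
  expect_equal(floor$duration_ms, 200)

  down <- update_difficulty(list(level = 3L, duration_ms = 1950L), 0.1,
                            game_config(max_duration_ms = 2000))
  expect_equal(down$level, 3)  # level never decreases
  expect_equal(down$duration_ms, 2000)

  expect_error(update_difficulty(list(level = 1L, duration_ms = 500L), 1.4, cfg),
               "outside")
})

test_that("game_config validates its invariants", {
  expect_error(game_config(up_threshold = 0.3, down_threshold = 0.7), "up_threshold")
  expect_error(game_config(min_duration_ms = 1500, initial_duration_ms = 1000))
  expect_error(game_config(eval_window = 0))
})

test_that("simulate_session limit agents behave deterministically", {
  perfect <- simulate_session(agent_model(capacity = Inf, lapse = 0),
                              n_trials = 30, seed = 1)
  expect_true(all(perfect$correct == 1))
  expect_equal(perfect$level[c(1, 11, 21)], c(1, 2, 3))  # rises every window

  hopeless <- simulate_session(agent_model(capacity = -Inf, lapse = 0),
                               game_config(initial_duration_ms = 1800,
                                           max_duration_ms = 2000),
                               n_trials = 40, seed = 1)
  expect_true(all(hopeless$correct == 0))
  expect_equal(hopeless$display_duration_ms[40], 2000)
  expect_equal(hopeless$level[40], 1)

  twice <- simulate_session(agent_model(), n_trials = 50, seed = 9)
  expect_identical(twice, simulate_session(agent_model(), n_trials = 50, seed = 9))
})

test_that("engine log round-trips through CSV without changing the metrics", {
  log <- simulate_session(agent_model(capacity = 7), n_trials = 60, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(log, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(score_session(back), score_session(log))
  expect_equal(back$running_score, cumsum(back$correct) / seq_len(nrow(back)),
               tolerance = 1e-12)
})

test_that("simulated mean score matches the analytic expectation", {
  # with fixed sequence length the per-trial recall probability is constant,
  # so E[mean of running means] equals that probability
  agent <- agent_model(capacity = 5, slope = 1, lapse = 0)
  p_true <- plogis((5 - 9) / 1)
  means <- vapply(1:500, function(s) {
    score_session(simulate_session(agent, n_trials = 200, seed = s))$mean_score
  }, numeric(1))
  expect_lt(abs(mean(means) - p_true), 0.03)
})
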
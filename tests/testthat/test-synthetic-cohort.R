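# Synthetic cohort generator: copula structure, narrative targets, truth.

test_that("cohort_config validates the latent correlation matrix", {
  bad <- diag(4); bad[1, 2] <- 0.5  # asymmetric
  expect_error(cohort_config(latent_corr = bad), "symmetric")
  nonpsd <- matrix(0.99, 4, 4) * (1 - diag(4)) * -1 + diag(4)
  expect_error(cohort_config(latent_corr = nonpsd), "positive semi-definite")
  nd <- diag(4) * 2
  expect_error(cohort_config(latent_corr = nd), "unit diagonal")
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(good_sleeper_fraction = 1.2), "good_sleeper_fraction")
})

test_that("regeneration under the same config is identical", {
  cfg <- cohort_config(n_participants = 5, blink_duration_s = 60,
                       sebr_rates = list(good = c(10, 12), poor = c(20, 20)),
                       n_trials = 15, seed = 42)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- cfg
  other$seed <- 43L
  expect_false(identical(generate_cohort(cfg), generate_cohort(other)))
})

test_that("participant bundles are complete and aligned with truth", {
  cfg <- cohort_config(n_participants = 4, blink_duration_s = 60,
                       sebr_rates = list(good = c(10, 12), poor = c(20, 20)),
                       n_trials = 10, n_stimuli = 4, seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co$participants, 4)
  ids <- vapply(co$participants, `[[`, character(1), "participant_id")
  expect_identical(rownames(co$truth$latent), ids)
  for (b in co$participants) {
    expect_false(is.null(b$psqi_items))
    expect_length(b$erq_responses, 10)
    expect_equal(nrow(b$trial_log), 10)
    expect_equal(nrow(b$ratings), 4)
    expect_false(is.null(b$eye_pre))
    id <- b$participant_id
    expect_equal(length(b$eye_pre$event_frames),
                 unname(co$truth$blink_counts[id, "pre"]))
  }
  # the sleep group in truth matches the scored questionnaires
  scored <- vapply(co$participants,
                   function(b) score_psqi(b$psqi_items)$group, character(1))
  expect_identical(unname(co$truth$sleep_group), scored)
})

test_that("an identity copula yields uncorrelated latent traits at n = 1000", {
  cfg <- cohort_config(n_participants = 1000, latent_corr = diag(4),
                       modalities = "questionnaires", seed = 11)
  co <- generate_cohort(cfg)
  z <- co$truth$latent
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(cor(z[, i], z[, j], method = "spearman")), 0.09)
  }
})

test_that("planted latent correlation survives the monotone observable maps", {
  # brute-force oracle at n = 1e5 (run once, frozen): latent rho(wm, er) = 0.6
  # maps to Spearman(WM mean score, ERQ total) = 0.495
  lc <- diag(4)
  dimnames(lc) <- list(createlab:::LATENT_TRAITS, createlab:::LATENT_TRAITS)
  lc["wm", "er"] <- lc["er", "wm"] <- 0.6
  cfg <- cohort_config(n_participants = 1000, latent_corr = lc,
                       modalities = c("wm", "questionnaires"), seed = 19)
  co <- generate_cohort(cfg)
  wm_mean <- vapply(co$participants,
                    function(b) score_session(b$trial_log)$mean_score, numeric(1))
  erq_tot <- vapply(co$participants,
                    function(b) score_erq(b$erq_responses)$total, numeric(1))
  obs <- cor(wm_mean, erq_tot, method = "spearman")
  expect_lt(abs(obs - 0.495), 0.10)
  expect_gt(obs, 0)  # sign preservation
})

test_that("the good-sleeper fraction converges to its target", {
  cfg <- cohort_config(n_participants = 500, good_sleeper_fraction = 1 / 3,
                       modalities = "questionnaires", seed = 23)
  co <- generate_cohort(cfg)
  frac <- mean(co$truth$sleep_group == "Good")
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / 500)
  expect_lt(abs(frac - 1 / 3), tol)
})

test_that("neutral narratives are pure filler scoring exactly (0, 0)", {
  txt <- generate_narrative(0, 0, n_tokens = 8, seed = 3)
  toks <- tokenize(txt)
  expect_length(toks, 8)
  lex <- sentiment_lexicon()
  expect_length(intersect(toks, lex$words), 0)
  ps <- polarity_subjectivity(toks, lex)
  expect_equal(ps, list(polarity = 0, subjectivity = 0))
})

test_that("narrative targets close the loop through the extractor", {
  lex <- sentiment_lexicon()
  txt <- generate_narrative(0.8, NULL, n_tokens = 12, seed = 5, tolerance = 0.1)
  toks <- tokenize(txt)
  expect_length(toks, 12)
  ps <- polarity_subjectivity(toks, lex)
  expect_gte(ps$polarity, 0.7)
  expect_lte(ps$polarity, 0.9)

  both <- generate_narrative(0.1, 0.5, n_tokens = 20, seed = 6, tolerance = 0.1)
  ps2 <- polarity_subjectivity(tokenize(both), lex)
  expect_lt(abs(ps2$polarity - 0.1), 0.11)
  expect_lt(abs(ps2$subjectivity - 0.5), 0.11)

  expect_identical(generate_narrative(0.4, 0.6, 10, seed = 9),
                   generate_narrative(0.4, 0.6, 10, seed = 9))
  expect_error(generate_narrative(0.99, NULL, 10, seed = 1), "unreachable")
})

test_that("cohort CSV writer emits all schemas plus the truth sidecar", {
  cfg <- cohort_config(n_participants = 3, blink_duration_s = 30,
                       sebr_rates = list(good = c(5, 6), poor = c(8, 8)),
                       n_trials = 8, n_stimuli = 3, seed = 6)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  expect_setequal(list.files(dir),
                  c("wm_trials.csv", "questionnaires.csv", "art_ratings.csv",
                    "eye_signals.csv", "truth.json"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_length(truth$sleep_group, 3)
  wm <- read.csv(file.path(dir, "wm_trials.csv"))
  expect_equal(nrow(wm), 3 * 8)
})
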
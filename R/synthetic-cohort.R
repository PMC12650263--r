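# Synthetic study cohorts with planted statistical structure. Latent traits
# (WM capacity, emotion-regulation level, sleep-problem tendency, dopaminergic
# tone) are drawn from a Gaussian copula and mapped monotonically onto the
# four observable modalities: game trial logs, questionnaire item responses,
# art ratings with short narratives, and eye-opening-ratio signals with
# planted blink events. Truth (latent values, planted events, targets) is
# always emitted alongside the data.

LATENT_TRAITS <- c("wm", "er", "sleep", "dopamine")

default_latent_corr <- function() {
  m <- diag(4)
  dimnames(m) <- list(LATENT_TRAITS, LATENT_TRAITS)
  m["wm", "er"] <- m["er", "wm"] <- 0.4
  m["er", "sleep"] <- m["sleep", "er"] <- 0.5
  m["sleep", "dopamine"] <- m["dopamine", "sleep"] <- 0.4
  m
}

#' Configuration of a synthetic cohort
#'
#' Defaults state the emulated study world: a 27-person cohort, one third
#' good sleepers, 15 stimuli, 70-trial game sessions, 300-second blink
#' recordings at 30 fps, and per-group session blink counts of (33, 42) for
#' good and (94, 95) for poor sleepers (pre, post).
#'
#' @param n_participants cohort size (>= 2).
#' @param latent_corr 4x4 positive semi-definite correlation matrix over the
#'   latent traits `wm`, `er`, `sleep`, `dopamine` (unit diagonal).
#' @param good_sleeper_fraction expected fraction with PSQI global <= 5.
#' @param sebr_rates list with numeric `good` and `poor`, each `c(pre, post)`
#'   mean blink counts per session.
#' @param text_params list of narrative targets: `polarity_mean/sd`,
#'   `subjectivity_mean/sd`, `tokens_mean/sd`, `er_loading` (how strongly the
#'   ER trait shifts a participant's subjectivity target).
#' @param n_stimuli number of rated stimuli (default 15).
#' @param n_trials game trials per session.
#' @param blink_duration_s,fps blink-recording length and sampling rate.
#' @param sebr_sd SD of the linear latent-to-count map for blink counts.
#' @param modalities subset of `c("wm", "questionnaires", "ratings", "blinks")`
#'   to generate (all by default; narrowing is a performance device for
#'   large-n statistical tests).
#' @param seed integer master seed; regeneration is byte-identical under it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 27L,
                          latent_corr = default_latent_corr(),
                          good_sleeper_fraction = 1 / 3,
                          sebr_rates = list(good = c(pre = 33, post = 42),
                                            poor = c(pre = 94, post = 95)),
                          text_params = list(polarity_mean = 0.07,
                                             polarity_sd = 0.09,
                                             subjectivity_mean = 0.49,
                                             subjectivity_sd = 0.14,
                                             tokens_mean = 10,
                                             tokens_sd = 5,
                                             er_loading = 0.6),
                          n_stimuli = 15L,
                          n_trials = 70L,
                          blink_duration_s = 300,
                          fps = 30,
                          sebr_sd = 15,
                          modalities = c("wm", "questionnaires", "ratings", "blinks"),
                          seed = 1L) {
  assert_scalar_num(n_participants, "n_participants", lower = 2)
  assert_scalar_num(good_sleeper_fraction, "good_sleeper_fraction", 0, 1)
  assert_scalar_num(n_stimuli, "n_stimuli", lower = 1)
  if (!is.matrix(latent_corr) || !identical(dim(latent_corr), c(4L, 4L))) {
    stop_validation("latent_corr must be a 4x4 matrix over (%s)",
                    paste(LATENT_TRAITS, collapse = ", "))
  }
  if (max(abs(latent_corr - t(latent_corr))) > 1e-10) {
    stop_validation("latent_corr must be symmetric")
  }
  if (max(abs(diag(latent_corr) - 1)) > 1e-10) {
    stop_validation("latent_corr must have a unit diagonal")
  }
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_validation("latent_corr is not positive semi-definite (min eigenvalue %.3g)",
                    min(ev))
  }
  modalities <- match.arg(modalities, several.ok = TRUE)
  structure(list(
    n_participants = as.integer(n_participants),
    latent_corr = latent_corr,
    good_sleeper_fraction = good_sleeper_fraction,
    sebr_rates = sebr_rates,
    text_params = text_params,
    n_stimuli = as.integer(n_stimuli),
    n_trials = as.integer(n_trials),
    blink_duration_s = blink_duration_s,
    fps = fps,
    sebr_sd = sebr_sd,
    modalities = modalities,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Eye-opening-ratio signal with planted blink events
#'
#' Baseline ratio with additive Gaussian noise; each planted blink is a
#' rectangular dip to `dip_depth` lasting `dip_frames` frames. Planted events
#' keep at least `min_separation_s` between onsets (which must exceed any
#' detector refractory period for exact recovery).
#'
#' @param rate planted blink count for the session (>= 0).
#' @param duration_s session length in seconds (> 0).
#' @param fps frames per second (> 0).
#' @param seed integer seed; the signal is deterministic under it.
#' @param baseline,noise_sd open-eye ratio level and noise SD.
#' @param dip_depth,dip_frames blink dip level and duration in frames.
#' @param min_separation_s minimum onset separation of planted events.
#' @return list with `signal`, `fps`, `event_frames` (onset frame of each
#'   planted blink), `event_times_s`, `rate`.
#' @export
generate_eye_signal <- function(rate, duration_s = 300, fps = 30, seed = 1L,
                                baseline = 0.32, noise_sd = 0.015,
                                dip_depth = 0.05, dip_frames = 4L,
                                min_separation_s = 0.5) {
  assert_scalar_num(rate, "rate", lower = 0)
  assert_scalar_num(duration_s, "duration_s")
  if (duration_s <= 0) stop_validation("`duration_s` must be > 0")
  assert_scalar_num(fps, "fps")
  if (fps <= 0) stop_validation("`fps` must be > 0")
  rate <- as.integer(round(rate))
  n_frames <- as.integer(round(duration_s * fps))
  margin <- min(1, duration_s / 10)
  usable <- duration_s - 2 * margin
  if (rate > 0 && rate * min_separation_s > usable) {
    stop_validation(
      "rate %d does not fit: %d events need %.1f s of separation but only %.1f s are usable",
      rate, rate, rate * min_separation_s, usable)
  }
  with_seed(derive_seed(seed, "eye"), {
    signal <- baseline + stats::rnorm(n_frames, 0, noise_sd)
    event_times <- numeric(0)
    if (rate > 0) {
      slack <- usable - rate * min_separation_s
      gaps <- stats::runif(rate + 1)
      gaps <- gaps / sum(gaps) * slack
      onsets <- margin + cumsum(gaps[seq_len(rate)] + min_separation_s) - min_separation_s
      event_times <- onsets
    }
    event_frames <- integer(0)
    for (t in event_times) {
      i0 <- as.integer(floor(t * fps)) + 1L
      i1 <- min(n_frames, i0 + dip_frames - 1L)
      signal[i0:i1] <- dip_depth + stats::rnorm(i1 - i0 + 1L, 0, noise_sd / 3)
      event_frames <- c(event_frames, i0)
    }
    list(signal = signal, fps = fps, event_frames = event_frames,
         event_times_s = event_times, rate = rate)
  })
}

NARRATIVE_FILLERS <- c(
  "the", "a", "this", "that", "and", "with", "over", "under", "across",
  "canvas", "painting", "image", "scene", "frame", "brushwork", "lines",
  "shapes", "colors", "tones", "light", "view", "piece", "work", "figure",
  "forms", "space", "surface", "paint", "strokes", "composition", "palette",
  "edges", "background", "foreground", "gallery", "wall", "corner", "middle",
  "here", "there", "again", "overall")

#' Generate a short narrative with target sentiment
#'
#' Draws words from the packaged sentiment lexicon plus neutral filler words
#' so that the computed Polarity (and, when constrained, Subjectivity) of the
#' output lands within `tolerance` of the targets. Both targets at 0 (or
#' `NULL`) yield pure filler text scoring exactly (0, 0). The text has
#' exactly `n_tokens` tokens under [tokenize()].
#'
#' @param polarity_target target polarity in [-1, 1], or `NULL`
#'   (unconstrained, treated as neutral).
#' @param subjectivity_target target subjectivity in [0, 1], or `NULL` to
#'   leave subjectivity unconstrained.
#' @param n_tokens total token count (>= 1).
#' @param seed integer seed (filler choice and word order only; the selected
#'   affect words are deterministic given the targets).
#' @param lexicon a [sentiment_lexicon()].
#' @param tolerance maximum accepted |achieved - target|; `NA` skips the
#'   check and returns the closest achievable text.
#' @return character string.
#' @export
generate_narrative <- function(polarity_target = 0, subjectivity_target = NULL,
                               n_tokens = 10L, seed = 1L,
                               lexicon = sentiment_lexicon(), tolerance = 0.1) {
  assert_scalar_num(n_tokens, "n_tokens", lower = 1)
  n_tokens <- as.integer(n_tokens)
  pt <- polarity_target
  st <- subjectivity_target
  if (!is.null(pt)) assert_scalar_num(pt, "polarity_target", -1, 1)
  if (!is.null(st)) assert_scalar_num(st, "subjectivity_target", 0, 1)
  neutral <- (is.null(pt) || pt == 0) && (is.null(st) || st == 0)
  pol_range <- range(lexicon$polarity)
  sub_range <- range(lexicon$subjectivity)
  if (!neutral) {
    if (!is.null(pt) && (pt < pol_range[1] || pt > pol_range[2])) {
      stop_validation("polarity_target %.2f unreachable; lexicon supports [%.2f, %.2f]",
                      pt, pol_range[1], pol_range[2])
    }
    if (!is.null(st) && st > 0 && (st < sub_range[1] - 1e-9 || st > sub_range[2] + 1e-9)) {
      stop_validation("subjectivity_target %.2f unreachable; lexicon supports [%.2f, %.2f]",
                      st, sub_range[1], sub_range[2])
    }
  }
  with_seed(derive_seed(seed, "narrative"), {
    if (neutral) {
      words <- sample(NARRATIVE_FILLERS, n_tokens, replace = TRUE)
      return(paste0(paste(words, collapse = " "), "."))
    }
    m <- max(1L, as.integer(round(n_tokens / 2)))
    # greedy selection over the lexicon: each pick minimizes the distance of
    # the running means to the targets, with a small reuse penalty to keep
    # lexical diversity; deterministic (first-index tie break, no RNG).
    pol_w <- unname(lexicon$polarity)
    sub_w <- unname(lexicon$subjectivity)
    used <- integer(length(pol_w))
    sp <- 0; ss <- 0
    picks <- integer(m)
    for (i in seq_len(m)) {
      err <- abs((sp + pol_w) / i - (if (is.null(pt)) (sp + pol_w) / i else pt))
      if (!is.null(st)) err <- err + abs((ss + sub_w) / i - st)
      err <- err + 0.02 * used
      k <- which.min(err)
      picks[i] <- k
      used[k] <- used[k] + 1L
      sp <- sp + pol_w[k]
      ss <- ss + sub_w[k]
    }
    if (!is.na(tolerance)) {
      if (!is.null(pt) && abs(sp / m - pt) > tolerance) {
        stop_validation(
          "achieved polarity %.3f misses target %.2f by more than %.2f (lexicon range [%.2f, %.2f])",
          sp / m, pt, tolerance, pol_range[1], pol_range[2])
      }
      if (!is.null(st) && abs(ss / m - st) > tolerance) {
        stop_validation(
          "achieved subjectivity %.3f misses target %.2f by more than %.2f (lexicon range [%.2f, %.2f])",
          ss / m, st, tolerance, sub_range[1], sub_range[2])
      }
    }
    affect_words <- lexicon$words[picks]
    fillers <- sample(NARRATIVE_FILLERS, n_tokens - m, replace = TRUE)
    words <- character(n_tokens)
    pos <- sort(sample.int(n_tokens, m))
    words[pos] <- affect_words
    words[setdiff(seq_len(n_tokens), pos)] <- fillers
    paste0(paste(words, collapse = " "), ".")
  })
}

# Decompose a PSQI global target (0..21) into seven 0-3 components with a
# realistic priority ordering, then construct item responses that score back
# to exactly those components.
psqi_components_for_global <- function(global) {
  order <- c("subjective_quality", "latency", "duration", "disturbances",
             "daytime_dysfunction", "efficiency", "medication")
  comps <- stats::setNames(integer(7), order)
  g <- global
  while (g > 0) {
    for (nm in order) {
      if (g == 0) break
      if (comps[nm] < 3L) {
        comps[nm] <- comps[nm] + 1L
        g <- g - 1
      }
    }
  }
  comps[c("subjective_quality", "latency", "duration", "efficiency",
          "disturbances", "medication", "daytime_dysfunction")]
}

format_clock <- function(hours) {
  hours <- hours %% 24
  h <- floor(hours)
  m <- round((hours - h) * 60)
  if (m == 60) { h <- (h + 1) %% 24; m <- 0 }
  sprintf("%02d:%02d", h, m)
}

psqi_items_for_components <- function(comps) {
  s2 <- 2L * comps[["latency"]]
  dist_latency <- min(3L, s2)
  lat_band <- s2 - dist_latency
  latency_min <- c(5, 20, 45, 90)[lat_band + 1L]
  sleep_hours <- c(7.5, 6.5, 5.5, 4)[comps[["duration"]] + 1L]
  eff_ratio <- c(0.93, 0.80, 0.70, 0.55)[comps[["efficiency"]] + 1L]
  time_in_bed <- sleep_hours / eff_ratio
  wake <- 7.5
  bed <- wake - time_in_bed
  dist_total <- c(0L, 5L, 14L, 23L)[comps[["disturbances"]] + 1L]
  base <- dist_total %/% 9L
  rem <- dist_total %% 9L
  dist <- rep(base, 9L) + c(rep(1L, rem), rep(0L, 9L - rem))
  s7 <- 2L * comps[["daytime_dysfunction"]]
  awake <- min(3L, s7)
  items <- c(
    list(bedtime = format_clock(bed), latency_min = latency_min,
         waketime = format_clock(wake), sleep_hours = sleep_hours,
         dist_latency = dist_latency),
    stats::setNames(as.list(dist), PSQI_DISTURBANCE_ITEMS),
    list(quality = comps[["subjective_quality"]],
         medication = comps[["medication"]],
         awake_trouble = awake, enthusiasm = s7 - awake)
  )
  items
}

stimulus_prototypes <- function(n_stimuli) {
  base <- rbind(
    c(8.0, 8.0), c(7.5, 7.0), c(8.5, 7.5), c(7.0, 8.5),   # HVHA
    c(3.0, 8.0), c(2.5, 7.5), c(3.5, 7.0),                 # LVHA
    c(3.0, 3.0), c(2.5, 3.5), c(3.0, 2.5), c(4.0, 3.0),    # LVLA
    c(8.0, 3.0), c(7.5, 3.5), c(7.0, 2.5), c(8.0, 4.0)     # HVLA
  )
  idx <- ((seq_len(n_stimuli) - 1L) %% nrow(base)) + 1L
  data.frame(stimulus_id = sprintf("s%02d", seq_len(n_stimuli)),
             valence_base = base[idx, 1], arousal_base = base[idx, 2],
             stringsAsFactors = FALSE)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a complete synthetic cohort
#'
#' Latent traits are drawn from a Gaussian copula with the configured
#' correlation matrix and mapped monotonically to the observables: WM trait
#' to the game agent's capacity (logistic recall), ER trait to ordinal ERQ
#' item responses, sleep trait to a PSQI global target realized through
#' instrument-consistent item responses, dopaminergic tone to per-session
#' blink counts (linear + rounding), and ER trait to per-participant
#' narrative subjectivity targets. Everything is deterministic under the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `config`,
#'   `participants` (per-participant bundles) and `truth` (latent trait
#'   matrix, sleep groups, planted blink counts and event frames, text
#'   targets, agent capacities).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_validation("`config` must be a cohort_config()")
  }
  n <- config$n_participants
  mods <- config$modalities
  # Gaussian copula draw: eigendecomposition handles PSD (possibly singular)
  ed <- eigen(config$latent_corr, symmetric = TRUE)
  root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
  latent <- with_seed(derive_seed(config$seed, "latent"), {
    z <- matrix(stats::rnorm(n * 4), n, 4)
    z %*% root
  })
  colnames(latent) <- LATENT_TRAITS
  ids <- sprintf("p%03d", seq_len(n))
  rownames(latent) <- ids

  tp <- config$text_params
  lex <- sentiment_lexicon()
  participants <- vector("list", n)
  truth_group <- character(n)
  truth_counts <- matrix(NA_integer_, n, 2, dimnames = list(ids, c("pre", "post")))
  truth_events <- vector("list", n)
  truth_text <- data.frame(participant_id = ids, polarity_target = NA_real_,
                           subjectivity_target = NA_real_)
  capacities <- numeric(n)
  protos <- stimulus_prototypes(config$n_stimuli)

  for (p in seq_len(n)) {
    z <- latent[p, ]
    bundle <- list(participant_id = ids[p])

    # --- sleep: PSQI target global from the sleep-trait percentile ----------
    u <- stats::pnorm(z[["sleep"]])
    f <- config$good_sleeper_fraction
    g_target <- if (f > 0 && u < f) {
      as.integer(floor(u / f * 6))                      # 0..5 -> Good
    } else if (f < 1) {
      min(21L, 6L + as.integer(floor((u - f) / (1 - f) * 16)))  # 6..21 -> Poor
    } else 0L
    comps <- psqi_components_for_global(g_target)
    psqi_items <- psqi_items_for_components(comps)
    group <- classify_sleeper(g_target)
    truth_group[p] <- group

    if ("questionnaires" %in% mods) {
      bundle$psqi_items <- psqi_items
      bundle$erq_responses <- with_seed(derive_seed(config$seed, "erq", p), {
        lat <- 0.8 * z[["er"]] + 0.6 * stats::rnorm(10)
        as.integer(findInterval(lat, stats::qnorm((1:6) / 7)) + 1L)
      })
    }

    # --- WM: agent capacity from the WM trait -------------------------------
    capacities[p] <- 6.8 + 1.5 * z[["wm"]]
    if ("wm" %in% mods) {
      agent <- agent_model(capacity = capacities[p], slope = 2, lapse = 0.02)
      bundle$trial_log <- simulate_session(
        agent, game_config(), n_trials = config$n_trials,
        seed = derive_seed(config$seed, "session", p), participant_id = ids[p])
    }

    # --- ratings + narratives ----------------------------------------------
    pol_t <- sub_t <- NA_real_
    if ("ratings" %in% mods) {
      rt <- with_seed(derive_seed(config$seed, "ratings", p), {
        ar_bias <- -0.6 * z[["wm"]] + stats::rnorm(1, 0, 0.7)
        val_bias <- stats::rnorm(1, 0, 0.5)
        arousal <- clamp(round(protos$arousal_base + ar_bias +
                                 stats::rnorm(config$n_stimuli, 0, 0.8)), 1, 10)
        valence <- clamp(round(protos$valence_base + val_bias +
                                 stats::rnorm(config$n_stimuli, 0, 0.8)), 1, 10)
        familiarity <- clamp(round(stats::rnorm(config$n_stimuli, 4, 2)), 1, 10)
        pol_t <- clamp(tp$polarity_mean + tp$polarity_sd * stats::rnorm(1),
                       -0.6, 0.8)
        sub_t <- clamp(tp$subjectivity_mean +
                         tp$subjectivity_sd * (tp$er_loading * z[["er"]] +
                                                 sqrt(1 - tp$er_loading^2) * stats::rnorm(1)),
                       0.2, 0.9)
        n_tok <- pmax(3, round(stats::rnorm(config$n_stimuli, tp$tokens_mean,
                                            tp$tokens_sd)))
        list(arousal = arousal, valence = valence, familiarity = familiarity,
             pol_t = pol_t, sub_t = sub_t, n_tok = n_tok)
      })
      pol_t <- rt$pol_t
      sub_t <- rt$sub_t
      comments <- vapply(seq_len(config$n_stimuli), function(s) {
        generate_narrative(rt$pol_t, rt$sub_t, n_tokens = rt$n_tok[s],
                           seed = derive_seed(config$seed, "text", p, s),
                           lexicon = lex, tolerance = NA)
      }, character(1))
      order_perm <- with_seed(derive_seed(config$seed, "order", p),
                              sample.int(config$n_stimuli))
      bundle$ratings <- data.frame(
        participant_id = ids[p],
        stimulus_id = protos$stimulus_id,
        presentation_index = order(order_perm),
        arousal = rt$arousal,
        valence = rt$valence,
        familiarity = rt$familiarity,
        comment = comments,
        timestamp = format(as.POSIXct("2026-01-01 10:00:00", tz = "UTC") +
                             60 * seq_len(config$n_stimuli), "%Y-%m-%dT%H:%M:%SZ"),
        stringsAsFactors = FALSE
      )
    }
    truth_text$polarity_target[p] <- pol_t
    truth_text$subjectivity_target[p] <- sub_t

    # --- blinks: per-group mean counts modulated by dopaminergic tone -------
    rates <- config$sebr_rates[[tolower(group)]]
    counts <- with_seed(derive_seed(config$seed, "sebr", p), {
      pre <- max(0, round(rates[[1]] + config$sebr_sd * z[["dopamine"]]))
      post <- max(0, round(rates[[2]] + config$sebr_sd * z[["dopamine"]] +
                             stats::rnorm(1, 0, 5)))
      c(pre, post)
    })
    truth_counts[p, ] <- as.integer(counts)
    if ("blinks" %in% mods) {
      eye_pre <- generate_eye_signal(counts[1], config$blink_duration_s,
                                     config$fps,
                                     seed = derive_seed(config$seed, "eyepre", p))
      eye_post <- generate_eye_signal(counts[2], config$blink_duration_s,
                                      config$fps,
                                      seed = derive_seed(config$seed, "eyepost", p))
      bundle$eye_pre <- eye_pre
      bundle$eye_post <- eye_post
      truth_events[[p]] <- list(pre = eye_pre$event_frames,
                                post = eye_post$event_frames)
    }
    participants[[p]] <- bundle
  }

  structure(list(
    config = config,
    participants = participants,
    truth = list(
      latent = latent,
      sleep_group = stats::setNames(truth_group, ids),
      blink_counts = truth_counts,
      blink_event_frames = stats::setNames(truth_events, ids),
      text_targets = truth_text,
      agent_capacity = stats::setNames(capacities, ids)
    )
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d participants (%d good / %d poor sleepers), seed %d\n",
              x$config$n_participants,
              sum(x$truth$sleep_group == "Good"),
              sum(x$truth$sleep_group == "Poor"),
              x$config$seed))
  invisible(x)
}

#' Write a cohort to the pipeline's CSV schemas
#'
#' Emits `wm_trials.csv`, `questionnaires.csv`, `art_ratings.csv`,
#' `eye_signals.csv` (long: participant_id, phase, frame, ratio) and a
#' `truth.json` sidecar of planted parameters.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- cohort$participants
  if (!is.null(parts[[1]]$trial_log)) {
    wm <- do.call(rbind, lapply(parts, `[[`, "trial_log"))
    utils::write.csv(wm, file.path(dir, "wm_trials.csv"), row.names = FALSE)
  }
  if (!is.null(parts[[1]]$psqi_items)) {
    q <- do.call(rbind, lapply(parts, function(b) {
      psqi <- data.frame(participant_id = b$participant_id, instrument = "PSQI",
                         item_id = names(b$psqi_items),
                         response = vapply(b$psqi_items, as.character, character(1)),
                         stringsAsFactors = FALSE)
      erq <- data.frame(participant_id = b$participant_id, instrument = "ERQ",
                        item_id = paste0("erq_", seq_along(b$erq_responses)),
                        response = as.character(b$erq_responses),
                        stringsAsFactors = FALSE)
      rbind(psqi, erq)
    }))
    utils::write.csv(q, file.path(dir, "questionnaires.csv"), row.names = FALSE)
  }
  if (!is.null(parts[[1]]$ratings)) {
    r <- do.call(rbind, lapply(parts, `[[`, "ratings"))
    utils::write.csv(r, file.path(dir, "art_ratings.csv"), row.names = FALSE)
  }
  if (!is.null(parts[[1]]$eye_pre)) {
    e <- do.call(rbind, lapply(parts, function(b) {
      rbind(
        data.frame(participant_id = b$participant_id, phase = "pre",
                   frame = seq_along(b$eye_pre$signal),
                   ratio = round(b$eye_pre$signal, 5)),
        data.frame(participant_id = b$participant_id, phase = "post",
                   frame = seq_along(b$eye_post$signal),
                   ratio = round(b$eye_post$signal, 5))
      )
    }))
    utils::write.csv(e, file.path(dir, "eye_signals.csv"), row.names = FALSE)
  }
  truth <- cohort$truth
  truth_json <- list(
    latent = as.data.frame(truth$latent),
    sleep_group = as.list(truth$sleep_group),
    blink_counts = as.data.frame(truth$blink_counts),
    text_targets = truth$text_targets,
    agent_capacity = as.list(truth$agent_capacity),
    seed = cohort$config$seed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
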
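# End-to-end pipeline: score all modalities, assemble the participant x
# variable cohort table, filter outliers, run the permutation correlation
# matrix, sleep-group Mann-Whitney comparisons, and the HVHA regression.

#' Analysis configuration
#'
#' Defaults encode the validated analysis choices: 2000 permutations, alpha
#' 0.05, a 2-SD listwise outlier filter, and a PSQI good/poor threshold of 5.
#'
#' @param n_perm permutations for the correlation matrix (>= 1).
#' @param alpha significance level in (0,1).
#' @param outlier_k SD multiplier for the outlier filter (> 0).
#' @param psqi_threshold good/poor sleeper cut on the PSQI global score.
#' @param variable_set `"paper"` (the published variable list: three WM
#'   scores, three ER scores, six PSQI components + global, sEBR pre/post/
#'   diff, six text features) or `"full"` (adds the remaining WM metrics,
#'   the medication component and the HVHA deviation).
#' @param score_mode per-trial score mode for [score_session()].
#' @param seed integer seed for the permutation machinery.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(n_perm = 2000, alpha = 0.05, outlier_k = 2,
                            psqi_threshold = 5L,
                            variable_set = c("paper", "full"),
                            score_mode = c("cumulative", "per_trial"),
                            seed = 1L) {
  variable_set <- match.arg(variable_set)
  score_mode <- match.arg(score_mode)
  assert_scalar_num(n_perm, "n_perm", lower = 1)
  assert_scalar_num(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_validation("`alpha` must be in (0,1)")
  assert_scalar_num(outlier_k, "outlier_k")
  if (outlier_k <= 0) stop_validation("`outlier_k` must be > 0")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 outlier_k = outlier_k,
                 psqi_threshold = as.integer(psqi_threshold),
                 variable_set = variable_set, score_mode = score_mode,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read pipeline input CSVs from a directory
#'
#' Expects the schemas written by [write_cohort_csv()]: `wm_trials.csv`,
#' `questionnaires.csv`, `art_ratings.csv`, `eye_signals.csv`.
#'
#' @param dir input directory.
#' @return list of data.frames (`wm_trials`, `questionnaires`, `art_ratings`,
#'   `eye_signals`), with `NULL` for files not present.
#' @export
read_cohort_csv <- function(dir) {
  rd <- function(name, required = FALSE) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      if (required) stop_validation("missing input file: %s", path)
      return(NULL)
    }
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  }
  list(wm_trials = rd("wm_trials.csv"),
       questionnaires = rd("questionnaires.csv", required = TRUE),
       art_ratings = rd("art_ratings.csv"),
       eye_signals = rd("eye_signals.csv"))
}

cohort_to_inputs <- function(cohort) {
  parts <- cohort$participants
  grab <- function(field) {
    vals <- lapply(parts, `[[`, field)
    if (all(vapply(vals, is.null, logical(1)))) NULL else vals
  }
  wm <- grab("trial_log")
  ratings <- grab("ratings")
  q <- lapply(parts, function(b) {
    if (is.null(b$psqi_items)) return(NULL)
    list(participant_id = b$participant_id, psqi_items = b$psqi_items,
         erq_responses = b$erq_responses)
  })
  eye <- lapply(parts, function(b) {
    if (is.null(b$eye_pre)) return(NULL)
    list(participant_id = b$participant_id, pre = b$eye_pre, post = b$eye_post)
  })
  list(wm_trials = if (is.null(wm)) NULL else do.call(rbind, wm),
       questionnaire_bundles = q,
       art_ratings = if (is.null(ratings)) NULL else do.call(rbind, ratings),
       eye_bundles = eye)
}

score_wm_table <- function(wm_trials, score_mode = "cumulative") {
  ids <- unique(wm_trials$participant_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- score_session(wm_trials[wm_trials$participant_id == id, , drop = FALSE],
                       score_mode = score_mode)
    cbind(data.frame(participant_id = id, stringsAsFactors = FALSE), s)
  }))
  out
}

questionnaires_long_to_bundles <- function(q) {
  need <- c("participant_id", "instrument", "item_id", "response")
  if (!all(need %in% names(q))) {
    stop_validation("questionnaires table needs columns: %s",
                    paste(need, collapse = ", "))
  }
  ids <- unique(q$participant_id)
  lapply(ids, function(id) {
    sub <- q[q$participant_id == id, , drop = FALSE]
    psqi <- sub[sub$instrument == "PSQI", , drop = FALSE]
    erq <- sub[sub$instrument == "ERQ", , drop = FALSE]
    items <- as.list(psqi$response)
    names(items) <- psqi$item_id
    for (nm in setdiff(names(items), c("bedtime", "waketime"))) {
      items[[nm]] <- as.numeric(items[[nm]])
    }
    erq_resp <- as.numeric(erq$response[order(as.integer(sub("erq_", "", erq$item_id)))])
    list(participant_id = id, psqi_items = items, erq_responses = erq_resp)
  })
}

score_questionnaire_bundles <- function(bundles, psqi_threshold = 5L) {
  do.call(rbind, lapply(bundles, function(b) {
    psqi <- score_psqi(b$psqi_items, threshold = psqi_threshold)
    erq <- score_erq(b$erq_responses)
    data.frame(
      participant_id = b$participant_id,
      psqi_subjective_quality = psqi$components[["subjective_quality"]],
      psqi_latency = psqi$components[["latency"]],
      psqi_duration = psqi$components[["duration"]],
      psqi_efficiency = psqi$components[["efficiency"]],
      psqi_disturbances = psqi$components[["disturbances"]],
      psqi_medication = psqi$components[["medication"]],
      psqi_daytime_dysfunction = psqi$components[["daytime_dysfunction"]],
      psqi_global = psqi$global,
      sleep_group = psqi$group,
      er_reappraisal = erq$cognitive_reappraisal,
      er_suppression = erq$expressive_suppression,
      er_total = erq$total,
      stringsAsFactors = FALSE
    )
  }))
}

text_feature_table <- function(art_ratings, lexicon = sentiment_lexicon()) {
  feats <- do.call(rbind, lapply(seq_len(nrow(art_ratings)), function(i) {
    text_features(art_ratings$comment[i], lexicon)
  }))
  feats$participant_id <- art_ratings$participant_id
  agg <- stats::aggregate(
    cbind(polarity, subjectivity, avg_word_length, token_count,
          unique_tokens, type_token_ratio) ~ participant_id,
    data = feats, FUN = mean, na.action = stats::na.omit)
  agg[order(agg$participant_id), , drop = FALSE]
}

eye_long_to_bundles <- function(eye_signals, fps = 30) {
  ids <- unique(eye_signals$participant_id)
  lapply(ids, function(id) {
    sub <- eye_signals[eye_signals$participant_id == id, , drop = FALSE]
    get_phase <- function(ph) {
      s <- sub[sub$phase == ph, , drop = FALSE]
      s <- s[order(s$frame), , drop = FALSE]
      list(signal = s$ratio, fps = fps)
    }
    list(participant_id = id, pre = get_phase("pre"), post = get_phase("post"))
  })
}

sebr_table <- function(eye_bundles, blink_cfg = blink_config()) {
  do.call(rbind, lapply(eye_bundles, function(b) {
    pre <- detect_blinks(b$pre$signal, fps = b$pre$fps, config = blink_cfg)
    post <- detect_blinks(b$post$signal, fps = b$post$fps, config = blink_cfg)
    s <- summarize_sebr(pre, post)
    data.frame(participant_id = b$participant_id, sebr_pre = s$sebr_pre,
               sebr_post = s$sebr_post, sebr_diff = s$sebr_diff,
               stringsAsFactors = FALSE)
  }))
}

paper_variable_set <- function() {
  c("num_correct_responses", "max_score", "mean_score",
    "er_total", "er_reappraisal", "er_suppression",
    "psqi_subjective_quality", "psqi_latency", "psqi_duration",
    "psqi_efficiency", "psqi_disturbances", "psqi_daytime_dysfunction",
    "psqi_global",
    "sebr_pre", "sebr_post", "sebr_diff",
    "polarity", "subjectivity", "avg_word_length",
    "token_count", "unique_tokens", "type_token_ratio")
}

full_variable_set <- function() {
  c(paper_variable_set(),
    "num_total_responses", "median_score", "count_above_0_25",
    "count_above_0_5", "successive_correct_count", "psqi_medication",
    "hvha_deviation")
}

#' Assemble the participant x variable cohort table
#'
#' Joins the scored modalities on `participant_id` (full outer join; missing
#' modalities yield missing cells). Every participant id present in the
#' trial, rating or blink data must appear in the questionnaires.
#'
#' @param wm_scores,quest_scores,text_feats,sebr,hvha per-modality score
#'   tables (any but `quest_scores` may be `NULL`).
#' @return data.frame keyed by `participant_id`.
#' @export
assemble_cohort_table <- function(wm_scores = NULL, quest_scores = NULL,
                                  text_feats = NULL, sebr = NULL, hvha = NULL) {
  if (is.null(quest_scores)) stop_validation("questionnaire scores are required")
  known <- quest_scores$participant_id
  tabs <- list(wm = wm_scores, text = text_feats, sebr = sebr, hvha = hvha)
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    if (is.null(t)) next
    orphans <- setdiff(t$participant_id, known)
    if (length(orphans)) {
      stop_validation("participant id(s) in %s data missing from questionnaires: %s",
                      nm, paste(sort(orphans), collapse = ", "))
    }
  }
  out <- quest_scores
  for (t in tabs) {
    if (is.null(t)) next
    out <- merge(out, t, by = "participant_id", all = TRUE, sort = TRUE)
  }
  out[order(out$participant_id), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Stages, in order: score all present modalities; assemble the cohort table;
#' listwise outlier filtering at `outlier_k` SDs over the selected analysis
#' variables; permutation-based Spearman correlation matrix; PSQI sleep-group
#' split with Mann-Whitney tests per variable; OLS regression of the WM mean
#' score on the HVHA arousal deviation. Deterministic under
#' (inputs, config seed).
#'
#' @param inputs a `synthetic_cohort`, a directory of input CSVs, or a list
#'   as returned by [read_cohort_csv()].
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, writes `cohort_table.csv`,
#'   `correlations.csv`, `group_tests.csv`, `regression_report.json`,
#'   `exclusions.csv` and `report.json`.
#' @param fps frames per second assumed for CSV-sourced eye signals.
#' @return an `analysis_report` list: `cohort_summary`, `cohort_table`,
#'   `filtered_table`, `exclusions`, `correlation`, `group_tests`,
#'   `regression`, `provenance`.
#' @export
run_pipeline <- function(inputs, config = analysis_config(), out_dir = NULL,
                         fps = 30) {
  if (inherits(inputs, "synthetic_cohort")) {
    src <- cohort_to_inputs(inputs)
    fps <- inputs$config$fps
  } else if (is.character(inputs) && length(inputs) == 1L) {
    raw <- read_cohort_csv(inputs)
    src <- list(
      wm_trials = raw$wm_trials,
      questionnaire_bundles = questionnaires_long_to_bundles(raw$questionnaires),
      art_ratings = raw$art_ratings,
      eye_bundles = if (is.null(raw$eye_signals)) NULL
                    else eye_long_to_bundles(raw$eye_signals, fps = fps)
    )
  } else if (is.list(inputs)) {
    src <- list(
      wm_trials = inputs$wm_trials,
      questionnaire_bundles = if (!is.null(inputs$questionnaire_bundles))
        inputs$questionnaire_bundles
      else questionnaires_long_to_bundles(inputs$questionnaires),
      art_ratings = inputs$art_ratings,
      eye_bundles = if (!is.null(inputs$eye_bundles)) inputs$eye_bundles
                    else if (is.null(inputs$eye_signals)) NULL
                    else eye_long_to_bundles(inputs$eye_signals, fps = fps)
    )
  } else {
    stop_validation("`inputs` must be a synthetic_cohort, a directory, or an input list")
  }
  if (is.null(src$questionnaire_bundles) ||
      all(vapply(src$questionnaire_bundles, is.null, logical(1)))) {
    stop_validation("questionnaire data are required (sleep grouping and ER scores)")
  }

  quest <- score_questionnaire_bundles(src$questionnaire_bundles,
                                       psqi_threshold = config$psqi_threshold)
  wm <- if (!is.null(src$wm_trials)) score_wm_table(src$wm_trials, config$score_mode)
  text <- if (!is.null(src$art_ratings)) text_feature_table(src$art_ratings)
  sebr <- if (!is.null(src$eye_bundles) &&
              !all(vapply(src$eye_bundles, is.null, logical(1))))
    sebr_table(src$eye_bundles)
  hvha <- if (!is.null(src$art_ratings)) {
    dev <- tryCatch(hvha_deviation(src$art_ratings),
                    createlab_validation_error = function(e) NULL)
    dev
  }
  table <- assemble_cohort_table(wm, quest, text, sebr, hvha)

  vars <- if (config$variable_set == "paper") paper_variable_set() else full_variable_set()
  vars <- intersect(vars, names(table))
  analysis_table <- table[, c("participant_id", vars), drop = FALSE]

  filt <- filter_outliers(analysis_table, k = config$outlier_k)
  filtered <- filt$table

  corr <- permutation_correlation_matrix(filtered, n_perm = config$n_perm,
                                         alpha = config$alpha,
                                         seed = config$seed)

  groups <- table$sleep_group[match(filtered$participant_id, table$participant_id)]
  group_tests <- NULL
  if (length(unique(groups)) == 2L) {
    group_tests <- do.call(rbind, lapply(vars, function(v) {
      a <- filtered[[v]][groups == "Good"]
      b <- filtered[[v]][groups == "Poor"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 1L || length(b) < 1L) return(NULL)
      mw <- mann_whitney(a, b, variable = v)
      data.frame(variable = v, n_good = mw$n1, n_poor = mw$n2, U = mw$U,
                 p_two_sided = mw$p_two_sided, method = mw$method,
                 stringsAsFactors = FALSE)
    }))
  }

  regression <- NULL
  if (!is.null(hvha) && "mean_score" %in% names(table)) {
    reg_tab <- merge(filtered[, c("participant_id", "mean_score")],
                     table[, c("participant_id", "hvha_deviation")],
                     by = "participant_id")
    ok <- stats::complete.cases(reg_tab[, c("mean_score", "hvha_deviation")])
    if (sum(ok) >= 4L && stats::sd(reg_tab$hvha_deviation[ok]) > 0) {
      regression <- ols_fit(reg_tab$hvha_deviation[ok], reg_tab$mean_score[ok])
    }
  }

  report <- list(
    cohort_summary = list(
      n_input = nrow(table),
      n_excluded = nrow(table) - nrow(filtered),
      n_analyzed = nrow(filtered),
      n_good = sum(groups == "Good"),
      n_poor = sum(groups == "Poor")
    ),
    cohort_table = table,
    filtered_table = filtered,
    exclusions = filt$excluded,
    correlation = corr,
    group_tests = group_tests,
    regression = regression,
    provenance = list(
      seed = config$seed, n_perm = config$n_perm, alpha = config$alpha,
      outlier_k = config$outlier_k, psqi_threshold = config$psqi_threshold,
      variable_set = config$variable_set, score_mode = config$score_mode,
      package_version = as.character(utils::packageVersion("createlab"))
    )
  )
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_analysis_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) if (is.numeric(x)) round(x, 10) else x
  tab <- report$cohort_table
  tab[] <- lapply(tab, num)
  utils::write.csv(tab, file.path(dir, "cohort_table.csv"), row.names = FALSE)
  cl <- correlation_long(report$correlation)
  cl$rho <- round(cl$rho, 10)
  utils::write.csv(cl, file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(report$group_tests)) {
    gt <- report$group_tests
    gt$p_two_sided <- round(gt$p_two_sided, 10)
    utils::write.csv(gt, file.path(dir, "group_tests.csv"), row.names = FALSE)
  }
  if (!is.null(report$regression)) {
    r <- report$regression
    reg_json <- list(
      n = r$n, r_squared = r$r_squared, adj_r_squared = r$adj_r_squared,
      f_statistic = r$f_statistic, prob_f = r$prob_f, aic = r$aic, bic = r$bic,
      intercept = r$coefficients$estimate[1],
      intercept_std_error = r$coefficients$std_error[1],
      intercept_p_value = r$coefficients$p_value[1],
      coefficient = r$coefficients$estimate[2],
      coefficient_std_error = r$coefficients$std_error[2],
      coefficient_t = r$coefficients$t_value[2],
      coefficient_p_value = r$coefficients$p_value[2],
      conf_int = c(r$coefficients$ci_lower[2], r$coefficients$ci_upper[2]),
      durbin_watson = r$durbin_watson, omnibus = r$omnibus,
      prob_omnibus = r$prob_omnibus, jarque_bera = r$jarque_bera,
      skewness = r$skewness, kurtosis = r$kurtosis,
      condition_number = r$condition_number
    )
    jsonlite::write_json(lapply(reg_json, num),
                         file.path(dir, "regression_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary_json <- c(report$cohort_summary, report$provenance)
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$cohort_summary
  cat(sprintf("analysis report: %d analyzed (%d excluded of %d); %d good / %d poor sleepers\n",
              s$n_analyzed, s$n_excluded, s$n_input, s$n_good, s$n_poor))
  sig <- correlation_long(x$correlation)
  sig <- sig[!is.na(sig$p) & sig$significant, , drop = FALSE]
  cat(sprintf("significant correlations at alpha %.2f: %d of %d tested pairs\n",
              x$correlation$alpha, nrow(sig),
              sum(!is.na(correlation_long(x$correlation)$p))))
  if (!is.null(x$regression)) {
    cat(sprintf("regression mean_score ~ hvha_deviation: R2 = %.3f, slope = %.3f (p = %.4f)\n",
                x$regression$r_squared, x$regression$coefficients$estimate[2],
                x$regression$coefficients$p_value[2]))
  }
  invisible(x)
}
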
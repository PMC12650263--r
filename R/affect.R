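# Valence-arousal plane analysis of 1-10 stimulus ratings: quadrant labels
# and the per-participant HVHA arousal-deviation predictor.

#' Classify a point in the valence-arousal plane
#'
#' Values strictly above the scale midpoint (5.5 for a 1-10 slider) count as
#' "high"; boundary values are "low", making the labeling deterministic.
#'
#' @param valence_mean,arousal_mean means within [1,10] (vectorized).
#' @param midpoint scale midpoint, default 5.5.
#' @return character vector of quadrant labels `HVHA`, `LVHA`, `LVLA`, `HVLA`.
#' @export
classify_quadrant <- function(valence_mean, arousal_mean, midpoint = 5.5) {
  if (any(valence_mean < 1 | valence_mean > 10) ||
      any(arousal_mean < 1 | arousal_mean > 10)) {
    stop_validation("valence/arousal means must lie in [1, 10]")
  }
  hv <- valence_mean > midpoint
  ha <- arousal_mean > midpoint
  ifelse(hv & ha, "HVHA", ifelse(!hv & ha, "LVHA", ifelse(!hv & !ha, "LVLA", "HVLA")))
}

validate_ratings <- function(ratings) {
  need <- c("participant_id", "stimulus_id", "arousal", "valence")
  missing_cols <- setdiff(need, names(ratings))
  if (length(missing_cols)) {
    stop_validation("ratings lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  for (col in c("arousal", "valence")) {
    v <- ratings[[col]]
    if (any(!is.finite(v)) || any(v < 1 | v > 10)) {
      stop_validation("`%s` ratings must lie in [1, 10]", col)
    }
  }
  invisible(ratings)
}

#' Per-stimulus and per-participant affect summary
#'
#' Computes mean valence/arousal per stimulus (over all participants) and per
#' participant (over all stimuli), labels each stimulus's quadrant from its
#' group means, and derives the per-participant HVHA arousal deviation.
#' Presentation order is metadata and never affects any output.
#'
#' @param ratings data.frame with `participant_id`, `stimulus_id`, `arousal`,
#'   `valence` (familiarity/comment columns are carried but unused here).
#' @param midpoint scale midpoint for [classify_quadrant()].
#' @param reduce how to aggregate a participant's signed arousal differences
#'   over HVHA stimuli: "mean" (default), "sum" or "median".
#' @return list with `stimulus_means` (data.frame: stimulus_id, valence_mean,
#'   arousal_mean, quadrant), `participant_means`, and `hvha_deviation`
#'   (data.frame: participant_id, hvha_deviation).
#' @export
affect_summary <- function(ratings, midpoint = 5.5,
                           reduce = c("mean", "sum", "median")) {
  reduce <- match.arg(reduce)
  validate_ratings(ratings)
  sm <- stats::aggregate(cbind(valence, arousal) ~ stimulus_id, data = ratings, FUN = mean)
  names(sm) <- c("stimulus_id", "valence_mean", "arousal_mean")
  sm <- sm[order(sm$stimulus_id), , drop = FALSE]
  sm$quadrant <- classify_quadrant(sm$valence_mean, sm$arousal_mean, midpoint)
  pm <- stats::aggregate(cbind(valence, arousal) ~ participant_id, data = ratings, FUN = mean)
  names(pm) <- c("participant_id", "valence_mean", "arousal_mean")
  pm <- pm[order(pm$participant_id), , drop = FALSE]
  dev <- hvha_deviation(ratings, stimulus_means = sm, reduce = reduce)
  list(stimulus_means = sm, participant_means = pm, hvha_deviation = dev)
}

#' Per-participant HVHA arousal deviation
#'
#' For stimuli whose group-mean valence and arousal classify as HVHA, each
#' participant's signed differences (own arousal rating minus the stimulus's
#' group-mean arousal) are aggregated (mean by default). Participants missing
#' ratings for some HVHA stimuli aggregate over the ones they rated.
#'
#' @inheritParams affect_summary
#' @param stimulus_means optionally precomputed stimulus means with a
#'   `quadrant` column (as from [affect_summary()]); recomputed otherwise.
#' @return data.frame with `participant_id` and `hvha_deviation`.
#' @export
hvha_deviation <- function(ratings, midpoint = 5.5, stimulus_means = NULL,
                           reduce = c("mean", "sum", "median")) {
  reduce <- match.arg(reduce)
  validate_ratings(ratings)
  if (is.null(stimulus_means)) {
    sm <- stats::aggregate(cbind(valence, arousal) ~ stimulus_id, data = ratings, FUN = mean)
    names(sm) <- c("stimulus_id", "valence_mean", "arousal_mean")
    sm$quadrant <- classify_quadrant(sm$valence_mean, sm$arousal_mean, midpoint)
  } else {
    sm <- stimulus_means
  }
  hvha_ids <- sm$stimulus_id[sm$quadrant == "HVHA"]
  if (length(hvha_ids) == 0L) {
    stop_validation(paste0(
      "no stimulus classifies as HVHA by its group means; ",
      "inspect the quadrant labels (affect_summary()$stimulus_means)"))
  }
  sub <- ratings[ratings$stimulus_id %in% hvha_ids, , drop = FALSE]
  mean_map <- stats::setNames(sm$arousal_mean, as.character(sm$stimulus_id))
  sub$diff <- sub$arousal - mean_map[as.character(sub$stimulus_id)]
  agg_fun <- switch(reduce, mean = mean, sum = sum, median = stats::median)
  out <- stats::aggregate(diff ~ participant_id, data = sub, FUN = agg_fun)
  names(out) <- c("participant_id", "hvha_deviation")
  out[order(out$participant_id), , drop = FALSE]
}
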
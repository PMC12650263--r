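# PSQI and ERQ questionnaire scoring and sleep-group classification.
#
# PSQI item schema used throughout the package (19 self-rated items):
#   bedtime          "HH:MM" usual bed time
#   latency_min      minutes to fall asleep
#   waketime         "HH:MM" usual getting-up time
#   sleep_hours      hours of actual sleep per night
#   dist_latency     cannot fall asleep within 30 min (0-3)     [disturbance a]
#   dist_wake, dist_bathroom, dist_breathe, dist_cough, dist_cold,
#   dist_hot, dist_dreams, dist_pain, dist_other                (each 0-3)
#   quality          subjective sleep quality (0 best - 3 worst)
#   medication       sleep medication use (0-3)
#   awake_trouble    trouble staying awake (0-3)
#   enthusiasm       problems keeping up enthusiasm (0-3)

PSQI_DISTURBANCE_ITEMS <- c("dist_wake", "dist_bathroom", "dist_breathe",
                            "dist_cough", "dist_cold", "dist_hot",
                            "dist_dreams", "dist_pain", "dist_other")

PSQI_ITEMS <- c("bedtime", "latency_min", "waketime", "sleep_hours",
                "dist_latency", PSQI_DISTURBANCE_ITEMS,
                "quality", "medication", "awake_trouble", "enthusiasm")

#' Standard ERQ item-to-subscale assignment
#'
#' Cognitive Reappraisal: items 1, 3, 5, 7, 8, 10; Expressive Suppression:
#' items 2, 4, 6, 9. Overridable wherever an item map is accepted.
#' @export
erq_item_map <- function() {
  list(reappraisal = c(1L, 3L, 5L, 7L, 8L, 10L),
       suppression = c(2L, 4L, 6L, 9L))
}

parse_clock <- function(x, name) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop_validation("`%s` ('%s') is not an HH:MM time", name, x)
  h <- as.numeric(m[2]); mn <- as.numeric(m[3])
  if (h > 23 || mn > 59) stop_validation("`%s` ('%s') is not a valid time", name, x)
  h + mn / 60
}

band4 <- function(x, cuts) {
  # cuts: increasing breakpoints c(a,b,c); x<=a -> 0, x<=b -> 1, x<=c -> 2, else 3
  sum(x > cuts)
}

#' Score the Pittsburgh Sleep Quality Index
#'
#' Computes the seven 0-3 components (subjective quality, latency, duration,
#' habitual efficiency, disturbances, medication use, daytime dysfunction),
#' the global score (their sum, 0-21) and the Good/Poor sleeper label.
#'
#' @param items named list or one-row data.frame holding the 19 items of the
#'   package's PSQI schema (see source header for names and ranges).
#' @param threshold global-score cut for [classify_sleeper()].
#' @return list with `components` (named integer vector of 7), `global`
#'   and `group` ("Good"/"Poor").
#' @export
score_psqi <- function(items, threshold = 5L) {
  items <- as.list(items)
  missing_items <- setdiff(PSQI_ITEMS, names(items))
  if (length(missing_items)) {
    stop_validation("missing PSQI item(s): %s", paste(missing_items, collapse = ", "))
  }
  ord <- c("dist_latency", PSQI_DISTURBANCE_ITEMS, "quality", "medication",
           "awake_trouble", "enthusiasm")
  for (nm in ord) {
    v <- items[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 3 || v != round(v)) {
      stop_validation("PSQI item `%s` must be an integer in 0-3", nm)
    }
  }
  latency_min <- items$latency_min
  sleep_hours <- items$sleep_hours
  assert_scalar_num(latency_min, "latency_min", lower = 0)
  assert_scalar_num(sleep_hours, "sleep_hours", lower = 0, upper = 24)

  c1 <- as.integer(items$quality)

  lat_band <- band4(latency_min, c(15, 30, 60))
  s2 <- lat_band + items$dist_latency
  c2 <- band4(s2, c(0, 2, 4))

  # duration bands: >7h -> 0, 6-7 -> 1, 5-<6 -> 2, <5 -> 3
  c3 <- if (sleep_hours > 7) 0L else if (sleep_hours >= 6) 1L else if (sleep_hours >= 5) 2L else 3L

  bed <- parse_clock(items$bedtime, "bedtime")
  wake <- parse_clock(items$waketime, "waketime")
  time_in_bed <- (wake - bed) %% 24
  if (time_in_bed == 0) time_in_bed <- 24
  eff <- 100 * sleep_hours / time_in_bed
  if (eff > 100) {
    warning("sleep efficiency > 100% (sleep_hours exceeds time in bed); clamped to 100")
    eff <- 100
  }
  c4 <- if (eff >= 85) 0L else if (eff >= 75) 1L else if (eff >= 65) 2L else 3L

  dist_sum <- sum(vapply(items[PSQI_DISTURBANCE_ITEMS], as.numeric, numeric(1)))
  c5 <- band4(dist_sum, c(0, 9, 18))

  c6 <- as.integer(items$medication)

  s7 <- items$awake_trouble + items$enthusiasm
  c7 <- band4(s7, c(0, 2, 4))

  components <- c(subjective_quality = c1, latency = as.integer(c2),
                  duration = c3, efficiency = c4,
                  disturbances = as.integer(c5), medication = c6,
                  daytime_dysfunction = as.integer(c7))
  global <- as.integer(sum(components))
  list(components = components, global = global,
       group = classify_sleeper(global, threshold))
}

#' Classify Good vs Poor sleeper from the PSQI global score
#'
#' Higher global scores indicate worse sleep; scores strictly above the
#' threshold (default 5) classify as Poor, at or below as Good.
#'
#' @param global PSQI global score in 0-21.
#' @param threshold integer cut, default 5.
#' @return `"Good"` or `"Poor"` (vectorized over `global`).
#' @export
classify_sleeper <- function(global, threshold = 5L) {
  if (any(!is.finite(global)) || any(global < 0) || any(global > 21)) {
    stop_validation("PSQI global score must lie in [0, 21]")
  }
  ifelse(global > threshold, "Poor", "Good")
}

#' Score the Emotion Regulation Questionnaire
#'
#' Ten 1-7 Likert items; Cognitive Reappraisal is the sum of six items and
#' Expressive Suppression the sum of the remaining four (standard assignment,
#' see [erq_item_map()]).
#'
#' @param responses numeric vector of 10 responses in item order 1..10.
#' @param item_map list with integer vectors `reappraisal` and `suppression`.
#' @return list with `cognitive_reappraisal`, `expressive_suppression`, `total`.
#' @export
score_erq <- function(responses, item_map = erq_item_map()) {
  responses <- as.numeric(responses)
  if (length(responses) != 10L) stop_validation("ERQ needs exactly 10 item responses")
  if (anyNA(responses) || any(responses < 1 | responses > 7) ||
      any(responses != round(responses))) {
    stop_validation("ERQ responses must be integers in 1-7")
  }
  if (length(intersect(item_map$reappraisal, item_map$suppression)) ||
      !setequal(c(item_map$reappraisal, item_map$suppression), 1:10)) {
    stop_validation("item_map must partition items 1..10")
  }
  reap <- sum(responses[item_map$reappraisal])
  supp <- sum(responses[item_map$suppression])
  list(cognitive_reappraisal = as.integer(reap),
       expressive_suppression = as.integer(supp),
       total = as.integer(reap + supp))
}
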
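# Spontaneous eye-blink detection from an eye-opening-ratio time series.
# The module boundary is the sampled ratio signal (the quantity a landmark
# tracker would plot); no camera or face-tracking dependency exists here.

#' Blink-detector configuration
#'
#' An event opens when the eye-opening ratio falls below `threshold` and
#' closes when it rises above `threshold + hysteresis`. Events whose
#' below-threshold span is shorter than `min_closed_frames` are discarded;
#' an onset within `refractory_ms` of the previous retained onset is merged
#' into that event. Defaults reflect typical blink physiology at 30 fps
#' (2 frames ~ 66 ms minimum closure, 100 ms refractory).
#'
#' @param threshold eye-opening ratio below which the eye counts as closed.
#' @param min_closed_frames minimum below-threshold frames per event (>= 1).
#' @param refractory_ms minimum gap between retained onsets.
#' @param hysteresis reopening margin added to `threshold`.
#' @return an object of class `blink_config`.
#' @export
blink_config <- function(threshold = 0.2, min_closed_frames = 2L,
                         refractory_ms = 100, hysteresis = 0.02) {
  assert_scalar_num(threshold, "threshold")
  if (threshold <= 0) stop_validation("`threshold` must be > 0")
  assert_scalar_num(min_closed_frames, "min_closed_frames", lower = 1)
  assert_scalar_num(refractory_ms, "refractory_ms", lower = 0)
  assert_scalar_num(hysteresis, "hysteresis", lower = 0)
  structure(list(threshold = threshold,
                 min_closed_frames = as.integer(min_closed_frames),
                 refractory_ms = refractory_ms,
                 hysteresis = hysteresis),
            class = "blink_config")
}

#' Detect blink events in an eye-opening-ratio signal
#'
#' @param signal numeric vector of eye-opening ratios, one per frame.
#' @param fps frames per second of the signal.
#' @param config a [blink_config()].
#' @param metadata optional list (e.g. name/age/sex) carried into the session.
#' @return an object of class `blink_session`: list with `events` (data.frame
#'   of `onset`, `offset` frame indices), `blink_count`, `duration_s`, `fps`,
#'   `config`, `metadata`.
#' @export
detect_blinks <- function(signal, fps = 30, config = blink_config(),
                          metadata = list()) {
  if (length(signal) < 2L) stop_validation("signal must have >= 2 frames")
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    stop_validation("non-finite sample at frame index %d", bad[1])
  }
  assert_scalar_num(fps, "fps")
  if (fps <= 0) stop_validation("`fps` must be > 0")
  thr <- config$threshold
  reopen <- thr + config$hysteresis
  refractory_frames <- config$refractory_ms / 1000 * fps

  onsets <- integer(0)
  offsets <- integer(0)
  in_event <- FALSE
  onset <- 0L
  closed_frames <- 0L
  for (i in seq_along(signal)) {
    v <- signal[i]
    if (!in_event) {
      if (v < thr) {
        in_event <- TRUE
        onset <- i
        closed_frames <- 1L
      }
    } else {
      if (v < thr) {
        closed_frames <- closed_frames + 1L
      } else if (v > reopen) {
        # event closes at the last frame before reopening
        if (closed_frames >= config$min_closed_frames) {
          if (length(onsets) &&
              (onset - onsets[length(onsets)]) <= refractory_frames) {
            offsets[length(offsets)] <- i - 1L  # merge into previous event
          } else {
            onsets <- c(onsets, onset)
            offsets <- c(offsets, i - 1L)
          }
        }
        in_event <- FALSE
      }
      # between thr and thr+hysteresis: hold state
    }
  }
  if (in_event && closed_frames >= config$min_closed_frames) {
    if (length(onsets) && (onset - onsets[length(onsets)]) <= refractory_frames) {
      offsets[length(offsets)] <- length(signal)
    } else {
      onsets <- c(onsets, onset)
      offsets <- c(offsets, length(signal))
    }
  }
  structure(list(
    events = data.frame(onset = onsets, offset = offsets),
    blink_count = length(onsets),
    duration_s = length(signal) / fps,
    fps = fps,
    config = config,
    metadata = metadata
  ), class = "blink_session")
}

#' @export
print.blink_session <- function(x, ...) {
  cat(sprintf("blink session: %d blinks in %.1f s (%.1f/min)\n",
              x$blink_count, x$duration_s, 60 * x$blink_count / x$duration_s))
  invisible(x)
}

#' Summarize pre/post blink sessions
#'
#' @param pre,post scored [detect_blinks()] sessions (or plain counts).
#' @return list with `sebr_pre`, `sebr_post`, `sebr_diff` (post - pre).
#' @export
summarize_sebr <- function(pre, post) {
  count_of <- function(x) {
    if (inherits(x, "blink_session")) x$blink_count
    else {
      assert_scalar_num(x, "blink count", lower = 0)
      as.integer(x)
    }
  }
  a <- count_of(pre)
  b <- count_of(post)
  list(sebr_pre = a, sebr_post = b, sebr_diff = b - a)
}

#' Write a blink session record as CSV
#'
#' One summary row (name, age, sex, threshold, duration_s, blink_count);
#' the per-event table can be written alongside with `events_path`.
#'
#' @param session a `blink_session`.
#' @param path output CSV path.
#' @param events_path optional CSV path for the per-event table.
#' @export
write_blink_csv <- function(session, path, events_path = NULL) {
  md <- session$metadata
  row <- data.frame(
    name = if (is.null(md$name)) "" else md$name,
    age = if (is.null(md$age)) NA else md$age,
    sex = if (is.null(md$sex)) "" else md$sex,
    threshold = session$config$threshold,
    duration_s = session$duration_s,
    blink_count = session$blink_count
  )
  utils::write.csv(row, path, row.names = FALSE)
  if (!is.null(events_path)) {
    utils::write.csv(session$events, events_path, row.names = FALSE)
  }
  invisible(path)
}
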
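## Velocity-based microsaccade detection from the cleaned horizontal gaze
## channel: absolute first-difference velocity, Gaussian smoothing over a
## 7-ms window, a trial-based threshold of 5x the median velocity, a 100-ms
## refractory period, pre/post-window magnitude and direction estimation,
## amplitude/displacement filters, and start/return classification against
## a median fixation reference.

#' Gaussian-weighted moving-average kernel
#'
#' Truncated Gaussian over an odd window, sigma = window/5, normalised to
#' unit sum.
#' @param window_samples odd window length in samples.
#' @return Numeric kernel of length `window_samples`.
#' @keywords internal
gaussian_kernel <- function(window_samples = 7) {
  stopifnot(window_samples %% 2 == 1)
  half <- (window_samples - 1) / 2
  sigma <- window_samples / 5
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Compute smoothed absolute gaze velocity
#'
#' Velocity is the absolute forward first difference of horizontal gaze
#' position scaled to degrees/second, then smoothed with a Gaussian-weighted
#' moving average over a 7-ms window. NaN gaze samples propagate through the
#' smoothing window; at the trace edges the kernel is renormalised over the
#' in-range samples.
#'
#' @param trace a `clean_gaze` data frame ([merge_eyes()], [pad_blinks()]).
#' @param window_ms smoothing window, ms.
#' @return A `velocity_trace` data frame with columns `time_ms, v` (deg/s,
#'   NaN where undefined) carrying the trace attributes.
#' @export
compute_velocity <- function(trace, window_ms = 7) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) stop("trace must carry a sampling_rate attribute")
  x <- trace$x
  n <- length(x)
  win <- max(3L, 2L * floor(window_ms * fs / 1000 / 2) + 1L)  # odd, >= 3
  if (n <= win) stop("trace shorter than the smoothing window")
  v_raw <- c(abs(diff(x)) * fs, NA_real_)
  w <- gaussian_kernel(win)
  half <- (win - 1L) / 2L
  num <- numeric(n)
  den <- numeric(n)
  for (k in -half:half) {
    wi <- w[k + half + 1L]
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    contrib <- rep(0, n)
    contrib[ok] <- wi * v_raw[src[ok]]   # NA in-source propagates
    num <- num + contrib
    den <- den + wi * ok
  }
  out <- data.frame(time_ms = trace$time_ms, v = num / den)
  for (a in c("sampling_rate", "encoding_offset_ms", "cue_onset_ms",
              "participant", "trial")) {
    attr(out, a) <- attr(trace, a)
  }
  class(out) <- c("velocity_trace", "data.frame")
  out
}

#' Trial-based velocity threshold
#'
#' Threshold = `mult` times the median of the defined velocity samples in
#' the given time window (by default the delay period between encoding
#' offset and cue onset, read from the trace annotations; otherwise the
#' whole trace).
#'
#' @param vel a `velocity_trace` from [compute_velocity()].
#' @param mult threshold multiplier (5 by default).
#' @param window optional `c(t0, t1)` ms window over which to take the
#'   median.
#' @return Threshold in deg/s.
#' @export
velocity_threshold <- function(vel, mult = 5, window = NULL) {
  if (is.null(window)) {
    eo <- attr(vel, "encoding_offset_ms"); cu <- attr(vel, "cue_onset_ms")
    window <- if (!is.null(eo) && !is.null(cu)) c(eo, cu) else
      range(vel$time_ms)
  }
  sel <- vel$time_ms >= window[1] & vel$time_ms <= window[2]
  med <- stats::median(vel$v[sel], na.rm = TRUE)
  if (is.na(med)) return(NA_real_)
  mult * med
}

#' Detect saccade onsets from a velocity trace
#'
#' Onsets are the first samples of supra-threshold velocity runs. To avoid
#' counting the same gaze shift multiple times, any onset within
#' `refractory_ms` after an accepted onset is discarded. NaN velocity never
#' exceeds the threshold, so onsets inside blink-padded regions are
#' excluded automatically.
#'
#' @param vel a `velocity_trace`.
#' @param threshold velocity threshold, deg/s (see [velocity_threshold()]).
#' @param refractory_ms minimum delay between successive accepted onsets.
#' @return Numeric vector of onset times (ms).
#' @export
detect_onsets <- function(vel, threshold, refractory_ms = 100) {
  v <- vel$v
  if (all(is.na(v))) {
    warning("velocity is all-NaN; no onsets")
    return(numeric(0))
  }
  above <- !is.na(v) & v > threshold
  if (!any(above)) return(numeric(0))
  run_start <- above & !c(FALSE, above[-length(above)])
  cand <- vel$time_ms[run_start]
  keep <- numeric(0)
  last <- -Inf
  for (tt in cand) {
    if (tt - last >= refractory_ms) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Measure a saccade's pre/post position, magnitude and direction
#'
#' Pre-saccade position is the mean horizontal gaze over \[-50, 0) ms before
#' onset; post-saccade position the mean over \[+50, +100\] ms after onset.
#' Magnitude is `|post - pre|`; direction follows the screen convention of
#' negative = left: `post < pre` is a leftward saccade.
#'
#' @param trace a `clean_gaze` data frame.
#' @param onset_ms saccade onset time.
#' @return A one-row data frame `(onset_ms, pre_pos_deg, post_pos_deg,
#'   magnitude_deg, displacement_deg, direction)`, or `NULL` when either
#'   window falls outside the trace or contains no defined sample (the event
#'   is dropped).
#' @export
measure_event <- function(trace, onset_ms) {
  t_ms <- trace$time_ms
  if (onset_ms - 50 < t_ms[1] || onset_ms + 100 > t_ms[length(t_ms)]) {
    return(NULL)
  }
  pre_sel <- t_ms >= onset_ms - 50 & t_ms < onset_ms
  post_sel <- t_ms >= onset_ms + 50 & t_ms <= onset_ms + 100
  pre <- mean(trace$x[pre_sel], na.rm = TRUE)
  post <- mean(trace$x[post_sel], na.rm = TRUE)
  if (is.nan(pre) || is.nan(post)) return(NULL)
  disp <- post - pre
  data.frame(onset_ms = onset_ms, pre_pos_deg = pre, post_pos_deg = post,
             magnitude_deg = abs(disp), displacement_deg = disp,
             direction = if (disp < 0) "left" else if (disp > 0) "right"
                         else NA_character_)
}

#' Amplitude and displacement filters
#'
#' Keeps events whose magnitude is below `max_magnitude_deg` (zooming in on
#' microsaccades) and whose absolute horizontal displacement is at least
#' `min_displacement_deg` (the 1%-of-eccentricity floor, 3.42 arcmin at
#' 5.7 degrees; applied symmetrically in both directions).
#'
#' @param events event data frame from [measure_event()] rows.
#' @param max_magnitude_deg magnitude ceiling, degrees (exclusive).
#' @param min_displacement_deg displacement floor, degrees (inclusive).
#' @return Filtered event data frame.
#' @export
filter_events <- function(events, max_magnitude_deg = 1.0,
                          min_displacement_deg = displacement_floor_arcmin() / 60) {
  if (!nrow(events)) return(events)
  keep <- events$magnitude_deg < max_magnitude_deg &
    abs(events$displacement_deg) >= min_displacement_deg
  events[keep, , drop = FALSE]
}

#' Fixation reference position
#'
#' Median horizontal gaze position over a reference window late in the delay
#' (default -1500 to -500 ms relative to cue onset), ignoring NaN. Used to
#' minimise the contribution of slow drift when classifying start vs return
#' microsaccades.
#'
#' @param trace a `clean_gaze` data frame.
#' @param cue_onset_ms cue onset (defaults to the trace annotation).
#' @param window window relative to cue onset, ms.
#' @return Fixation x position, degrees.
#' @export
fixation_reference <- function(trace, cue_onset_ms = attr(trace, "cue_onset_ms"),
                               window = c(-1500, -500)) {
  if (is.null(cue_onset_ms)) stop("cue onset annotation required")
  sel <- trace$time_ms >= cue_onset_ms + window[1] &
    trace$time_ms <= cue_onset_ms + window[2]
  fx <- stats::median(trace$x[sel], na.rm = TRUE)
  if (is.na(fx)) stop("fixation reference window contains no defined samples")
  fx
}

#' Classify microsaccades as start or return
#'
#' A saccade is a *start* microsaccade when the post-saccade distance from
#' the fixation reference exceeds the pre-saccade distance (gaze moves away
#' from fixation) and a *return* microsaccade when it is smaller. Exact ties
#' get `NA` and are excluded from the start/return split while remaining in
#' the all-saccade pool.
#'
#' @param events event data frame with `pre_pos_deg`, `post_pos_deg`.
#' @param fixation_x fixation reference position ([fixation_reference()]).
#' @return `events` with a `type` column (`"start"`, `"return"`, or `NA`).
#' @export
classify_start_return <- function(events, fixation_x) {
  if (!nrow(events)) {
    events$type <- character(0)
    return(events)
  }
  d_pre <- abs(events$pre_pos_deg - fixation_x)
  d_post <- abs(events$post_pos_deg - fixation_x)
  events$type <- ifelse(d_post > d_pre, "start",
                        ifelse(d_post < d_pre, "return", NA_character_))
  events
}

#' Restrict events to the spontaneous-fixation delay window
#'
#' Keeps microsaccades whose onset lies at least `margin_ms` after the
#' visual-encoding offset and at least `margin_ms` before cue onset.
#'
#' @param events event data frame with `onset_ms`.
#' @param encoding_offset_ms,cue_onset_ms trial annotations, ms.
#' @param margin_ms guard margin, ms.
#' @return Filtered event data frame.
#' @export
select_delay_events <- function(events, encoding_offset_ms, cue_onset_ms,
                                margin_ms = 500) {
  if (is.null(encoding_offset_ms) || is.null(cue_onset_ms) ||
      is.na(encoding_offset_ms) || is.na(cue_onset_ms)) {
    stop("trial annotations (encoding offset, cue onset) are required")
  }
  if (!nrow(events)) return(events)
  keep <- events$onset_ms >= encoding_offset_ms + margin_ms &
    events$onset_ms <= cue_onset_ms - margin_ms
  events[keep, , drop = FALSE]
}

#' Detect microsaccades in one gaze recording
#'
#' Full single-trial detection chain: binocular merge, blink padding,
#' velocity computation and smoothing, 5x-median thresholding over the delay
#' period, onset detection with a 100-ms refractory period, pre/post-window
#' measurement, magnitude/displacement filtering, and start/return
#' classification.
#'
#' @param rec a `gaze_recording` data frame.
#' @param vel_mult velocity-threshold multiplier.
#' @param refractory_ms minimum delay between gaze shifts, ms.
#' @param max_magnitude_deg magnitude ceiling, degrees.
#' @param min_displacement_deg displacement floor, degrees.
#' @param smooth_window_ms velocity smoothing window, ms.
#' @param delay_only if `TRUE`, restrict to the delay window with a 500-ms
#'   guard margin ([select_delay_events()]); if `FALSE` return all events.
#' @return An event data frame of class `ms_events` with columns
#'   `participant, trial, onset_ms, direction, type, magnitude_deg,
#'   displacement_deg, pre_pos_deg, post_pos_deg`.
#' @export
#' @examples
#' sim <- simulate_gaze(sim_config(n_participants = 1,
#'                                 n_trials_per_participant = 2, seed = 7))
#' ev <- detect_microsaccades(sim$trials[[1]][[1]])
#' ev[, c("onset_ms", "direction", "type", "magnitude_deg")]
detect_microsaccades <- function(rec, vel_mult = 5, refractory_ms = 100,
                                 max_magnitude_deg = 1.0,
                                 min_displacement_deg = displacement_floor_arcmin() / 60,
                                 smooth_window_ms = 7,
                                 delay_only = FALSE) {
  trace <- pad_blinks(merge_eyes(rec))
  vel <- compute_velocity(trace, window_ms = smooth_window_ms)
  thr <- velocity_threshold(vel, mult = vel_mult)
  onsets <- if (is.na(thr)) numeric(0) else
    detect_onsets(vel, thr, refractory_ms = refractory_ms)
  rows <- lapply(onsets, function(o) measure_event(trace, o))
  events <- do.call(rbind, rows)
  if (is.null(events)) {
    events <- data.frame(onset_ms = numeric(0), pre_pos_deg = numeric(0),
                         post_pos_deg = numeric(0), magnitude_deg = numeric(0),
                         displacement_deg = numeric(0), direction = character(0))
  }
  events <- filter_events(events, max_magnitude_deg, min_displacement_deg)
  cue <- attr(rec, "cue_onset_ms")
  if (!is.null(cue) && nrow(events)) {
    fx <- fixation_reference(trace)
    events <- classify_start_return(events, fx)
  } else {
    events$type <- rep(NA_character_, nrow(events))
  }
  if (delay_only) {
    events <- select_delay_events(events, attr(rec, "encoding_offset_ms"), cue)
  }
  p <- attr(rec, "participant"); tr <- attr(rec, "trial")
  events <- cbind(data.frame(participant = rep(if (is.null(p)) NA_integer_ else p,
                                               nrow(events)),
                             trial = rep(if (is.null(tr)) NA_integer_ else tr,
                                         nrow(events))),
                  events)
  rownames(events) <- NULL
  attr(events, "threshold_deg_s") <- thr
  class(events) <- c("ms_events", "data.frame")
  events
}

#' Detect microsaccades across a whole gaze simulation
#'
#' @param gaze a `gaze_sim` object from [simulate_gaze()].
#' @param ... passed to [detect_microsaccades()].
#' @return One `ms_events` data frame over all participants and trials.
#' @export
detect_all <- function(gaze, ...) {
  out <- list()
  for (p in seq_along(gaze$trials)) {
    for (tr in seq_along(gaze$trials[[p]])) {
      ev <- detect_microsaccades(gaze$trials[[p]][[tr]], ...)
      if (nrow(ev)) out[[length(out) + 1L]] <- as.data.frame(ev)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(participant = integer(0), trial = integer(0),
               onset_ms = numeric(0), pre_pos_deg = numeric(0),
               post_pos_deg = numeric(0), magnitude_deg = numeric(0),
               displacement_deg = numeric(0), direction = character(0),
               type = character(0))
  class(res) <- c("ms_events", "data.frame")
  res
}

#' Score detection against ground truth
#'
#' One-to-one matches detected events to injected events within a trial
#' (nearest onset within `match_window_ms`), then reports recall, precision,
#' mean absolute onset error on matched events, and the fraction of matched
#' events whose detected direction equals the injected direction.
#'
#' @param truth ground-truth table from [simulate_gaze()].
#' @param detected detected events ([detect_all()]).
#' @param match_window_ms maximum onset distance for a match, ms.
#' @return List with `recall`, `precision`, `mean_onset_error_ms`,
#'   `direction_agreement`, `n_true`, `n_detected`, `n_matched`.
#' @export
detection_recovery <- function(truth, detected, match_window_ms = 25) {
  n_true <- nrow(truth); n_det <- nrow(detected)
  matched_err <- numeric(0)
  dir_ok <- logical(0)
  n_matched <- 0L
  keys <- unique(truth[, c("participant", "trial")])
  for (i in seq_len(nrow(keys))) {
    tt <- truth[truth$participant == keys$participant[i] &
                truth$trial == keys$trial[i], , drop = FALSE]
    dd <- detected[detected$participant == keys$participant[i] &
                   detected$trial == keys$trial[i], , drop = FALSE]
    used <- rep(FALSE, nrow(dd))
    for (j in seq_len(nrow(tt))) {
      if (!nrow(dd)) next
      d <- abs(dd$onset_ms - tt$onset_ms[j])
      d[used] <- Inf
      k <- which.min(d)
      if (length(k) && d[k] <= match_window_ms) {
        used[k] <- TRUE
        n_matched <- n_matched + 1L
        matched_err <- c(matched_err, d[k])
        dir_ok <- c(dir_ok, dd$direction[k] == tt$direction[j])
      }
    }
  }
  list(recall = if (n_true) n_matched / n_true else NA_real_,
       precision = if (n_det) n_matched / n_det else NA_real_,
       mean_onset_error_ms = if (n_matched) mean(matched_err) else NA_real_,
       direction_agreement = if (n_matched) mean(dir_ok) else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_matched)
}

#' @export
print.ms_events <- function(x, ...) {
  cat(sprintf("Microsaccade events: %d (left %d / right %d; start %d / return %d)\n",
              nrow(x), sum(x$direction == "left"), sum(x$direction == "right"),
              sum(x$type == "start", na.rm = TRUE),
              sum(x$type == "return", na.rm = TRUE)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
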
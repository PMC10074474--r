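## Synthetic gaze + EEG generator.
##
## Trial clock: recording starts at t = 0; the encoding display appears at
## PRE_MARGIN_MS, lasts encoding_duration_ms, and is followed by the variable
## retention delay; the cue arrives at the end of the delay and recording
## continues POST_MARGIN_MS further. The margins exist so that +/-1200 ms
## saccade-locked epochs fit inside a trial.

PRE_MARGIN_MS <- 1500
POST_MARGIN_MS <- 1500
SACCADE_RISE_MS <- 20       # sigmoidal (raised-cosine) displacement transition
EVENT_MIN_GAP_MS <- 150     # spacing imposed between injected events
RETURN_DELAY_RANGE_MS <- c(200, 400)

# one RNG substream per participant, two lanes (gaze, EEG), derived from the
# master seed so gaze regenerates identically whether or not EEG is generated
participant_seeds <- function(cfg) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  matrix(sample.int(2147483646L, 2L * cfg$n_participants),
         nrow = 2L, dimnames = list(c("gaze", "eeg"), NULL))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

# raised-cosine unit step over SACCADE_RISE_MS
saccade_step <- function(t_ms, onset_ms, rise = SACCADE_RISE_MS) {
  u <- (t_ms - onset_ms) / rise
  s <- ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
  s
}

# slow quasi-periodic fixational drift: a sum of low-frequency sinusoids with
# random frequencies, amplitudes and phases, rescaled to the target SD.
# Bounded velocity keeps the 5x-median detector threshold out of its reach.
drift_trace <- function(n, fs, target_sd) {
  if (target_sd <= 0) return(numeric(n))
  t_s <- (seq_len(n) - 1L) / fs
  k <- 4L
  f <- stats::runif(k, 0.2, 1.2)
  a <- abs(stats::rnorm(k))
  ph <- stats::runif(k, 0, 2 * pi)
  d <- colSums(a * sin(outer(2 * pi * f, t_s) + ph))
  sdd <- stats::sd(d)
  if (sdd > 0) d <- d * (target_sd / sdd)
  d
}

# sample injected event times/kinds for one trial; returns a data.frame
inject_events <- function(cfg, window_lo, window_hi) {
  rate <- cfg$microsaccade_rate
  out <- list()
  if (rate <= 0 || window_hi <= window_lo) {
    return(data.frame(onset_ms = numeric(0), direction = character(0),
                      type = character(0), displacement_deg = numeric(0)))
  }
  t_cur <- window_lo + stats::rexp(1, rate / 1000)
  while (t_cur <= window_hi) {
    mag <- stats::runif(1, cfg$microsaccade_magnitude_range[1],
                        cfg$microsaccade_magnitude_range[2])
    dir_sign <- sample(c(-1, 1), 1)
    disp <- dir_sign * mag
    out[[length(out) + 1L]] <- data.frame(
      onset_ms = t_cur,
      direction = if (dir_sign < 0) "left" else "right",
      type = "start", displacement_deg = disp)
    t_last <- t_cur
    if (stats::runif(1) < cfg$start_return_pairing_prob) {
      t_ret <- t_cur + stats::runif(1, RETURN_DELAY_RANGE_MS[1],
                                    RETURN_DELAY_RANGE_MS[2])
      if (t_ret <= window_hi) {
        ret_disp <- -disp * stats::runif(1, 0.85, 1.0)  # near-complete return
        out[[length(out) + 1L]] <- data.frame(
          onset_ms = t_ret,
          direction = if (ret_disp < 0) "left" else "right",
          type = "return", displacement_deg = ret_disp)
        t_last <- t_ret
      }
    }
    t_cur <- t_last + EVENT_MIN_GAP_MS + stats::rexp(1, rate / 1000)
  }
  if (!length(out)) {
    return(data.frame(onset_ms = numeric(0), direction = character(0),
                      type = character(0), displacement_deg = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

simulate_gaze_trial <- function(cfg, participant, trial) {
  fs <- cfg$sampling_rate
  delay <- stats::runif(1, cfg$delay_duration_range[1], cfg$delay_duration_range[2])
  encoding_offset <- PRE_MARGIN_MS + cfg$encoding_duration_ms
  cue_onset <- encoding_offset + delay
  n <- floor(cue_onset + POST_MARGIN_MS)
  t_ms <- seq_len(n) - 1

  ev <- inject_events(cfg, encoding_offset + 300, cue_onset - 300)

  x_true <- drift_trace(n, fs, cfg$drift_sd)
  y_true <- drift_trace(n, fs, cfg$drift_sd / 2)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      x_true <- x_true + ev$displacement_deg[i] * saccade_step(t_ms, ev$onset_ms[i])
    }
  }

  ns <- cfg$eye_noise_sd
  rec <- data.frame(
    time_ms = t_ms,
    x_left_deg  = x_true + stats::rnorm(n, 0, ns),
    y_left_deg  = y_true + stats::rnorm(n, 0, ns),
    x_right_deg = x_true + stats::rnorm(n, 0, ns),
    y_right_deg = y_true + stats::rnorm(n, 0, ns)
  )

  # blinks: one NaN run per affected trial, kept clear of injected events so
  # ground truth stays recoverable (blinks and microsaccades rarely co-occur)
  if (stats::runif(1) < cfg$blink_prob_per_trial) {
    dur <- round(stats::runif(1, 100, 300))
    for (try in 1:20) {
      b0 <- round(stats::runif(1, 200, n - dur - 200))
      clear <- !nrow(ev) ||
        all(ev$onset_ms < b0 - 350 | ev$onset_ms > b0 + dur + 250)
      if (clear) {
        idx <- b0:(b0 + dur - 1)
        rec[idx, c("x_left_deg", "y_left_deg")] <- NaN
        rec[idx, c("x_right_deg", "y_right_deg")] <- NaN
        break
      }
    }
  }

  attr(rec, "sampling_rate") <- fs
  attr(rec, "encoding_offset_ms") <- encoding_offset
  attr(rec, "cue_onset_ms") <- cue_onset
  attr(rec, "participant") <- participant
  attr(rec, "trial") <- trial
  class(rec) <- c("gaze_recording", "data.frame")
  list(rec = rec, events = ev,
       info = data.frame(participant = participant, trial = trial,
                         n_samples = n, encoding_offset_ms = encoding_offset,
                         cue_onset_ms = cue_onset))
}

#' Simulate binocular gaze recordings with known microsaccades
#'
#' Generates, per participant and trial, a binocular gaze recording at the
#' configured sampling rate containing slow fixational drift, step-like
#' saccadic displacements with a ~20-ms raised-cosine transition, small
#' independent per-eye tracker noise, and optional blink NaN runs. Injected
#' start microsaccades occur at the configured rate during the retention
#' delay; each is followed, with the configured probability, by a return
#' microsaccade of opposite direction 200--400 ms later. All injected events
#' are listed in the ground-truth table.
#'
#' @param cfg a [sim_config()] object.
#' @return A list of class `"gaze_sim"` with elements `trials` (nested list,
#'   `trials[[participant]][[trial]]` = a `gaze_recording` data frame with
#'   columns `time_ms, x_left_deg, y_left_deg, x_right_deg, y_right_deg` and
#'   attributes `sampling_rate`, `encoding_offset_ms`, `cue_onset_ms`),
#'   `truth` (data frame: `participant, trial, onset_ms, direction, type,
#'   displacement_deg`) and `trial_info` (per-trial timing table).
#' @seealso [simulate_eeg()], [detect_microsaccades()]
#' @export
#' @examples
#' sim <- simulate_gaze(sim_config(n_participants = 1,
#'                                 n_trials_per_participant = 2, seed = 42))
#' head(sim$truth)
simulate_gaze <- function(cfg) {
  validate_config(cfg)
  seeds <- participant_seeds(cfg)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  trials <- vector("list", cfg$n_participants)
  truth <- list()
  info <- list()
  for (p in seq_len(cfg$n_participants)) {
    set.seed(seeds["gaze", p])
    trials[[p]] <- vector("list", cfg$n_trials_per_participant)
    for (tr in seq_len(cfg$n_trials_per_participant)) {
      sim <- simulate_gaze_trial(cfg, p, tr)
      trials[[p]][[tr]] <- sim$rec
      if (nrow(sim$events)) {
        truth[[length(truth) + 1L]] <- cbind(
          data.frame(participant = p, trial = tr), sim$events)
      }
      info[[length(info) + 1L]] <- sim$info
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(participant = integer(0), trial = integer(0),
               onset_ms = numeric(0), direction = character(0),
               type = character(0), displacement_deg = numeric(0))
  structure(list(trials = trials, truth = truth,
                 trial_info = do.call(rbind, info), config = cfg),
            class = "gaze_sim")
}

# 1/f^a background noise via spectral shaping, RMS-normalised
colored_noise <- function(n, fs, exponent, target_sd) {
  f <- seq(0, fs - fs / n, length.out = n)
  f_fold <- pmin(f, fs - f)
  amp <- rep(0, n)
  nz <- f_fold >= 0.5                     # leave DC/ultra-slow bins empty
  amp[nz] <- f_fold[nz]^(-exponent / 2)
  z <- stats::rnorm(n) + 1i * stats::rnorm(n)
  x <- Re(stats::fft(z * amp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (target_sd / s)
  x
}

# saccade-locked broadband evoked transient: Gaussian bump peaking ~100 ms
# after onset (sigma 50 ms), spectral content concentrated below ~5 Hz
erp_waveform <- function(t_ms, onset_ms, amplitude) {
  amplitude * exp(-((t_ms - onset_ms - 100)^2) / (2 * 50^2))
}

#' Simulate saccade-locked EEG with an injected ipsilateral alpha effect
#'
#' For each trial of a gaze simulation, generates multichannel EEG at the
#' same clock: 1/f-like background noise on every channel, a saccade-locked
#' broadband evoked transient on all (posterior) channels, and a 10-Hz burst
#' with a Hanning envelope added only to the channels ipsilateral to each
#' injected microsaccade's direction (left saccade -> left-hemisphere
#' channels PO7/O1). A fraction of the burst amplitude has fixed phase
#' relative to saccade onset; the remainder gets a random phase per event.
#'
#' @param cfg a [sim_config()] object (the one used for the gaze simulation).
#' @param truth ground-truth event table from [simulate_gaze()].
#' @param trial_info per-trial timing table from [simulate_gaze()].
#' @return A list of class `"eeg_sim"`: `trials[[participant]][[trial]]` is a
#'   channels x samples matrix (microvolt) with rownames the channel labels
#'   and attribute `sampling_rate`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 1, n_trials_per_participant = 2)
#' g <- simulate_gaze(cfg)
#' e <- simulate_eeg(cfg, g$truth, g$trial_info)
#' dim(e$trials[[1]][[1]])
simulate_eeg <- function(cfg, truth, trial_info) {
  validate_config(cfg)
  seeds <- participant_seeds(cfg)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  chans <- cfg$channels
  left_ch <- chans[grepl("[13579]$", chans)]
  right_ch <- chans[grepl("[02468]$", chans)]
  if (!length(left_ch) || !length(right_ch)) {
    stop("montage must contain left- and right-hemisphere channel labels")
  }
  fs <- cfg$sampling_rate
  burst_n <- round(cfg$alpha_burst_duration_ms * fs / 1000)
  env <- hanning_window(burst_n)
  a_burst <- cfg$alpha_effect_amplitude * cfg$eeg_noise_sd
  f_pl <- cfg$alpha_phase_locked_fraction

  trials <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    set.seed(seeds["eeg", p])
    p_info <- trial_info[trial_info$participant == p, , drop = FALSE]
    trials[[p]] <- vector("list", nrow(p_info))
    for (k in seq_len(nrow(p_info))) {
      tr <- p_info$trial[k]
      n <- p_info$n_samples[k]
      t_ms <- seq_len(n) - 1
      dat <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
      for (ci in seq_along(chans)) {
        dat[ci, ] <- colored_noise(n, fs, cfg$noise_exponent, cfg$eeg_noise_sd)
      }
      ev <- truth[truth$participant == p & truth$trial == tr, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        on <- ev$onset_ms[i]
        dat <- dat + rep(erp_waveform(t_ms, on, cfg$erp_amplitude),
                         each = length(chans))
        if (a_burst > 0) {
          idx0 <- round(on) + 1L
          idx <- idx0:min(idx0 + burst_n - 1L, n)
          tt <- (idx - idx0) / fs
          phi <- stats::runif(1, 0, 2 * pi)
          osc <- a_burst * env[seq_along(idx)] *
            (f_pl * cos(2 * pi * cfg$alpha_freq_hz * tt) +
             (1 - f_pl) * cos(2 * pi * cfg$alpha_freq_hz * tt + phi))
          ipsi <- if (ev$direction[i] == "left") left_ch else right_ch
          dat[ipsi, idx] <- dat[ipsi, idx] + rep(osc, each = length(ipsi))
        }
      }
      attr(dat, "sampling_rate") <- fs
      trials[[p]][[tr]] <- dat
    }
  }
  structure(list(trials = trials, config = cfg, channels = chans),
            class = "eeg_sim")
}

#' Simulate a full study (gaze + EEG)
#'
#' Convenience wrapper running [simulate_gaze()] then [simulate_eeg()].
#'
#' @param cfg a [sim_config()] object.
#' @return List with elements `gaze`, `eeg`, `truth`, `trial_info`, `config`.
#' @export
simulate_study <- function(cfg) {
  g <- simulate_gaze(cfg)
  e <- simulate_eeg(cfg, g$truth, g$trial_info)
  list(gaze = g, eeg = e, truth = g$truth, trial_info = g$trial_info,
       config = cfg)
}
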
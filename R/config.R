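#' Simulation configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' gaze and EEG generators. Defaults encode the study design they emulate:
#' a working-memory task whose trials contain a 250-ms encoding display
#' followed by a variable retention delay (uniform 2000--2500 ms) during
#' which participants fixate a central cross, recorded at 1000 Hz; 2 sessions
#' of 10 blocks of 60 trials (1200 trials) per participant; 23 participants.
#' Spontaneous microsaccades are injected during the delay, and the EEG
#' carries a 10-Hz burst ipsilateral to each microsaccade's direction.
#'
#' @param n_participants number of simulated participants.
#' @param n_trials_per_participant trials per participant. The default is the
#'   full session structure (`n_sessions * n_blocks_per_session *
#'   n_trials_per_block`); pass a smaller number for desk-scale runs.
#' @param n_sessions,n_blocks_per_session,n_trials_per_block session
#'   bookkeeping used to derive the default trial count.
#' @param sampling_rate sampling rate of gaze and EEG, Hz.
#' @param delay_duration_range retention-delay duration bounds, ms
#'   (uniformly drawn per trial).
#' @param encoding_duration_ms duration of the encoding display, ms.
#' @param microsaccade_rate rate of injected *start* microsaccades during the
#'   delay, events per second.
#' @param start_return_pairing_prob probability that a start microsaccade is
#'   followed (200--400 ms later) by a return microsaccade of opposite
#'   direction.
#' @param microsaccade_magnitude_range bounds of injected saccade magnitude,
#'   degrees of visual angle.
#' @param drift_sd standard deviation of slow fixational drift, degrees.
#' @param eye_noise_sd per-sample, per-eye tracker noise, degrees.
#' @param blink_prob_per_trial probability that a trial contains one blink
#'   (a NaN run of 100--300 ms in both eyes).
#' @param alpha_effect_amplitude peak amplitude of the ipsilateral 10-Hz
#'   burst, expressed as a multiple of the background EEG RMS (unitless
#'   gain; 0 disables the effect).
#' @param alpha_phase_locked_fraction fraction in `[0, 1]` of the alpha-burst
#'   amplitude whose phase is fixed relative to saccade onset (the remainder
#'   gets a random phase per event).
#' @param alpha_freq_hz burst frequency, Hz.
#' @param alpha_burst_duration_ms burst duration (Hanning envelope), ms.
#' @param erp_amplitude peak amplitude of the saccade-locked broadband evoked
#'   transient added to all posterior channels, microvolt.
#' @param eeg_noise_sd RMS of the 1/f background EEG noise, microvolt.
#' @param noise_exponent spectral slope of the background EEG
#'   (power ~ 1/f^exponent).
#' @param channels EEG montage labels; must contain both the PO7/PO8 and
#'   O1/O2 pairs.
#' @param seed master seed; identical seed and config give bit-identical
#'   simulated recordings.
#'
#' @return A list of class `"msa_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_trials_per_participant = 5)
#' cfg$delay_duration_range
sim_config <- function(n_participants = 23,
                       n_trials_per_participant = NULL,
                       n_sessions = 2,
                       n_blocks_per_session = 10,
                       n_trials_per_block = 60,
                       sampling_rate = 1000,
                       delay_duration_range = c(2000, 2500),
                       encoding_duration_ms = 250,
                       microsaccade_rate = 1.0,
                       start_return_pairing_prob = 0.5,
                       microsaccade_magnitude_range = c(0.1, 0.9),
                       drift_sd = 0.05,
                       eye_noise_sd = 0.002,
                       blink_prob_per_trial = 0.1,
                       alpha_effect_amplitude = 1.0,
                       alpha_phase_locked_fraction = 0.5,
                       alpha_freq_hz = 10,
                       alpha_burst_duration_ms = 250,
                       erp_amplitude = 4,
                       eeg_noise_sd = 10,
                       noise_exponent = 1,
                       channels = c("PO7", "PO8", "O1", "O2"),
                       seed = 1L) {
  if (is.null(n_trials_per_participant)) {
    n_trials_per_participant <- n_sessions * n_blocks_per_session * n_trials_per_block
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials_per_participant = as.integer(n_trials_per_participant),
    n_sessions = as.integer(n_sessions),
    n_blocks_per_session = as.integer(n_blocks_per_session),
    n_trials_per_block = as.integer(n_trials_per_block),
    sampling_rate = sampling_rate,
    delay_duration_range = delay_duration_range,
    encoding_duration_ms = encoding_duration_ms,
    microsaccade_rate = microsaccade_rate,
    start_return_pairing_prob = start_return_pairing_prob,
    microsaccade_magnitude_range = microsaccade_magnitude_range,
    drift_sd = drift_sd,
    eye_noise_sd = eye_noise_sd,
    blink_prob_per_trial = blink_prob_per_trial,
    alpha_effect_amplitude = alpha_effect_amplitude,
    alpha_phase_locked_fraction = alpha_phase_locked_fraction,
    alpha_freq_hz = alpha_freq_hz,
    alpha_burst_duration_ms = alpha_burst_duration_ms,
    erp_amplitude = erp_amplitude,
    eeg_noise_sd = eeg_noise_sd,
    noise_exponent = noise_exponent,
    channels = channels,
    seed = as.integer(seed)
  )
  class(cfg) <- "msa_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1, cfg$n_trials_per_participant >= 1,
            cfg$sampling_rate > 0)
  r <- cfg$delay_duration_range
  if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
    stop("delay_duration_range must be a non-negative (low, high) pair with low <= high")
  }
  m <- cfg$microsaccade_magnitude_range
  if (length(m) != 2 || any(m <= 0) || m[1] > m[2]) {
    stop("microsaccade_magnitude_range must be a positive (low, high) pair")
  }
  for (p in c("start_return_pairing_prob", "blink_prob_per_trial",
              "alpha_phase_locked_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must lie in [0, 1]", p))
  }
  if (cfg$microsaccade_rate < 0) stop("microsaccade_rate must be non-negative")
  # events must keep >= 100 ms apart (plus return insertions); above ~6/s the
  # sequential placement cannot reach the requested rate
  if (cfg$microsaccade_rate > 6) {
    stop("microsaccade_rate too high: the 100-ms minimum inter-event interval ",
         "(refractory spacing) cannot be satisfied at rates above 6 events/s")
  }
  need <- c("PO7", "PO8", "O1", "O2")
  if (!all(need %in% cfg$channels)) {
    stop("channel montage must include the posterior pairs PO7/PO8 and O1/O2")
  }
  if (anyDuplicated(cfg$channels)) stop("channel labels must be unique")
  invisible(cfg)
}

#' Trials implied by the session structure
#'
#' @param n_sessions,n_blocks_per_session,n_trials_per_block session layout.
#' @return Total trial count per participant.
#' @export
#' @examples
#' session_trial_count() # 2 sessions x 10 blocks x 60 trials = 1200
session_trial_count <- function(n_sessions = 2, n_blocks_per_session = 10,
                                n_trials_per_block = 60) {
  n_sessions * n_blocks_per_session * n_trials_per_block
}

#' Microsaccade displacement exclusion floor
#'
#' Horizontal-displacement floor below which detected saccades are excluded,
#' defined as a fraction of the stimulus eccentricity. At the default
#' eccentricity of 5.7 degrees and a 1% criterion the floor is 3.42 minutes
#' of arc (0.057 degrees).
#'
#' @param eccentricity_deg stimulus eccentricity, degrees of visual angle.
#' @param fraction criterion fraction of the eccentricity.
#' @return Floor in minutes of arc.
#' @export
#' @examples
#' displacement_floor_arcmin() # 3.42
displacement_floor_arcmin <- function(eccentricity_deg = 5.7, fraction = 0.01) {
  eccentricity_deg * fraction * 60
}

#' @export
print.msa_config <- function(x, ...) {
  cat("Synthetic microsaccade/EEG study configuration\n")
  cat(sprintf("  %d participants x %d trials (fs = %g Hz, seed = %d)\n",
              x$n_participants, x$n_trials_per_participant, x$sampling_rate,
              x$seed))
  cat(sprintf("  delay %g-%g ms; start rate %g /s; pairing p = %g; magnitudes %g-%g deg\n",
              x$delay_duration_range[1], x$delay_duration_range[2],
              x$microsaccade_rate, x$start_return_pairing_prob,
              x$microsaccade_magnitude_range[1], x$microsaccade_magnitude_range[2]))
  cat(sprintf("  alpha effect: gain %g at %g Hz (%g ms burst), phase-locked fraction %g\n",
              x$alpha_effect_amplitude, x$alpha_freq_hz,
              x$alpha_burst_duration_ms, x$alpha_phase_locked_fraction))
  invisible(x)
}
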
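## Time-frequency decomposition and derived quantities: Hanning-taper STFT,
## contra/ipsi lateralisation contrast, baselined log power, topographic
## left/right contrast, and inter-trial phase coherence (ITPC).

#' Hanning window
#' @param n window length in samples.
#' @return Numeric taper of length `n`.
#' @keywords internal
hanning_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' Short-time Fourier transform of saccade-locked epochs
#'
#' Hanning-tapered sliding-window Fourier decomposition: a `window_ms`
#' segment centred on each output time point is tapered and zero-padded to
#' `pad_ms` (1 s by default, giving a 1-Hz frequency grid from a 300-ms
#' window), and the Fourier coefficient at each requested frequency is kept.
#' Coefficients are scaled so that a unit-amplitude sinusoid at a bin
#' frequency has magnitude ~1. Time points whose window exceeds the epoch
#' are `NA`, not zero-filled.
#'
#' @param epochs an `eeg_epochs` object.
#' @param freqs frequencies of interest, Hz (default 1--50 in 1-Hz steps).
#' @param toi_ms centre time points, ms relative to saccade onset (default
#'   -1200 to 1200 in 20-ms steps).
#' @param window_ms sliding-window length, ms.
#' @param pad_ms zero-padding target, ms (sets the DFT bin spacing).
#' @param channels channel subset (default: all channels in the epochs).
#' @return An object of class `eeg_tfr`: list with `coef` (complex array
#'   epochs x channels x frequency x time), `freqs`, `time_ms`, `channels`,
#'   `meta` (copied from the epochs).
#' @export
stft_epochs <- function(epochs, freqs = 1:50,
                        toi_ms = seq(-1200, 1200, by = 20),
                        window_ms = 300, pad_ms = 1000,
                        channels = NULL) {
  fs <- epochs$sampling_rate
  if (any(freqs > fs / 2)) stop("requested frequency above Nyquist")
  if (is.null(channels)) channels <- epochs$channels
  win_n <- round(window_ms * fs / 1000)
  pad_n <- round(pad_ms * fs / 1000)
  if (dim(epochs$data)[3] < win_n) stop("epochs shorter than the STFT window")
  taper <- hanning_window(win_n)
  scale <- 2 / sum(taper)
  df <- fs / pad_n
  bin <- round(freqs / df) + 1L
  if (any(abs(freqs / df - round(freqs / df)) > 1e-8)) {
    warning("some frequencies do not sit on the padded DFT grid; nearest bins used")
  }
  t_axis <- epochs$time_ms
  half_lo <- floor((win_n - 1) / 2)   # samples before the centre
  half_hi <- win_n - 1 - half_lo      # samples after
  centre_idx <- round((toi_ms - t_axis[1]) * fs / 1000) + 1L
  defined <- centre_idx - half_lo >= 1L &
    centre_idx + half_hi <= length(t_axis) &
    toi_ms >= t_axis[1] & toi_ms <= t_axis[length(t_axis)]
  n_ep <- dim(epochs$data)[1]
  out <- array(NA_complex_,
               c(n_ep, length(channels), length(freqs), length(toi_ms)),
               dimnames = list(NULL, channels, freqs, toi_ms))
  def_idx <- which(defined)
  if (length(def_idx)) {
    seg_rows <- matrix(0, nrow = pad_n, ncol = length(def_idx))
    offs <- -half_lo:half_hi
    for (ch in channels) {
      ci <- match(ch, epochs$channels)
      for (e in seq_len(n_ep)) {
        sig <- epochs$data[e, ci, ]
        for (j in seq_along(def_idx)) {
          seg <- sig[centre_idx[def_idx[j]] + offs]
          seg_rows[seq_len(win_n), j] <- seg * taper
        }
        co <- stats::mvfft(seg_rows)[bin, , drop = FALSE] * scale
        out[e, match(ch, channels), , def_idx] <- co
      }
    }
  }
  structure(list(coef = out, freqs = freqs, time_ms = toi_ms,
                 channels = channels, meta = epochs$meta,
                 sampling_rate = fs, window_ms = window_ms, pad_ms = pad_ms),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$coef)
  cat(sprintf("Time-frequency decomposition: %d epochs x %d channels x %d freqs x %d times\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  %g-%g Hz; %g..%g ms (%g-ms Hanning window)\n",
              min(x$freqs), max(x$freqs), min(x$time_ms), max(x$time_ms),
              x$window_ms))
  invisible(x)
}

#' Spectral power of a TFR
#'
#' @param tfr an `eeg_tfr` object.
#' @return Real array (epochs x channels x frequency x time) of squared
#'   coefficient magnitudes.
#' @export
tfr_power <- function(tfr) {
  p <- Mod(tfr$coef)^2
  dimnames(p) <- dimnames(tfr$coef)
  p
}

#' Normalised lateralisation contrast
#'
#' `100 * (contra - ipsi) / (contra + ipsi)`, elementwise; cells where the
#' denominator is zero are undefined (`NA`).
#'
#' @param p_contra,p_ipsi power arrays of identical shape (e.g.
#'   trial-averaged frequency x time maps).
#' @return Contrast in percent, bounded in `[-100, 100]` where both powers
#'   are positive.
#' @export
#' @examples
#' lateralisation_contrast(1, 3)  # -50
lateralisation_contrast <- function(p_contra, p_ipsi) {
  den <- p_contra + p_ipsi
  out <- 100 * (p_contra - p_ipsi) / den
  out[den == 0] <- NA_real_
  out
}

# trial-averaged power map (freq x time) for one channel over a set of epochs
avg_power_map <- function(power, epoch_sel, channel, channels) {
  ci <- match(channel, channels)
  if (is.na(ci)) stop("unknown channel label: ", channel)
  m <- power[epoch_sel, ci, , , drop = FALSE]
  apply(m, c(3, 4), mean)
}

#' Participant-level lateralisation map
#'
#' For each electrode of the pair, power is averaged over epochs separately
#' for left and right saccades; the electrode's contrast
#' `100 * (contra - ipsi) / (contra + ipsi)` (contralateral = saccade away
#' from the electrode's hemisphere) is formed and the two electrode
#' contrasts are averaged, yielding a frequency x time map in percent.
#'
#' @param tfr an `eeg_tfr` containing both electrodes of `pair`.
#' @param pair `c(left_label, right_label)`.
#' @return Frequency x time matrix (percent), `NA` at undefined time points.
#' @export
participant_lateralisation <- function(tfr, pair = c("PO7", "PO8")) {
  pw <- tfr_power(tfr)
  dirs <- tfr$meta$direction
  sel_l <- dirs == "left"; sel_r <- dirs == "right"
  if (!any(sel_l) || !any(sel_r)) {
    stop("need at least one epoch per saccade direction")
  }
  # left electrode: contralateral trials are rightward saccades
  L_left <- lateralisation_contrast(
    avg_power_map(pw, sel_r, pair[1], tfr$channels),
    avg_power_map(pw, sel_l, pair[1], tfr$channels))
  L_right <- lateralisation_contrast(
    avg_power_map(pw, sel_l, pair[2], tfr$channels),
    avg_power_map(pw, sel_r, pair[2], tfr$channels))
  (L_left + L_right) / 2
}

#' Trial-averaged power maps by channel role
#'
#' Averages power over epochs for the contralateral and ipsilateral
#' configuration of an electrode pair: the left electrode with rightward
#' saccades and the right electrode with leftward saccades contribute to the
#' contralateral map, and vice versa for the ipsilateral map; the two
#' electrodes' maps are averaged.
#'
#' @param tfr an `eeg_tfr` object.
#' @param pair `c(left_label, right_label)`.
#' @return List with `contra` and `ipsi` frequency x time matrices.
#' @export
role_power_maps <- function(tfr, pair = c("PO7", "PO8")) {
  pw <- tfr_power(tfr)
  dirs <- tfr$meta$direction
  sel_l <- dirs == "left"; sel_r <- dirs == "right"
  contra <- (avg_power_map(pw, sel_r, pair[1], tfr$channels) +
             avg_power_map(pw, sel_l, pair[2], tfr$channels)) / 2
  ipsi <- (avg_power_map(pw, sel_l, pair[1], tfr$channels) +
           avg_power_map(pw, sel_r, pair[2], tfr$channels)) / 2
  list(contra = contra, ipsi = ipsi)
}

#' Baseline-corrected log power
#'
#' Log-transforms a (trial-averaged) power map and subtracts, per frequency,
#' the mean log power over the pre-saccade baseline window.
#'
#' @param power_map frequency x time matrix of power (all entries > 0 within
#'   the defined region).
#' @param time_ms time axis matching the columns.
#' @param baseline_ms `c(t0, t1)` baseline window, ms.
#' @return Frequency x time matrix of log-power change (natural log units).
#' @export
#' @examples
#' p <- matrix(2, 1, 5)        # stationary -> zero change
#' baselined_log_power(p, seq(-500, 300, by = 200), c(-500, -150))
baselined_log_power <- function(power_map, time_ms, baseline_ms = c(-500, -150)) {
  bl_cols <- which(time_ms >= baseline_ms[1] & time_ms <= baseline_ms[2])
  if (!length(bl_cols)) stop("baseline window contains no time points")
  bl <- power_map[, bl_cols, drop = FALSE]
  if (any(!is.na(bl) & bl <= 0)) {
    bad <- which(bl <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive power in baseline at frequency row %d, baseline column %d",
                 bad[1], bad[2]))
  }
  lp <- log(power_map)
  lp - rowMeans(log(bl), na.rm = TRUE)
}

#' Inter-trial phase coherence
#'
#' Fourier coefficients are normalised to unit length and averaged across
#' trials; ITPC is the modulus of that average, between 0 (random phases)
#' and 1 (perfect phase consistency). Zero-magnitude coefficients carry no
#' phase and are excluded from the mean.
#'
#' @param coef complex array whose *first* dimension indexes trials/epochs
#'   (e.g. `tfr$coef[, ch, , ]`), or a trials x cells matrix.
#' @return Array of the remaining dimensions with ITPC values in `[0, 1]`;
#'   cells where every coefficient is zero are `NA`.
#' @export
#' @examples
#' itpc(matrix(c(1i, 2i, 3i), 3, 1))   # identical phases -> 1
#' itpc(matrix(c(1, -1), 2, 1))        # opposite phases -> 0
itpc <- function(coef) {
  d <- dim(coef)
  if (is.null(d)) {
    coef <- matrix(coef, ncol = 1)
    d <- dim(coef)
  }
  n_tr <- d[1]
  m <- matrix(coef, nrow = n_tr)
  mag <- Mod(m)
  ok <- !is.na(mag) & mag > 0
  re <- Re(m) / mag
  im <- Im(m) / mag
  re[!ok] <- 0
  im[!ok] <- 0
  cnt <- colSums(ok)
  r <- sqrt(colSums(re)^2 + colSums(im)^2) / cnt
  r[cnt == 0] <- NA_real_
  if (length(d) > 2) {
    array(r, d[-1], dimnames = dimnames(coef)[-1])
  } else {
    names(r) <- colnames(coef)
    r
  }
}

#' ITPC maps by channel role
#'
#' ITPC is computed within condition (left-saccade epochs at one electrode,
#' right-saccade epochs at the other) and the two electrodes' maps averaged
#' per role.
#'
#' @param tfr an `eeg_tfr` object.
#' @param pair `c(left_label, right_label)`.
#' @return List with `contra` and `ipsi` frequency x time ITPC matrices.
#' @export
role_itpc_maps <- function(tfr, pair = c("PO7", "PO8")) {
  dirs <- tfr$meta$direction
  sel_l <- which(dirs == "left"); sel_r <- which(dirs == "right")
  ci_l <- match(pair[1], tfr$channels); ci_r <- match(pair[2], tfr$channels)
  if (is.na(ci_l) || is.na(ci_r)) stop("pair channels not present in TFR")
  it <- function(epochs_sel, ci) {
    co <- tfr$coef[epochs_sel, ci, , , drop = FALSE]
    itpc(array(co, dim(co)[c(1, 3, 4)],
               dimnames = dimnames(co)[c(1, 3, 4)]))
  }
  contra <- (it(sel_r, ci_l) + it(sel_l, ci_r)) / 2
  ipsi <- (it(sel_l, ci_l) + it(sel_r, ci_r)) / 2
  list(contra = contra, ipsi = ipsi)
}

#' Topographic left/right power contrast
#'
#' Per channel, power is averaged over the 8--12 Hz band (by default) and a
#' post-saccade time window, separately for left- and right-saccade epochs,
#' and expressed as `100 * (left - right) / (left + right)`.
#'
#' @param tfr an `eeg_tfr` containing the channels to map.
#' @param band_hz frequency band, Hz.
#' @param window_ms time window, ms.
#' @return Named numeric vector (percent), one value per channel.
#' @export
topography_contrast <- function(tfr, band_hz = c(8, 12), window_ms = c(0, 250)) {
  pw <- tfr_power(tfr)
  fr <- which(tfr$freqs >= band_hz[1] & tfr$freqs <= band_hz[2])
  tc <- which(tfr$time_ms >= window_ms[1] & tfr$time_ms <= window_ms[2])
  dirs <- tfr$meta$direction
  sel_l <- dirs == "left"; sel_r <- dirs == "right"
  if (!any(sel_l) || !any(sel_r)) stop("need epochs of both directions")
  out <- vapply(seq_along(tfr$channels), function(ci) {
    pl <- mean(pw[sel_l, ci, fr, tc], na.rm = TRUE)
    pr <- mean(pw[sel_r, ci, fr, tc], na.rm = TRUE)
    if (pl + pr == 0) NA_real_ else 100 * (pl - pr) / (pl + pr)
  }, numeric(1))
  names(out) <- tfr$channels
  out
}

#' Band-averaged time course of a frequency x time map
#'
#' @param map frequency x time matrix with frequency rownames, or an array
#'   participants x frequency x time.
#' @param freqs frequency axis matching the rows.
#' @param band_hz band to average, Hz.
#' @return Time-course vector (or participants x time matrix).
#' @export
band_timecourse <- function(map, freqs, band_hz = c(8, 12)) {
  fr <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  if (length(dim(map)) == 3) {
    apply(map[, fr, , drop = FALSE], c(1, 3), mean)
  } else {
    colMeans(map[fr, , drop = FALSE])
  }
}

#' Group mean and 95% confidence interval across participants
#'
#' Mean plus/minus 1.96 standard errors across the first array dimension.
#'
#' @param x participants x ... array (participants first).
#' @return List with `mean`, `lo`, `hi` arrays.
#' @export
group_ci <- function(x) {
  n <- dim(x)[1]
  m <- apply(x, seq_along(dim(x))[-1], mean)
  s <- apply(x, seq_along(dim(x))[-1], stats::sd) / sqrt(n)
  list(mean = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}
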
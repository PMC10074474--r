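## Microsaccade-locked EEG epoching and contra/ipsi channel-role mapping.

#' Contra/ipsilateral role assignment for an electrode pair
#'
#' For a left/right electrode pair and a saccade direction, returns which
#' electrode is contralateral and which ipsilateral: a left saccade makes
#' the right-hemisphere electrode contralateral.
#'
#' @param direction `"left"` or `"right"`.
#' @param pair `c(left_label, right_label)`, default `c("PO7", "PO8")`.
#' @return Named character vector `c(contra = , ipsi = )`.
#' @export
#' @examples
#' assign_roles("left")            # contra PO8, ipsi PO7
#' assign_roles("right", c("O1", "O2"))
assign_roles <- function(direction, pair = c("PO7", "PO8")) {
  if (length(pair) != 2) stop("pair must name one left and one right electrode")
  if (!direction %in% c("left", "right")) {
    stop("unknown saccade direction: ", direction)
  }
  if (direction == "left") c(contra = pair[2], ipsi = pair[1])
  else c(contra = pair[1], ipsi = pair[2])
}

#' Cut microsaccade-locked EEG epochs
#'
#' Extracts, for every event, a window of `window_ms` before to `window_ms`
#' after saccade onset from the trial's EEG. Events whose window exceeds the
#' trial recording are dropped (counted in the `n_dropped` attribute).
#'
#' @param eeg an `eeg_sim` object ([simulate_eeg()]) or, for a single
#'   participant, a list of channels x samples matrices indexed by trial.
#' @param events event table ([detect_all()] or [detect_microsaccades()])
#'   with columns `participant, trial, onset_ms, direction, type`.
#' @param window_ms half-window, ms (2401 samples at 1000 Hz for 1200 ms).
#' @return An object of class `eeg_epochs`: list with `data`
#'   (epochs x channels x time array, microvolt), `time_ms` (symmetric about
#'   0), `channels`, `meta` (per-epoch `participant, trial, onset_ms,
#'   direction, type`), `sampling_rate`.
#' @export
epoch_eeg <- function(eeg, events, window_ms = 1200) {
  trials <- if (inherits(eeg, "eeg_sim")) eeg$trials else list(eeg)
  fs <- NULL
  epochs <- list()
  meta <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$participant[i]; tr <- events$trial[i]
    dat <- if (inherits(eeg, "eeg_sim")) trials[[p]][[tr]] else eeg[[tr]]
    if (is.null(fs)) fs <- attr(dat, "sampling_rate")
    half <- round(window_ms * fs / 1000)
    on_idx <- round(events$onset_ms[i] * fs / 1000) + 1L
    a <- on_idx - half; b <- on_idx + half
    if (a < 1L || b > ncol(dat)) {
      n_dropped <- n_dropped + 1L
      next
    }
    epochs[[length(epochs) + 1L]] <- dat[, a:b, drop = FALSE]
    meta[[length(meta) + 1L]] <- events[i, c("participant", "trial",
                                             "onset_ms", "direction", "type")]
  }
  if (!length(epochs)) stop("no events survive epoching")
  chans <- rownames(epochs[[1]])
  half <- (ncol(epochs[[1]]) - 1L) / 2L
  arr <- array(NA_real_, c(length(epochs), length(chans), 2L * half + 1L),
               dimnames = list(NULL, chans, NULL))
  for (k in seq_along(epochs)) arr[k, , ] <- epochs[[k]]
  out <- list(data = arr,
              time_ms = seq(-half, half) * 1000 / fs,
              channels = chans,
              meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
              sampling_rate = fs,
              n_dropped = n_dropped)
  class(out) <- "eeg_epochs"
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("Saccade-locked EEG epochs: %d epochs x %d channels x %d samples (%g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sampling_rate))
  cat(sprintf("  time %g..%g ms; dropped at boundaries: %d\n",
              min(x$time_ms), max(x$time_ms), x$n_dropped))
  dirs <- table(x$meta$direction)
  cat("  directions:", paste(names(dirs), dirs, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Subset epochs
#'
#' @param x an `eeg_epochs` object.
#' @param i epoch indices (logical or integer).
#' @return An `eeg_epochs` object with the selected epochs.
#' @export
subset_epochs <- function(x, i) {
  x$data <- x$data[i, , , drop = FALSE]
  x$meta <- x$meta[i, , drop = FALSE]
  x
}
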
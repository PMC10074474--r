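## Gaze preprocessing: binocular averaging and blink NaN-padding.
## The detector consumes a single cleaned horizontal channel.

#' Merge the two eyes into a single gaze channel
#'
#' Averages the horizontal (and vertical) gaze positions of the left and
#' right eyes. The merge is strict about missing data: a sample is NaN in
#' the output whenever either eye is NaN there, which avoids half-blink
#' velocity artifacts. If one eye is missing for the whole trial the other
#' eye is used alone (with a message); if both are, the trial is flagged
#' unusable.
#'
#' @param rec a `gaze_recording` data frame (see [simulate_gaze()]) with
#'   columns `time_ms, x_left_deg, y_left_deg, x_right_deg, y_right_deg`.
#' @return A `clean_gaze` data frame with columns `time_ms, x, y, blink`
#'   (logical: sample missing), carrying over the recording's attributes.
#' @export
merge_eyes <- function(rec) {
  stopifnot(all(c("time_ms", "x_left_deg", "x_right_deg") %in% names(rec)))
  xl <- rec$x_left_deg; xr <- rec$x_right_deg
  yl <- rec$y_left_deg; yr <- rec$y_right_deg
  left_gone <- all(is.na(xl)); right_gone <- all(is.na(xr))
  if (left_gone && right_gone) {
    stop("trial unusable: both eyes are missing for the whole recording")
  }
  if (left_gone || right_gone) {
    message("one eye entirely missing; falling back to the other eye")
    x <- if (left_gone) xr else xl
    y <- if (left_gone) yr else yl
  } else {
    x <- (xl + xr) / 2   # NaN wherever either eye is NaN
    y <- (yl + yr) / 2
  }
  out <- data.frame(time_ms = rec$time_ms, x = x, y = y, blink = is.na(x))
  for (a in c("sampling_rate", "encoding_offset_ms", "cue_onset_ms",
              "participant", "trial")) {
    attr(out, a) <- attr(rec, a)
  }
  class(out) <- c("clean_gaze", "data.frame")
  out
}

#' Pad missing-data runs to remove residual blink artifacts
#'
#' Every maximal NaN run in the horizontal channel is extended by
#' `pad_ms` on each side (clipped to the trace bounds), and the extended
#' samples are set to NaN in both channels. Padding operates on the NaN
#' clusters currently present, so applying it twice widens each run by a
#' further margin; the pipeline applies it exactly once, before velocity
#' computation.
#'
#' @param trace a `clean_gaze` data frame from [merge_eyes()].
#' @param pad_ms padding on each side of a NaN run, ms.
#' @return The trace with padded NaN runs and an updated `blink` column.
#' @export
pad_blinks <- function(trace, pad_ms = 100) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) stop("trace must carry a sampling_rate attribute")
  miss <- is.na(trace$x)
  if (!any(miss)) return(trace)
  pad <- round(pad_ms * fs / 1000)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(miss)
  out_miss <- miss
  for (k in which(runs$values)) {
    a <- max(1L, starts[k] - pad)
    b <- min(n, ends[k] + pad)
    out_miss[a:b] <- TRUE
  }
  trace$x[out_miss] <- NaN
  if ("y" %in% names(trace)) trace$y[out_miss] <- NaN
  trace$blink <- out_miss
  trace
}

#' Read / write gaze recordings as TSV
#'
#' Tab-separated columns `time_ms, x_left_deg, y_left_deg, x_right_deg,
#' y_right_deg`; trial annotations (sampling rate, encoding offset, cue
#' onset) travel in `# key: value` header comment lines.
#'
#' @param rec a `gaze_recording` data frame.
#' @param path file path.
#' @return `read_gaze_tsv` returns a `gaze_recording` data frame;
#'   `write_gaze_tsv` returns `path` invisibly.
#' @export
write_gaze_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in c("sampling_rate", "encoding_offset_ms", "cue_onset_ms")) {
    v <- attr(rec, a)
    if (!is.null(v)) writeLines(sprintf("# %s: %.10g", a, v), con)
  }
  utils::write.table(as.data.frame(rec), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^# ", lines, value = TRUE)
  rec <- utils::read.delim(path, comment.char = "#")
  for (h in hdr) {
    m <- regmatches(h, regexec("^# ([a-z_]+): ([-0-9.eE+]+)$", h))[[1]]
    if (length(m) == 3) attr(rec, m[2]) <- as.numeric(m[3])
  }
  class(rec) <- c("gaze_recording", "data.frame")
  rec
}

#' Write a detected-event table as TSV
#'
#' @param events an event data frame (see [detect_microsaccades()]).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path)
}
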
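# Shared fixtures and independent oracles, built in code at test time.

.fixtures <- new.env(parent = emptyenv())

# small simulated study reused across files
small_study <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- sim_config(n_participants = 2, n_trials_per_participant = 8,
                      seed = 101)
    .fixtures$study <- simulate_study(cfg)
  }
  .fixtures$study
}

# moderate pipeline run reused by the effect-recovery checks
effect_report <- function() {
  if (is.null(.fixtures$report)) {
    cfg <- sim_config(n_participants = 8, n_trials_per_participant = 30,
                      seed = 5)
    .fixtures$report <- run_pipeline(cfg, n_permutations = 2000,
                                     verbose = FALSE)
  }
  .fixtures$report
}

# build a clean_gaze trace from a bare x vector
make_trace <- function(x, fs = 1000, encoding_offset = NULL, cue_onset = NULL) {
  df <- data.frame(time_ms = seq_along(x) - 1, x = x, y = 0, blink = is.na(x))
  attr(df, "sampling_rate") <- fs
  if (!is.null(encoding_offset)) attr(df, "encoding_offset_ms") <- encoding_offset
  if (!is.null(cue_onset)) attr(df, "cue_onset_ms") <- cue_onset
  class(df) <- c("clean_gaze", "data.frame")
  df
}

# build a binocular gaze recording from per-eye vectors
make_rec <- function(xl, xr, yl = rep(0, length(xl)), yr = rep(0, length(xr)),
                     fs = 1000, encoding_offset = NULL, cue_onset = NULL) {
  df <- data.frame(time_ms = seq_along(xl) - 1, x_left_deg = xl,
                   y_left_deg = yl, x_right_deg = xr, y_right_deg = yr)
  attr(df, "sampling_rate") <- fs
  if (!is.null(encoding_offset)) attr(df, "encoding_offset_ms") <- encoding_offset
  if (!is.null(cue_onset)) attr(df, "cue_onset_ms") <- cue_onset
  class(df) <- c("gaze_recording", "data.frame")
  df
}

# minimal eeg_epochs object from an epochs x channels x time array
make_epochs <- function(arr, channels, direction, type = NULL, fs = 1000) {
  half <- (dim(arr)[3] - 1) / 2
  dimnames(arr) <- list(NULL, channels, NULL)
  structure(list(data = arr, time_ms = seq(-half, half) * 1000 / fs,
                 channels = channels,
                 meta = data.frame(participant = 1L,
                                   trial = seq_len(dim(arr)[1]),
                                   onset_ms = 0,
                                   direction = direction,
                                   type = if (is.null(type))
                                     rep(NA_character_, dim(arr)[1]) else type),
                 sampling_rate = fs, n_dropped = 0L),
            class = "eeg_epochs")
}

# --- independent oracles -----------------------------------------------------

# direct-convolution smoothing oracle (explicit loop, edge-renormalised)
oracle_smooth <- function(v, window = 7, sigma = window / 5) {
  half <- (window - 1) / 2
  w <- exp(-(-half:half)^2 / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (k in -half:half) {
      j <- i + k
      if (j >= 1 && j <= n) {
        num <- num + w[k + half + 1] * v[j]
        den <- den + w[k + half + 1]
      }
    }
    out[i] <- num / den
  }
  out
}

# direct-DFT oracle for one Hanning-tapered zero-padded segment
oracle_dft_coef <- function(x, freq, fs = 1000, pad_n = 1000) {
  n <- length(x)
  tap <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  xt <- c(x * tap, rep(0, pad_n - n))
  k <- freq * pad_n / fs
  idx <- seq(0, pad_n - 1)
  sum(xt * exp(-2i * pi * k * idx / pad_n)) * 2 / sum(tap)
}

# naive 4-adjacency clustering of a t matrix (BFS in plain R)
oracle_cluster_sums <- function(tmat, tcrit) {
  nf <- nrow(tmat); nt <- ncol(tmat)
  seen <- matrix(FALSE, nf, nt)
  sums <- numeric(0)
  for (j in seq_len(nt)) for (i in seq_len(nf)) {
    if (seen[i, j] || abs(tmat[i, j]) < tcrit) next
    sgn <- sign(tmat[i, j])
    queue <- list(c(i, j)); seen[i, j] <- TRUE; s <- 0
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      s <- s + tmat[c0[1], c0[2]]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- c0[1] + d[1]; jj <- c0[2] + d[2]
        if (ii >= 1 && ii <= nf && jj >= 1 && jj <= nt && !seen[ii, jj] &&
            abs(tmat[ii, jj]) >= tcrit && sign(tmat[ii, jj]) == sgn) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
    sums <- c(sums, s)
  }
  sums
}

oracle_tmap <- function(x) {
  # x: participants x f x t
  apply(x, c(2, 3), function(v) {
    m <- mean(v); s <- sd(v)
    if (s == 0) return(if (m == 0) 0 else sign(m) * 1e12)
    m / (s / sqrt(length(v)))
  })
}

# exhaustive sign-flip enumeration, fully independent of the package kernel
oracle_exact_p <- function(x, alpha = 0.05) {
  n <- dim(x)[1]
  tcrit <- qt(1 - alpha / 2, n - 1)
  obs <- oracle_cluster_sums(oracle_tmap(x), tcrit)
  patt <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  maxima <- apply(patt, 1, function(s) {
    xs <- x * s  # recycles s down the participant dimension
    su <- oracle_cluster_sums(oracle_tmap(xs), tcrit)
    if (length(su)) max(abs(su)) else 0
  })
  list(obs = obs, maxima = maxima,
       p = vapply(abs(obs), function(o) mean(maxima >= o), numeric(1)))
}
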
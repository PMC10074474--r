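make_signal_epochs <- function(..., channels = "PO7", direction = NULL) {
  sigs <- list(...)
  n <- length(sigs[[1]])
  arr <- array(0, c(length(sigs), length(channels), n))
  for (i in seq_along(sigs)) for (j in seq_along(channels)) {
    arr[i, j, ] <- sigs[[i]]
  }
  if (is.null(direction)) direction <- rep("left", length(sigs))
  make_epochs(arr, channels, direction)
}

test_that("STFT of silence is zero power; frequencies above Nyquist error", {
  ep <- make_signal_epochs(rep(0, 2401))
  tfr <- stft_epochs(ep, freqs = c(5, 10), toi_ms = c(-400, 0, 400))
  expect_true(all(tfr_power(tfr) == 0))
  expect_error(stft_epochs(ep, freqs = 600), "Nyquist")
})

test_that("a pure 10-Hz sinusoid matches the direct-DFT oracle and peaks at 10 Hz", {
  t_s <- seq(-1200, 1200) / 1000
  x <- sin(2 * pi * 10 * t_s)
  ep <- make_signal_epochs(x)
  tfr <- stft_epochs(ep, freqs = 1:50, toi_ms = 0)
  co <- tfr$coef[1, 1, , 1]
  # oracle: direct DFT of the tapered 300-sample segment centred at t = 0
  centre <- 1201
  seg <- x[(centre - 149):(centre + 150)]
  expect_equal(co[["10"]], oracle_dft_coef(seg, 10), tolerance = 1e-10)
  pw <- Mod(co)^2
  expect_equal(names(which.max(pw)), "10")
  expect_gt(pw[["10"]], 50 * pw[["20"]])
  # unit-amplitude sinusoid -> coefficient magnitude ~ 1 under the scaling
  expect_equal(Mod(co[["10"]]), 1, tolerance = 0.05)
})

test_that("power scales quadratically and coefficients linearly", {
  set.seed(42)
  x <- rnorm(2401); y <- rnorm(2401)
  tf <- function(sig) stft_epochs(make_signal_epochs(sig), freqs = c(4, 11, 23),
                                  toi_ms = c(-300, 0, 300))$coef
  expect_equal(tfr_power(list(coef = tf(2 * x))),
               4 * Mod(tf(x))^2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tf(1.5 * x - 2 * y), 1.5 * tf(x) - 2 * tf(y), tolerance = 1e-10)
})

test_that("edge time points whose window leaves the epoch are undefined", {
  ep <- make_signal_epochs(rnorm(2401))
  tfr <- stft_epochs(ep, freqs = 10, toi_ms = c(-1200, -1100, -1050, 0, 1050, 1100))
  v <- tfr$coef[1, 1, 1, ]
  # the 300-ms window fits only for centres in [-1051, 1050]
  expect_true(all(is.na(v[c("-1200", "-1100", "1100")])))
  expect_false(anyNA(v[c("-1050", "0", "1050")]))
})

test_that("lateralisation contrast follows its normalised formula", {
  expect_equal(lateralisation_contrast(1, 1), 0)
  expect_equal(lateralisation_contrast(1, 3), -50)
  expect_equal(lateralisation_contrast(3, 1), 50)
  expect_true(is.na(lateralisation_contrast(0, 0)))
  # antisymmetry under contra/ipsi exchange, bounded in [-100, 100]
  set.seed(9)
  pc <- runif(100); pi_ <- runif(100)
  L <- lateralisation_contrast(pc, pi_)
  expect_equal(L, -lateralisation_contrast(pi_, pc))
  expect_true(all(abs(L) <= 100))
})

test_that("baselined log power is zero for stationary power and log-ratio for steps", {
  tm <- seq(-600, 600, by = 100)
  p <- matrix(2.5, nrow = 3, ncol = length(tm))
  expect_equal(baselined_log_power(p, tm), matrix(0, 3, length(tm)),
               ignore_attr = TRUE)
  p2 <- p
  p2[, tm > 0] <- 5
  d <- baselined_log_power(p2, tm)
  expect_equal(d[1, tm > 0], rep(log(2), sum(tm > 0)), ignore_attr = TRUE)
  expect_equal(d[1, tm <= 0], rep(0, sum(tm <= 0)), ignore_attr = TRUE)
  p3 <- p
  p3[2, 2] <- 0
  expect_error(baselined_log_power(p3, tm), "frequency row 2")
})

test_that("ITPC is 1 for identical phases, 0 for opposite pairs, scale-invariant", {
  expect_equal(itpc(matrix(c(1i, 2i, 5i), 3, 1)), 1, ignore_attr = TRUE)
  expect_equal(itpc(matrix(exp(1i * c(0.3, 0.3, 0.3)), 3, 1)), 1,
               ignore_attr = TRUE)
  expect_equal(itpc(matrix(c(1 + 0i, -2 + 0i), 2, 1)), 0, ignore_attr = TRUE,
               tolerance = 1e-12)
  set.seed(3)
  z <- matrix(complex(modulus = runif(60, 0.1, 4),
                      argument = runif(60, 0, 2 * pi)), 20, 3)
  scale_per_trial <- runif(20, 0.01, 10)
  expect_equal(itpc(z * scale_per_trial), itpc(z), tolerance = 1e-12)
  expect_true(all(itpc(z) >= 0 & itpc(z) <= 1))
  # zero-magnitude coefficients are excluded, all-zero cells undefined
  z0 <- matrix(c(0 + 0i, 1i, 1i, 0 + 0i, 0 + 0i, 0 + 0i), 3, 2)
  out <- itpc(z0)
  expect_equal(out[1], 1, ignore_attr = TRUE)
  expect_true(is.na(out[2]))
})

test_that("null ITPC matches the Rayleigh expectation from a Monte-Carlo oracle", {
  n <- 100
  # oracle: resultant length of n uniform unit phasors, 10^4 replicates
  set.seed(77)
  oracle <- replicate(1e4, {
    th <- runif(n, 0, 2 * pi)
    Mod(mean(exp(1i * th)))
  })
  # package estimate over independent replicates
  reps <- 300
  vals <- replicate(reps, itpc(matrix(exp(1i * runif(n, 0, 2 * pi)), n, 1)))
  se <- sd(oracle) * sqrt(1 / reps + 1 / 1e4)
  expect_lt(abs(mean(vals) - mean(oracle)), 2 * se)
  # and both agree with the asymptotic closed form sqrt(pi)/(2 sqrt(n))
  expect_lt(abs(mean(oracle) - sqrt(pi) / (2 * sqrt(n))), 0.002)
})

test_that("fully phase-locked bursts give higher ipsilateral ITPC in the alpha window", {
  cfg <- sim_config(n_participants = 2, n_trials_per_participant = 25,
                    alpha_phase_locked_fraction = 1, blink_prob_per_trial = 0,
                    seed = 55)
  st <- simulate_study(cfg)
  ep <- epoch_eeg(st$eeg, st$truth)
  it_ipsi <- 0; it_contra <- 0
  for (p in 1:2) {
    tfr <- stft_epochs(subset_epochs(ep, ep$meta$participant == p),
                       freqs = 8:12, toi_ms = seq(0, 240, 40),
                       channels = c("PO7", "PO8"))
    ri <- role_itpc_maps(tfr)
    it_ipsi <- it_ipsi + mean(ri$ipsi)
    it_contra <- it_contra + mean(ri$contra)
  }
  expect_gt(it_ipsi, it_contra)
})

test_that("topographic left/right contrast vanishes for identical trial sets", {
  set.seed(8)
  sig <- rnorm(2401)
  arr <- array(0, c(2, 4, 2401))
  for (i in 1:2) for (j in 1:4) arr[i, j, ] <- sig
  ep <- make_epochs(arr, c("PO7", "PO8", "O1", "O2"), c("left", "right"))
  tfr <- stft_epochs(ep, freqs = 8:12, toi_ms = seq(0, 240, 40))
  topo <- topography_contrast(tfr)
  expect_equal(unname(topo), rep(0, 4))
  expect_named(topo, c("PO7", "PO8", "O1", "O2"))
})
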
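test_that("velocity of a constant trace is zero and NaN propagates", {
  tr <- make_trace(rep(0.4, 200))
  v <- compute_velocity(tr)
  expect_true(all(v$v[!is.na(v$v)] == 0))
  x <- rep(0.4, 200); x[100] <- NaN
  v2 <- compute_velocity(make_trace(x))
  # the NaN sample corrupts first differences 99 and 100, and smoothing
  # spreads NaN over the 7-sample window around them
  expect_true(all(is.na(v2$v[96:103])))
  expect_false(anyNA(v2$v[1:95]))
})

test_that("a single-sample step matches the direct-convolution oracle", {
  x <- c(rep(0, 100), rep(0.5, 100))
  tr <- make_trace(x)
  raw <- abs(diff(x)) * 1000
  expect_equal(max(raw), 500)            # pre-smoothing peak 0.5 deg x 1000 Hz
  v <- compute_velocity(tr)
  expected <- oracle_smooth(c(raw, NA))
  expect_equal(v$v, expected)
  expect_lt(max(v$v, na.rm = TRUE), 500) # smoothing attenuates the impulse
})

test_that("onsets are first supra-threshold samples of a 5x-median excursion", {
  # constant slope 0.02 deg/sample -> v = 20 deg/s; one steeper excursion
  slopes <- rep(0.02, 600)
  slopes[300:304] <- 0.15               # excursion to 150 deg/s
  tr <- make_trace(cumsum(c(0, slopes)))
  v <- compute_velocity(tr)
  thr <- velocity_threshold(v)
  expect_equal(thr, 100)                # 5 x median of 20
  onsets <- detect_onsets(v, thr)
  sm <- oracle_smooth(c(abs(diff(tr$x)) * 1000, NA))
  expect_equal(onsets, tr$time_ms[which(sm > 100)[1]])
  expect_length(onsets, 1)
})

test_that("the 100-ms refractory period suppresses close successors", {
  slopes <- rep(0.02, 900)
  slopes[300:302] <- 0.2
  slopes[353:355] <- 0.2                # 53 ms later: suppressed
  slopes[603:605] <- 0.2                # 300 ms later: kept
  tr <- make_trace(cumsum(c(0, slopes)))
  v <- compute_velocity(tr)
  onsets <- detect_onsets(v, velocity_threshold(v))
  expect_length(onsets, 2)
  expect_true(all(diff(onsets) >= 100))
  expect_lt(abs(onsets[1] - 300), 5)
  expect_lt(abs(onsets[2] - 603), 5)
})

test_that("no onsets when nothing exceeds threshold; all-NaN warns empty", {
  tr <- make_trace(cumsum(c(0, rep(0.02, 300))))
  v <- compute_velocity(tr)
  expect_length(detect_onsets(v, velocity_threshold(v)), 0)
  v$v[] <- NA_real_
  expect_warning(o <- detect_onsets(v, 10), "all-NaN")
  expect_length(o, 0)
})

test_that("event measurement uses the -50..0 and +50..+100 ms windows", {
  x <- c(rep(-0.2, 300), seq(-0.2, 0.3, length.out = 21), rep(0.3, 300))
  tr <- make_trace(x)
  ev <- measure_event(tr, onset_ms = 300)
  expect_equal(ev$pre_pos_deg, -0.2)
  expect_equal(ev$post_pos_deg, 0.3)
  expect_equal(ev$magnitude_deg, 0.5)
  expect_equal(ev$direction, "right")
  down <- measure_event(make_trace(c(rep(0, 300), rep(-0.3, 300))), 300)
  expect_equal(down$direction, "left")
  # pre window overlapping the trace start drops the event
  expect_null(measure_event(tr, onset_ms = 30))
  expect_null(measure_event(tr, onset_ms = length(x) - 60))
})

test_that("magnitude and displacement filters apply the 1-degree and 3.42-arcmin rules", {
  ev <- data.frame(onset_ms = 1:4 * 100,
                   pre_pos_deg = 0, post_pos_deg = 0,
                   magnitude_deg = c(1.2, 0.03, 0.5, 0.057),
                   displacement_deg = c(1.2, 0.03, 0.5, 0.057),
                   direction = "right")
  out <- filter_events(ev)
  expect_equal(out$magnitude_deg, c(0.5, 0.057))  # 1.2 too big, 0.03 below floor
  # the floor is exactly 3.42 arcmin and inclusive
  expect_equal(displacement_floor_arcmin() / 60, 0.057)
})

test_that("start/return classification compares distances to fixation, ties excluded", {
  ev <- data.frame(pre_pos_deg = c(0.05, 0.45, -0.2),
                   post_pos_deg = c(0.45, 0.05, 0.2))
  out <- classify_start_return(ev, fixation_x = 0)
  expect_equal(out$type, c("start", "return", NA))
})

test_that("delay selection keeps onsets 500 ms inside the delay bounds", {
  ev <- data.frame(onset_ms = c(2050, 2300, 3300, 3700))
  out <- select_delay_events(ev, encoding_offset_ms = 1750, cue_onset_ms = 3750)
  expect_equal(out$onset_ms, 2300)
  expect_error(select_delay_events(ev, NULL, 3750), "annotations")
})

test_that("detected onsets respect the refractory spacing on synthetic trials", {
  st <- small_study()
  det <- detect_all(st$gaze)
  by_trial <- split(det$onset_ms, paste(det$participant, det$trial))
  ok <- vapply(by_trial, function(o) length(o) < 2 || all(diff(sort(o)) >= 100),
               logical(1))
  expect_true(all(ok))
})

test_that("scaling gaze by c > 0 leaves the detected onset set unchanged", {
  st <- small_study()
  rec <- st$gaze$trials[[1]][[3]]
  ev1 <- detect_microsaccades(rec)
  for (c_ in c(0.5, 3.7)) {
    rec2 <- rec
    rec2$x_left_deg <- rec$x_left_deg * c_
    rec2$x_right_deg <- rec$x_right_deg * c_
    ev2 <- detect_microsaccades(rec2, min_displacement_deg = 0.057 * c_,
                                max_magnitude_deg = 1.0 * c_)
    expect_equal(ev2$onset_ms, ev1$onset_ms)
  }
})

test_that("mirroring gaze flips directions and preserves start/return labels", {
  st <- small_study()
  found <- 0
  for (tr_i in seq_along(st$gaze$trials[[1]])) {
    rec <- st$gaze$trials[[1]][[tr_i]]
    ev1 <- detect_microsaccades(rec)
    if (!nrow(ev1)) next
    rec2 <- rec
    rec2$x_left_deg <- -rec$x_left_deg
    rec2$x_right_deg <- -rec$x_right_deg
    ev2 <- detect_microsaccades(rec2)
    expect_equal(ev2$onset_ms, ev1$onset_ms)
    expect_equal(ev2$direction, ifelse(ev1$direction == "left", "right", "left"))
    expect_equal(ev2$type, ev1$type)
    found <- found + nrow(ev1)
  }
  expect_gt(found, 0)
})

test_that("detection recovers injected events with matching directions", {
  st <- small_study()
  det <- detect_all(st$gaze)
  rec <- detection_recovery(st$truth, det)
  expect_gt(rec$recall, 0.9)
  expect_gt(rec$precision, 0.95)
  expect_lt(rec$mean_onset_error_ms, 10)
  expect_equal(rec$direction_agreement, 1)
})
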
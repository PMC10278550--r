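test_that("blink interpolation reconstructs values on a linear ramp and spares edges", {
  # fully valid series is untouched
  s <- series_from_segments(list(c("left", 500)))
  out <- preprocess_pupil(s)
  expect_equal(out$pupil, s$pupil)
  expect_false(any(out$reconstructed))

  # invalid run inside a linear ramp: interpolation equals the ramp
  n <- 1000
  ramp <- 2000 + 0.5 * (0:(n - 1))
  pup <- ramp
  pup[400:500] <- 0
  s <- sample_series("P01", "P01", 0:(n - 1), rep(500, n), rep(500, n),
                     pup, pup > 0)
  out <- preprocess_pupil(s, pad_ms = 50)
  expect_equal(out$pupil, ramp)
  expect_equal(which(out$reconstructed), 350:550)  # padded run

  # run touching the series start stays unfilled
  pup2 <- ramp
  pup2[1:100] <- 0
  s2 <- sample_series("P01", "P01", 0:(n - 1), rep(500, n), rep(500, n),
                      pup2, pup2 > 0)
  out2 <- preprocess_pupil(s2, pad_ms = 50)
  expect_equal(out2$pupil[1:100], rep(0, 100))
  expect_false(any(out2$reconstructed[1:100]))
  expect_false(any(out2$valid[1:100]))

  s3 <- s
  s3$valid[] <- FALSE
  expect_error(preprocess_pupil(s3), "no valid samples")
})

test_that("baseline is the window median and is robust to outliers", {
  t_rel <- -150:1100
  e <- make_epoch(t_rel, rep(2000, length(t_rel)))
  expect_equal(baseline_size(e), 2000)

  # symmetric ramp across the baseline window medians to its centre
  pup <- rep(2000, length(t_rel))
  pup[t_rel >= -100 & t_rel < 0] <- seq(1990, 2010, length.out = 100)
  expect_equal(baseline_size(make_epoch(t_rel, pup)), 2000)

  pup2 <- rep(2000, length(t_rel))
  pup2[t_rel == -37] <- 5000
  expect_equal(baseline_size(make_epoch(t_rel, pup2)), 2000)

  # sample at t_rel = 0 is outside the (half-open) baseline window
  pup3 <- rep(2000, length(t_rel))
  pup3[t_rel == 0] <- 1e6
  expect_equal(baseline_size(make_epoch(t_rel, pup3)), 2000)
})

test_that("a window with too few valid samples yields an absent metric", {
  t_rel <- -150:1100
  v <- rep(TRUE, length(t_rel))
  v[t_rel >= -100 & t_rel < -40] <- FALSE   # 60% of baseline window invalid
  e <- make_epoch(t_rel, rep(2000, length(t_rel)), v)
  expect_true(is.na(baseline_size(e)))
  expect_false(is.na(orienting_amplitude(e)))
})

test_that("baseline correction zeroes the window median and composes to identity", {
  t_rel <- -150:1100
  e <- make_epoch(t_rel, rep(2000, length(t_rel)))
  ec <- baseline_correct(e, 2000)
  expect_true(all(ec$pupil == 0))
  expect_equal(baseline_correct(e, 0)$pupil, e$pupil)
  expect_error(baseline_correct(e, NA_real_), "NA")

  set.seed(41)
  for (r in 1:25) {
    e <- make_epoch(t_rel, 2000 + cumsum(rnorm(length(t_rel))))
    b <- baseline_size(e)
    expect_equal(baseline_size(baseline_correct(e, b)), 0)
  }
})

test_that("orienting amplitude uses the constriction-magnitude sign convention", {
  t_rel <- -150:1100
  e0 <- make_epoch(t_rel, rep(0, length(t_rel)))
  expect_equal(orienting_amplitude(e0), 0)

  pup <- rep(0, length(t_rel))
  pup[t_rel >= 500 & t_rel <= 1000] <- -40
  e <- make_epoch(t_rel, pup)
  expect_equal(orienting_amplitude(e), 40)
  expect_equal(orienting_amplitude(e, signed = TRUE), -40)

  # planted kernel matches a brute-force window median
  k <- kernel_params(amplitude = -63)
  e2 <- make_epoch(t_rel, ifelse(t_rel >= 0, pupil_kernel(pmax(t_rel, 0), k), 0))
  win <- e2$pupil[e2$t_rel >= 500 & e2$t_rel <= 1000]
  expect_equal(orienting_amplitude(e2), -brute_median(win))
})

test_that("the control metric is max(early) minus min(orienting window)", {
  t_rel <- -150:1100
  expect_equal(orienting_control(make_epoch(t_rel, rep(7, length(t_rel)))), 0)

  pup <- rep(0, length(t_rel))
  pup[t_rel == 150] <- 10      # early dilation bump
  pup[t_rel == 700] <- -40     # trough
  expect_equal(orienting_control(make_epoch(t_rel, pup)), 50)

  ramp <- -0.05 * pmax(t_rel, 0)
  e <- make_epoch(t_rel, ramp)
  w_early <- ramp[t_rel >= 0 & t_rel <= 300]
  w_late <- ramp[t_rel >= 500 & t_rel <= 1000]
  expect_equal(orienting_control(e), max(w_early) - min(w_late))
})

test_that("orienting amplitude grows monotonically with the planted constriction", {
  amps <- c(10, 40, 80, 160)
  t_rel <- -150:1100
  meas <- vapply(amps, function(a) {
    k <- kernel_params(amplitude = -a)
    e <- make_epoch(t_rel, ifelse(t_rel >= 0, pupil_kernel(pmax(t_rel, 0), k), 0))
    orienting_amplitude(e)
  }, numeric(1))
  expect_true(all(diff(meas) > 0))
})

test_that("the gaze filter keeps events that stay on the expanded grid", {
  g <- test_geometry()
  cfg <- analysis_config()
  roi <- g$model_grid_roi
  center <- c(mean(roi[c(1, 3)]), mean(roi[c(2, 4)]))
  n <- 3000
  mk <- function(gx, gy) {
    sample_series("P01", "P01", 0:(n - 1), gx, gy, rep(2000, n), TRUE)
  }
  ev <- data.frame(t_model_onset = 1000)

  s <- mk(rep(center[1], n), rep(center[2], n))
  expect_true(gaze_inclusion(s, ev, g, cfg))

  # leaves the expanded ROI at onset+400 for 200 ms
  gx <- rep(center[1], n)
  gx[1400:1600] <- roi[1] - cfg$inclusion_margin_deg * g$px_per_degree - 50
  expect_false(gaze_inclusion(mk(gx, rep(center[2], n)), ev, g, cfg))

  # exactly on the expanded boundary counts as inside
  edge <- roi[3] + cfg$inclusion_margin_deg * g$px_per_degree
  expect_true(gaze_inclusion(mk(rep(edge, n), rep(center[2], n)), ev, g, cfg))

  # cumulative mode tolerates interruptions that continuous mode rejects
  cfg2 <- analysis_config(inclusion_mode = "cumulative",
                          inclusion_window_ms = 800)
  expect_true(gaze_inclusion(mk(gx, rep(center[2], n)), ev, g, cfg2))
})

test_that("robust z-scores centre on the median and scale by the unscaled MAD", {
  expect_equal(robust_z(c(1, 2, 3), rep("a", 3)), c(-1, 0, 1))
  expect_error(robust_z(rep(5, 4), rep("a", 4)), "MAD is zero")

  set.seed(43)
  x <- rnorm(201)
  z <- robust_z(x, rep("a", 201))
  expect_equal(median(z), 0)
  expect_equal(median(abs(z - median(z))), 1)

  # per-participant: each participant standardized independently
  x2 <- c(x, 100 + 3 * rnorm(201))
  pid <- rep(c("a", "b"), each = 201)
  z2 <- robust_z(x2, pid)
  for (p in c("a", "b")) expect_equal(median(z2[pid == p]), 0)
})

test_that("feature-augmented events carry absent metrics when windows are blinked out", {
  p <- copy_sim_params(n_participants = 1, n_trials_per_condition = 2,
                       pupil_noise_sd = 0, blink_rate_hz = 0,
                       flicker_rate_hz = 0, p_all_correct = 1)
  sim <- simulate_copy_task(p, test_geometry(), seed = 44)
  s <- sim$samples[[1]]
  ev <- segment_sampling_events(s, sim$trials, analysis_config(),
                                test_geometry())
  # blot out one event's entire baseline window
  t0 <- ev$t_model_onset[1]
  idx <- s$time >= t0 - 100 & s$time < t0
  s$valid[idx] <- FALSE
  s$pupil[idx] <- 0
  fe <- add_pupil_features(ev, s, analysis_config(), test_geometry())
  expect_true(is.na(fe$baseline_pupil[1]))
  expect_true(is.na(fe$orienting_amplitude[1]))
  expect_false(any(is.na(fe$baseline_pupil[-1])))
})
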
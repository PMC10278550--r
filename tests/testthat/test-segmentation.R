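test_that("visits alternate and cover the recording", {
  s <- series_from_segments(list(c("left", 2000), c("right", 1000)))
  v <- detect_visits(s, test_geometry(), 100)
  expect_equal(v$side, c("left", "right"))
  expect_equal(v$t_enter, c(0, 2000))
  expect_equal(v$t_leave, c(2000, 3000))
})

test_that("sub-hysteresis excursions are absorbed; sustained ones end the visit", {
  g <- test_geometry()
  # 50-ms right excursion at 500: single left visit
  s <- series_from_segments(list(c("left", 500), c("right", 50),
                                 c("left", 1450), c("right", 500)))
  v <- detect_visits(s, g, 100)
  expect_equal(v$side, c("left", "right"))
  expect_equal(v$t_leave[1], 2000)

  # 120-ms right excursion at 500 ends the left visit there
  s <- series_from_segments(list(c("left", 500), c("right", 120),
                                 c("left", 1380), c("right", 500)))
  v <- detect_visits(s, g, 100)
  expect_equal(v$side, c("left", "right", "left", "right"))
  expect_equal(v$t_leave[1], 500)
})

test_that("blink samples inherit the current side and never split a visit", {
  s <- series_from_segments(list(c("left", 1000), c("right", 1000)))
  s$valid[400:600] <- FALSE
  s$pupil[400:600] <- 0
  v <- detect_visits(s, test_geometry(), 100)
  expect_equal(nrow(v), 2)
  expect_equal(v$t_leave[1], 1000)
})

test_that("a left visit shorter than the delay produces no sampling event", {
  s <- series_from_segments(list(c("right", 500), c("left", 1000),
                                 c("right", 3500)))
  ev <- segment_sampling_events(s, one_trial(delay = 1500, t_end = 5000),
                                analysis_config(), test_geometry())
  expect_equal(nrow(ev), 0)
})

test_that("a surviving visit yields model onset after the delay and the traced dwell", {
  s <- series_from_segments(list(c("left", 2000), c("right", 3000)))
  ev <- segment_sampling_events(s, one_trial(delay = 1500, t_end = 5000),
                                analysis_config(), test_geometry())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_model_onset, 1500)
  expect_equal(ev$dwell_ms, 500)
  expect_equal(ev$build_ms, 3000)  # dwell end (2000) to trial end (5000)
  expect_equal(ev$ended_by, "trial-end")
})

test_that("dwell follows the hand-traced hysteresis rule from either reference point", {
  # model onset at 1500; right flicker of 50 ms at onset+200; sustained
  # right at onset+800
  segs <- list(c("left", 1700), c("right", 50), c("left", 550),
               c("right", 2000))
  s <- series_from_segments(segs)
  g <- test_geometry()
  trial <- one_trial(delay = 1500, t_end = 4300)
  ev <- segment_sampling_events(s, trial, analysis_config(), g)
  expect_equal(ev$dwell_ms, 800)

  cfg_vs <- analysis_config(dwell_reference = "visit_start")
  ev2 <- segment_sampling_events(s, trial, cfg_vs, g)
  expect_equal(ev2$dwell_ms, 2300)

  # immediate sustained departure at onset: dwell 0
  s0 <- series_from_segments(list(c("left", 1500), c("right", 1000)))
  ev0 <- segment_sampling_events(s0, one_trial(delay = 1500, t_end = 2500),
                                 analysis_config(), g)
  expect_equal(ev0$dwell_ms, 0)
})

test_that("build duration runs to the first sustained left return or trial end", {
  g <- test_geometry()
  cfg <- analysis_config()
  # sustained left return 1000 ms after dwell end
  s <- series_from_segments(list(c("left", 2000), c("right", 1000),
                                 c("left", 2000)))
  ev <- segment_sampling_events(s, one_trial(delay = 1500, t_end = 5000),
                                cfg, g)
  expect_equal(ev$build_ms[1], 1000)
  expect_equal(ev$ended_by[1], "gaze-return")

  # 80-ms left flicker at +400 does not end the build; sustained left
  # at +1200 does
  s <- series_from_segments(list(c("left", 2000), c("right", 400),
                                 c("left", 80), c("right", 720),
                                 c("left", 2000)))
  ev <- segment_sampling_events(s, one_trial(delay = 1500, t_end = 5200),
                                cfg, g)
  expect_equal(ev$build_ms[1], 1200)

  # trial ends 700 ms after dwell end with no return
  s <- series_from_segments(list(c("left", 2000), c("right", 700)))
  ev <- segment_sampling_events(s, one_trial(delay = 1500, t_end = 2700),
                                cfg, g)
  expect_equal(ev$build_ms, 700)
  expect_equal(ev$ended_by, "trial-end")
})

test_that("compute_dwell and compute_build agree with the segmenter", {
  g <- test_geometry()
  cfg <- analysis_config()
  s <- series_from_segments(list(c("left", 2000), c("right", 1000),
                                 c("left", 2000)))
  trial <- one_trial(delay = 1500, t_end = 5000)
  visits <- detect_visits(s, g, cfg$hysteresis_ms)
  ev <- segment_sampling_events(s, trial, cfg, g)
  expect_equal(compute_dwell(ev[1, ], visits, cfg, trial), ev$dwell_ms[1])
  b <- compute_build(ev[1, ], visits, trial, cfg)
  expect_equal(b$build_ms, ev$build_ms[1])
  expect_equal(b$ended_by, ev$ended_by[1])
})

test_that("trial and condition filters drop events with an auditable log", {
  ev <- random_event_table(10)
  ev$participant_id <- "P01"
  ev$trial_id <- 1
  ev$condition_delay_ms <- 1500
  trials <- one_trial(correct = FALSE)
  out <- suppressMessages(filter_events(ev, trials))
  expect_equal(nrow(out), 0)
  expect_equal(unname(attr(out, "drop_log")["incorrect-trial"]), 10L)

  # mixed fixture: 2 incorrect-trial, 1 short-condition, 3 clean
  ev <- random_event_table(6)
  ev$participant_id <- "P01"
  ev$trial_id <- c(1, 1, 2, 3, 3, 3)
  ev$condition_delay_ms <- c(1500, 1500, 200, 3000, 3000, 3000)
  ev$included_gaze_filter <- TRUE
  trials <- rbind(one_trial(trial = 1, correct = FALSE),
                  one_trial(trial = 2, delay = 200, t_start = 10000,
                            t_end = 20000),
                  one_trial(trial = 3, delay = 3000, t_start = 20000,
                            t_end = 30000))
  out <- suppressMessages(filter_events(ev, trials))
  expect_equal(nrow(out), 3)
  log <- attr(out, "drop_log")
  expect_equal(unname(log[c("incorrect-trial", "condition")]), c(2L, 1L))
})

test_that("raising the hysteresis threshold never yields more visits", {
  set.seed(21)
  g <- test_geometry()
  for (r in 1:40) {
    n_seg <- sample(3:12, 1)
    segs <- lapply(seq_len(n_seg), function(i) {
      c(if (i %% 2) "left" else "right", sample(30:400, 1))
    })
    s <- series_from_segments(segs, g)
    counts <- vapply(c(50, 100, 200), function(h) {
      nrow(detect_visits(s, g, h))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("hysteresis merging is a fixed point", {
  set.seed(22)
  g <- test_geometry()
  roi <- g$model_grid_roi
  for (r in 1:20) {
    segs <- lapply(1:8, function(i) {
      c(sample(c("left", "right"), 1), sample(30:400, 1))
    })
    s <- series_from_segments(segs, g)
    v <- detect_visits(s, g, 100)
    # rewrite gaze to the detected visit side, re-detect
    gx <- s$gaze_x
    for (i in seq_len(nrow(v))) {
      idx <- s$time >= v$t_enter[i] & s$time < v$t_leave[i]
      gx[idx] <- if (v$side[i] == "left") mean(roi[c(1, 3)]) else
        (g$midline_x + g$screen_width_px) / 2
    }
    s2 <- sample_series("P01", "P01", s$time, gx, s$gaze_y, s$pupil, s$valid)
    v2 <- detect_visits(s2, g, 100)
    expect_equal(v2, v)
  }
})

test_that("noiseless synthetic recordings segment into non-overlapping events within the span", {
  p <- copy_sim_params(n_participants = 1, n_trials_per_condition = 3,
                       pupil_noise_sd = 0, blink_rate_hz = 0,
                       flicker_rate_hz = 0, p_all_correct = 1)
  sim <- simulate_copy_task(p, test_geometry(), seed = 31)
  ev <- segment_sampling_events(sim$samples[[1]], sim$trials,
                                analysis_config(), test_geometry())
  span_ms <- nrow(sim$samples[[1]])
  expect_true(all(diff(ev$t_visit_start) > 0))
  ends <- ev$t_model_onset + ev$dwell_ms + ifelse(is.na(ev$build_ms), 0,
                                                  ev$build_ms)
  expect_true(all(ends[-length(ends)] <= ev$t_visit_start[-1]))
  expect_lte(sum(ev$dwell_ms + ifelse(is.na(ev$build_ms), 0, ev$build_ms)),
             span_ms)
})
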
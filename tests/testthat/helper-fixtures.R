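# Fixture builders used across the suite. All fixtures are generated in
# code; no binary data.

test_geometry <- function() {
  geometry_config(screen_width_px = 1920, screen_height_px = 1080,
                  midline_x = 960, model_grid_roi = c(260, 240, 760, 840),
                  px_per_degree = 40)
}

# Build a sample_series from (side, duration_ms) segments. Gaze sits at
# fixed points well inside each half; pupil is constant unless given.
series_from_segments <- function(segments, g = test_geometry(),
                                 pupil = 2000, pid = "P01",
                                 valid = NULL) {
  side <- rep(vapply(segments, `[[`, "", 1),
              vapply(segments, function(x) as.integer(x[[2]]), 1L))
  n <- length(side)
  roi <- g$model_grid_roi
  gx <- ifelse(side == "left", mean(roi[c(1, 3)]),
               (g$midline_x + g$screen_width_px) / 2)
  gy <- rep(g$screen_height_px / 2, n)
  pup <- if (length(pupil) == 1) rep(pupil, n) else pupil
  v <- if (is.null(valid)) rep(TRUE, n) else valid
  sample_series(pid, pid, seq_len(n) - 1, gx, gy, pup, v)
}

one_trial <- function(pid = "P01", trial = 1, delay = 1500, exp = 1,
                      correct = TRUE, t_start = 0, t_end = 10000) {
  data.frame(participant = pid, trial = trial,
             condition_delay_ms = delay, experiment = exp,
             all_correct = correct, t_start = t_start, t_end = t_end,
             stringsAsFactors = FALSE)
}

# An epoch data frame on a 1-ms grid with the columns the feature
# extractors expect.
make_epoch <- function(t_rel, pupil, valid = TRUE) {
  e <- data.frame(t_rel = t_rel, pupil = pupil,
                  valid = rep_len(valid, length(t_rel)))
  e$usable <- e$valid
  class(e) <- c("pupil_epoch", "data.frame")
  e
}

# Sort-based brute-force median (independent of stats::median).
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

random_event_table <- function(n) {
  data.frame(
    participant_id = sample(sprintf("P%02d", 1:4), n, replace = TRUE),
    trial_id = sample.int(70, n, replace = TRUE),
    event_index = sample.int(3, n, replace = TRUE),
    condition_delay_ms = sample(c(1500, 3000), n, replace = TRUE),
    experiment = sample(1:2, n, replace = TRUE),
    t_visit_start = sample.int(1e6, n),
    t_model_onset = sample.int(1e6, n),
    dwell_ms = round(runif(n, 0, 5000)),
    build_ms = ifelse(runif(n) < 0.1, NA, runif(n, 100, 8000)),
    ended_by = sample(c("gaze-return", "trial-end"), n, replace = TRUE),
    baseline_pupil = rnorm(n, 3000, 300),
    orienting_amplitude = runif(n, 0, 200),
    included_gaze_filter = runif(n) < 0.6,
    stringsAsFactors = FALSE
  )
}
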
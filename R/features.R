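#' Interpolate blinks in a pupil trace
#'
#' Linearly interpolates invalid runs (blinks / track loss) after
#' padding each run by `pad_ms` on both sides, the standard minimal
#' blink treatment for pupillometry. Runs touching either recording
#' edge cannot be interpolated and remain invalid. The original
#' validity mask is preserved in `valid`; samples whose pupil value was
#' filled in are flagged in a new logical column `reconstructed`.
#'
#' @param s A [sample_series()].
#' @param pad_ms Padding (ms) applied to each side of an invalid run
#'   before interpolation.
#' @return The series with interpolated `pupil` and an added
#'   `reconstructed` column.
#' @export
preprocess_pupil <- function(s, pad_ms = 50) {
  validate_sample_series(s)
  if (!any(s$valid))
    stop("sample series has no valid samples to interpolate from",
         call. = FALSE)
  bad <- !s$valid
  if (!any(bad)) {
    s$reconstructed <- FALSE
    return(s)
  }
  step <- sample_step_ms(s)
  pad_n <- ceiling(pad_ms / step)
  n <- nrow(s)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill <- rep(FALSE, n)
  for (i in which(r$values)) {
    a <- max(1L, starts[i] - pad_n)
    b <- min(n, ends[i] + pad_n)
    fill[a:b] <- TRUE
  }
  # runs (after padding) touching an edge stay invalid
  fr <- rle(fill)
  fe <- cumsum(fr$lengths)
  fs <- fe - fr$lengths + 1L
  pupil <- s$pupil
  recon <- rep(FALSE, n)
  for (i in which(fr$values)) {
    a <- fs[i]; b <- fe[i]
    if (a == 1L || b == n) next
    t0 <- s$time[a - 1L]; t1 <- s$time[b + 1L]
    p0 <- pupil[a - 1L]; p1 <- pupil[b + 1L]
    tt <- s$time[a:b]
    pupil[a:b] <- p0 + (p1 - p0) * (tt - t0) / (t1 - t0)
    recon[a:b] <- TRUE
  }
  s$pupil <- pupil
  s$valid <- s$valid & !recon
  s$reconstructed <- recon
  # keep the class invariant: reconstructed samples are usable values
  s$valid[recon] <- FALSE
  class(s) <- c("sample_series", "data.frame")
  s
}

#' Extract a model-onset-locked pupil epoch
#'
#' Cuts the samples around an event's model onset into an epoch with
#' time expressed relative to onset (`t_rel`, ms). The epoch carries
#' the original validity mask and, if present, the `reconstructed`
#' flags from [preprocess_pupil()].
#'
#' @param s A [sample_series()] (ideally preprocessed).
#' @param t_onset Model/stimulus onset time (ms, recording clock).
#' @param range_ms Length-2 relative range to extract; the default
#'   covers the baseline and orienting windows.
#' @return A data frame with columns `t_rel`, `pupil`, `valid`, and
#'   `usable` (valid or reconstructed), of class `pupil_epoch`.
#' @export
extract_epoch <- function(s, t_onset, range_ms = c(-100, 1000)) {
  idx <- s$time >= t_onset + range_ms[1] & s$time <= t_onset + range_ms[2]
  e <- data.frame(t_rel = s$time[idx] - t_onset,
                  pupil = s$pupil[idx],
                  valid = s$valid[idx],
                  stringsAsFactors = FALSE)
  e$usable <- e$valid | (if ("reconstructed" %in% names(s))
    s$reconstructed[idx] else FALSE)
  class(e) <- c("pupil_epoch", "data.frame")
  e
}

window_values <- function(e, window, closed_left = TRUE,
                          closed_right = TRUE) {
  lo <- if (closed_left) e$t_rel >= window[1] else e$t_rel > window[1]
  hi <- if (closed_right) e$t_rel <= window[2] else e$t_rel < window[2]
  e[lo & hi, , drop = FALSE]
}

window_metric <- function(e, window, fun, min_valid_frac,
                          closed_right = TRUE) {
  w <- window_values(e, window, closed_right = closed_right)
  if (nrow(w) == 0) return(NA_real_)
  if (mean(w$valid) < min_valid_frac) return(NA_real_)
  fun(w$pupil[w$usable])
}

#' Baseline pupil size of an epoch
#'
#' The median pupil size over the 100 ms preceding model onset
#' (half-open window, `[-100, 0)` ms by default), an index of tonic
#' arousal at the moment encoding becomes possible. Returns `NA` (the
#' event is flagged rather than guessed) when fewer than
#' `cfg$min_valid_frac` of the window's samples are valid.
#'
#' @param e A `pupil_epoch` from [extract_epoch()].
#' @param cfg An [analysis_config()].
#' @return Median baseline pupil size (a.u.), or `NA`.
#' @export
baseline_size <- function(e, cfg = analysis_config()) {
  window_metric(e, cfg$baseline_window_ms, stats::median,
                cfg$min_valid_frac, closed_right = FALSE)
}

#' Subtractive baseline correction
#'
#' Subtracts the baseline pupil size from the epoch's trace, so the
#' corrected trace is 0 (in median) over the baseline window.
#'
#' @param e A `pupil_epoch`.
#' @param b Baseline value (a.u.); must not be `NA`.
#' @return The epoch with corrected `pupil`.
#' @export
baseline_correct <- function(e, b) {
  if (is.na(b)) stop("baseline is NA; cannot correct", call. = FALSE)
  e$pupil <- e$pupil - b
  e
}

#' Orienting-response amplitude
#'
#' The amplitude of the stimulus-locked pupil orienting constriction:
#' the negated median of the baseline-corrected trace over the
#' orienting window (closed `[500, 1000]` ms by default). Stored as a
#' constriction magnitude — positive when the pupil constricted below
#' baseline — so that a positive regression coefficient reads
#' "stronger orienting, longer build". Use `signed = TRUE` for the raw
#' signed median.
#'
#' @param e A baseline-corrected `pupil_epoch`.
#' @param cfg An [analysis_config()].
#' @param signed Return the signed window median instead of the
#'   negated magnitude.
#' @return Orienting amplitude (a.u.), or `NA` if the window has too
#'   few valid samples.
#' @export
orienting_amplitude <- function(e, cfg = analysis_config(),
                                signed = FALSE) {
  m <- window_metric(e, cfg$orienting_window_ms, stats::median,
                     cfg$min_valid_frac)
  if (signed) m else -m
}

#' Control orienting metric
#'
#' A constriction-depth measure insensitive to the small early
#' dilation sometimes visible right after onset: the maximum of the
#' corrected trace over the early window (`[0, 300]` ms) minus the
#' minimum over the orienting window (`[500, 1000]` ms). Positive when
#' the pupil falls.
#'
#' @inheritParams orienting_amplitude
#' @return Control metric (a.u.), or `NA`.
#' @export
orienting_control <- function(e, cfg = analysis_config()) {
  early <- window_metric(e, cfg$control_window_ms, max, cfg$min_valid_frac)
  late <- window_metric(e, cfg$orienting_window_ms, min, cfg$min_valid_frac)
  early - late
}

#' Gaze-deviation inclusion filter
#'
#' Pupil size estimates are biased by gaze angle, so only events during
#' which gaze stayed on the model grid — within
#' `cfg$inclusion_margin_deg` of it — for `cfg$inclusion_window_ms`
#' after model onset are retained. Under the default `"continuous"`
#' interpretation every valid sample in the window must lie within the
#' expanded grid rectangle (closed boundary); under `"cumulative"`, at
#' least `inclusion_window_ms` worth of in-grid samples suffice.
#'
#' @param s A [sample_series()].
#' @param event One-row event (needs `t_model_onset`).
#' @param g A [geometry_config()].
#' @param cfg An [analysis_config()].
#' @return `TRUE` if the event passes the filter.
#' @export
gaze_inclusion <- function(s, event, g = geometry_config(),
                           cfg = analysis_config()) {
  margin <- cfg$inclusion_margin_deg * g$px_per_degree
  r <- g$model_grid_roi + c(-margin, -margin, margin, margin)
  t0 <- event$t_model_onset
  if (cfg$inclusion_mode == "continuous") {
    # half-open window: gaze on the grid over [0, window) ms satisfies
    # "at least window ms after onset"
    idx <- s$time >= t0 & s$time < t0 + cfg$inclusion_window_ms & s$valid
    if (!any(idx)) return(FALSE)
    all(s$gaze_x[idx] >= r[1] & s$gaze_x[idx] <= r[3] &
          s$gaze_y[idx] >= r[2] & s$gaze_y[idx] <= r[4])
  } else {
    # cumulative: total on-grid time anywhere after onset
    idx <- s$time >= t0 & s$valid
    if (!any(idx)) return(FALSE)
    inside <- s$gaze_x[idx] >= r[1] & s$gaze_x[idx] <= r[3] &
      s$gaze_y[idx] >= r[2] & s$gaze_y[idx] <= r[4]
    sum(inside) * sample_step_ms(s) >= cfg$inclusion_window_ms
  }
}

#' Robust z-scores (median / MAD) per participant
#'
#' Standardizes a variable within each participant by subtracting the
#' participant's median and dividing by the unscaled median absolute
#' deviation (no 1.4826 consistency factor). Used for visualization of
#' trial-level relationships; models are fit on raw scales.
#'
#' @param values Numeric vector.
#' @param participant Vector of participant labels, same length.
#' @return Numeric vector of robust z-scores (median 0, MAD 1 within
#'   each participant).
#' @export
robust_z <- function(values, participant) {
  stopifnot(length(values) == length(participant))
  out <- rep(NA_real_, length(values))
  for (p in unique(participant)) {
    i <- which(participant == p)
    v <- values[i]
    ctr <- stats::median(v, na.rm = TRUE)
    sc <- stats::median(abs(v - ctr), na.rm = TRUE)
    if (!is.finite(sc) || sc == 0)
      stop("MAD is zero for participant ", p,
           "; robust z-scores undefined", call. = FALSE)
    out[i] <- (v - ctr) / sc
  }
  out
}

#' Add pupil features to an event table
#'
#' Runs blink interpolation, epochs each event around its model onset,
#' and adds `baseline_pupil`, `orienting_amplitude`,
#' `orienting_control`, and `included_gaze_filter` columns.
#'
#' @param s A [sample_series()] for one participant.
#' @param events Event rows of that participant (from
#'   [segment_sampling_events()]).
#' @param cfg An [analysis_config()].
#' @param g A [geometry_config()].
#' @return `events` with the four feature columns appended.
#' @export
add_pupil_features <- function(events, s, cfg = analysis_config(),
                               g = geometry_config()) {
  if (nrow(events) == 0) {
    events$baseline_pupil <- numeric(0)
    events$orienting_amplitude <- numeric(0)
    events$orienting_control <- numeric(0)
    events$included_gaze_filter <- logical(0)
    return(events)
  }
  sp <- preprocess_pupil(s, cfg$pad_ms)
  range_ms <- c(cfg$baseline_window_ms[1],
                max(cfg$orienting_window_ms[2], cfg$inclusion_window_ms))
  base <- orient <- ctrl <- rep(NA_real_, nrow(events))
  incl <- rep(NA, nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- extract_epoch(sp, events$t_model_onset[i], range_ms)
    b <- baseline_size(e, cfg)
    base[i] <- b
    if (!is.na(b)) {
      ec <- baseline_correct(e, b)
      orient[i] <- orienting_amplitude(ec, cfg)
      ctrl[i] <- orienting_control(ec, cfg)
    }
    incl[i] <- gaze_inclusion(sp, events[i, ], g, cfg)
  }
  events$baseline_pupil <- base
  events$orienting_amplitude <- orient
  events$orienting_control <- ctrl
  events$included_gaze_filter <- incl
  events
}
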
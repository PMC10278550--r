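#' Detect left/right screen visits with hysteresis
#'
#' Classifies every sample as left or right of the display midline and
#' groups samples into alternating visits. An excursion to the
#' opposite half shorter than `hysteresis_ms` does not end the current
#' visit: a visit only ends at the start of the first opposite-half
#' period lasting at least `hysteresis_ms`. Invalid samples (blinks,
#' track loss) inherit the current side so a blink can never split a
#' visit. Intervals are half-open `[t_enter, t_leave)` in ms; a sample
#' exactly on the midline counts as right.
#'
#' @param s A [sample_series()].
#' @param g A [geometry_config()].
#' @param hysteresis_ms Minimum sustained opposite-half duration (ms).
#' @return A data frame with columns `side` (`"left"`/`"right"`),
#'   `t_enter`, `t_leave`, covering the recording.
#' @export
detect_visits <- function(s, g, hysteresis_ms = 100) {
  validate_sample_series(s)
  if (hysteresis_ms <= 0) stop("hysteresis_ms must be > 0", call. = FALSE)
  side <- ifelse(s$gaze_x < g$midline_x, "left", "right")
  side[!s$valid | is.na(side)] <- NA
  if (all(is.na(side)))
    stop("no valid samples to classify", call. = FALSE)
  # invalid samples inherit the last valid side (leading ones the first)
  side <- fill_forward(side)
  side <- rev(fill_forward(rev(side)))

  r <- rle(side)
  n_runs <- length(r$lengths)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  step <- sample_step_ms(s)
  run_start <- s$time[starts_idx]
  run_leave <- c(s$time[starts_idx[-1]], s$time[nrow(s)] + step)
  run_dur <- run_leave - run_start

  cur_side <- r$values[1]
  cur_start <- run_start[1]
  out_side <- character(0)
  out_enter <- numeric(0)
  if (n_runs > 1) {
    for (i in 2:n_runs) {
      if (r$values[i] != cur_side && run_dur[i] >= hysteresis_ms) {
        out_side <- c(out_side, cur_side)
        out_enter <- c(out_enter, cur_start)
        cur_side <- r$values[i]
        cur_start <- run_start[i]
      }
    }
  }
  out_side <- c(out_side, cur_side)
  out_enter <- c(out_enter, cur_start)
  data.frame(side = out_side,
             t_enter = out_enter,
             t_leave = c(out_enter[-1], run_leave[n_runs]),
             stringsAsFactors = FALSE)
}

fill_forward <- function(x) {
  ok <- !is.na(x)
  idx <- cumsum(ok)
  pos <- which(ok)[pmax(idx, 1)]
  out <- x[pos]
  out[idx == 0] <- NA
  out
}

#' Segment a recording into sampling events
#'
#' Implements the sampling-event definition of the copy task: a
#' sampling event occurs whenever the participant's gaze enters the
#' left (model) half of the display and stays there for the trial's
#' entire delay duration, at which point the model is presented. Left
#' visits shorter than the delay are aborted samples and produce no
#' event (the delay timer does not carry over). For each event, dwell
#' time runs from the dwell reference point (model onset by default)
#' until the first right-half period sustained for the hysteresis
#' duration, and build duration runs from dwell end until the first
#' sustained left return or the trial end.
#'
#' @param s A [sample_series()].
#' @param trials Trial table for this participant (see
#'   [read_trials()]); rows for other participants are ignored.
#' @param cfg An [analysis_config()].
#' @param g A [geometry_config()].
#' @return A data frame of sampling events ordered by `t_visit_start`,
#'   with columns `participant_id`, `trial_id`, `event_index`,
#'   `condition_delay_ms`, `experiment`, `t_visit_start`,
#'   `t_model_onset`, `dwell_ms`, `build_ms` (`NA` when gaze never
#'   reached the right half before trial end), and `ended_by`.
#' @export
segment_sampling_events <- function(s, trials, cfg = analysis_config(),
                                    g = geometry_config()) {
  validate_sample_series(s)
  pid <- attr(s, "participant_id")
  tr <- trials[trials$participant == pid, , drop = FALSE]
  if (nrow(tr) == 0)
    stop("no trials for participant ", pid, call. = FALSE)
  visits <- detect_visits(s, g, cfg$hysteresis_ms)
  out <- list()
  for (i in seq_len(nrow(tr))) {
    trial <- tr[i, ]
    v <- clip_visits(visits, trial$t_start, trial$t_end)
    if (nrow(v) == 0) {
      warning("trial ", trial$trial, " of participant ", pid,
              " has no samples; no events", call. = FALSE)
      next
    }
    left <- which(v$side == "left" &
                    (v$t_leave - v$t_enter) >= trial$condition_delay_ms)
    ev_i <- 0L
    for (j in left) {
      ev_i <- ev_i + 1L
      t_visit <- v$t_enter[j]
      t_model <- t_visit + trial$condition_delay_ms
      dwell_end <- v$t_leave[j]   # start of first sustained right period
      ref <- if (cfg$dwell_reference == "model_onset") t_model else t_visit
      dwell <- dwell_end - ref
      nxt_left <- which(v$side == "left" & v$t_enter > v$t_enter[j])
      if (dwell_end >= trial$t_end || j == nrow(v)) {
        build <- NA_real_
        ended <- "trial-end"
      } else if (length(nxt_left)) {
        build <- v$t_enter[nxt_left[1]] - dwell_end
        ended <- "gaze-return"
      } else {
        build <- trial$t_end - dwell_end
        ended <- "trial-end"
      }
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid,
        trial_id = trial$trial,
        event_index = ev_i,
        condition_delay_ms = trial$condition_delay_ms,
        experiment = trial$experiment,
        t_visit_start = t_visit,
        t_model_onset = t_model,
        dwell_ms = dwell,
        build_ms = build,
        ended_by = ended,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(participant_id = character(0), trial_id = numeric(0),
                      event_index = integer(0),
                      condition_delay_ms = numeric(0),
                      experiment = numeric(0), t_visit_start = numeric(0),
                      t_model_onset = numeric(0), dwell_ms = numeric(0),
                      build_ms = numeric(0), ended_by = character(0),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$t_visit_start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

clip_visits <- function(visits, t0, t1) {
  v <- visits[visits$t_leave > t0 & visits$t_enter < t1, , drop = FALSE]
  if (nrow(v)) {
    v$t_enter <- pmax(v$t_enter, t0)
    v$t_leave <- pmin(v$t_leave, t1)
  }
  v
}

#' Dwell time of a sampling event
#'
#' Time from the dwell reference point (model onset by default, visit
#' start if configured) until the start of the first right-half period
#' sustained for at least the hysteresis duration, truncated at trial
#' end.
#'
#' @param event A one-row data frame (or list) with `t_visit_start`
#'   and `t_model_onset`.
#' @param visits Visit table from [detect_visits()].
#' @param cfg An [analysis_config()].
#' @param trial Optional one-row trial record used to truncate at
#'   `t_end`.
#' @return Dwell duration in ms (>= 0).
#' @export
compute_dwell <- function(event, visits, cfg = analysis_config(),
                          trial = NULL) {
  j <- which(visits$side == "left" &
               visits$t_enter <= event$t_visit_start &
               visits$t_leave > event$t_visit_start)
  if (!length(j))
    stop("event's visit not found in visit table", call. = FALSE)
  dwell_end <- visits$t_leave[j[1]]
  if (!is.null(trial)) dwell_end <- min(dwell_end, trial$t_end)
  ref <- if (cfg$dwell_reference == "model_onset") event$t_model_onset
         else event$t_visit_start
  max(dwell_end - ref, 0)
}

#' Build duration of a sampling event
#'
#' Time the gaze remains on the right (response) half after dwell
#' ends, until the first left-half period sustained for the hysteresis
#' duration, or until the trial ends. Returns `NA` build when gaze
#' never reached the right half before trial end.
#'
#' @inheritParams compute_dwell
#' @param trial One-row trial record (required; supplies `t_end`).
#' @return A list with `build_ms` and `ended_by`
#'   (`"gaze-return"`/`"trial-end"`).
#' @export
compute_build <- function(event, visits, trial, cfg = analysis_config()) {
  j <- which(visits$side == "left" &
               visits$t_enter <= event$t_visit_start &
               visits$t_leave > event$t_visit_start)
  if (!length(j))
    stop("event's visit not found in visit table", call. = FALSE)
  dwell_end <- visits$t_leave[j[1]]
  if (dwell_end >= trial$t_end)
    return(list(build_ms = NA_real_, ended_by = "trial-end"))
  nxt <- which(visits$side == "left" & visits$t_enter > dwell_end &
                 visits$t_enter < trial$t_end)
  if (length(nxt)) {
    list(build_ms = visits$t_enter[nxt[1]] - dwell_end,
         ended_by = "gaze-return")
  } else {
    list(build_ms = trial$t_end - dwell_end, ended_by = "trial-end")
  }
}

#' Filter sampling events by trial-level criteria
#'
#' Drops events from trials that were not fully correct (only trials
#' in which all items were placed correctly enter the analysis), from
#' delay conditions outside the included set (by default the 200-ms
#' condition is dropped), and optionally events failing the
#' gaze-deviation inclusion filter. The counts of each drop reason are
#' attached as attribute `"drop_log"` and reported via `message()`.
#'
#' @param events Event table (from [segment_sampling_events()],
#'   possibly feature-augmented).
#' @param trials Trial table supplying `all_correct` per trial.
#' @param cfg An [analysis_config()].
#' @param drop_gaze_excluded Also drop events whose
#'   `included_gaze_filter` column is `FALSE` (if present).
#' @return The retained events, with a `drop_log` attribute (named
#'   integer vector: `incorrect-trial`, `condition`, `gaze-filter`).
#' @export
filter_events <- function(events, trials, cfg = analysis_config(),
                          drop_gaze_excluded = TRUE) {
  if (nrow(events) == 0) return(events)
  key <- paste(events$participant_id, events$trial_id)
  tkey <- paste(trials$participant, trials$trial)
  correct <- trials$all_correct[match(key, tkey)]
  correct[is.na(correct)] <- FALSE
  keep <- rep(TRUE, nrow(events))
  log <- c("incorrect-trial" = 0L, "condition" = 0L, "gaze-filter" = 0L)

  drop <- keep & !correct
  log["incorrect-trial"] <- sum(drop)
  keep <- keep & !drop

  drop <- keep & !(events$condition_delay_ms %in% cfg$included_conditions_ms)
  log["condition"] <- sum(drop)
  keep <- keep & !drop

  if (drop_gaze_excluded && "included_gaze_filter" %in% names(events)) {
    drop <- keep & !events$included_gaze_filter
    log["gaze-filter"] <- sum(drop)
    keep <- keep & !drop
  }
  message(sprintf(
    "filter_events: retained %d/%d (dropped: incorrect-trial %d, condition %d, gaze-filter %d)",
    sum(keep), length(keep), log["incorrect-trial"], log["condition"],
    log["gaze-filter"]))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- log
  out
}
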
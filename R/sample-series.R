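#' Construct a gaze/pupil sample series
#'
#' A `sample_series` is a uniformly sampled (nominally 1-ms step)
#' recording of gaze position and pupil size from one eye, with a
#' validity mask marking blinks and track loss. It is stored as a
#' data frame with columns `time` (ms, strictly increasing), `gaze_x`,
#' `gaze_y` (screen pixels), `pupil` (arbitrary recorder units), and
#' `valid` (logical), plus `participant_id` / `recording_id`
#' attributes.
#'
#' @param participant_id,recording_id Opaque labels.
#' @param time Integer-valued sample times in ms, strictly increasing.
#' @param gaze_x,gaze_y Gaze position in screen pixels.
#' @param pupil Pupil size in arbitrary recorder units; must be > 0
#'   wherever `valid` is `TRUE` (EyeLink emits 0 during blinks).
#' @param valid Logical mask; defaults to `pupil > 0`.
#'
#' @return A data frame of class `sample_series`.
#' @export
sample_series <- function(participant_id, recording_id = participant_id,
                          time, gaze_x, gaze_y, pupil,
                          valid = pupil > 0) {
  s <- data.frame(time = as.numeric(time),
                  gaze_x = as.numeric(gaze_x),
                  gaze_y = as.numeric(gaze_y),
                  pupil = as.numeric(pupil),
                  valid = as.logical(valid))
  attr(s, "participant_id") <- as.character(participant_id)
  attr(s, "recording_id") <- as.character(recording_id)
  class(s) <- c("sample_series", "data.frame")
  validate_sample_series(s)
}

#' Validate a sample series
#'
#' Checks the `sample_series` invariants: equal column lengths, strictly
#' increasing time, and strictly positive pupil wherever the validity
#' mask is `TRUE`.
#'
#' @param s A `sample_series`.
#' @return `s`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_sample_series <- function(s) {
  stopifnot(is.data.frame(s))
  need <- c("time", "gaze_x", "gaze_y", "pupil", "valid")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(s) == 0)
    stop("sample series is empty", call. = FALSE)
  if (any(diff(s$time) <= 0))
    stop("sample series time must be strictly increasing", call. = FALSE)
  if (any(s$valid & !(s$pupil > 0)))
    stop("pupil must be > 0 wherever valid is TRUE", call. = FALSE)
  s
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> participant %s, recording %s: %d samples, %s-%s ms, %.1f%% valid\n",
              attr(x, "participant_id"), attr(x, "recording_id"), nrow(x),
              format(x$time[1]), format(x$time[nrow(x)]),
              100 * mean(x$valid)))
  invisible(x)
}

sample_step_ms <- function(s) {
  if (nrow(s) < 2) return(1)
  stats::median(diff(s$time))
}
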
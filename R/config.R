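#' Screen geometry configuration
#'
#' Describes the display the gaze coordinates refer to: its pixel
#' dimensions, the vertical midline separating the model (left) half
#' from the response (right) half, the rectangle occupied by the model
#' grid, and the pixel size of one degree of visual angle. Coordinates
#' follow the EyeLink convention: origin at the top-left corner, x
#' increasing rightward, units in screen pixels.
#'
#' @param screen_width_px,screen_height_px Display size in pixels.
#' @param midline_x Pixel x-coordinate of the left/right boundary.
#'   Samples with `gaze_x < midline_x` are on the left (model) half;
#'   a sample exactly at the midline counts as right (half-open
#'   convention).
#' @param model_grid_roi Numeric length-4 vector `c(x0, y0, x1, y1)`
#'   giving the model-grid rectangle in pixels, contained in the screen.
#' @param px_per_degree Pixels per degree of visual angle (> 0), used to
#'   convert the gaze-deviation inclusion margin from degrees to pixels.
#'
#' @return An object of class `geometry_config` (a named list).
#' @examples
#' g <- geometry_config()
#' g$midline_x
#' @export
geometry_config <- function(screen_width_px = 1920,
                            screen_height_px = 1080,
                            midline_x = screen_width_px / 2,
                            model_grid_roi = c(260, 240, 760, 840),
                            px_per_degree = 40) {
  g <- list(
    screen_width_px = as.numeric(screen_width_px),
    screen_height_px = as.numeric(screen_height_px),
    midline_x = as.numeric(midline_x),
    model_grid_roi = as.numeric(model_grid_roi),
    px_per_degree = as.numeric(px_per_degree)
  )
  if (!(g$midline_x > 0 && g$midline_x < g$screen_width_px))
    stop("midline_x must lie strictly inside the screen width", call. = FALSE)
  if (g$px_per_degree <= 0)
    stop("px_per_degree must be > 0", call. = FALSE)
  r <- g$model_grid_roi
  if (length(r) != 4 || r[1] >= r[3] || r[2] >= r[4])
    stop("model_grid_roi must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1",
         call. = FALSE)
  if (r[1] < 0 || r[2] < 0 || r[3] > g$screen_width_px ||
      r[4] > g$screen_height_px)
    stop("model_grid_roi must lie within the screen", call. = FALSE)
  structure(g, class = "geometry_config")
}

#' Analysis configuration
#'
#' Holds every fixed constant of the analysis: the hysteresis duration
#' for gaze-side changes, the baseline and orienting windows relative
#' to model onset, the gaze-deviation inclusion filter, the delay
#' condition vocabulary, the significance threshold, the time-course
#' bin width, and the precision-group bin edges.
#'
#' Window conventions (fixed so that results are bit-reproducible at
#' 1000 Hz): the baseline window is half-open `[-100, 0)` ms and the
#' orienting window closed `[500, 1000]` ms relative to model onset.
#'
#' @param hysteresis_ms Minimum duration (ms, > 0) an excursion to the
#'   opposite screen half must last to end the current visit.
#' @param baseline_window_ms Length-2 window (ms, half-open) for the
#'   baseline pupil-size median.
#' @param orienting_window_ms Length-2 window (ms, closed) for the
#'   orienting-response median.
#' @param control_window_ms Length-2 early window (ms, closed) whose
#'   maximum enters the control orienting metric.
#' @param inclusion_window_ms Duration (ms) after model onset over which
#'   gaze must stay near the model grid for the event to pass the
#'   gaze-deviation filter.
#' @param inclusion_margin_deg Allowed deviation from the model grid, in
#'   degrees of visual angle.
#' @param delay_conditions_ms Closed vocabulary of imposed sampling
#'   delays (ms).
#' @param included_conditions_ms Delay conditions retained for analysis
#'   (the short 200-ms condition is dropped by default: its dwell times
#'   are too short for reliable pupil estimates).
#' @param t_threshold Significance threshold on |t| (normal
#'   approximation; 1.96 corresponds to alpha = 0.05).
#' @param timecourse_bin_ms Bin width (ms) for time-resolved models.
#' @param precision_bin_edges_deg Ascending error cut points (degrees)
#'   separating precise / intermediate / imprecise report groups.
#' @param dwell_reference Where dwell time starts: `"model_onset"`
#'   (default; encoding-relevant viewing) or `"visit_start"`.
#' @param pad_ms Padding (ms) added to each side of an invalid run
#'   before blink interpolation.
#' @param min_valid_frac Minimum fraction of originally valid samples a
#'   window must contain for its median/extremum to be computed.
#' @param inclusion_mode `"continuous"` (default): gaze must remain
#'   within the expanded grid for the whole inclusion window;
#'   `"cumulative"`: at least `inclusion_window_ms` of in-grid samples.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(hysteresis_ms = 100,
                            baseline_window_ms = c(-100, 0),
                            orienting_window_ms = c(500, 1000),
                            control_window_ms = c(0, 300),
                            inclusion_window_ms = 1000,
                            inclusion_margin_deg = 2.0,
                            delay_conditions_ms = c(200, 1500, 3000),
                            included_conditions_ms = c(1500, 3000),
                            t_threshold = 1.96,
                            timecourse_bin_ms = 10,
                            precision_bin_edges_deg = c(15, 30),
                            dwell_reference = c("model_onset", "visit_start"),
                            pad_ms = 50,
                            min_valid_frac = 0.5,
                            inclusion_mode = c("continuous", "cumulative")) {
  cfg <- list(
    hysteresis_ms = as.numeric(hysteresis_ms),
    baseline_window_ms = as.numeric(baseline_window_ms),
    orienting_window_ms = as.numeric(orienting_window_ms),
    control_window_ms = as.numeric(control_window_ms),
    inclusion_window_ms = as.numeric(inclusion_window_ms),
    inclusion_margin_deg = as.numeric(inclusion_margin_deg),
    delay_conditions_ms = as.numeric(delay_conditions_ms),
    included_conditions_ms = as.numeric(included_conditions_ms),
    t_threshold = as.numeric(t_threshold),
    timecourse_bin_ms = as.numeric(timecourse_bin_ms),
    precision_bin_edges_deg = as.numeric(precision_bin_edges_deg),
    dwell_reference = match.arg(dwell_reference),
    pad_ms = as.numeric(pad_ms),
    min_valid_frac = as.numeric(min_valid_frac),
    inclusion_mode = match.arg(inclusion_mode)
  )
  if (cfg$hysteresis_ms <= 0)
    stop("hysteresis_ms must be > 0", call. = FALSE)
  for (w in c("baseline_window_ms", "orienting_window_ms",
              "control_window_ms")) {
    if (length(cfg[[w]]) != 2 || cfg[[w]][1] >= cfg[[w]][2])
      stop(w, " must be a non-empty c(lo, hi) interval", call. = FALSE)
  }
  if (!all(cfg$included_conditions_ms %in% cfg$delay_conditions_ms))
    stop("included_conditions_ms must be a subset of delay_conditions_ms",
         call. = FALSE)
  if (is.unsorted(cfg$precision_bin_edges_deg, strictly = TRUE))
    stop("precision_bin_edges_deg must be strictly ascending", call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Read a run configuration file
#'
#' Loads a YAML file with optional top-level keys `geometry`,
#' `analysis`, and `simulation`, each mapping 1:1 onto the arguments of
#' [geometry_config()], [analysis_config()], and [copy_sim_params()].
#' Missing keys fall back to the defaults of those constructors.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `geometry`, `analysis`, and `simulation`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) raw <- list()
  unlist_windows <- function(x) {
    lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  }
  geometry <- do.call(geometry_config,
                      unlist_windows(raw$geometry %||% list()))
  analysis <- do.call(analysis_config,
                      unlist_windows(raw$analysis %||% list()))
  simulation <- do.call(copy_sim_params,
                        unlist_windows(raw$simulation %||% list()))
  list(geometry = geometry, analysis = analysis, simulation = simulation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
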
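#' Read a gaze/pupil sample stream
#'
#' Two dialects are supported. The plain-table dialect (the package's
#' canonical interchange format) is a TSV/CSV with header columns
#' `time_ms`, `gaze_x`, `gaze_y`, `pupil`, and optionally `valid`; when
#' `valid` is absent it is derived as `pupil > 0` (EyeLink emits a
#' pupil size of 0 during blinks). The `eyelink-asc-subset` dialect
#' reads a minimal subset of EyeLink ASC exports: numeric sample lines
#' (`<time> <x> <y> <pupil>`, with `.` for missing values) and
#' `SBLINK`/`EBLINK` marker pairs; all samples within a blink interval
#' (inclusive) are marked invalid. It is not a full ASC parser.
#'
#' @param path Path to the file.
#' @param dialect `"plain-table"` (default) or `"eyelink-asc-subset"`.
#' @param participant_id,recording_id Labels attached to the series;
#'   default to the file name without extension.
#' @return A [sample_series()].
#' @export
read_samples <- function(path, dialect = c("plain-table", "eyelink-asc-subset"),
                         participant_id = NULL, recording_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("sample file not found: ", path, call. = FALSE)
  id <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  rid <- recording_id %||% id
  if (dialect == "plain-table") {
    d <- read_delim_auto(path)
    need <- c("time_ms", "gaze_x", "gaze_y", "pupil")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    num <- function(col) suppressWarnings(as.numeric(d[[col]]))
    tm <- num("time_ms")
    bad <- which(!is.finite(tm) | !is.finite(num("pupil")))
    if (length(bad))
      stop("malformed sample row at line ", bad[1] + 1L,
           " of ", path, call. = FALSE)
    if (any(diff(tm) <= 0))
      stop("non-increasing time in ", path, call. = FALSE)
    pupil <- num("pupil")
    valid <- if ("valid" %in% names(d)) {
      as.logical(d$valid) & pupil > 0
    } else {
      pupil > 0
    }
    sample_series(id, rid, tm, num("gaze_x"), num("gaze_y"), pupil, valid)
  } else {
    read_asc_subset(path, id, rid)
  }
}

read_asc_subset <- function(path, id, rid) {
  lines <- readLines(path, warn = FALSE)
  first <- sub("\\s.*$", "", trimws(lines))
  is_sample <- grepl("^[0-9]+$", first)
  blink <- list()
  for (i in which(first == "EBLINK")) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 4)
      stop("malformed EBLINK at line ", i, " of ", path, call. = FALSE)
    blink[[length(blink) + 1L]] <- as.numeric(f[3:4])
  }
  rows <- lines[is_sample]
  if (!length(rows))
    stop("no sample lines found in ", path, call. = FALSE)
  num <- function(v) suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  fields <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4)) {
    bad <- which(is_sample)[which(nf < 4)[1]]
    stop("malformed sample line at line ", bad, " of ", path, call. = FALSE)
  }
  m <- t(vapply(fields, function(f) num(f[1:4]), numeric(4)))
  time <- m[, 1]
  if (any(diff(time) <= 0))
    stop("non-increasing time in ", path, call. = FALSE)
  pupil <- m[, 4]
  pupil[is.na(pupil)] <- 0
  valid <- pupil > 0
  for (b in blink) valid[time >= b[1] & time <= b[2]] <- FALSE
  sample_series(id, rid, time, m[, 2], m[, 3], pupil, valid)
}

#' Read a trial table
#'
#' Expects columns `participant`, `trial`, `condition_delay_ms`,
#' `experiment`, `all_correct`, `t_start`, `t_end`. Records are sorted
#' by `(participant, t_start)`; delays are validated against the
#' configured closed vocabulary, and overlapping trials within a
#' participant are rejected.
#'
#' @param path Path to a TSV/CSV trial table.
#' @param cfg An [analysis_config()] supplying `delay_conditions_ms`.
#' @return A data frame of trial records.
#' @export
read_trials <- function(path, cfg = analysis_config()) {
  if (!file.exists(path))
    stop("trial file not found: ", path, call. = FALSE)
  d <- read_delim_auto(path)
  validate_trials(d, cfg)
}

#' Validate a trial table
#'
#' @param trials A data frame of trial records (see [read_trials()]).
#' @param cfg An [analysis_config()].
#' @return The sorted, validated trial table.
#' @export
validate_trials <- function(trials, cfg = analysis_config()) {
  need <- c("participant", "trial", "condition_delay_ms", "experiment",
            "all_correct", "t_start", "t_end")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trials$all_correct <- as.logical(trials$all_correct)
  bad <- setdiff(unique(trials$condition_delay_ms), cfg$delay_conditions_ms)
  if (length(bad))
    stop("unknown delay condition(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(cfg$delay_conditions_ms, collapse = ", "), ")",
         call. = FALSE)
  if (any(trials$t_start >= trials$t_end))
    stop("trial t_start must be < t_end", call. = FALSE)
  trials <- trials[order(trials$participant, trials$t_start), , drop = FALSE]
  rownames(trials) <- NULL
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, , drop = FALSE]
    if (nrow(tp) > 1 && any(tp$t_start[-1] < tp$t_end[-nrow(tp)]))
      stop("overlapping trials for participant ", p, call. = FALSE)
  }
  trials
}

#' Write / read a sampling-event table
#'
#' Events are serialized as TSV, one row per sampling event. Real
#' values are printed with 17 significant digits so a write/read
#' round-trip reproduces every field exactly.
#'
#' @param events A data frame of sampling events.
#' @param path Output (or input) path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  out <- events
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- out[[j]]
      out[[j]] <- ifelse(is.na(v), NA,
                         ifelse(v == round(v) & abs(v) < 2^53,
                                sprintf("%.0f", v),
                                sprintf("%.17g", v)))
    }
  }
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write events to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path))
    stop("event file not found: ", path, call. = FALSE)
  d <- read_delim_auto(path)
  for (col in c("included_gaze_filter", "all_correct"))
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  d
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}
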
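#' Fitted mixed-model summary
#'
#' Light-weight container for a fitted linear mixed-effects model:
#' the formula, the fixed-effect coefficient table (estimate, SE, t),
#' per-term significance flags via the |t| > threshold rule (normal
#' approximation, no df correction), AIC, sizes, and convergence
#' status.
#'
#' @param fit A fitted `lmerMod` (or `lm` for degenerate fallbacks).
#' @param t_threshold Significance threshold on |t|.
#' @return An object of class `fit_result`.
#' @keywords internal
fit_result <- function(fit, t_threshold = 1.96) {
  if (inherits(fit, "lmerMod")) {
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    n_groups <- lme4::ngrps(fit)[1]
    msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(msgs) || !length(msgs)
    singular <- lme4::isSingular(fit, tol = 1e-4)
    form <- deparse1(stats::formula(fit))
  } else {
    sm <- summary(fit)$coefficients
    co <- sm[, 1]
    se <- sm[, 2]
    n_groups <- NA_integer_
    converged <- TRUE
    singular <- FALSE
    form <- deparse1(stats::formula(fit))
  }
  tval <- ifelse(se > 0, co / se, ifelse(co == 0, 0, sign(co) * Inf))
  coefs <- data.frame(term = names(co), beta = as.numeric(co),
                      se = as.numeric(se), t = as.numeric(tval),
                      significant = abs(tval) > t_threshold,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(formula = form,
                 coefficients = coefs,
                 significant = stats::setNames(coefs$significant, coefs$term),
                 aic = tryCatch(stats::AIC(fit), error = function(e) NA_real_),
                 n_obs = stats::nobs(fit),
                 n_groups = as.integer(n_groups),
                 n_par = attr(stats::logLik(fit), "df"),
                 converged = converged,
                 singular = singular,
                 t_threshold = t_threshold),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$formula, "\n", sep = "")
  cat(sprintf("n_obs = %d, n_groups = %s, AIC = %.1f, converged = %s%s\n",
              x$n_obs, x$n_groups, x$aic, x$converged,
              if (isTRUE(x$singular)) " (singular)" else ""))
  co <- x$coefficients
  co$beta <- signif(co$beta, 4)
  co$se <- signif(co$se, 4)
  co$t <- round(co$t, 2)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Coefficient of a fitted model
#'
#' @param x A `fit_result`.
#' @param term Term name (as in the coefficient table).
#' @return One-row data frame with `beta`, `se`, `t`, `significant`.
#' @export
coef_term <- function(x, term) {
  co <- x$coefficients
  i <- match(term, co$term)
  if (is.na(i)) stop("no term '", term, "' in fit (have: ",
                     paste(co$term, collapse = ", "), ")", call. = FALSE)
  co[i, c("beta", "se", "t", "significant")]
}

lmer_ctrl <- function() {
  lme4::lmerControl(check.scaleX = "ignore",
                    check.conv.singular = lme4::.makeCC(action = "ignore",
                                                        tol = 1e-4),
                    calc.derivs = FALSE)
}

prepare_event_model_frame <- function(events, cfg) {
  d <- events
  d$condition <- factor(ifelse(d$condition_delay_ms == 1500, "medium",
                               ifelse(d$condition_delay_ms == 3000, "long",
                                      "short")),
                        levels = c("medium", "long", "short"))
  d$condition <- droplevels(d$condition)
  d$experiment <- factor(paste0("exp", d$experiment))
  d$dwell_s <- d$dwell_ms / 1000
  d$build_s <- d$build_ms / 1000
  d
}

check_outcome <- function(y, what) {
  y <- y[!is.na(y)]
  if (length(y) < 3 || stats::sd(y) == 0)
    stop("degenerate fit: outcome '", what,
         "' is constant or nearly empty", call. = FALSE)
}

#' Condition contrasts for an ocular outcome
#'
#' Fits `outcome ~ condition + experiment + (1 + condition |
#' participant)`, the model used to compare the medium and long delay
#' conditions on dwell time, build duration, baseline pupil size, or
#' orienting amplitude. The medium (1500 ms) condition is the
#' reference level; durations enter in seconds, pupil metrics in
#' recorder units.
#'
#' @param events Feature-augmented event table.
#' @param outcome One of `"dwell"`, `"build"`, `"baseline"`,
#'   `"orienting"`.
#' @param cfg An [analysis_config()] (supplies `t_threshold`).
#' @param REML Use REML (default) or ML estimation.
#' @return A `fit_result`.
#' @export
fit_condition_model <- function(events, outcome = c("dwell", "build",
                                                    "baseline", "orienting"),
                                cfg = analysis_config(), REML = TRUE) {
  outcome <- match.arg(outcome)
  d <- prepare_event_model_frame(events, cfg)
  d$.y <- switch(outcome,
                 dwell = d$dwell_s,
                 build = d$build_s,
                 baseline = d$baseline_pupil,
                 orienting = d$orienting_amplitude)
  d <- d[!is.na(d$.y), , drop = FALSE]
  if (length(unique(d$participant_id)) < 2)
    stop("need >= 2 participants", call. = FALSE)
  if (length(unique(d$condition)) < 2)
    stop("need both delay conditions", call. = FALSE)
  check_outcome(d$.y, outcome)
  fit <- lme4::lmer(.y ~ condition + experiment +
                      (1 + condition | participant_id),
                    data = d, REML = REML, control = lmer_ctrl())
  fit_result(fit, cfg$t_threshold)
}

#' Trial-level build-duration model
#'
#' The central model of the pipeline: build duration predicted by
#' baseline pupil size, orienting amplitude, and dwell time, each
#' interacting with experiment, adjusting for delay condition, with a
#' random intercept and condition slope per participant:
#'
#' `build_s ~ baseline * experiment + orienting * experiment +
#'  dwell_s * experiment + condition + (1 + condition | participant)`
#'
#' Predictors enter on their raw scales (a.u.; durations in seconds).
#'
#' @inheritParams fit_condition_model
#' @return A `fit_result`.
#' @export
fit_build_model <- function(events, cfg = analysis_config(), REML = TRUE) {
  need <- c("baseline_pupil", "orienting_amplitude", "dwell_ms", "build_ms")
  miss <- need[!need %in% names(events)]
  if (length(miss))
    stop("events lack feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- prepare_event_model_frame(events, cfg)
  d <- d[stats::complete.cases(d[, c("build_s", "baseline_pupil",
                                     "orienting_amplitude", "dwell_s")]),
         , drop = FALSE]
  if (length(unique(d$experiment)) < 2)
    stop("need both experiments; use fit_per_experiment() for one",
         call. = FALSE)
  check_outcome(d$build_s, "build")
  fit <- lme4::lmer(build_s ~ baseline_pupil * experiment +
                      orienting_amplitude * experiment +
                      dwell_s * experiment + condition +
                      (1 + condition | participant_id),
                    data = d, REML = REML, control = lmer_ctrl())
  fit_result(fit, cfg$t_threshold)
}

#' Per-experiment follow-up build model
#'
#' The reduced model fit within one experiment when interaction terms
#' of the full model are significant:
#' `build_s ~ baseline + orienting + dwell_s + condition +
#'  (1 + condition | participant)`.
#'
#' @inheritParams fit_condition_model
#' @param experiment Which experiment's events to fit (1 or 2).
#' @return A `fit_result`.
#' @export
fit_per_experiment <- function(events, experiment,
                               cfg = analysis_config(), REML = TRUE) {
  d <- events[events$experiment == experiment, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no events for experiment ", experiment, call. = FALSE)
  d <- prepare_event_model_frame(d, cfg)
  d <- d[stats::complete.cases(d[, c("build_s", "baseline_pupil",
                                     "orienting_amplitude", "dwell_s")]),
         , drop = FALSE]
  check_outcome(d$build_s, "build")
  fit <- lme4::lmer(build_s ~ baseline_pupil + orienting_amplitude +
                      dwell_s + condition +
                      (1 + condition | participant_id),
                    data = d, REML = REML, control = lmer_ctrl())
  fit_result(fit, cfg$t_threshold)
}

#' AIC-based model selection
#'
#' Returns the candidate with the smallest AIC; exact ties go to the
#' model with fewer parameters. All candidates must be fit to the same
#' observations (checked via `n_obs`). For comparisons across
#' fixed-effect structures, fit the candidates with ML (`REML =
#' FALSE`).
#'
#' @param candidates A list of `fit_result` objects.
#' @return The selected `fit_result`.
#' @export
aic_select <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1) return(candidates[[1]])
  n <- vapply(candidates, function(x) x$n_obs, numeric(1))
  if (length(unique(n)) != 1)
    stop("candidates fit on different observations (n_obs: ",
         paste(n, collapse = ", "), ")", call. = FALSE)
  aic <- vapply(candidates, function(x) x$aic, numeric(1))
  npar <- vapply(candidates, function(x) x$n_par, numeric(1))
  best <- which(aic == min(aic))
  if (length(best) > 1) best <- best[which.min(npar[best])]
  candidates[[best[1]]]
}

#' Assign continuous-report precision groups
#'
#' Partitions trials by angular response error into precise (<= 15
#' deg), intermediate (> 15 and <= 30 deg), and imprecise (> 30 deg)
#' groups. The partition is total and exclusive; boundary values fall
#' in the lower group.
#'
#' @param trials Data frame with `response_error_deg` in \[0, 180\].
#' @param cfg An [analysis_config()] (supplies the bin edges).
#' @return `trials` with an added ordered factor `precision_group`.
#' @export
assign_precision_groups <- function(trials, cfg = analysis_config()) {
  err <- trials$response_error_deg
  if (any(is.na(err)) || any(err < 0))
    stop("response errors must be non-negative and non-missing",
         call. = FALSE)
  e <- cfg$precision_bin_edges_deg
  idx <- findInterval(err, e, left.open = TRUE)  # 0,1,2
  trials$precision_group <- factor(c("precise", "intermediate",
                                     "imprecise")[idx + 1L],
                                   levels = c("precise", "intermediate",
                                              "imprecise"))
  trials
}

# Fit one time-course bin, degrading gracefully on degenerate data:
# a constant outcome yields a non-significant stub; if the mixed model
# errors out (e.g. zero residual variance in noiseless simulations),
# the fixed-effects linear model is used, with t = +/-Inf where the
# residual is exactly zero.
fit_bin <- function(d, fixed, random, t_threshold) {
  if (stats::sd(d$.y) == 0) {
    co <- data.frame(term = "(Intercept)", beta = mean(d$.y), se = 0,
                     t = 0, significant = FALSE,
                     stringsAsFactors = FALSE)
    return(structure(list(formula = "constant outcome",
                          coefficients = co,
                          significant = c("(Intercept)" = FALSE),
                          aic = NA_real_, n_obs = nrow(d),
                          n_groups = NA_integer_, n_par = NA_real_,
                          converged = TRUE, singular = TRUE,
                          t_threshold = t_threshold),
                     class = "fit_result"))
  }
  f_mixed <- stats::as.formula(paste(".y ~", fixed, "+", random))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(f_mixed, data = d, REML = TRUE, control = lmer_ctrl()))),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- stats::lm(stats::as.formula(paste(".y ~", fixed)), data = d)
  fit_result(fit, t_threshold)
}

#' Time-resolved precision-group models
#'
#' Bins each trial's stimulus-locked pupil trace into
#' `cfg$timecourse_bin_ms` bins and fits, per bin,
#' `pupil ~ precision_group * set_size * prototypicality +
#' (1 + set_size * prototypicality | participant)`. Reports the
#' per-bin coefficient tables plus the contiguous runs of bins in
#' which any precision-group term is significant (uncorrected |t| >
#' threshold, mirroring the run-based reporting convention).
#'
#' Bins whose pupil values are constant, or in which fewer than two
#' precision groups are present, are skipped (logged, never
#' significant).
#'
#' @param epochs Long data frame `participant_id`, `trial_uid`,
#'   `t_rel`, `pupil` (1-ms samples or pre-binned).
#' @param trials Trial table with `precision_group`, `set_size`,
#'   `prototypical` (see [assign_precision_groups()]).
#' @param cfg An [analysis_config()].
#' @param random Random-effects structure: `"full"` (by-participant
#'   intercept and set size x prototypicality slopes) or
#'   `"intercept"`.
#' @return A list with `bins` (per-bin term table: `bin_start_ms`,
#'   `term`, `beta`, `se`, `t`, `significant`, `skipped`),
#'   `group_significant` (logical per bin), and `runs` (data frame of
#'   significant runs `t_start_ms`, `t_end_ms`).
#' @export
timecourse_lme <- function(epochs, trials, cfg = analysis_config(),
                           random = c("full", "intercept")) {
  random <- match.arg(random)
  if (!"precision_group" %in% names(trials))
    stop("trials lack precision_group; run assign_precision_groups()",
         call. = FALSE)
  bw <- cfg$timecourse_bin_ms
  epochs$bin <- floor(epochs$t_rel / bw) * bw
  agg <- stats::aggregate(pupil ~ participant_id + trial_uid + bin,
                          data = epochs, FUN = mean)
  tr <- trials[, c("trial_uid", "precision_group", "set_size",
                   "prototypical")]
  agg <- merge(agg, tr, by = "trial_uid")
  agg$prototypical <- factor(agg$prototypical)
  agg$.y <- agg$pupil
  rnd <- if (random == "full")
    "(1 + set_size * prototypical | participant_id)"
  else "(1 | participant_id)"
  fixed <- "precision_group * set_size * prototypical"
  bins <- sort(unique(agg$bin))
  res <- vector("list", length(bins))
  sig <- logical(length(bins))
  skipped <- logical(length(bins))
  for (i in seq_along(bins)) {
    d <- agg[agg$bin == bins[i], , drop = FALSE]
    if (length(unique(d$precision_group)) < 2) {
      skipped[i] <- TRUE
      message("timecourse bin ", bins[i],
              " ms skipped: < 2 precision groups")
      next
    }
    fr <- fit_bin(d, fixed, rnd, cfg$t_threshold)
    co <- fr$coefficients
    co$bin_start_ms <- bins[i]
    res[[i]] <- co
    gterms <- grepl("^precision_group(intermediate|imprecise)$", co$term)
    sig[i] <- any(co$significant[gterms])
  }
  bin_table <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  runs <- significance_runs(bins, sig, bw)
  list(bins = bin_table,
       group_significant = stats::setNames(sig, bins),
       skipped = stats::setNames(skipped, bins),
       runs = runs)
}

significance_runs <- function(bins, sig, bin_width) {
  if (!any(sig))
    return(data.frame(t_start_ms = numeric(0), t_end_ms = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(t_start_ms = bins[starts[keep]],
             t_end_ms = bins[ends[keep]] + bin_width)
}

#' Trial-level precision model
#'
#' `response_error ~ baseline + orienting + set_size * prototypicality
#' + (1 + set_size * prototypicality | participant)`: do baseline
#' pupil size and the orienting response predict continuous-report
#' precision trial by trial, over and above set size and colour
#' prototypicality?
#'
#' @param trials Trial table with pupil features (`baseline_pupil`,
#'   `orienting_amplitude`), `set_size`, `prototypical`,
#'   `response_error_deg`.
#' @param cfg An [analysis_config()].
#' @param REML Use REML (default) or ML.
#' @return A `fit_result`.
#' @export
fit_precision_trial_model <- function(trials, cfg = analysis_config(),
                                      REML = TRUE) {
  need <- c("baseline_pupil", "orienting_amplitude", "set_size",
            "prototypical", "response_error_deg")
  miss <- need[!need %in% names(trials)]
  if (length(miss))
    stop("trials lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- trials[stats::complete.cases(trials[, need]), , drop = FALSE]
  check_outcome(d$response_error_deg, "response_error_deg")
  d$prototypical <- factor(d$prototypical)
  fit <- lme4::lmer(response_error_deg ~ baseline_pupil +
                      orienting_amplitude + set_size * prototypical +
                      (1 + set_size * prototypical | participant_id),
                    data = d, REML = REML, control = lmer_ctrl())
  fit_result(fit, cfg$t_threshold)
}

#' Rank correlation of placements with build duration
#'
#' Validates build duration as a proxy for encoding depth: the
#' Spearman rank correlation between the number of correctly placed
#' items per sampling event and the event's build duration.
#'
#' @param placements Correct-placement counts per event.
#' @param build_ms Build durations per event (same length, n >= 3).
#' @return Spearman's rho.
#' @export
validate_build_proxy <- function(placements, build_ms) {
  ok <- stats::complete.cases(placements, build_ms)
  x <- placements[ok]; y <- build_ms[ok]
  if (length(x) < 3)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}
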
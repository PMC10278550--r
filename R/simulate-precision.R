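#' Parameters for the synthetic continuous-report precision task
#'
#' Generative model for a colour continuous-report task: on each trial
#' a participant memorizes 1-4 colours (prototypical or not) and
#' reproduces one on a colour wheel; the angular response error (deg)
#' is generated as
#'
#' `error = intercept + b_ss * set_size + b_base * baseline
#'          + b_orient * orienting + participant terms + noise`
#'
#' truncated to \[0, 180\] degrees, where `orienting` is the planted
#' constriction magnitude (positive = stronger constriction). The
#' default set-size slope of 5.78 deg per item matches the reported
#' trial-level estimate for this task family; the default pupil
#' effects are signed so that larger baselines and weaker constrictions
#' produce larger errors. Each trial also carries a stimulus-locked
#' pupil trace (baseline + orienting kernel + noise).
#'
#' A planted precision-group effect (`group_effect_au`, default 0) adds
#' a group-dependent pupil offset inside `group_effect_window_ms`; it
#' exists to validate the time-resolved models by plant-and-recover.
#'
#' @param n_participants,n_trials Counts (trials are per participant).
#' @param set_sizes Integer set sizes, a subset of 1:4.
#' @param p_prototypical Probability a trial uses prototypical colours.
#' @param intercept_deg Mean error at set size 0 and centred pupil
#'   metrics (deg).
#' @param effect_setsize Planted slope, deg per memorized item.
#' @param effect_baseline Planted slope, deg per a.u. of baseline
#'   (applied to the deviation from the grand baseline mean).
#' @param effect_orienting Planted slope, deg per a.u. of constriction
#'   magnitude (negative = stronger constriction, smaller error).
#' @param noise_sd_deg Residual error SD (deg).
#' @param participant_sd_deg SD of participant error intercepts (deg).
#' @param setsize_slope_sd SD of participant set-size slopes (deg/item).
#' @param baseline_mean,baseline_sd_participant,baseline_sd_event
#'   Baseline pupil distribution (a.u.), as in [copy_sim_params()].
#' @param amp_mean,amp_sd Orienting constriction magnitude distribution
#'   (a.u., truncated at 0).
#' @param kernel A [kernel_params()].
#' @param pupil_noise_sd White-noise SD of the rendered trace (a.u.).
#' @param epoch_range_ms Length-2 span of the per-trial epoch relative
#'   to stimulus onset (ms).
#' @param group_effect_au Planted pupil offset per precision-group step
#'   (a.u.; 0 disables the plant).
#' @param group_effect_window_ms Window of the planted group effect.
#' @param precision_bin_edges_deg Error cut points used when planting
#'   the group effect.
#' @param seed Optional integer seed.
#' @return An object of class `precision_sim_params`.
#' @export
precision_sim_params <- function(n_participants = 24,
                                 n_trials = 100,
                                 set_sizes = 1:4,
                                 p_prototypical = 0.5,
                                 intercept_deg = 12,
                                 effect_setsize = 5.78,
                                 effect_baseline = 0.002,
                                 effect_orienting = -0.004,
                                 noise_sd_deg = 15,
                                 participant_sd_deg = 3,
                                 setsize_slope_sd = 1,
                                 baseline_mean = 3000,
                                 baseline_sd_participant = 300,
                                 baseline_sd_event = 150,
                                 amp_mean = 100,
                                 amp_sd = 30,
                                 kernel = kernel_params(),
                                 pupil_noise_sd = 5,
                                 epoch_range_ms = c(-200, 2000),
                                 group_effect_au = 0,
                                 group_effect_window_ms = c(500, 1000),
                                 precision_bin_edges_deg = c(15, 30),
                                 seed = NULL) {
  p <- as.list(environment())
  p$n_participants <- as.integer(n_participants)
  p$n_trials <- as.integer(n_trials)
  p$set_sizes <- as.integer(set_sizes)
  if (!all(p$set_sizes %in% 1:4))
    stop("set_sizes must be within 1..4", call. = FALSE)
  if (p$n_participants < 1 || p$n_trials < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (any(c(noise_sd_deg, participant_sd_deg, setsize_slope_sd,
            baseline_sd_participant, baseline_sd_event, amp_sd,
            pupil_noise_sd) < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(p, class = "precision_sim_params")
}

#' Simulate continuous-report precision trials
#'
#' @param p A [precision_sim_params()].
#' @param seed Integer seed; overrides `p$seed`.
#' @param return_epochs If `TRUE` (default), also return per-trial
#'   pupil epochs at 1-ms resolution (long format); disable for large
#'   trial-only simulations.
#' @return A list with `trials` (one row per trial: identifiers,
#'   `set_size`, `prototypical`, `baseline_pupil`,
#'   `orienting_amplitude`, `response_error_deg`) and `epochs` (long
#'   data frame `participant_id`, `trial_uid`, `t_rel`, `pupil`, or
#'   `NULL`). Planted coefficients are attached to `trials` as
#'   attribute `"planted"`.
#' @export
simulate_precision_task <- function(p = precision_sim_params(),
                                    seed = p$seed,
                                    return_epochs = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- p$n_participants * p$n_trials
  pid <- rep(sprintf("P%02d", seq_len(p$n_participants)), each = p$n_trials)
  u_int <- stats::rnorm(p$n_participants, 0, p$participant_sd_deg)
  u_slope <- stats::rnorm(p$n_participants, 0, p$setsize_slope_sd)
  base_p <- stats::rnorm(p$n_participants, p$baseline_mean,
                         p$baseline_sd_participant)
  pidx <- rep(seq_len(p$n_participants), each = p$n_trials)

  set_size <- sample(p$set_sizes, n, replace = TRUE)
  prototypical <- stats::runif(n) < p$p_prototypical
  baseline <- stats::rnorm(n, base_p[pidx], p$baseline_sd_event)
  amp <- pmax(0, stats::rnorm(n, p$amp_mean, p$amp_sd))
  err <- p$intercept_deg +
    (p$effect_setsize + u_slope[pidx]) * set_size +
    p$effect_baseline * (baseline - p$baseline_mean) +
    p$effect_orienting * amp +
    u_int[pidx] +
    stats::rnorm(n, 0, p$noise_sd_deg)
  err <- pmin(180, pmax(0, err))

  trials <- data.frame(
    participant_id = pid,
    trial_uid = seq_len(n),
    trial_id = rep(seq_len(p$n_trials), p$n_participants),
    set_size = set_size,
    prototypical = prototypical,
    baseline_pupil = baseline,
    orienting_amplitude = amp,
    response_error_deg = err,
    stringsAsFactors = FALSE
  )
  attr(trials, "planted") <- list(
    intercept_deg = p$intercept_deg,
    effect_setsize = p$effect_setsize,
    effect_baseline = p$effect_baseline,
    effect_orienting = p$effect_orienting,
    group_effect_au = p$group_effect_au,
    group_effect_window_ms = p$group_effect_window_ms
  )

  epochs <- NULL
  if (return_epochs) {
    t_rel <- seq(p$epoch_range_ms[1], p$epoch_range_ms[2], by = 1)
    m <- length(t_rel)
    gain <- kernel_window_gain(p$kernel)
    shape <- kernel_shape(pmax(t_rel, 0), p$kernel)
    shape[t_rel < 0] <- 0
    edges <- p$precision_bin_edges_deg
    gcode <- findInterval(err, edges, left.open = TRUE)  # 0,1,2
    # half-open plant window, so the effect occupies exactly the
    # time-course bins whose left edges lie inside it
    in_win <- t_rel >= p$group_effect_window_ms[1] &
      t_rel < p$group_effect_window_ms[2]
    pupil <- rep(baseline, each = m) +
      rep(-amp / gain, each = m) * rep(shape, n) +
      p$group_effect_au * rep(gcode, each = m) * rep(in_win, n)
    if (p$pupil_noise_sd > 0)
      pupil <- pupil + stats::rnorm(n * m, 0, p$pupil_noise_sd)
    epochs <- data.frame(
      participant_id = rep(pid, each = m),
      trial_uid = rep(trials$trial_uid, each = m),
      t_rel = rep(t_rel, n),
      pupil = pupil,
      stringsAsFactors = FALSE
    )
  }
  list(trials = trials, epochs = epochs)
}
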
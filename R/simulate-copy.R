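#' Parameters for the synthetic copy task
#'
#' Defines the generative model for synthetic copy-task data. The
#' defaults emulate the study conditions of the source experiments: 24
#' participants split evenly over two experiments, 35 trials per delay
#' condition, medium (1500 ms) and long (3000 ms) delay conditions, and
#' roughly 1.65 sampling events per trial (about 2,770 events in
#' total). Build duration is generated from a linear model with
#' planted effects of baseline pupil size, orienting amplitude, and
#' dwell time, plus a participant random intercept and residual noise:
#'
#' `build_s = intercept + b1 * (baseline - exp. mean) + b2[exp] * orienting
#'            + b3[exp] * dwell_s + direct condition effect + u_p + e`
#'
#' floored at `build_floor_s`. Orienting amplitudes are stored on the
#' constriction-magnitude scale (positive = stronger constriction).
#' Condition shifts are expressed relative to the 1500-ms condition.
#'
#' @param n_participants Number of participants (half per experiment).
#' @param n_trials_per_condition Trials per delay condition per
#'   participant.
#' @param delays_ms Delay conditions simulated (ms).
#' @param events_per_trial_probs Named numeric vector of probabilities
#'   over event counts per trial; names are the counts.
#' @param kernel A [kernel_params()]; its `amplitude` field is
#'   overridden per event.
#' @param baseline_mean Grand-mean baseline pupil size (a.u.).
#' @param baseline_sd_participant SD of participant baseline means
#'   (a.u.).
#' @param baseline_sd_event Within-participant, per-event baseline SD
#'   (a.u.).
#' @param baseline_exp2_shift Baseline offset of experiment 2 (a.u.);
#'   the second experiment used darker stimuli, dilating the pupil.
#' @param amp_mean,amp_sd Mean and SD of the per-event orienting
#'   constriction magnitude (a.u., truncated at 0).
#' @param cond_amp_shift,cond_dwell_shift_s Named vectors (names =
#'   delays in ms) of condition shifts for orienting magnitude (a.u.)
#'   and mean dwell (s).
#' @param dwell_mean_s,dwell_sdlog Dwell durations are lognormal with
#'   median `dwell_mean_s` seconds and log-scale SD `dwell_sdlog`
#'   (right-skewed, as empirical dwell distributions are), shifted by
#'   the condition term and floored at `dwell_floor_s`.
#' @param intercept_s Mean build duration at centered predictors (s).
#' @param effect_baseline Planted build effect of baseline (s per
#'   a.u.), applied to the deviation from the experiment-specific
#'   baseline mean (recorder offsets differ between experiments; the
#'   arousal effect acts on fluctuations around them).
#' @param effect_orienting Planted build effect of orienting magnitude
#'   (s per a.u.); length 1 (both experiments) or 2 (per experiment).
#' @param effect_dwell Planted build effect of dwell (s per s); length
#'   1 or 2 as above.
#' @param effect_condition_s Direct (unmediated) build shift of the
#'   long condition (s). The default 0 makes the marginal condition
#'   effect on build arise through the planted dwell and orienting
#'   condition shifts.
#' @param participant_sd SD of participant build intercepts (s).
#' @param residual_sd Residual build SD (s).
#' @param build_floor_s,dwell_floor_s Physical lower bounds (s).
#' @param p_all_correct Probability a trial ends with all items placed
#'   correctly (incorrect trials are excluded from analysis).
#' @param pupil_noise_sd White-noise SD added to rendered pupil
#'   samples (a.u.).
#' @param gaze_jitter_sd_px Fixation jitter SD (px), clamped so gaze
#'   stays inside the fixated region.
#' @param blink_rate_hz Blink rate (events per second of recording).
#' @param flicker_rate_hz Rate of sub-100-ms excursions to the
#'   opposite screen half (per second), exercising the hysteresis rule.
#' @param p_abort_visit Probability of inserting an aborted left visit
#'   (shorter than the delay, producing no sampling event) before a
#'   real one.
#' @param p_gaze_violation Probability an event's gaze leaves the
#'   expanded model-grid region during the inclusion window.
#' @param pre_visit_gap_ms Right-side period at the start of each trial
#'   before the first visit (ms).
#' @param seed Optional integer seed stored with the parameters.
#' @return An object of class `copy_sim_params`.
#' @export
copy_sim_params <- function(n_participants = 24,
                            n_trials_per_condition = 35,
                            delays_ms = c(1500, 3000),
                            events_per_trial_probs = c("1" = 0.45,
                                                       "2" = 0.45,
                                                       "3" = 0.10),
                            kernel = kernel_params(),
                            baseline_mean = 3000,
                            baseline_sd_participant = 300,
                            baseline_sd_event = 150,
                            baseline_exp2_shift = 1312.68,
                            amp_mean = 100,
                            amp_sd = 30,
                            cond_amp_shift = c("200" = 0, "1500" = 0,
                                               "3000" = 59.53),
                            cond_dwell_shift_s = c("200" = -0.9,
                                                   "1500" = 0,
                                                   "3000" = 1.64),
                            dwell_mean_s = 1.2,
                            dwell_sdlog = 0.6,
                            intercept_s = 2.0,
                            effect_baseline = 0.0009,
                            effect_orienting = c(0.003, 0.0001),
                            effect_dwell = c(0.10, 0.19),
                            effect_condition_s = 0,
                            participant_sd = 0.5,
                            residual_sd = 0.6,
                            build_floor_s = 0.1,
                            dwell_floor_s = 0.2,
                            p_all_correct = 0.8863,
                            pupil_noise_sd = 5,
                            gaze_jitter_sd_px = 4,
                            blink_rate_hz = 0.05,
                            flicker_rate_hz = 0.05,
                            p_abort_visit = 0,
                            p_gaze_violation = 0,
                            pre_visit_gap_ms = 400,
                            seed = NULL) {
  two <- function(x) if (length(x) == 1) rep(as.numeric(x), 2) else as.numeric(x)
  p <- list(n_participants = as.integer(n_participants),
            n_trials_per_condition = as.integer(n_trials_per_condition),
            delays_ms = as.numeric(delays_ms),
            events_per_trial_probs = events_per_trial_probs,
            kernel = kernel,
            baseline_mean = baseline_mean,
            baseline_sd_participant = baseline_sd_participant,
            baseline_sd_event = baseline_sd_event,
            baseline_exp2_shift = baseline_exp2_shift,
            amp_mean = amp_mean, amp_sd = amp_sd,
            cond_amp_shift = cond_amp_shift,
            cond_dwell_shift_s = cond_dwell_shift_s,
            dwell_mean_s = dwell_mean_s, dwell_sdlog = dwell_sdlog,
            intercept_s = intercept_s,
            effect_baseline = as.numeric(effect_baseline),
            effect_orienting = two(effect_orienting),
            effect_dwell = two(effect_dwell),
            effect_condition_s = as.numeric(effect_condition_s),
            participant_sd = participant_sd,
            residual_sd = residual_sd,
            build_floor_s = build_floor_s,
            dwell_floor_s = dwell_floor_s,
            p_all_correct = p_all_correct,
            pupil_noise_sd = pupil_noise_sd,
            gaze_jitter_sd_px = gaze_jitter_sd_px,
            blink_rate_hz = blink_rate_hz,
            flicker_rate_hz = flicker_rate_hz,
            p_abort_visit = p_abort_visit,
            p_gaze_violation = p_gaze_violation,
            pre_visit_gap_ms = as.numeric(pre_visit_gap_ms),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  if (p$n_participants < 1 || p$n_trials_per_condition < 1)
    stop("counts must be >= 1", call. = FALSE)
  sds <- c(p$baseline_sd_participant, p$baseline_sd_event, p$amp_sd,
           p$dwell_sd_s, p$participant_sd, p$residual_sd,
           p$pupil_noise_sd, p$gaze_jitter_sd_px)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(sum(p$events_per_trial_probs) - 1) > 1e-8)
    stop("events_per_trial_probs must sum to 1", call. = FALSE)
  if (is.null(names(p$events_per_trial_probs)))
    stop("events_per_trial_probs must be named by event count", call. = FALSE)
  for (nm in c("cond_amp_shift", "cond_dwell_shift_s")) {
    if (!all(as.character(p$delays_ms) %in% names(p[[nm]])))
      stop(nm, " must name every delay in delays_ms", call. = FALSE)
  }
  structure(p, class = "copy_sim_params")
}

cond_shift <- function(shifts, delays_ms) {
  as.numeric(shifts[as.character(delays_ms)])
}

#' Simulate copy-task sampling events (event level)
#'
#' Draws the per-event ground-truth table of the synthetic copy task
#' without rendering sample-level gaze/pupil streams. This is the
#' generative model behind [simulate_copy_task()] and the workhorse for
#' model parameter-recovery studies, where only the event table is
#' needed.
#'
#' @param p A [copy_sim_params()].
#' @param seed Integer seed; overrides `p$seed`. Fixed seed implies
#'   bit-identical output.
#' @return A data frame with one row per planted sampling event:
#'   identifiers, condition, experiment, `all_correct`,
#'   `baseline_pupil` (a.u.), `orienting_amplitude` (constriction
#'   magnitude, a.u.), `dwell_ms`, `build_ms`, and the latent
#'   `participant_effect`. The planted coefficients are attached as
#'   attribute `"planted"`.
#' @export
simulate_copy_events <- function(p = copy_sim_params(), seed = p$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_cond <- length(p$delays_ms)
  counts <- as.integer(names(p$events_per_trial_probs))
  pupil_gain <- kernel_window_gain(p$kernel)

  out <- vector("list", p$n_participants)
  for (i in seq_len(p$n_participants)) {
    pid <- sprintf("P%02d", i)
    experiment <- if (i <= ceiling(p$n_participants / 2)) 1L else 2L
    u_p <- stats::rnorm(1, 0, p$participant_sd)
    base_p <- stats::rnorm(1, p$baseline_mean, p$baseline_sd_participant) +
      (experiment == 2L) * p$baseline_exp2_shift
    delay <- rep(p$delays_ms, each = p$n_trials_per_condition)
    delay <- delay[sample.int(length(delay))]
    n_trials <- length(delay)
    all_correct <- stats::runif(n_trials) < p$p_all_correct
    n_ev <- counts[sample.int(length(counts), n_trials, replace = TRUE,
                              prob = p$events_per_trial_probs)]
    trial_idx <- rep(seq_len(n_trials), n_ev)
    m <- length(trial_idx)
    d_ev <- delay[trial_idx]
    baseline <- stats::rnorm(m, base_p, p$baseline_sd_event)
    amp <- pmax(0, stats::rnorm(
      m, p$amp_mean + cond_shift(p$cond_amp_shift, d_ev), p$amp_sd))
    dwell_s <- pmax(p$dwell_floor_s,
                    stats::rlnorm(m, log(p$dwell_mean_s), p$dwell_sdlog) +
                      cond_shift(p$cond_dwell_shift_s, d_ev))
    e <- experiment
    exp_base_mean <- p$baseline_mean + (e == 2L) * p$baseline_exp2_shift
    build_s <- pmax(p$build_floor_s,
                    p$intercept_s +
                      p$effect_baseline * (baseline - exp_base_mean) +
                      p$effect_orienting[e] * amp +
                      p$effect_dwell[e] * dwell_s +
                      p$effect_condition_s * (d_ev == max(p$delays_ms) &
                                                n_cond > 1) +
                      u_p +
                      stats::rnorm(m, 0, p$residual_sd))
    ev_index <- stats::ave(trial_idx, trial_idx, FUN = seq_along)
    out[[i]] <- data.frame(
      participant_id = pid,
      trial_id = trial_idx,
      event_index = as.integer(ev_index),
      condition_delay_ms = d_ev,
      experiment = experiment,
      all_correct = all_correct[trial_idx],
      baseline_pupil = baseline,
      orienting_amplitude = amp,
      dwell_ms = round(dwell_s * 1000),
      build_ms = pmax(round(build_s * 1000), 100),
      participant_effect = u_p,
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  attr(events, "planted") <- list(
    intercept_s = p$intercept_s,
    effect_baseline = p$effect_baseline,
    effect_orienting = p$effect_orienting,
    effect_dwell = p$effect_dwell,
    effect_condition_s = p$effect_condition_s,
    marginal_condition_build_s = marginal_condition_effect(p),
    pupil_gain = pupil_gain
  )
  events
}

#' Expected marginal condition effect on build duration
#'
#' The planted direct condition effect plus the component mediated by
#' the condition shifts in dwell and orienting magnitude, averaged over
#' the two experiments. This is the estimand of the condition-only
#' build model (which does not adjust for dwell or orienting).
#'
#' @param p A [copy_sim_params()] with exactly two delay conditions.
#' @return Expected long-vs-medium build difference in seconds.
#' @export
marginal_condition_effect <- function(p) {
  if (length(p$delays_ms) != 2) return(NA_real_)
  d <- sort(p$delays_ms)
  d_dwell <- cond_shift(p$cond_dwell_shift_s, d[2]) -
    cond_shift(p$cond_dwell_shift_s, d[1])
  d_amp <- cond_shift(p$cond_amp_shift, d[2]) -
    cond_shift(p$cond_amp_shift, d[1])
  p$effect_condition_s +
    mean(p$effect_dwell) * d_dwell +
    mean(p$effect_orienting) * d_amp
}

#' Simulate a full copy-task recording
#'
#' Renders the event-level ground truth of [simulate_copy_events()]
#' into 1000-Hz gaze/pupil sample streams: for each planted event gaze
#' enters the left screen half, holds through the delay (model onset),
#' dwells on the model grid, then moves right for the planted build
#' duration; the pupil trace is the per-event baseline plus the
#' orienting kernel locked to model onset plus white noise. Optional
#' blinks, sub-100-ms gaze flickers, aborted visits, and gaze-deviation
#' violations exercise the downstream filters.
#'
#' Planted orienting amplitudes are divided by the kernel's median
#' window gain (see [kernel_window_gain()]) before rendering, so that
#' in the noiseless limit the extracted orienting feature equals the
#' planted value exactly.
#'
#' @param p A [copy_sim_params()].
#' @param g A [geometry_config()].
#' @param seed Integer seed; overrides `p$seed`.
#' @return A list with `samples` (named list of [sample_series()], one
#'   per participant), `trials` (trial table), and `truth` (the planted
#'   event table with realized timing columns `t_visit_start`,
#'   `t_model_onset`, `ended_by`, and `gaze_in_roi`).
#' @export
simulate_copy_task <- function(p = copy_sim_params(), g = geometry_config(),
                               seed = p$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (p$pre_visit_gap_ms < 100)
    stop("pre_visit_gap_ms must be >= 100 (the hysteresis duration)",
         call. = FALSE)
  events <- simulate_copy_events(p, seed = NULL)
  events$t_visit_start <- NA_real_
  events$t_model_onset <- NA_real_
  events$ended_by <- NA_character_
  events$gaze_in_roi <- NA

  roi <- g$model_grid_roi
  left_xy <- c(mean(roi[c(1, 3)]), mean(roi[c(2, 4)]))
  right_xy <- c((g$midline_x + g$screen_width_px) / 2, g$screen_height_px / 2)

  samples <- list()
  trials_out <- list()
  truth_out <- list()
  for (pid in unique(events$participant_id)) {
    ev_p <- events[events$participant_id == pid, , drop = FALSE]
    trial_ids <- unique(ev_p$trial_id)
    cursor <- 0
    side_runs <- list()   # (side, start, end) half-open
    tr_rows <- list()
    for (tid in trial_ids) {
      ev_t <- ev_p[ev_p$trial_id == tid, , drop = FALSE]
      delay <- ev_t$condition_delay_ms[1]
      t_start <- cursor
      for (j in seq_len(nrow(ev_t))) {
        gap <- if (j == 1) p$pre_visit_gap_ms else 0
        if (gap > 0) {
          side_runs[[length(side_runs) + 1L]] <-
            list("right", cursor, cursor + gap)
          cursor <- cursor + gap
        }
        if (p$p_abort_visit > 0 && stats::runif(1) < p$p_abort_visit) {
          ab <- ceiling(delay * stats::runif(1, 0.2, 0.7))
          side_runs[[length(side_runs) + 1L]] <-
            list("left", cursor, cursor + ab)
          side_runs[[length(side_runs) + 1L]] <-
            list("right", cursor + ab, cursor + ab + 200)
          cursor <- cursor + ab + 200
        }
        t_visit <- cursor
        t_model <- t_visit + delay
        dwell_end <- t_model + ev_t$dwell_ms[j]
        build_end <- dwell_end + ev_t$build_ms[j]
        side_runs[[length(side_runs) + 1L]] <-
          list("left", t_visit, dwell_end)
        side_runs[[length(side_runs) + 1L]] <-
          list("right", dwell_end, build_end)
        cursor <- build_end
        k <- which(events$participant_id == pid &
                     events$trial_id == tid)[j]
        events$t_visit_start[k] <- t_visit
        events$t_model_onset[k] <- t_model
        events$ended_by[k] <- if (j == nrow(ev_t)) "trial-end" else "gaze-return"
      }
      tr_rows[[length(tr_rows) + 1L]] <- data.frame(
        participant = pid, trial = tid,
        condition_delay_ms = delay,
        experiment = ev_t$experiment[1],
        all_correct = ev_t$all_correct[1],
        t_start = t_start, t_end = cursor,
        stringsAsFactors = FALSE)
    }
    total <- cursor
    time <- seq(0, total - 1)
    side <- character(total)
    for (r in side_runs) {
      if (r[[3]] > r[[2]]) side[(r[[2]] + 1):r[[3]]] <- r[[1]]
    }

    # gaze: jittered fixation inside the fixated region
    n <- total
    jit <- function(sd, lo, hi, center) {
      pmin(hi, pmax(lo, center + stats::rnorm(n, 0, sd)))
    }
    gx <- ifelse(side == "left",
                 jit(p$gaze_jitter_sd_px, roi[1], roi[3], left_xy[1]),
                 jit(p$gaze_jitter_sd_px, g$midline_x + 20,
                     g$screen_width_px - 1, right_xy[1]))
    gy <- ifelse(side == "left",
                 jit(p$gaze_jitter_sd_px, roi[2], roi[4], left_xy[2]),
                 jit(p$gaze_jitter_sd_px, 0, g$screen_height_px - 1,
                     right_xy[2]))

    # sub-hysteresis flickers to the opposite half
    if (p$flicker_rate_hz > 0) {
      n_fl <- stats::rpois(1, p$flicker_rate_hz * total / 1000)
      if (n_fl > 0) {
        starts <- sort(sample.int(total - 100, n_fl))
        for (fs in starts) {
          dur <- sample(30:80, 1)
          idx <- fs:(fs + dur - 1)
          # flip only strictly inside one run (at least one original-side
          # sample on each flank), so the excursion cannot merge with a
          # neighbouring opposite-side run and move a planted boundary
          if (fs > 1 && max(idx) < total &&
              length(unique(side[idx])) == 1 &&
              side[fs - 1] == side[idx[1]] &&
              side[max(idx) + 1] == side[idx[1]]) {
            to_right <- side[idx[1]] == "left"
            gx[idx] <- if (to_right) right_xy[1] else left_xy[1]
            gy[idx] <- if (to_right) right_xy[2] else left_xy[2]
          }
        }
      }
    }

    # pupil: baseline per event, orienting kernel locked to model onset
    ev_idx <- which(events$participant_id == pid)
    base_p_level <- mean(events$baseline_pupil[ev_idx])
    pupil <- rep(base_p_level, total)
    events$gaze_in_roi[ev_idx] <- TRUE
    for (k in ev_idx) {
      t_v <- events$t_visit_start[k]
      t_m <- events$t_model_onset[k]
      span_end <- min(t_m + events$dwell_ms[k] + events$build_ms[k], total)
      idx <- (t_v + 1):span_end
      pupil[idx] <- events$baseline_pupil[k]
      kk <- p$kernel
      kk$amplitude <- -events$orienting_amplitude[k] /
        kernel_window_gain(p$kernel)
      krange <- t_m:min(t_m + kk$recovery_end_ms, total - 1)
      pupil[krange + 1] <- pupil[krange + 1] +
        pupil_kernel(krange - t_m, kk)
      if (p$p_gaze_violation > 0 && stats::runif(1) < p$p_gaze_violation) {
        vio <- (t_m + 300):(t_m + 600)
        vio <- vio[vio < total]
        gx[vio + 1] <- g$midline_x - 30   # left half, far from the grid
        gy[vio + 1] <- 5
        events$gaze_in_roi[k] <- FALSE
      }
    }
    if (p$pupil_noise_sd > 0)
      pupil <- pupil + stats::rnorm(total, 0, p$pupil_noise_sd)

    valid <- rep(TRUE, total)
    if (p$blink_rate_hz > 0) {
      n_bl <- stats::rpois(1, p$blink_rate_hz * total / 1000)
      if (n_bl > 0) {
        bs <- sample.int(total - 250, n_bl)
        for (b in bs) {
          dur <- sample(80:200, 1)
          idx <- b:(b + dur - 1)
          valid[idx] <- FALSE
          pupil[idx] <- 0
        }
      }
    }

    samples[[pid]] <- sample_series(pid, pid, time, gx, gy, pupil, valid)
    trials_out[[pid]] <- do.call(rbind, tr_rows)
    truth_out[[pid]] <- events[ev_idx, , drop = FALSE]
  }
  trials <- do.call(rbind, trials_out)
  rownames(trials) <- NULL
  truth <- do.call(rbind, truth_out)
  rownames(truth) <- NULL
  attr(truth, "planted") <- attr(events, "planted")
  list(samples = samples, trials = trials, truth = truth)
}
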
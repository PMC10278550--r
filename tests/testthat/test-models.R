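test_that("significance flags are a pure function of beta, se, and the threshold", {
  ev <- simulate_copy_events(copy_sim_params(n_participants = 6,
                                             n_trials_per_condition = 10),
                             seed = 51)
  f <- fit_build_model(ev)
  co <- f$coefficients
  expect_equal(co$significant, abs(co$beta / co$se) > 1.96)
  expect_equal(co$t, co$beta / co$se)

  cfg9 <- analysis_config(t_threshold = 9)
  f9 <- fit_build_model(ev, cfg9)
  expect_equal(f9$coefficients$significant,
               abs(f9$coefficients$t) > 9)
})

test_that("the condition model recovers a planted condition effect on build", {
  p <- copy_sim_params()
  ev <- simulate_copy_events(p, seed = 52)
  plant <- marginal_condition_effect(p)
  f <- fit_condition_model(ev, "build")
  ct <- coef_term(f, "conditionlong")
  expect_lt(abs(ct$beta - plant), 2.58 * ct$se)
  expect_equal(f$n_groups, 24L)

  # orienting responses are stronger in the long condition by the plant
  fo <- fit_condition_model(ev, "orienting")
  cto <- coef_term(fo, "conditionlong")
  expect_lt(abs(cto$beta - 59.53), 2.58 * cto$se)
})

test_that("degenerate outcomes and undersized designs are rejected", {
  ev <- simulate_copy_events(copy_sim_params(n_participants = 4,
                                             n_trials_per_condition = 5),
                             seed = 53)
  ev$build_ms <- 1000
  expect_error(fit_condition_model(ev, "build"), "degenerate")

  ev1 <- simulate_copy_events(copy_sim_params(n_participants = 1,
                                              n_trials_per_condition = 5),
                              seed = 54)
  expect_error(fit_condition_model(ev1, "build"), "2 participants")

  ev2 <- simulate_copy_events(copy_sim_params(n_participants = 4,
                                              n_trials_per_condition = 5),
                              seed = 55)
  ev2$orienting_amplitude <- NULL
  expect_error(fit_build_model(ev2), "orienting_amplitude")
  expect_error(fit_per_experiment(ev2[0, ], 1), "no events")
})

test_that("the full build model recovers planted per-experiment slopes", {
  p <- copy_sim_params()
  ev <- simulate_copy_events(p, seed = 56)
  f <- fit_build_model(ev)
  expect_true(f$converged)
  # 99% CIs: single-seed checks; coverage at the nominal 95% level is
  # established over replicates in the acceptance suite
  for (chk in list(c("baseline_pupil", 0.0009),
                   c("orienting_amplitude", 0.003),
                   c("dwell_s", 0.10))) {
    ct <- coef_term(f, chk[1])
    expect_lt(abs(ct$beta - as.numeric(chk[2])), 2.58 * ct$se)
  }
  # experiment-specific dwell slopes (0.10 vs 0.19) make the
  # interaction detectable at study scale
  ct <- coef_term(f, "experimentexp2:dwell_s")
  expect_true(ct$significant)

  # per-experiment follow-ups recover their own slopes
  f1 <- fit_per_experiment(ev, 1)
  f2 <- fit_per_experiment(ev, 2)
  ct1 <- coef_term(f1, "dwell_s")
  ct2 <- coef_term(f2, "dwell_s")
  expect_lt(abs(ct1$beta - 0.10), 2.58 * ct1$se)
  expect_lt(abs(ct2$beta - 0.19), 2.58 * ct2$se)
})

test_that("AIC selection takes the smallest AIC, breaking ties toward parsimony", {
  mk <- function(aic, n_par, n_obs = 100) {
    structure(list(formula = "f", coefficients = data.frame(),
                   aic = aic, n_obs = n_obs, n_par = n_par,
                   converged = TRUE),
              class = "fit_result")
  }
  a <- mk(100, 5); b <- mk(90, 7); c <- mk(90, 6)
  expect_identical(aic_select(list(a)), a)
  expect_identical(aic_select(list(a, b, c)), c)      # tie -> fewer params
  expect_identical(aic_select(list(c, b, a)), c)      # order invariant
  expect_identical(aic_select(list(b, a)), b)
  expect_error(aic_select(list(a, mk(80, 3, n_obs = 99))),
               "different observations")
})

test_that("ML-fitted nested models are comparable by AIC and prefer the truth", {
  # planted-zero extra term: the reduced model should usually win
  set.seed(57)
  wins <- 0L
  for (r in 1:10) {
    ev <- simulate_copy_events(
      copy_sim_params(n_participants = 12, n_trials_per_condition = 10,
                      effect_baseline = 0),
      seed = 570 + r)
    d <- ev
    d$dwell_s <- d$dwell_ms / 1000
    d$build_s <- d$build_ms / 1000
    full <- lme4::lmer(build_s ~ baseline_pupil + orienting_amplitude +
                         dwell_s + (1 | participant_id),
                       data = d, REML = FALSE)
    red <- lme4::lmer(build_s ~ orienting_amplitude + dwell_s +
                        (1 | participant_id),
                      data = d, REML = FALSE)
    sel <- aic_select(list(pupilcopy:::fit_result(full),
                           pupilcopy:::fit_result(red)))
    if (sel$n_par == 5) wins <- wins + 1L
  }
  expect_gte(wins, 7)
})

test_that("precision groups partition errors with boundary values in the lower group", {
  tr <- data.frame(response_error_deg = c(0, 15, 15.0001, 30, 30.0001, 179))
  out <- assign_precision_groups(tr)
  expect_equal(as.character(out$precision_group),
               c("precise", "precise", "intermediate", "intermediate",
                 "imprecise", "imprecise"))
  expect_error(assign_precision_groups(
    data.frame(response_error_deg = c(-1, 10))), "non-negative")
})

test_that("the trial-level precision model recovers planted slopes and rejects degenerate input", {
  sim <- simulate_precision_task(precision_sim_params(), seed = 58,
                                 return_epochs = FALSE)
  f <- fit_precision_trial_model(sim$trials)
  ct <- coef_term(f, "set_size")
  expect_lt(abs(ct$beta - 5.78), 2.58 * ct$se)
  expect_true(ct$significant)

  tr <- sim$trials
  tr$response_error_deg <- 20
  expect_error(fit_precision_trial_model(tr), "degenerate")
  expect_error(fit_precision_trial_model(tr[, -4]), "lack column")
})

test_that("time-course models handle single-bin input and skip underpopulated bins", {
  sim <- simulate_precision_task(
    precision_sim_params(n_participants = 6, n_trials = 30,
                         epoch_range_ms = c(0, 9)),
    seed = 59)
  tr <- assign_precision_groups(sim$trials)
  tc <- timecourse_lme(sim$epochs, tr, random = "intercept")
  expect_equal(length(tc$group_significant), 1L)

  # all trials in one group: the only bin is skipped
  tr2 <- tr
  tr2$precision_group <- factor("precise",
                                levels = levels(tr$precision_group))
  expect_message(tc2 <- timecourse_lme(sim$epochs, tr2,
                                       random = "intercept"),
                 "skipped")
  expect_true(all(tc2$skipped))
  expect_equal(nrow(tc2$runs), 0L)
})

test_that("build duration's proxy validity is measured by Spearman rank correlation", {
  expect_equal(validate_build_proxy(1:6, c(10, 20, 30, 40, 50, 60) * 100), 1)
  expect_equal(validate_build_proxy(1:6, rev(1:6) * 100), -1)

  # 6-pair fixture vs the hand rank formula rho = 1 - 6*sum(d^2)/(n(n^2-1))
  placements <- c(1, 2, 3, 4, 5, 6)
  build <- c(1200, 900, 2500, 2100, 3000, 2800)
  d2 <- sum((rank(placements) - rank(build))^2)
  expect_equal(validate_build_proxy(placements, build),
               1 - 6 * d2 / (6 * (36 - 1)))

  expect_error(validate_build_proxy(rep(3, 5), 1:5), "constant")
  expect_error(validate_build_proxy(1:2, 1:2), "at least 3")
})
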
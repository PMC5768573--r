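cfg <- controller_config()

test_that("control starts on two successive high BG within the window", {
  expect_true(should_start(data.frame(t = c(0, 120), value = c(8.5, 8.2)), cfg))
  expect_false(should_start(data.frame(t = c(0, 120), value = c(8.5, 7.9)), cfg))
  expect_false(should_start(data.frame(t = c(0, 300), value = c(8.5, 8.3)), cfg))
  expect_false(should_start(data.frame(t = numeric(), value = numeric()), cfg))
  expect_false(should_start(data.frame(t = 0, value = 12), cfg))
  # an intervening low measurement breaks the succession
  expect_false(should_start(
    data.frame(t = c(0, 60, 120), value = c(8.5, 7.0, 8.5)), cfg))
  expect_true(should_start(
    list(bg_measurement(0, 9), bg_measurement(60, 8.4)), cfg))
})

test_that("candidate interventions respect nutrition and insulin limits", {
  c100 <- candidate_interventions(intervention(2, 100, 1), cfg)
  expect_true(all(c100$en_rate >= 70 & c100$en_rate <= 100))
  c30 <- candidate_interventions(intervention(2, 30, 1), cfg)
  expect_true(all(c30$en_rate >= 30))
  c40 <- candidate_interventions(intervention(2, 40, 1), cfg)
  expect_equal(max(c40$en_rate), 70)
  expect_true(all(abs(c40$insulin_rate - 2) <= cfg$max_insulin_step + 1e-9))
  expect_true(all(c40$insulin_rate %in% cfg$insulin_grid))
  # current intervention always present
  expect_true(any(c40$en_rate == 40 & c40$insulin_rate == 2))
  # a 2 h interval doubles the reachable nutrition change
  c2h <- candidate_interventions(intervention(2, 40, 1), cfg, interval = 2)
  expect_equal(max(c2h$en_rate), 100)
})

test_that("nutrition is raised whenever predictions allow it", {
  # stable mid-band patient, deterministic forecast
  p <- icing_params(SI = 5e-4)
  u <- patient_inputs(uex = insulin_U_h_to_mU_min(2), uen = 0.3)
  s0 <- warm_state(p, u, g0 = 6.5)
  dec <- select_intervention(s0, 5e-4, si_lognormal_walk(0),
                             intervention(2, 60, 1), 1800, cfg, params = p)
  expect_equal(dec$intervention$en_rate, 90) # 60 + 30
  expect_true(dec$feasible)
  expect_false(dec$risk_warning)
})

test_that("nutrition is cut once the insulin route is exhausted", {
  # insulin-resistant hyperglycaemic patient already at the maximum insulin
  # rate: no insulin raise is available, so BG can only be brought down by
  # reducing nutrition
  p <- icing_params(SI = 1e-4)
  u <- patient_inputs(uex = insulin_U_h_to_mU_min(6), uen = 0.34)
  s0 <- warm_state(p, u, g0 = 10)
  dec <- select_intervention(s0, 1e-4, si_lognormal_walk(0.05),
                             intervention(6, 80, 1), 1800, cfg, params = p)
  expect_lt(dec$intervention$en_rate, 80)
})

test_that("equally good candidates resolve to the lower insulin rate", {
  # fully saturated insulin effect: every candidate at the top EN rate gives
  # the same in-band prediction, so the tie-break must pick the lowest
  # reachable insulin rate
  p <- icing_params(SI = 8.8e-3, alphaG = 1)
  u <- patient_inputs(uex = insulin_U_h_to_mU_min(2),
                      uen = en_pct_to_glucose_mmol_min(100, 1800))
  s0 <- warm_state(p, u, g0 = 7)
  dec <- select_intervention(s0, 8.8e-3, si_lognormal_walk(0),
                             intervention(2, 100, 1), 1800, cfg, params = p)
  expect_equal(dec$intervention$insulin_rate, 0)
})

test_that("tightening the risk constraint never raises selected nutrition", {
  set.seed(21)
  cfg5 <- controller_config(risk = 0.05)
  cfg1 <- controller_config(risk = 0.01)
  model <- si_lognormal_walk(0.25)
  for (i in 1:12) {
    si <- exp(runif(1, log(2e-4), log(1.5e-3)))
    p <- icing_params(SI = si)
    u <- patient_inputs(uex = insulin_U_h_to_mU_min(runif(1, 0, 4)),
                        uen = runif(1, 0.1, 0.5))
    s0 <- warm_state(p, u, g0 = runif(1, 5, 9))
    cur <- intervention(round(runif(1, 0, 4) * 2) / 2,
                        sample(seq(30, 100, 10), 1), 1)
    d5 <- select_intervention(s0, si, model, cur, 1800, cfg5, params = p)
    d1 <- select_intervention(s0, si, model, cur, 1800, cfg1, params = p)
    expect_lte(d1$intervention$en_rate, d5$intervention$en_rate)
  }
})

test_that("an infeasible decision state returns the safest option, flagged", {
  p <- icing_params(SI = 3e-3)
  s0 <- patient_state(G = 4.6, I = 60, Q = 50)
  dec <- select_intervention(s0, 3e-3, si_lognormal_walk(0.6),
                             intervention(4, 100, 1), 2400, cfg, params = p)
  expect_true(dec$risk_warning)
  expect_false(dec$feasible)
  # the safest option feeds maximally: glucose input props BG up against the
  # imminent insulin-driven fall
  expect_equal(dec$intervention$en_rate, 100)
})

test_that("deterministic closed loop settles into the band at full feed", {
  pat <- list(params = icing_params(SI = 5e-4), si_hourly = rep(5e-4, 48),
              G0 = 10, I0 = 15, Q0 = 10, goal_kcal = 1800, id = "D1")
  log <- run_closed_loop(pat, si_lognormal_walk(0), duration_h = 48)
  r <- log$records
  bg <- r$bg_mmol_L[!is.na(r$bg_mmol_L)]
  expect_true(all(tail(bg, 24) >= 4.4 & tail(bg, 24) <= 8.0))
  expect_equal(tail(100 * r$en_kcal_h / (1800 / 24), 1), 100, tolerance = 1e-9)
  # with identified SI equal to truth, predictions bracket realized BG
  d <- attr(log, "decisions")
  meas <- attr(log, "measurements")
  realized <- meas$value[match((d$t_h + 1) * 60, meas$t)]
  ok <- !is.na(realized)
  expect_true(all(realized[ok] >= d$bg_pred_low[ok] - 0.01))
  expect_true(all(realized[ok] <= d$bg_pred_high[ok] + 0.01))
})

test_that("closed-loop nutrition obeys the protocol bounds and step limits", {
  spec <- cohort_spec(n_patients = 3, seed = 31)
  co <- generate_cohort(spec, horizon_h = 36)
  model <- si_lognormal_walk(0.1)
  for (pat in co) {
    log <- suppressWarnings(run_closed_loop(pat, model, duration_h = 36))
    r <- log$records
    gc <- r$on_gc == 1 & !vapply(seq_len(nrow(r)), function(i)
      isTRUE(pat$en_interrupted[i]), logical(1))
    en_pct <- 100 * r$en_kcal_h / (log$goal_kcal / 24)
    expect_true(all(en_pct[gc] >= 30 - 1e-9 & en_pct[gc] <= 100 + 1e-9))
    d <- attr(log, "decisions")
    expect_true(all(abs(diff(d$en_pct)) <= 30 * max(diff(d$t_h)) + 1e-9))
  }
})
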
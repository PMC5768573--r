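test_that("percent of goal per day is rate-based over observed GC hours", {
  # constant delivery at exactly the goal rate
  lg <- log_from_rates(rep(100, 48), goal = 2400)
  d <- pct_goal_per_day(lg)
  expect_equal(d$pct_goal, c(100, 100))
  # EN at 80% plus PN at 30% exceeds the goal
  lg2 <- log_from_rates(rep(80, 24), goal = 2400, pn_pct = 30)
  expect_equal(pct_goal_per_day(lg2)$pct_goal, 110)
  # only 12 observed GC hours that day, at 50% of the goal rate
  lg3 <- log_from_rates(rep(50, 24), goal = 2400,
                        on_gc = rep(c(1L, 0L), each = 12))
  d3 <- pct_goal_per_day(lg3)
  expect_equal(d3$pct_goal, 50)
  expect_equal(d3$hours_observed, 12)
  expect_error(treatment_log(lg3$records, "X", goal_kcal = 0), "goal_kcal")
})

test_that("the exclusion rule drops strictly-below-floor hours only", {
  pct <- c(rep(0, 10), rep(80, 90))
  lg <- apply_exclusion(log_from_rates(pct), floor = 30)
  expect_equal(attr(lg, "excluded_pct"), 10)
  expect_equal(sum(lg$records$excluded), 10)
  # exactly at the floor is retained
  lg2 <- apply_exclusion(log_from_rates(c(30, 80)), floor = 30)
  expect_equal(sum(lg2$records$excluded), 0)
  # all at or above the floor: a no-op
  lg3 <- apply_exclusion(log_from_rates(rep(50, 20)), floor = 30)
  expect_identical(lg3$records[names(lg3$records) != "excluded"],
                   log_from_rates(rep(50, 20))$records)
  # raising the floor can only shrink retention and raise the mean
  lg4a <- apply_exclusion(log_from_rates(c(rep(35, 10), rep(90, 10))), 30)
  lg4b <- apply_exclusion(log_from_rates(c(rep(35, 10), rep(90, 10))), 50)
  s_a <- per_patient_stats(list(lg4a))$per_patient
  s_b <- per_patient_stats(list(lg4b))$per_patient
  expect_lt(s_a$hours, 21)
  expect_gt(s_b$mean_pct, s_a$mean_pct)
})

test_that("per-patient feed statistics match hand computation", {
  lg <- log_from_rates(rep(90, 30))
  s <- per_patient_stats(list(lg))$per_patient
  expect_equal(s$mean_pct, 90)
  expect_equal(s$sd_pct, 0)
  # alternating 60/100 in equal hours: mean 80, sample SD just over 20
  pct <- rep(c(60, 100), 24)
  s2 <- per_patient_stats(list(log_from_rates(pct)))$per_patient
  expect_equal(s2$mean_pct, 80)
  expect_equal(s2$sd_pct, 20 * sqrt(48 / 47), tolerance = 1e-12)
  # identical patients give zero-width cohort IQR
  logs <- lapply(1:5, function(i) log_from_rates(rep(c(60, 100), 24),
                                                 id = paste0("P", i)))
  coh <- per_patient_stats(logs)$cohort
  expect_equal(coh["mean_pct", "q25"], coh["mean_pct", "q75"])
})

test_that("threshold exceedance counts strictly-above patients per day", {
  logs <- lapply(1:4, function(i)
    log_from_rates(rep(c(100, 100, 80, 90)[i], 24), id = paste0("P", i)))
  ds <- cohort_day_summary(logs)
  ex <- threshold_exceedance(ds, 85)
  expect_equal(ex$pct_above, 75) # 100, 100, 90 exceed; 80 does not
  ex90 <- threshold_exceedance(ds, 90)
  expect_equal(ex90$pct_above, 50) # strict: 90 does not exceed 90
  # per-day reference curve
  ref <- data.frame(day = 1, reference = 95)
  expect_equal(threshold_exceedance(ds, ref)$pct_above, 50)
})

test_that("day-boundary records split proportionally and conserve calories", {
  # 90-min records straddling the day boundary
  n <- 40
  rec <- data.frame(t_min = (seq_len(n) - 1) * 90, bg_mmol_L = NA_real_,
                    insulin_U_h = 0,
                    en_kcal_h = runif(n, 40, 110),
                    pn_kcal_h = 0, on_gc = 1L)
  set.seed(5)
  lg <- treatment_log(rec, "B1", goal_kcal = 2000)
  d <- pct_goal_per_day(lg)
  hours <- rep(1.5, n)
  expect_equal(sum(d$kcal), sum(rec$en_kcal_h * hours))
  expect_equal(sum(d$hours_observed), sum(hours))
  expect_equal(nrow(d), 3) # 60 h span 3 ICU days
})

test_that("cohort medians and IQRs reproduce a brute-force percentile count", {
  set.seed(9)
  logs <- lapply(1:7, function(i)
    log_from_rates(pmax(30, pmin(100, round(rnorm(48, 70, 15)))),
                   id = paste0("P", i)))
  ds <- cohort_day_summary(logs)
  for (dd in ds$cohort$day) {
    v <- ds$per_patient_day$pct_goal[ds$per_patient_day$day == dd]
    row <- ds$cohort[ds$cohort$day == dd, ]
    expect_equal(row$median, median(v))
    expect_true(row$q25 <= row$median && row$median <= row$q75)
    expect_equal(row$n, 7)
    # brute-force exceedance count
    expect_equal(threshold_exceedance(ds, 85)$pct_above[dd],
                 100 * sum(v > 85) / length(v))
  }
})

test_that("treatment logs survive a CSV round trip", {
  lg <- log_from_rates(round(runif(30, 30, 100)), goal = 1800, pn_pct = 10)
  path <- tempfile(fileext = ".csv")
  write_treatment_log(lg, path)
  lg2 <- read_treatment_log(path)
  expect_equal(lg2$goal_kcal, 1800)
  expect_equal(lg2$records$en_kcal_h, lg$records$en_kcal_h)
  expect_equal(lg2$patient_id, lg$patient_id)
  unlink(path)
})

test_that("analytics reproduce the generator's analytic ground truth exactly", {
  fx <- make_fixture_logs(cohort_spec(n_patients = 4, seed = 13), days = 3)
  for (id in names(fx$logs)) {
    tru <- fx$truth[fx$truth$patient_id == id, ]
    # before exclusion
    d_all <- pct_goal_per_day(fx$logs[[id]])
    expect_equal(d_all$pct_goal, tru$pct_goal_all[match(d_all$day, tru$day)],
                 tolerance = 1e-10)
    # after the 30% exclusion rule
    d_ex <- pct_goal_per_day(apply_exclusion(fx$logs[[id]], 30))
    keep <- !is.na(tru$pct_goal_excl)
    expect_equal(d_ex$day, tru$day[keep])
    expect_equal(d_ex$pct_goal, tru$pct_goal_excl[keep], tolerance = 1e-10)
  }
})
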
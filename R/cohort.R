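#' Specification of a synthetic virtual-patient cohort
#'
#' Defaults emulate a mixed medical-surgical adult ICU population requiring
#' glycaemic control: age centred in the 60-79 band, two-thirds male, mostly
#' medium-framed (so the median caloric goal sits near 1800 kcal/day);
#' insulin sensitivity starts lognormal and follows an hourly lognormal
#' random walk whose volatility decays over the stay as the metabolic state
#' stabilises; enteral feeding is interrupted by a Poisson process with
#' lognormal durations (surgery, imaging, gastric intolerance); a fraction
#' of patients receive clinician-set parenteral nutrition.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed RNG seed.
#' @param frame_probs probabilities of small/medium/large frame (sum to 1).
#' @param age_mean,age_sd age distribution (years, truncated at 16).
#' @param p_male probability of male sex.
#' @param si0_median,si0_sdlog initial-SI lognormal distribution
#'   (L/(mU min)).
#' @param sigma_w_0 initial hourly log-SI volatility (per h).
#' @param sigma_w_floor long-run volatility floor (per h).
#' @param sigma_w_tau volatility e-folding time (h); volatility at hour t is
#'   \code{floor + (sigma_w_0 - floor) * exp(-t / tau)}.
#' @param interrupt_rate feeding-interruption rate (events per hour).
#' @param interrupt_dur_med,interrupt_dur_sdlog lognormal interruption
#'   duration (h).
#' @param pn_prob probability a patient receives any PN.
#' @param pn_pct_med,pn_pct_sdlog lognormal PN rate (% of caloric goal).
#' @param stay_med,stay_sdlog lognormal ICU stay length (days).
#' @param G0_range initial BG range (mmol/L), uniform (hyperglycaemic
#'   admission).
#' @return An object of class \code{cohort_spec}.
#' @examples cohort_spec(n_patients = 5, seed = 1)
#' @export
cohort_spec <- function(n_patients = 50, seed = 1,
                        frame_probs = c(small = 0.25, medium = 0.5,
                                        large = 0.25),
                        age_mean = 63, age_sd = 13, p_male = 0.661,
                        si0_median = 4e-4, si0_sdlog = 0.45,
                        sigma_w_0 = 0.10, sigma_w_floor = 0.05,
                        sigma_w_tau = 36,
                        interrupt_rate = 0.03, interrupt_dur_med = 4,
                        interrupt_dur_sdlog = 0.5,
                        pn_prob = 0.468, pn_pct_med = 6.4,
                        pn_pct_sdlog = 1.68,
                        stay_med = 8.4, stay_sdlog = 1.19,
                        G0_range = c(8.5, 12)) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (abs(sum(frame_probs) - 1) > 1e-9) stop("frame_probs must sum to 1")
  if (si0_sdlog <= 0 || sigma_w_0 < 0 || sigma_w_floor < 0)
    stop("volatilities must be non-negative and si0_sdlog positive")
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

# volatility schedule (per h) at hours tt since admission
.sigma_w_at <- function(spec, tt) {
  spec$sigma_w_floor +
    (spec$sigma_w_0 - spec$sigma_w_floor) * exp(-tt / spec$sigma_w_tau)
}

#' Generate a synthetic virtual-patient cohort
#'
#' Draws demographics, caloric goals, model parameters, hourly
#' insulin-sensitivity trajectories, feeding-interruption schedules and PN
#' schedules per the spec. Reproducible: the same spec (including its seed)
#' yields an identical cohort.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param horizon_h hours of SI trajectory / schedules to generate per
#'   patient (default covers the simulated stay, capped at 14 days).
#' @return A list of class \code{star_cohort}; each element is a patient
#'   list with \code{id}, \code{demographics}, \code{goal_kcal},
#'   \code{params}, \code{si_hourly}, \code{G0}, \code{I0}, \code{Q0},
#'   \code{stay_h}, \code{en_interrupted} (hourly logical),
#'   \code{pn_kcal_h} (hourly vector).
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 3, seed = 7))
#' co[[1]]$goal_kcal
#' @export
generate_cohort <- function(spec, horizon_h = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  frames <- c("small", "medium", "large")
  out <- lapply(seq_len(spec$n_patients), function(i) {
    frame <- sample(frames, 1, prob = spec$frame_probs)
    age <- max(16, rnorm(1, spec$age_mean, spec$age_sd))
    sex <- if (runif(1) < spec$p_male) "male" else "female"
    demo <- demographics(frame, age, sex)
    goal <- daily_goal_kcal(demo)
    stay_h <- max(24, round(24 * rlnorm(1, log(spec$stay_med),
                                        spec$stay_sdlog)))
    H <- if (is.null(horizon_h)) min(stay_h, 14 * 24) else horizon_h
    # hourly SI random walk with decaying volatility
    si0 <- rlnorm(1, log(spec$si0_median), spec$si0_sdlog)
    sw <- .sigma_w_at(spec, seq_len(H) - 1)
    si <- si0 * exp(cumsum(c(0, sw[-H] * rnorm(H - 1))))
    si <- pmin(pmax(si, .si_bounds[1]), .si_bounds[2])
    # non-overlapping feeding interruptions (Poisson onsets, lognormal
    # durations)
    interrupted <- rep(FALSE, H)
    t_ev <- 0
    while (TRUE) {
      t_ev <- t_ev + rexp(1, spec$interrupt_rate)
      if (t_ev >= H) break
      dur <- rlnorm(1, log(spec$interrupt_dur_med), spec$interrupt_dur_sdlog)
      hrs <- seq(floor(t_ev) + 1, min(H, ceiling(t_ev + dur)))
      interrupted[hrs] <- TRUE
      t_ev <- t_ev + dur
    }
    # clinician-set PN: a contiguous block of days at a constant rate
    pn <- rep(0, H)
    if (runif(1) < spec$pn_prob) {
      pn_pct <- min(rlnorm(1, log(spec$pn_pct_med), spec$pn_pct_sdlog), 100)
      pn_days <- max(1, round(rlnorm(1, log(2), 0.9)))
      pn_start_h <- sample.int(max(1, H - 24), 1)
      pn_hrs <- pn_start_h:min(H, pn_start_h + pn_days * 24 - 1)
      pn[pn_hrs] <- pn_pct / 100 * goal / 24
    }
    list(id = sprintf("P%03d", i), demographics = demo, goal_kcal = goal,
         params = icing_params(SI = si0),
         si_hourly = si, G0 = runif(1, spec$G0_range[1], spec$G0_range[2]),
         I0 = 15, Q0 = 10, stay_h = stay_h,
         en_interrupted = interrupted, pn_kcal_h = pn)
  })
  structure(out, class = "star_cohort", spec = spec)
}

#' @export
print.star_cohort <- function(x, ...) {
  goals <- vapply(x, `[[`, 0, "goal_kcal")
  pn_any <- vapply(x, function(p) any(p$pn_kcal_h > 0), logical(1))
  cat(sprintf("Synthetic ICU cohort: %d patients\n", length(x)))
  cat(sprintf("  caloric goal median %.0f [%.0f-%.0f] kcal/day\n",
              median(goals), quantile(goals, 0.25), quantile(goals, 0.75)))
  cat(sprintf("  PN in %.0f%% of patients\n", 100 * mean(pn_any)))
  invisible(x)
}

#' Write a cohort to CSV
#' @param cohort a \code{star_cohort}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- do.call(rbind, lapply(cohort, function(p) data.frame(
    patient_id = p$id, frame = p$demographics$frame,
    age = p$demographics$age, sex = p$demographics$sex,
    goal_kcal = p$goal_kcal, si0 = p$si_hourly[1], G0 = p$G0,
    stay_h = p$stay_h, pn_any = as.integer(any(p$pn_kcal_h > 0)))))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Build SI transitions for stochastic-model training
#'
#' Collects hourly (SI now, SI next) pairs from a cohort's truth
#' trajectories - the training set a clinical implementation would build
#' from retrospective identified-SI series.
#'
#' @param cohort a \code{star_cohort}, or a list of numeric SI series.
#' @param max_hours cap on hours used per patient.
#' @return Data frame with columns \code{si_now}, \code{si_next},
#'   \code{gap} (1 h).
#' @export
si_transitions <- function(cohort, max_hours = Inf) {
  series <- lapply(cohort, function(p)
    if (is.list(p)) p$si_hourly else p)
  do.call(rbind, lapply(series, function(s) {
    s <- s[seq_len(min(length(s), max_hours))]
    if (length(s) < 2) return(NULL)
    data.frame(si_now = s[-length(s)], si_next = s[-1], gap = 1)
  }))
}

#' Fixture treatment logs with known ground truth
#'
#' Builds hourly treatment logs directly from generated feeding schedules
#' (no physiology involved) together with analytically computed per-day
#' percent-of-goal values, before and after the 30% exclusion rule - an
#' oracle for the analytics pipeline.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param days days of log per patient.
#' @param floor exclusion floor (% goal) used for the post-exclusion truth.
#' @return List with \code{logs} (list of \code{\link{treatment_log}}s) and
#'   \code{truth}: data frame of patient_id, day, \code{pct_goal_all}
#'   (no exclusion), \code{pct_goal_excl} (after exclusion; NA if the whole
#'   day is excluded).
#' @examples
#' fx <- make_fixture_logs(cohort_spec(n_patients = 2, seed = 3), days = 2)
#' fx$truth
#' @export
make_fixture_logs <- function(spec, days = 4, floor = 30) {
  stopifnot(inherits(spec, "cohort_spec"))
  co <- generate_cohort(spec, horizon_h = days * 24)
  set.seed(spec$seed + 1)
  logs <- list()
  truth <- list()
  for (p in co) {
    H <- days * 24
    # patient-specific tolerated EN rate, varying mildly hour to hour
    base <- runif(1, 40, 100)
    en_pct <- pmin(100, pmax(30, round(base + 5 * rnorm(H))))
    en_pct[p$en_interrupted[seq_len(H)]] <- 0
    en_kcal_h <- en_pct / 100 * p$goal_kcal / 24
    pn_kcal_h <- p$pn_kcal_h[seq_len(H)]
    bg <- round(rnorm(H, 6.6, 1.0), 1)
    rec <- data.frame(t_min = (seq_len(H) - 1) * 60, bg_mmol_L = bg,
                      insulin_U_h = 2, en_kcal_h = en_kcal_h,
                      pn_kcal_h = pn_kcal_h, on_gc = 1L)
    lg <- treatment_log(rec, p$id, p$goal_kcal)
    logs[[p$id]] <- lg
    # analytic ground truth, straight from the schedule arithmetic
    rate_pct <- 100 * (en_kcal_h + pn_kcal_h) / (p$goal_kcal / 24)
    day_of <- rep(seq_len(days), each = 24)
    for (dd in seq_len(days)) {
      v <- rate_pct[day_of == dd]
      kept <- v[v >= floor]
      truth[[length(truth) + 1]] <- data.frame(
        patient_id = p$id, day = dd, pct_goal_all = mean(v),
        pct_goal_excl = if (length(kept)) mean(kept) else NA_real_)
    }
  }
  list(logs = logs, truth = do.call(rbind, truth))
}
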
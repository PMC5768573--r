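#' One prescribed treatment interval
#' @param insulin_rate IV insulin rate (U/h), >= 0.
#' @param en_rate enteral nutrition rate (% of daily caloric goal); while on
#'   glycaemic control the protocol holds this in [30, 100].
#' @param interval intervention length (h): 1, 2 or 3.
#' @return An object of class \code{intervention}.
#' @examples intervention(2, 100, 1)
#' @export
intervention <- function(insulin_rate, en_rate, interval = 1) {
  if (insulin_rate < 0) stop("insulin_rate must be >= 0")
  if (en_rate < 30 || en_rate > 100)
    stop("en_rate must lie in [30, 100] % of goal while on GC")
  if (!interval %in% c(1, 2, 3)) stop("interval must be 1, 2 or 3 h")
  structure(list(insulin_rate = insulin_rate, en_rate = en_rate,
                 interval = interval), class = "intervention")
}

#' Controller configuration
#'
#' Settings of the dosing logic: the target band, the hypoglycaemia risk
#' constraint, nutrition modulation limits (30-100% of goal, at most
#' +/- 30% of goal per hour), the insulin grid, and the protocol start rule
#' (two successive BG over 8.0 mmol/L within 4 h).
#'
#' @param bg_band target BG band (mmol/L).
#' @param hypo_threshold light-hypoglycaemia limit the risk constraint
#'   protects (mmol/L); 4.4 by default, 4.6 is the common upper alternative.
#' @param risk accepted probability of BG below \code{hypo_threshold} (0.05).
#' @param en_min,en_max nutrition modulation range (% goal).
#' @param max_nutrition_step maximum EN change (% goal per hour).
#' @param en_step granularity of candidate EN rates (% goal).
#' @param insulin_grid allowed insulin rates (U/h).
#' @param max_insulin_step maximum insulin change per intervention (U/h).
#' @param start_bg_threshold,start_window start rule: two successive BG above
#'   this threshold (mmol/L) within this window (h).
#' @param min_descent when all predictions lie above the band, the minimum
#'   required predicted BG fall (mmol/L per h) before nutrition is reduced.
#' @param si_prior fallback SI (L/(mU min)) when an interval is
#'   unidentifiable and no previous estimate exists.
#' @param interval_options allowed measurement intervals (h); the first is
#'   the default, longer ones are taken only when the predicted interval
#'   lies wholly inside the band.
#' @param feed \code{\link{feed_composition}}.
#' @return An object of class \code{controller_config}.
#' @examples controller_config(risk = 0.01)
#' @export
controller_config <- function(bg_band = c(4.4, 8.0), hypo_threshold = 4.4,
                              risk = 0.05, en_min = 30, en_max = 100,
                              max_nutrition_step = 30, en_step = 10,
                              insulin_grid = seq(0, 6, by = 0.5),
                              max_insulin_step = 2,
                              start_bg_threshold = 8.0, start_window = 4,
                              min_descent = 0.3, si_prior = 4e-4,
                              interval_options = 1,
                              feed = feed_composition()) {
  if (risk <= 0 || risk >= 0.5) stop("risk must lie in (0, 0.5)")
  if (bg_band[1] >= bg_band[2]) stop("bg_band lower must be below upper")
  if (hypo_threshold <= 0 || start_bg_threshold <= 0 || start_window <= 0)
    stop("thresholds must be positive")
  structure(list(bg_band = bg_band, hypo_threshold = hypo_threshold,
                 risk = risk, en_min = en_min, en_max = en_max,
                 max_nutrition_step = max_nutrition_step, en_step = en_step,
                 insulin_grid = sort(insulin_grid),
                 max_insulin_step = max_insulin_step,
                 start_bg_threshold = start_bg_threshold,
                 start_window = start_window, min_descent = min_descent,
                 si_prior = si_prior, interval_options = interval_options,
                 feed = feed), class = "controller_config")
}

#' Should glycaemic control start?
#'
#' Start rule: two successive BG measurements both above the start threshold
#' (8.0 mmol/L) and no more than the start window (4 h) apart.
#'
#' @param history data frame with columns \code{t} (min) and \code{value}
#'   (mmol/L), time-ordered, or a list of \code{\link{bg_measurement}}s.
#' @param cfg \code{\link{controller_config}}.
#' @return logical.
#' @examples
#' should_start(data.frame(t = c(0, 120), value = c(8.5, 8.2)),
#'              controller_config())
#' @export
should_start <- function(history, cfg = controller_config()) {
  if (is.list(history) && !is.data.frame(history) && length(history) &&
      inherits(history[[1]], "bg_measurement")) {
    history <- data.frame(t = vapply(history, `[[`, 0, "t"),
                          value = vapply(history, `[[`, 0, "value"))
  }
  if (NROW(history) < 2) return(FALSE)
  if (is.unsorted(history$t)) stop("history must be time-ordered")
  over <- history$value > cfg$start_bg_threshold
  gap_ok <- diff(history$t) <= cfg$start_window * 60
  any(over[-length(over)] & over[-1] & gap_ok)
}

#' Enumerate candidate interventions
#'
#' All insulin/EN combinations reachable from the current intervention:
#' EN within [30, 100]% of goal and within +/- 30% of goal per hour of the
#' current rate; insulin on the configured grid within the maximum step.
#' The current intervention is always included.
#'
#' @param current current \code{\link{intervention}}.
#' @param cfg \code{\link{controller_config}}.
#' @param interval candidate interval length (h); default the current one.
#' @return Data frame with columns \code{insulin_rate}, \code{en_rate},
#'   \code{interval}.
#' @examples
#' nrow(candidate_interventions(intervention(2, 70), controller_config()))
#' @export
candidate_interventions <- function(current, cfg = controller_config(),
                                    interval = current$interval) {
  stopifnot(inherits(current, "intervention"))
  en_lo <- max(cfg$en_min, current$en_rate - cfg$max_nutrition_step * interval)
  en_hi <- min(cfg$en_max, current$en_rate + cfg$max_nutrition_step * interval)
  en <- seq(ceiling(en_lo / cfg$en_step) * cfg$en_step, en_hi, by = cfg$en_step)
  en <- sort(unique(c(en, en_lo, en_hi,
                      min(max(current$en_rate, cfg$en_min), cfg$en_max))))
  en <- en[en >= en_lo - 1e-9 & en <= en_hi + 1e-9]
  ins <- cfg$insulin_grid[abs(cfg$insulin_grid - current$insulin_rate) <=
                            cfg$max_insulin_step + 1e-9]
  ins <- sort(unique(c(ins, current$insulin_rate)))
  out <- expand.grid(insulin_rate = ins, en_rate = en, interval = interval,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(-out$en_rate, out$insulin_rate), , drop = FALSE]
}

#' Select the next insulin/nutrition intervention
#'
#' The dosing decision: enumerate reachable interventions, bound each one's
#' BG outcome by forward simulation at the 5th/95th forecast percentiles of
#' insulin sensitivity, discard any whose lower (5th-percentile) BG bound
#' falls below the hypoglycaemia threshold at any point of the interval, and
#' choose by preference: highest nutrition first; within a nutrition rate,
#' the candidate whose predicted BG interval best overlaps the 4.4-8.0 band;
#' ties go to less insulin. A nutrition rate is only accepted if some
#' hypo-safe insulin choice either overlaps the band or (when every
#' prediction sits above the band) descends by at least \code{min_descent}
#' per hour - otherwise nutrition is reduced, realising the
#' insulin-before-nutrition preference. If no candidate is hypo-safe the
#' safest one (maximum predicted lower bound) is returned flagged
#' \code{risk_warning}.
#'
#' @param state current \code{\link{patient_state}} (G = latest measurement).
#' @param si_now current identified insulin sensitivity (L/(mU min)).
#' @param model fitted \code{si_stochastic} forecast model.
#' @param current current \code{\link{intervention}}.
#' @param goal_kcal daily caloric goal (kcal/day).
#' @param cfg \code{\link{controller_config}}.
#' @param params \code{\link{icing_params}} used for prediction (its
#'   \code{SI} is replaced by the forecast percentiles).
#' @param pn_kcal_h clinician-set parenteral rate (kcal/h), not modulated.
#' @param interval intervention length (h); default the first configured
#'   option.
#' @return List with elements \code{intervention}, end-of-interval bounds
#'   \code{bg_low}, \code{bg_high}, worst-case \code{bg_low_min},
#'   \code{si_bounds}, \code{feasible} and \code{risk_warning}.
#' @examples
#' dec <- select_intervention(patient_state(G = 9, I = 20, Q = 15), 5e-4,
#'                            si_lognormal_walk(0.1), intervention(1, 70),
#'                            goal_kcal = 1800)
#' dec$intervention
#' @export
select_intervention <- function(state, si_now, model, current, goal_kcal,
                                cfg = controller_config(),
                                params = icing_params(), pn_kcal_h = 0,
                                interval = cfg$interval_options[1]) {
  stopifnot(inherits(state, "patient_state"), inherits(model, "si_stochastic"))
  si_b <- predict(model, si_now, c(cfg$risk, 1 - cfg$risk), gap = interval)
  cand <- candidate_interventions(current, cfg, interval)
  y0 <- unclass(state)[-1]
  pvec <- .param_vector(params)
  upn <- kcal_h_to_glucose_mmol_min(pn_kcal_h, cfg$feed$pn_cho_frac, cfg$feed)
  horizon <- interval * 60
  band <- cfg$bg_band
  bg_now <- y0[["G"]]

  ev <- lapply(seq_len(nrow(cand)), function(i) {
    uex <- insulin_U_h_to_mU_min(cand$insulin_rate[i])
    uen <- en_pct_to_glucose_mmol_min(cand$en_rate[i], goal_kcal, cfg$feed)
    g_lo <- .icing_rk4(y0, `[<-`(pvec, 2, si_b[2]), uex, uen, upn,
                       0, horizon, 1)[, 2]
    g_hi <- .icing_rk4(y0, `[<-`(pvec, 2, si_b[1]), uex, uen, upn,
                       0, horizon, 1)[, 2]
    n <- length(g_lo)
    lo_end <- g_lo[n]; hi_end <- g_hi[n]
    w <- hi_end - lo_end
    overlap <- if (w < 1e-9) {
      as.numeric(lo_end >= band[1] && lo_end <= band[2])
    } else {
      max(0, min(hi_end, band[2]) - max(lo_end, band[1])) / w
    }
    list(lo_min = min(g_lo), lo_end = lo_end, hi_end = hi_end,
         overlap = overlap)
  })
  lo_min <- vapply(ev, `[[`, 0, "lo_min")
  lo_end <- vapply(ev, `[[`, 0, "lo_end")
  hi_end <- vapply(ev, `[[`, 0, "hi_end")
  overlap <- vapply(ev, `[[`, 0, "overlap")
  safe <- lo_min >= cfg$hypo_threshold

  pick <- function(i, feasible, warn = FALSE) {
    list(intervention = intervention(cand$insulin_rate[i], cand$en_rate[i],
                                     interval),
         bg_low = lo_end[i], bg_high = hi_end[i], bg_low_min = lo_min[i],
         si_bounds = si_b, feasible = feasible, risk_warning = warn)
  }

  for (en in sort(unique(cand$en_rate), decreasing = TRUE)) {
    at_en <- which(cand$en_rate == en & safe)
    if (!length(at_en)) next
    with_overlap <- at_en[overlap[at_en] > 0]
    if (length(with_overlap)) {
      best <- with_overlap[order(-overlap[with_overlap],
                                 cand$insulin_rate[with_overlap])][1]
      return(pick(best, TRUE))
    }
    # everything hypo-safe at this EN predicts above band: accept only if it
    # descends usefully, else try less nutrition
    if (min(lo_end[at_en]) > band[2]) {
      descending <- at_en[hi_end[at_en] <= bg_now - cfg$min_descent * interval]
      if (length(descending)) {
        best <- descending[order(hi_end[descending],
                                 cand$insulin_rate[descending])][1]
        return(pick(best, TRUE))
      }
    }
  }
  if (any(safe)) {
    # stuck above band even at minimum nutrition: drive BG down as fast as
    # safely possible
    idx <- which(safe)
    best <- idx[order(hi_end[idx], cand$insulin_rate[idx])][1]
    return(pick(best, TRUE))
  }
  best <- which.max(lo_min)
  pick(best, FALSE, warn = TRUE)
}
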
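#' Time-stamped per-patient treatment log
#'
#' The unit of the nutrition-delivery analytics: a record of BG measurements,
#' insulin, and enteral/parenteral caloric rates, with times in minutes since
#' ICU admission. Rows are piecewise-constant: each row's rates hold from its
#' \code{t_min} until the next row (the last row inherits the preceding
#' duration).
#'
#' @param records data frame with columns \code{t_min}, \code{bg_mmol_L}
#'   (NA when no measurement), \code{insulin_U_h}, \code{en_kcal_h},
#'   \code{pn_kcal_h}, \code{on_gc} (0/1).
#' @param patient_id identifier.
#' @param goal_kcal daily caloric goal (kcal/day), > 0.
#' @param admission admission timestamp (informative only; times are
#'   relative minutes).
#' @return An object of class \code{treatment_log}.
#' @export
treatment_log <- function(records, patient_id, goal_kcal,
                          admission = "2026-01-01T00:00:00") {
  need <- c("t_min", "bg_mmol_L", "insulin_U_h", "en_kcal_h", "pn_kcal_h",
            "on_gc")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(records$t_min, strictly = TRUE))
    stop("record times must be strictly increasing")
  rates <- c(records$insulin_U_h, records$en_kcal_h, records$pn_kcal_h)
  if (any(rates < 0, na.rm = TRUE)) stop("rates must be non-negative")
  if (!is.numeric(goal_kcal) || goal_kcal <= 0) stop("goal_kcal must be > 0")
  structure(list(records = as.data.frame(records), patient_id = patient_id,
                 goal_kcal = goal_kcal, admission = admission),
            class = "treatment_log")
}

#' @export
print.treatment_log <- function(x, ...) {
  r <- x$records
  cat(sprintf("Treatment log %s: %d records over %.1f h, goal %.0f kcal/day\n",
              x$patient_id, nrow(r), diff(range(r$t_min)) / 60, x$goal_kcal))
  cat(sprintf("  on GC: %.0f%% of records; BG measured at %d times\n",
              100 * mean(r$on_gc), sum(!is.na(r$bg_mmol_L))))
  invisible(x)
}

#' @export
summary.treatment_log <- function(object, ...) {
  r <- object$records
  gc <- r[r$on_gc == 1, , drop = FALSE]
  bg <- gc$bg_mmol_L[!is.na(gc$bg_mmol_L)]
  out <- list(
    patient_id = object$patient_id,
    hours = sum(.record_hours(r)),
    gc_hours = sum(.record_hours(r)[r$on_gc == 1]),
    bg_median = median(bg), bg_in_band = mean(bg >= 4.4 & bg <= 8.0),
    bg_below_44 = mean(bg < 4.4),
    mean_feed_pct = mean(100 * (gc$en_kcal_h + gc$pn_kcal_h) /
                           (object$goal_kcal / 24)))
  class(out) <- "summary.treatment_log"
  out
}

#' @export
print.summary.treatment_log <- function(x, ...) {
  cat(sprintf("Patient %s: %.0f h logged (%.0f h on GC)\n", x$patient_id,
              x$hours, x$gc_hours))
  cat(sprintf("  BG median %.2f mmol/L; %.1f%% in 4.4-8.0; %.2f%% < 4.4\n",
              x$bg_median, 100 * x$bg_in_band, 100 * x$bg_below_44))
  cat(sprintf("  mean feed rate %.1f%% of goal\n", x$mean_feed_pct))
  invisible(x)
}

# per-row durations in hours (row holds until next row; last row inherits)
.record_hours <- function(records) {
  t_h <- records$t_min / 60
  if (nrow(records) == 1) return(1)
  d <- diff(t_h)
  c(d, d[length(d)])
}

#' Write / read a treatment log as CSV
#'
#' Plain-text interchange format: a comment header line carrying the caloric
#' goal, then columns \code{patient_id}, \code{admission_iso}, \code{t_min},
#' \code{bg_mmol_L}, \code{insulin_U_h}, \code{en_kcal_h}, \code{pn_kcal_h},
#' \code{on_gc}.
#'
#' @param log a \code{\link{treatment_log}}.
#' @param path file path.
#' @return \code{write_treatment_log} returns \code{path} invisibly;
#'   \code{read_treatment_log} returns a \code{treatment_log}.
#' @export
write_treatment_log <- function(log, path) {
  r <- log$records
  out <- data.frame(patient_id = log$patient_id,
                    admission_iso = log$admission, r)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# goal_kcal: %.6g", log$goal_kcal), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_treatment_log
#' @export
read_treatment_log <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# goal_kcal:", hdr)) stop("missing goal_kcal header in ", path)
  goal <- as.numeric(sub("^# goal_kcal:\\s*", "", hdr))
  d <- read.csv(path, skip = 1)
  treatment_log(d[, setdiff(names(d), c("patient_id", "admission_iso"))],
                patient_id = d$patient_id[1], goal_kcal = goal,
                admission = d$admission_iso[1])
}

#' Percent of caloric goal achieved per ICU day
#'
#' For each ICU day (24 h blocks from admission), the delivered EN + PN
#' calories over the observed glycaemic-control hours, expressed as a
#' percentage of the 24 h-equivalent goal rate:
#' \code{100 * sum(kcal) / (observed_hours * goal_kcal / 24)}. Records
#' flagged excluded (see \code{\link{apply_exclusion}}) and off-GC records
#' are not observed; rows spanning a day boundary are split proportionally.
#' Days with no observed hours are omitted. PN can push a day over 100%.
#'
#' @param log a \code{\link{treatment_log}}.
#' @return Data frame with columns \code{day}, \code{pct_goal},
#'   \code{hours_observed}, \code{kcal}.
#' @export
pct_goal_per_day <- function(log) {
  stopifnot(inherits(log, "treatment_log"))
  r <- log$records
  keep <- r$on_gc == 1
  if ("excluded" %in% names(r)) keep <- keep & !r$excluded
  r <- r[keep, , drop = FALSE]
  if (!nrow(r)) return(data.frame(day = integer(), pct_goal = numeric(),
                                  hours_observed = numeric(), kcal = numeric()))
  dur <- .record_hours(log$records)[keep]
  t0 <- r$t_min / 60
  t1 <- t0 + dur
  rate <- r$en_kcal_h + r$pn_kcal_h
  # split each record across the 24 h day boundaries it crosses
  pieces <- lapply(seq_along(t0), function(i) {
    days <- seq(floor(t0[i] / 24), ceiling(t1[i] / 24 - 1e-12) - 1)
    lo <- pmax(t0[i], days * 24)
    hi <- pmin(t1[i], (days + 1) * 24)
    data.frame(day = days + 1L, hours = hi - lo, kcal = (hi - lo) * rate[i])
  })
  pc <- do.call(rbind, pieces)
  agg <- aggregate(pc[c("hours", "kcal")], by = list(day = pc$day), FUN = sum)
  agg <- agg[agg$hours > 1e-12, , drop = FALSE]
  data.frame(day = agg$day,
             pct_goal = 100 * agg$kcal / (agg$hours * log$goal_kcal / 24),
             hours_observed = agg$hours, kcal = agg$kcal)
}

#' Exclude low-feeding periods from rate statistics
#'
#' Clinical interruptions (surgery, imaging, gastric intolerance) stop or
#' reduce feeding for reasons unrelated to the dosing algorithm; hours whose
#' combined EN + PN rate is strictly below the floor (as % of goal on a
#' 24 h-rate basis) are flagged and omitted from all downstream rate
#' statistics. A rate exactly at the floor is retained.
#'
#' @param log a \code{\link{treatment_log}}.
#' @param floor exclusion floor (% of goal), default 30.
#' @return The log with an \code{excluded} flag column; attributes
#'   \code{excluded_hours} and \code{excluded_pct} (of on-GC hours) report
#'   how much was removed.
#' @export
apply_exclusion <- function(log, floor = 30) {
  stopifnot(inherits(log, "treatment_log"), floor >= 0)
  r <- log$records
  rate_pct <- 100 * (r$en_kcal_h + r$pn_kcal_h) / (log$goal_kcal / 24)
  r$excluded <- r$on_gc == 1 & rate_pct < floor
  hrs <- .record_hours(r)
  log$records <- r
  attr(log, "excluded_hours") <- sum(hrs[r$excluded])
  gc_hours <- sum(hrs[r$on_gc == 1])
  attr(log, "excluded_pct") <- if (gc_hours > 0)
    100 * sum(hrs[r$excluded]) / gc_hours else 0
  log
}

# hourly feed-rate values (% goal) retained for rate statistics
.retained_rates <- function(log) {
  r <- log$records
  keep <- r$on_gc == 1
  if ("excluded" %in% names(r)) keep <- keep & !r$excluded
  list(pct = 100 * (r$en_kcal_h[keep] + r$pn_kcal_h[keep]) /
         (log$goal_kcal / 24),
       hours = .record_hours(r)[keep])
}

#' Per-patient feed-rate statistics
#'
#' Mean and (sample) standard deviation of the hourly feed rate, as % of
#' caloric goal, over each patient's whole stay after exclusion, plus the
#' cohort-level median and IQR of both - the inter- versus intra-patient
#' variability comparison.
#'
#' @param logs list of \code{\link{treatment_log}}s (exclusion applied
#'   beforehand if desired).
#' @return List with \code{per_patient} (patient_id, mean_pct, sd_pct,
#'   hours) and \code{cohort} (median and quartiles of each statistic).
#' @export
per_patient_stats <- function(logs) {
  if (inherits(logs, "treatment_log")) logs <- list(logs)
  pp <- do.call(rbind, lapply(logs, function(lg) {
    rr <- .retained_rates(lg)
    if (!length(rr$pct)) return(NULL)
    data.frame(patient_id = lg$patient_id,
               mean_pct = sum(rr$pct * rr$hours) / sum(rr$hours),
               sd_pct = if (length(rr$pct) > 1) sd(rr$pct) else 0,
               hours = sum(rr$hours))
  }))
  qs <- function(v) setNames(quantile(v, c(0.5, 0.25, 0.75), names = FALSE),
                             c("median", "q25", "q75"))
  cohort <- rbind(mean_pct = qs(pp$mean_pct), sd_pct = qs(pp$sd_pct))
  list(per_patient = pp, cohort = as.data.frame(cohort))
}

#' Cohort nutrition delivery per ICU day
#'
#' Per-(patient, day) percent of goal achieved, with cohort distribution
#' statistics per day (mean, median, IQR, 5th-95th percentiles, patient
#' count).
#'
#' @param logs list of \code{\link{treatment_log}}s.
#' @return List with \code{per_patient_day} and per-day \code{cohort} data
#'   frames.
#' @export
cohort_day_summary <- function(logs) {
  if (inherits(logs, "treatment_log")) logs <- list(logs)
  ppd <- do.call(rbind, lapply(logs, function(lg) {
    d <- pct_goal_per_day(lg)
    if (!nrow(d)) return(NULL)
    cbind(patient_id = lg$patient_id, d)
  }))
  days <- sort(unique(ppd$day))
  cohort <- do.call(rbind, lapply(days, function(dd) {
    v <- ppd$pct_goal[ppd$day == dd]
    data.frame(day = dd, n = length(v), mean = mean(v), median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE),
               p5 = quantile(v, 0.05, names = FALSE),
               p95 = quantile(v, 0.95, names = FALSE))
  }))
  list(per_patient_day = ppd, cohort = cohort)
}

#' Percent of patients above a reference nutrition curve
#'
#' For each ICU day, the percentage of that day's patients whose percent of
#' goal achieved strictly exceeds the reference (a constant such as the 85%
#' mortality-optimum benchmark, or a user-supplied per-day survey curve).
#'
#' @param day_summary result of \code{\link{cohort_day_summary}} (or its
#'   \code{per_patient_day} component).
#' @param reference scalar, or data frame with columns \code{day} and
#'   \code{reference}.
#' @return Data frame with columns \code{day}, \code{reference},
#'   \code{pct_above}, \code{n}.
#' @export
threshold_exceedance <- function(day_summary, reference) {
  ppd <- if (is.list(day_summary) && "per_patient_day" %in% names(day_summary))
    day_summary$per_patient_day else day_summary
  days <- sort(unique(ppd$day))
  ref_at <- function(dd) {
    if (is.data.frame(reference)) {
      i <- match(dd, reference$day)
      if (is.na(i)) NA_real_ else reference$reference[i]
    } else reference
  }
  out <- do.call(rbind, lapply(days, function(dd) {
    rf <- ref_at(dd)
    if (is.na(rf)) return(NULL)
    v <- ppd$pct_goal[ppd$day == dd]
    data.frame(day = dd, reference = rf, pct_above = 100 * mean(v > rf),
               n = length(v))
  }))
  out
}
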
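#' Forward-simulate the glucose-insulin system
#'
#' Integrates the compartmental model with a fixed-step 4th-order Runge-Kutta
#' scheme, holding inputs piecewise constant. Deterministic: identical
#' arguments give an identical trajectory.
#'
#' @param state0 initial \code{\link{patient_state}}.
#' @param params \code{\link{icing_params}}.
#' @param inputs \code{\link{patient_inputs}} defined on \code{[0, horizon]}
#'   (times relative to \code{state0["t"]}).
#' @param horizon simulation length (min).
#' @param dt integration step (min), at most 1.
#' @return A data frame of class \code{patient_trajectory} with columns
#'   \code{t_min}, \code{G}, \code{I}, \code{Q}, \code{P1}, \code{P2},
#'   one row per step from 0 to \code{horizon}.
#' @examples
#' s0 <- patient_state(G = 9, I = 15, Q = 10)
#' p  <- icing_params(SI = 4e-4)
#' u  <- patient_inputs(uex = insulin_U_h_to_mU_min(3), uen = 0.4)
#' tr <- simulate_patient(s0, p, u, horizon = 180)
#' tail(tr, 1)
#' @export
simulate_patient <- function(state0, params, inputs, horizon, dt = 1) {
  stopifnot(inherits(state0, "patient_state"), inherits(params, "icing_params"))
  if (!inherits(inputs, "patient_inputs")) stop("inputs must be patient_inputs")
  if (horizon <= 0) stop("horizon must be positive")
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1] min")
  m <- .simulate_core(unclass(state0)[-1], .param_vector(params), inputs,
                      t0 = unname(state0["t"]), horizon = horizon, dt = dt)
  out <- as.data.frame(m)
  names(out) <- c("t_min", "G", "I", "Q", "P1", "P2")
  class(out) <- c("patient_trajectory", "data.frame")
  out
}

# Segment the horizon at input break times and run the compiled RK4 core on
# each constant-input piece. y0 is c(G, I, Q, P1, P2); returns a matrix.
.simulate_core <- function(y0, pvec, inputs, t0, horizon, dt) {
  br <- inputs$times
  keep <- br < horizon
  seg_start <- br[keep]
  seg_end <- c(seg_start[-1], horizon)
  pieces <- vector("list", length(seg_start))
  y <- y0
  for (i in seq_along(seg_start)) {
    idx <- which(keep)[i]
    m <- .icing_rk4(y, pvec, inputs$uex[idx], inputs$uen[idx],
                    inputs$upn[idx], t0 + seg_start[i],
                    seg_end[i] - seg_start[i], dt)
    y <- m[nrow(m), 2:6]
    pieces[[i]] <- if (i == 1) m else m[-1, , drop = FALSE]
  }
  do.call(rbind, pieces)
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat("Simulated glucose-insulin trajectory:", nrow(x), "time points,",
      sprintf("t = %.0f..%.0f min\n", x$t_min[1], x$t_min[nrow(x)]))
  cat(sprintf("  BG %.2f -> %.2f mmol/L (range %.2f-%.2f)\n",
              x$G[1], x$G[nrow(x)], min(x$G), max(x$G)))
  invisible(x)
}

#' @export
plot.patient_trajectory <- function(x, ...) {
  plot(x$t_min / 60, x$G, type = "l", xlab = "time (h)",
       ylab = "BG (mmol/L)", ...)
  abline(h = c(4.4, 8.0), lty = 3)
  invisible(x)
}

#' Percentile blood-glucose prediction bounds
#'
#' Forward-simulates the model twice, once with insulin sensitivity at its
#' forecast upper percentile (giving the lower BG bound) and once at the lower
#' percentile (upper BG bound), as the dosing logic does when bounding the
#' outcome of a candidate intervention.
#'
#' @inheritParams simulate_patient
#' @param si_low,si_high lower/upper insulin-sensitivity percentile values
#'   (L/(mU min)), \code{0 < si_low <= si_high}.
#' @return A list with \code{t_min} and BG trajectories \code{bg_low}
#'   (from \code{si_high}) and \code{bg_high} (from \code{si_low}),
#'   \code{bg_low <= bg_high} pointwise.
#' @examples
#' s0 <- patient_state(G = 8, I = 20, Q = 15)
#' b <- bg_prediction_bounds(s0, icing_params(), patient_inputs(uex = 30),
#'                           si_low = 3e-4, si_high = 6e-4, horizon = 60)
#' range(b$bg_high - b$bg_low)
#' @export
bg_prediction_bounds <- function(state0, params, inputs, si_low, si_high,
                                 horizon, dt = 1) {
  if (!(si_low > 0 && si_low <= si_high))
    stop("require 0 < si_low <= si_high")
  lo <- simulate_patient(state0, `[[<-`(params, "SI", si_high), inputs,
                         horizon, dt)
  hi <- simulate_patient(state0, `[[<-`(params, "SI", si_low), inputs,
                         horizon, dt)
  list(t_min = lo$t_min, bg_low = lo$G, bg_high = hi$G)
}
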
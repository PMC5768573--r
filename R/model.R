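#' Glucose-insulin model parameters
#'
#' Construct the parameter set of the glucose-insulin system used throughout
#' the package: a compartmental model of the ICING family with endogenous
#' glucose balance, saturable insulin-mediated uptake, two-pool insulin
#' kinetics with saturable hepatic clearance, and a two-compartment gut.
#'
#' The state equations are
#' \deqn{dG/dt = -p_G G - S_I G \frac{Q}{1+\alpha_G Q} + \frac{P(t) + EGP - CNS}{V_G}}
#' \deqn{dI/dt = -n_K I - \frac{n_L I}{1+\alpha_I I} - n_I (I - Q) + u_{ex}(t)/V_I}
#' \deqn{dQ/dt = n_I (I - Q) - \frac{n_C Q}{1+\alpha_G Q}}
#' \deqn{dP_1/dt = -d_1 P_1 + u_{en}(t), \quad dP_2/dt = -d_2 P_2 + d_1 P_1}
#' with glucose appearance \eqn{P(t) = d_2 P_2 + u_{pn}(t)}.
#'
#' Defaults are representative adult-ICU values and are fully configurable;
#' the same set ships as a plain-text config file in
#' \code{system.file("extdata", "icing_params.csv", package = "starGC")}.
#'
#' @param ... named overrides of any default parameter.
#' @param file optional path to a two-column (key, value) CSV holding
#'   parameter overrides, applied before \code{...}.
#'
#' @return An object of class \code{icing_params}: a named list with elements
#'   \code{pG} (endogenous glucose clearance, 1/min), \code{SI} (insulin
#'   sensitivity, L/(mU min)), \code{alphaG} (insulin-effect saturation,
#'   L/mU), \code{alphaI} (hepatic-clearance saturation, L/mU), \code{nI},
#'   \code{nK}, \code{nL}, \code{nC} (insulin kinetic rates, 1/min),
#'   \code{VG}, \code{VI} (distribution volumes, L), \code{EGP} (endogenous
#'   glucose production, mmol/min), \code{CNS} (insulin-independent uptake,
#'   mmol/min), \code{xL} (first-pass hepatic extraction fraction, carried
#'   for completeness; endogenous insulin secretion is not modelled),
#'   \code{d1}, \code{d2} (gut transport rates, 1/min).
#'
#' @examples
#' p <- icing_params(SI = 5e-4)
#' p$SI
#' @export
icing_params <- function(..., file = NULL) {
  p <- list(
    pG = 0.006, SI = 5e-4, alphaG = 1 / 65, alphaI = 0.0017,
    nI = 0.003, nK = 0.0542, nL = 0.1578, nC = 0.003,
    VG = 13.3, VI = 4.0, EGP = 1.16, CNS = 0.3, xL = 0.67,
    d1 = 0.0347, d2 = 0.0069
  )
  if (!is.null(file)) {
    cfg <- read.csv(file, stringsAsFactors = FALSE)
    if (!all(c("key", "value") %in% names(cfg)))
      stop("parameter config must have columns 'key' and 'value'")
    for (i in seq_len(nrow(cfg))) {
      k <- cfg$key[i]
      if (!k %in% names(p)) stop("unknown parameter in config: ", k)
      p[[k]] <- as.numeric(cfg$value[i])
    }
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_icing_params(p)
  structure(p, class = "icing_params")
}

validate_icing_params <- function(p) {
  pos <- c("pG", "SI", "nI", "nK", "nL", "nC", "VG", "VI", "EGP", "CNS",
           "d1", "d2")
  for (k in pos) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1 || !is.finite(p[[k]]) ||
        p[[k]] <= 0)
      stop("parameter ", k, " must be a positive finite scalar")
  }
  if (p$alphaG < 0 || p$alphaI < 0) stop("alphaG and alphaI must be >= 0")
  if (p$xL < 0 || p$xL >= 1) stop("xL must lie in [0, 1)")
  invisible(p)
}

#' @export
print.icing_params <- function(x, ...) {
  cat("Glucose-insulin model parameters (ICING-family)\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

# fixed layout consumed by the C++ integrator
.param_vector <- function(p) {
  c(p$pG, p$SI, p$alphaG, p$alphaI, p$nI, p$nK, p$nL, p$nC,
    p$VG, p$VI, p$EGP, p$CNS, p$d1, p$d2)
}

#' Instantaneous physiological state of a virtual patient
#'
#' @param G blood glucose (mmol/L), must be positive.
#' @param I plasma insulin (mU/L).
#' @param Q interstitial insulin (mU/L).
#' @param P1,P2 gut glucose compartments (mmol).
#' @param t time stamp (min).
#' @return An object of class \code{patient_state} (named numeric vector).
#' @examples
#' patient_state(G = 9.5)
#' @export
patient_state <- function(G, I = 0, Q = 0, P1 = 0, P2 = 0, t = 0) {
  s <- c(t = t, G = G, I = I, Q = Q, P1 = P1, P2 = P2)
  if (any(!is.finite(s))) stop("patient state must be finite")
  if (G <= 0) stop("G must be positive")
  if (any(s[c("I", "Q", "P1", "P2")] < 0)) stop("I, Q, P1, P2 must be >= 0")
  structure(s, class = "patient_state")
}

#' Exogenous inputs to the glucose-insulin system
#'
#' Piecewise-constant intravenous insulin, enteral glucose and parenteral
#' glucose rates. Each rate is held constant from its break time until the
#' next break.
#'
#' @param uex IV insulin rate(s) (mU/min).
#' @param uen enteral glucose appearance rate(s) (mmol/min).
#' @param upn parenteral glucose rate(s) (mmol/min).
#' @param times break times (min); the first must be 0. Scalar rates are
#'   recycled to \code{length(times)}.
#' @return An object of class \code{patient_inputs}.
#' @examples
#' # 2 U/h insulin for the first hour, then 3 U/h
#' patient_inputs(uex = insulin_U_h_to_mU_min(c(2, 3)), times = c(0, 60))
#' @export
patient_inputs <- function(uex = 0, uen = 0, upn = 0, times = 0) {
  n <- length(times)
  if (times[1] != 0) stop("first break time must be 0")
  if (n > 1 && any(diff(times) <= 0)) stop("break times must be increasing")
  rec <- function(v) {
    if (length(v) == 1) rep(v, n) else if (length(v) == n) v else
      stop("input rate length must be 1 or length(times)")
  }
  x <- list(times = as.numeric(times), uex = rec(uex), uen = rec(uen),
            upn = rec(upn))
  if (any(unlist(x[c("uex", "uen", "upn")]) < 0))
    stop("input rates must be non-negative")
  structure(x, class = "patient_inputs")
}

#' Convert an insulin infusion rate from U/h to mU/min
#' @param rate_U_h insulin rate (U/h).
#' @return rate in mU/min.
#' @examples insulin_U_h_to_mU_min(3)  # 50 mU/min
#' @export
insulin_U_h_to_mU_min <- function(rate_U_h) rate_U_h * 1000 / 60
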
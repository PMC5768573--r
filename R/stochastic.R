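#' Fit the stochastic model of insulin-sensitivity variability
#'
#' Models the hour-scale variability of identified insulin sensitivity as a
#' conditional distribution of the next-interval value given the current one.
#' A two-dimensional Gaussian product-kernel density is fitted on the pairs
#' \eqn{(x, r) = (\log S_{I,now},\ \log S_{I,next}/S_{I,now})}; conditioning
#' on \eqn{x} and renormalising gives the forecast density of the hourly
#' log-change, from which arbitrary percentiles of the next-interval
#' \eqn{S_I} follow. Working on the log-change scale keeps \eqn{S_I}
#' positive and keeps the forecast interval calibrated (the conditioning
#' bandwidth does not smear the conditional mean into the interval width).
#' Bandwidths follow the two-dimensional Silverman/Scott rule
#' \eqn{h = 1.06\, \hat\sigma\, n^{-1/6}}.
#'
#' @param transitions data frame with columns \code{si_now}, \code{si_next}
#'   (both L/(mU min), positive) and optionally \code{gap} (interval length,
#'   h; transitions are binned to the 1 h reference gap, and only gap == 1
#'   rows are used for fitting).
#' @param min_n minimum number of transitions required.
#' @return An object of class \code{si_stochastic} with
#'   \code{\link{predict.si_stochastic}} (percentile queries),
#'   \code{print}, \code{summary}, \code{plot} and \code{simulate} methods.
#' @examples
#' set.seed(1)
#' si <- exp(runif(500, log(1e-4), log(1.5e-3)))
#' tr <- data.frame(si_now = si, si_next = si * exp(0.1 * rnorm(500)))
#' m <- fit_stochastic_si(tr)
#' predict(m, si_now = 4e-4, p = c(0.05, 0.5, 0.95))
#' @export
fit_stochastic_si <- function(transitions, min_n = 50) {
  stopifnot(is.data.frame(transitions),
            all(c("si_now", "si_next") %in% names(transitions)))
  tr <- transitions
  if ("gap" %in% names(tr)) tr <- tr[round(tr$gap) == 1, , drop = FALSE]
  if (nrow(tr) < min_n)
    stop("too few transitions to fit the stochastic model (need >= ", min_n, ")")
  if (any(tr$si_now <= 0 | tr$si_next <= 0))
    stop("SI values must be positive")
  x <- log(tr$si_now)
  r <- log(tr$si_next / tr$si_now)
  n <- length(x)
  silverman2d <- function(v) 1.06 * sd(v) * n^(-1 / 6)
  hx <- max(silverman2d(x), 1e-3)
  hr <- max(silverman2d(r), 1e-8)
  support <- range(x)
  # conditioning grid + row-normalised kernel weights, precomputed for the
  # percentile query cache
  xgrid <- if (diff(support) > 1e-12)
    seq(support[1], support[2], length.out = 121) else support[1]
  W <- dnorm(outer(xgrid, x, "-") / hx)
  W <- W / rowSums(W)
  structure(list(x = x, r = r, hx = hx, hr = hr, n = n,
                 support = support, xgrid = xgrid, W = W,
                 cache = new.env(parent = emptyenv())),
            class = "si_stochastic")
}

# conditional quantile curve of the hourly log-change on the x grid,
# bisection on the kernel-mixture CDF; cached per probability
.si_quantile_curve <- function(object, p) {
  key <- sprintf("%.12g", p)
  cur <- object$cache[[key]]
  if (!is.null(cur)) return(cur)
  ri <- object$r
  hr <- object$hr
  ng <- length(object$xgrid)
  lo <- rep(min(ri) - 8 * hr, ng)
  hi <- rep(max(ri) + 8 * hr, ng)
  for (it in 1:55) {
    mid <- (lo + hi) / 2
    Fm <- rowSums(object$W * pnorm(outer(mid, ri, "-") / hr))
    up <- Fm < p
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  cur <- (lo + hi) / 2
  assign(key, cur, envir = object$cache)
  cur
}

#' Parametric stochastic model: lognormal random walk
#'
#' Small-sample / generator-side counterpart of
#' \code{\link{fit_stochastic_si}}: the next-interval insulin sensitivity is
#' \eqn{S_{I,next} = S_{I,now} \exp(\mu + \sigma \varepsilon)},
#' \eqn{\varepsilon \sim N(0,1)} per hour, so percentile queries are closed
#' form. \code{sigma = 0} gives a deterministic (zero-variability) model,
#' useful as a limiting case.
#'
#' @param sigma hourly log-SI volatility (>= 0).
#' @param mu hourly log-SI drift (default 0).
#' @return An object of class \code{si_stochastic}.
#' @examples
#' m <- si_lognormal_walk(0.1)
#' predict(m, 4e-4, c(0.05, 0.95))
#' @export
si_lognormal_walk <- function(sigma, mu = 0) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, mu = mu, parametric = TRUE),
            class = "si_stochastic")
}

#' Forecast percentiles of next-interval insulin sensitivity
#'
#' @param object an \code{si_stochastic} model.
#' @param si_now current insulin sensitivity (L/(mU min), scalar).
#' @param p probabilities in (0, 1).
#' @param gap forecast horizon in hours; horizons beyond the 1 h reference
#'   are handled by chaining the 1 h percentile map \code{round(gap)} times
#'   (conservative: slightly wider than the exact multi-step quantile).
#' @param ... unused.
#' @return Numeric vector of SI percentile values, non-decreasing in
#'   \code{p}, clamped to the plausibility bounds [1e-5, 1e-2]. Querying
#'   outside the training support warns and answers at the nearest supported
#'   SI (the hourly change distribution at the nearest support is applied to
#'   the actual \code{si_now}).
#' @examples
#' m <- si_lognormal_walk(0.1)
#' predict(m, 4e-4, c(0.05, 0.5, 0.95), gap = 2)
#' @export
predict.si_stochastic <- function(object, si_now, p, gap = 1, ...) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0, 1)")
  if (length(si_now) != 1 || si_now <= 0) stop("si_now must be a positive scalar")
  k <- max(1L, as.integer(round(gap)))
  ord <- order(p)
  s <- rep(si_now, length(p))
  for (step in seq_len(k)) {
    s <- vapply(seq_along(p), function(i) .si_step_quantile(object, s[i], p[i]),
                numeric(1))
  }
  s <- pmin(pmax(s, .si_bounds[1]), .si_bounds[2])
  # enforce exact monotonicity in p (root-finding tolerance can tie)
  s[ord] <- cummax(s[ord])
  s
}

# one-hour-ahead conditional quantile of si_next given si_now
.si_step_quantile <- function(object, si_now, p) {
  if (isTRUE(object$parametric)) {
    return(si_now * exp(object$mu + object$sigma * qnorm(p)))
  }
  x0 <- log(si_now)
  if (x0 < object$support[1] || x0 > object$support[2]) {
    warning("si_now outside training support; answering at nearest support")
    x0 <- min(max(x0, object$support[1]), object$support[2])
  }
  cur <- .si_quantile_curve(object, p)
  rp <- if (length(object$xgrid) == 1) cur[1] else
    approx(object$xgrid, cur, xout = x0)$y
  si_now * exp(rp)
}

#' Simulate next-interval insulin sensitivity draws
#' @param object an \code{si_stochastic} model.
#' @param nsim number of draws.
#' @param seed optional RNG seed.
#' @param si_now current SI (L/(mU min)).
#' @param ... unused.
#' @return Numeric vector of \code{nsim} draws of the next-interval SI.
#' @export
simulate.si_stochastic <- function(object, nsim = 1, seed = NULL,
                                   si_now, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(object$parametric)) {
    return(si_now * exp(object$mu + object$sigma * rnorm(nsim)))
  }
  x0 <- min(max(log(si_now), object$support[1]), object$support[2])
  w <- dnorm(x0, mean = object$x, sd = object$hx)
  w <- w / sum(w)
  idx <- sample.int(object$n, nsim, replace = TRUE, prob = w)
  si_now * exp(object$r[idx] + object$hr * rnorm(nsim))
}

#' Percentile table over an SI grid
#'
#' Evaluates forecast percentiles on a grid of current-SI values, the tabular
#' summary written by the command-line interface and a convenient
#' precomputation for repeated queries.
#'
#' @param model an \code{si_stochastic} model.
#' @param si_grid grid of current SI values; default 25 log-spaced points over
#'   the training support (or [1e-4, 1.5e-3] for parametric models).
#' @param p probabilities (default 5th, 25th, 50th, 75th, 95th percentiles).
#' @return Data frame with column \code{si_now} and one column per percentile.
#' @export
si_percentile_table <- function(model, si_grid = NULL,
                                p = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (is.null(si_grid)) {
    rng <- if (isTRUE(model$parametric)) log(c(1e-4, 1.5e-3)) else model$support
    si_grid <- exp(seq(rng[1], rng[2], length.out = 25))
  }
  out <- t(vapply(si_grid, function(s) predict(model, s, p), numeric(length(p))))
  out <- data.frame(si_now = si_grid, out)
  names(out)[-1] <- paste0("p", formatC(100 * p, format = "g"))
  out
}

#' @export
print.si_stochastic <- function(x, ...) {
  if (isTRUE(x$parametric)) {
    cat(sprintf("Stochastic SI model: lognormal random walk (mu=%.3g, sigma=%.3g per h)\n",
                x$mu, x$sigma))
  } else {
    cat(sprintf(
      "Stochastic SI model: conditional kernel density, %d transitions\n", x$n))
    cat(sprintf("  bandwidths: hx=%.3g (log SI), hr=%.3g (log change)\n",
                x$hx, x$hr))
    cat(sprintf("  SI support: %.3g - %.3g L/(mU min)\n",
                exp(x$support[1]), exp(x$support[2])))
  }
  invisible(x)
}

#' @export
summary.si_stochastic <- function(object, ...) {
  tab <- si_percentile_table(object)
  cat("Forecast percentiles of next-hour SI:\n")
  print(cbind(si_now = signif(tab$si_now, 3),
              round(tab[-1] / tab$si_now, 3)))
  cat("(values shown as ratios to si_now)\n")
  invisible(tab)
}

#' @export
plot.si_stochastic <- function(x, ...) {
  tab <- si_percentile_table(x)
  matplot(tab$si_now, tab[, -1], type = "l", log = "xy", lty = c(3, 2, 1, 2, 3),
          col = 1, xlab = "SI now (L/(mU min))", ylab = "SI next (L/(mU min))",
          ...)
  invisible(x)
}
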
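# Modified Gompertz growth model on the ln-abundance scale, fitted by
# multi-start bounded robust least squares, and derived growth statistics.

#' Parameter bounds for Gompertz fitting
#'
#' Box constraints on the four parameters of [gompertz_ln()]:
#' carrying-capacity amplitude `A`, maximum specific growth rate `mu`
#' (per hour), lag time `lam` (hours) and inoculum offset `A0`
#' (ln-abundance units).  The defaults restrict the search to biologically
#' plausible anaerobic growth: the `mu` ceiling of 2.6/h corresponds to a
#' doubling time on the order of 15 min, the fastest recorded for an
#' anaerobe, and the `A`/`A0` ceilings to the largest amount of DNA seen
#' in replicate droplet samples.  The lag lower bound is left well below 0
#' because pinning it at 0 makes fitted lags collapse onto the boundary.
#'
#' @param lower,upper Named numeric vectors with entries `A`, `mu`, `lam`,
#'   `A0`; `lower` must be elementwise below `upper`.
#' @return A list of class `"gompertz_bounds"` with elements `lower` and
#'   `upper`.
#' @export
gompertz_bounds <- function(lower = c(A = 0, mu = 0, lam = -50, A0 = 0),
                            upper = c(A = 15, mu = 2.6, lam = 12, A0 = 15)) {
  nm <- c("A", "mu", "lam", "A0")
  if (!all(nm %in% names(lower)) || !all(nm %in% names(upper))) {
    stop("bounds must be named vectors with entries A, mu, lam, A0")
  }
  lower <- lower[nm]
  upper <- upper[nm]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("lower bounds must be finite and strictly below upper bounds")
  }
  structure(list(lower = lower, upper = upper), class = "gompertz_bounds")
}

#' Modified Gompertz curve on the ln-abundance scale
#'
#' Evaluates `y(t) = A * exp(-exp((mu * e / A) * (lam - t) + 1)) + A0`,
#' the Zwietering reparameterisation of the Gompertz law in which `mu` is
#' the maximum slope (here, specific growth rate per hour), `lam` the lag
#' time at which the tangent at the inflection crosses the baseline, `A`
#' the total rise, plus an offset `A0` for the inoculum level.  `y` is the
#' natural log of absolute abundance, so the curve rises from `A0` to
#' `A0 + A`.  `A = 0` is handled as the constant-`A0` limit.
#'
#' @param t Time in hours (vectorised; must be finite).
#' @param A Carrying-capacity amplitude, ln-abundance units (>= 0).
#' @param mu Maximum specific growth rate, per hour (>= 0).
#' @param lam Lag time, hours.
#' @param A0 Inoculum offset, ln-abundance units.
#' @return `y(t)`, same length as `t`.
#' @examples
#' gompertz_ln(0:10, A = 5, mu = 1, lam = 3, A0 = 2)
#' @export
gompertz_ln <- function(t, A, mu, lam, A0) {
  if (any(!is.finite(t))) stop("'t' must be finite")
  if (A < 0 || mu < 0) stop("'A' and 'mu' must be >= 0")
  if (A == 0) return(rep(A0, length(t)))
  u <- (mu * exp(1) / A) * (lam - t) + 1
  A * exp(-exp(u)) + A0
}

# Evaluate curve and its gradient for a parameter vector c(A, mu, lam, A0).
# Underflow-safe: exp(u - exp(u)) -> 0 smoothly for large |u|.
.gompertz_eval <- function(t, par, grad = FALSE) {
  A <- par[[1L]]; mu <- par[[2L]]; lam <- par[[3L]]; A0 <- par[[4L]]
  A <- max(A, 1e-10)  # optimizer may touch the A = 0 face
  u <- (mu * exp(1) / A) * (lam - t) + 1
  eu <- exp(pmin(u, 700))
  s <- exp(-eu)            # exp(-exp(u))
  g <- exp(u - eu)         # exp(u) * exp(-exp(u)), underflow-safe
  y <- A * s + A0
  if (!grad) return(y)
  dA   <- s + (mu * exp(1) * (lam - t) / A) * g
  dmu  <- -exp(1) * (lam - t) * g
  dlam <- -mu * exp(1) * g
  dA0  <- rep(1, length(t))
  list(y = y, jac = cbind(A = dA, mu = dmu, lam = dlam, A0 = dA0))
}

# Smooth-L1 ("soft L1") robust loss: per-residual 2 * (sqrt(1 + r^2) - 1).
.soft_l1 <- function(r) sum(2 * (sqrt(1 + r^2) - 1))

#' Fit the modified Gompertz model to an ln-abundance time series
#'
#' Performs `n_restarts` bounded robust least-squares fits of
#' [gompertz_ln()] with starting points drawn uniformly inside the bound
#' box, minimising the smooth-L1 loss `sum(2 * (sqrt(1 + r^2) - 1))` over
#' the residuals `yhat - y`.  Fits whose growth rate collapses onto the
#' `mu` ceiling (`mu >= mu_retain`) are discarded; among the remainder
#' the fit with the lowest loss is returned (ties broken toward smaller
#' `mu`, then earlier restart, so results are deterministic given the
#' seed).  If every restart is discarded or fails, a failure-flagged fit
#' is returned rather than an error.
#'
#' @param times Observation times in hours (>= 5 values, within 0--200 h).
#' @param values ln-abundance observations, same length as `times`.
#' @param bounds A [gompertz_bounds()] object.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Optional integer seed controlling the restart draws.
#' @param mu_retain Retention ceiling: fits with `mu >= mu_retain` are
#'   discarded as boundary collapses (default 2.5, slightly below the
#'   default `mu` upper bound of 2.6).
#' @param window Time window `c(t_start, t_end)` over which the total
#'   growth `delta_total = y(t_end) - y(t_start)` is evaluated (default
#'   `c(0, 127)`, the span of a 127-h sampling series).
#' @return An object of class `"gompertz_fit"`: a list with `params`
#'   (named vector `A`, `mu`, `lam`, `A0`), `loss`, `retained` (`FALSE`
#'   if no restart survived), `n_restarts_retained`, `delta_total`, and
#'   the fitting `window`.
#' @seealso [total_growth()], [time_to_capacity_fraction()]
#' @export
fit_gompertz <- function(times, values, bounds = gompertz_bounds(),
                         n_restarts = 100, seed = NULL, mu_retain = 2.5,
                         window = c(0, 127)) {
  if (!inherits(bounds, "gompertz_bounds")) {
    stop("'bounds' must be a gompertz_bounds() object")
  }
  if (length(times) != length(values)) {
    stop("'times' and 'values' must have the same length")
  }
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]
  values <- values[keep]
  if (length(times) < 5L) {
    stop("at least 5 finite observations are required to fit the model")
  }
  if (any(times < 0 | times > 200)) {
    stop("'times' must lie within [0, 200] hours")
  }
  lower <- bounds$lower
  upper <- bounds$upper
  lower[["A"]] <- max(lower[["A"]], 1e-8)  # keep mu*e/A finite

  obj <- function(par) {
    .soft_l1(.gompertz_eval(times, par) - values)
  }
  grad <- function(par) {
    ev <- .gompertz_eval(times, par, grad = TRUE)
    r <- ev$y - values
    w <- 2 * r / sqrt(1 + r^2)
    as.numeric(crossprod(ev$jac, w))
  }

  starts <- .with_seed(
    seed,
    matrix(stats::runif(4L * n_restarts, min = rep(lower, n_restarts),
                        max = rep(upper, n_restarts)),
           ncol = 4L, byrow = TRUE, dimnames = list(NULL, names(lower)))
  )

  best <- NULL
  n_retained <- 0L
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$par[["mu"]] >= mu_retain) next  # boundary collapse, discard
    n_retained <- n_retained + 1L
    if (is.null(best) ||
        res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 &&
         res$par[["mu"]] < best$par[["mu"]])) {
      best <- res
    }
  }

  if (is.null(best)) {
    fit <- structure(
      list(params = c(A = NA_real_, mu = NA_real_, lam = NA_real_,
                      A0 = NA_real_),
           loss = NA_real_, retained = FALSE, n_restarts_retained = 0L,
           delta_total = NA_real_, window = window, bounds = bounds),
      class = "gompertz_fit")
    return(fit)
  }

  fit <- structure(
    list(params = best$par, loss = best$value, retained = TRUE,
         n_restarts_retained = n_retained, delta_total = NA_real_,
         window = window, bounds = bounds),
    class = "gompertz_fit")
  fit$delta_total <- total_growth(fit, t_start = window[1L],
                                  t_end = window[2L])
  fit
}

#' @export
print.gompertz_fit <- function(x, digits = 4, ...) {
  if (!x$retained) {
    cat("Gompertz fit: FAILED (no restart retained)\n")
    return(invisible(x))
  }
  p <- x$params
  cat(sprintf(
    "Gompertz fit: A = %s, mu = %s /h, lam = %s h, A0 = %s\n",
    format(p[["A"]], digits = digits), format(p[["mu"]], digits = digits),
    format(p[["lam"]], digits = digits), format(p[["A0"]], digits = digits)))
  cat(sprintf("  loss %s over %d retained restarts; total growth %s ln-units (%s doublings) on [%g, %g] h\n",
              format(x$loss, digits = digits), x$n_restarts_retained,
              format(x$delta_total, digits = digits),
              format(doublings_from_delta_ln(x$delta_total), digits = digits),
              x$window[1L], x$window[2L]))
  invisible(x)
}

#' Predicted ln-abundance from a fitted Gompertz model
#'
#' @param object A retained [fit_gompertz()] result.
#' @param t Times (hours) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted ln-abundance at `t`.
#' @export
predict.gompertz_fit <- function(object, t, ...) {
  p <- .fit_params(object)
  gompertz_ln(t, p[["A"]], p[["mu"]], p[["lam"]], p[["A0"]])
}

# Accept a gompertz_fit or a bare named parameter vector/list.
.fit_params <- function(fit) {
  if (inherits(fit, "gompertz_fit")) {
    if (!isTRUE(fit$retained)) {
      stop("fit was not retained; its parameters are undefined")
    }
    return(fit$params)
  }
  p <- unlist(fit)
  nm <- c("A", "mu", "lam", "A0")
  if (!all(nm %in% names(p))) {
    stop("parameters must be named A, mu, lam, A0")
  }
  p[nm]
}

#' Total growth over a time window
#'
#' The growth statistic of a fitted curve: `delta = y(t_end) - y(t_start)`
#' in ln-abundance units.  With the default window this is the rise of the
#' fitted curve over a 127-hour sampling series.
#'
#' @param fit A retained [fit_gompertz()] result, or a named parameter
#'   vector/list with entries `A`, `mu`, `lam`, `A0`.
#' @param t_start,t_end Window endpoints in hours (defaults 0 and 127).
#' @return Non-negative total growth in ln-units.
#' @export
total_growth <- function(fit, t_start = 0, t_end = 127) {
  p <- .fit_params(fit)
  y <- gompertz_ln(c(t_start, t_end), p[["A"]], p[["mu"]], p[["lam"]],
                   p[["A0"]])
  max(y[2L] - y[1L], 0)
}

#' Convert an ln-abundance change into cell doublings
#'
#' A change of `log(2)` ln-units is one doubling, so the conversion is
#' `delta_ln / log(2)`.  The growth limit of detection of 1.48 ln-units
#' corresponds to 2.14 doublings.
#'
#' @param delta_ln Change in ln abundance (finite, vectorised).
#' @return Number of doublings.
#' @examples
#' doublings_from_delta_ln(1.48)  # ~2.14
#' @export
doublings_from_delta_ln <- function(delta_ln) {
  if (any(!is.finite(delta_ln))) stop("'delta_ln' must be finite")
  delta_ln / log(2)
}

#' Time at which a fitted curve reaches a fraction of carrying capacity
#'
#' Solves `(y(t) - A0) / A = q` in closed form:
#' `t = lam + (A / (mu * e)) * (1 - log(-log(q)))`.  The fraction is
#' measured relative to the amplitude `A` alone (the carrying capacity of
#' the growth, excluding the inoculum offset).
#'
#' @param fit A retained fit or named parameter vector with `A > 0`.
#' @param q Capacity fraction in (0, 1).
#' @return Time in hours.
#' @examples
#' time_to_capacity_fraction(c(A = 10, mu = 1, lam = 2, A0 = 0), 0.8)
#' @export
time_to_capacity_fraction <- function(fit, q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 ||
      q >= 1) {
    stop("'q' must be a single fraction strictly between 0 and 1")
  }
  p <- .fit_params(fit)
  if (p[["A"]] <= 0) stop("'A' must be > 0 to define a capacity fraction")
  if (p[["mu"]] <= 0) {
    stop("'mu' = 0: the curve never reaches any capacity fraction")
  }
  unname(p[["lam"]] + (p[["A"]] / (p[["mu"]] * exp(1))) *
           (1 - log(-log(q))))
}

#' Fraction of taxa at or above a capacity fraction over time
#'
#' For a collection of retained fits, computes at each requested time the
#' fraction of taxa whose closed-form [time_to_capacity_fraction()] has
#' already been reached -- the empirical CDF of the per-taxon times to
#' `q`-capacity, evaluated on `times`.
#'
#' @param fits A list of retained [fit_gompertz()] results (or named
#'   parameter vectors), all with `A > 0` and `mu > 0`.
#' @param q Capacity fraction in (0, 1); default 0.8.
#' @param times Evaluation grid in hours.
#' @return A data frame with columns `time` and `fraction`
#'   (non-decreasing in `time`).
#' @export
capacity_fraction_curve <- function(fits, q = 0.8, times) {
  if (length(fits) == 0L) stop("'fits' must contain at least one fit")
  if (length(times) == 0L || any(!is.finite(times))) {
    stop("'times' must be a non-empty finite numeric vector")
  }
  t_q <- vapply(fits, time_to_capacity_fraction, numeric(1L), q = q)
  data.frame(
    time = times,
    fraction = vapply(times, function(tt) mean(t_q <= tt), numeric(1L))
  )
}
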
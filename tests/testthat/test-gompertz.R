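# Modified Gompertz model, multi-start robust fitting, and derived
# growth statistics.

test_that("gompertz_ln matches its closed-form anchor points", {
  # at t = lam the curve sits at A * exp(-e) + A0
  expect_equal(gompertz_ln(3, A = 10, mu = 1, lam = 3, A0 = 1),
               10 * exp(-exp(1)) + 1, tolerance = 1e-12)
  expect_equal(gompertz_ln(3, A = 10, mu = 1, lam = 3, A0 = 1), 1.65988,
               tolerance = 1e-5)
  # saturation and floor limits
  expect_equal(gompertz_ln(1e6, A = 5, mu = 1, lam = 3, A0 = 2), 7)
  expect_equal(gompertz_ln(-1e6, A = 5, mu = 1, lam = 3, A0 = 2), 2)
  # A = 0 degenerates to the constant offset
  expect_equal(gompertz_ln(c(0, 10), A = 0, mu = 1, lam = 3, A0 = 2),
               c(2, 2))
  expect_error(gompertz_ln(Inf, 1, 1, 1, 0), "finite")
})

test_that("the maximum slope of the curve equals mu", {
  A <- 6; mu <- 0.8; lam <- 4; A0 <- 1
  t_inf <- lam + A / (mu * exp(1))  # inflection: exponent u = 0
  h <- 1e-5
  slope <- (gompertz_ln(t_inf + h, A, mu, lam, A0) -
              gompertz_ln(t_inf - h, A, mu, lam, A0)) / (2 * h)
  expect_equal(slope, mu, tolerance = 1e-6)
})

test_that("curve output is bounded and nondecreasing", {
  set.seed(11)
  for (i in 1:20) {
    A <- runif(1, 0.5, 14); mu <- runif(1, 0.05, 2.5)
    lam <- runif(1, -40, 11); A0 <- runif(1, 0, 14)
    y <- gompertz_ln(seq(0, 200, by = 0.5), A, mu, lam, A0)
    expect_true(all(y >= A0 - 1e-9 & y <= A0 + A + 1e-9))
    expect_true(all(diff(y) >= -1e-9))
  }
})

test_that("gompertz_bounds validates its box", {
  b <- gompertz_bounds()
  expect_equal(unname(b$upper), c(15, 2.6, 12, 15))
  expect_equal(unname(b$lower), c(0, 0, -50, 0))
  expect_error(gompertz_bounds(lower = c(A = 2, mu = 0, lam = 0, A0 = 0),
                               upper = c(A = 1, mu = 1, lam = 1, A0 = 1)),
               "below")
  expect_error(gompertz_bounds(lower = c(A = 0, mu = 0)), "named")
})

test_that("fitting noiseless data recovers the generating curve", {
  tt <- design_times()
  y <- gompertz_ln(tt, A = 5, mu = 1, lam = 3, A0 = 2)
  fit <- fit_gompertz(tt, y, n_restarts = 40, seed = 7)
  expect_true(fit$retained)
  expect_lt(max(abs(predict(fit, tt) - y)), 1e-2)
  expect_equal(fit$delta_total, y[length(y)] - y[1L], tolerance = 1e-3)
})

test_that("a constant series fits as no growth", {
  tt <- design_times()
  fit <- fit_gompertz(tt, rep(3.2, length(tt)), n_restarts = 30, seed = 2)
  expect_true(fit$retained)
  expect_lt(abs(fit$delta_total), 1e-3)
  expect_lt(max(abs(predict(fit, tt) - 3.2)), 1e-2)
})

test_that("fitting is deterministic under a fixed seed", {
  tt <- design_times()
  set.seed(99)
  y <- gompertz_ln(tt, 4, 0.5, 5, 1) + rnorm(length(tt), sd = 0.1)
  f1 <- fit_gompertz(tt, y, n_restarts = 25, seed = 123)
  f2 <- fit_gompertz(tt, y, n_restarts = 25, seed = 123)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss, f2$loss)
})

test_that("fits on the mu ceiling are never selected", {
  # data generated at mu = 2.55 (inside the box but above the retention
  # cut): the lowest-loss restarts collapse toward the ceiling and must
  # be discarded in favour of an in-policy fit
  tt <- c(seq(0, 6, by = 0.25), 8, 10, 12, 24, 48)
  y <- gompertz_ln(tt, A = 8, mu = 2.55, lam = 2, A0 = 1)
  fit <- fit_gompertz(tt, y, n_restarts = 50, seed = 5)
  if (fit$retained) expect_lt(fit$params[["mu"]], 2.5)
  # and an unconstrained check: every retained fit ever returned obeys it
  set.seed(31)
  for (i in 1:3) {
    yy <- gompertz_ln(tt, runif(1, 2, 8), runif(1, 0.3, 2.4),
                      runif(1, 0, 6), 1) + rnorm(length(tt), sd = 0.05)
    f <- fit_gompertz(tt, yy, n_restarts = 25, seed = i)
    if (f$retained) expect_lt(f$params[["mu"]], 2.5)
  }
})

test_that("fitting demands at least five observations", {
  expect_error(fit_gompertz(1:4, 1:4, n_restarts = 5), "5")
  expect_error(fit_gompertz(c(0, 10, 20, 30, 250), rep(1, 5),
                            n_restarts = 5), "200")
})

test_that("refitting a fitted curve's own predictions does not worsen loss", {
  tt <- design_times()
  set.seed(4)
  y <- gompertz_ln(tt, 5, 0.7, 4, 2) + rnorm(length(tt), sd = 0.15)
  f1 <- fit_gompertz(tt, y, n_restarts = 30, seed = 10)
  f2 <- fit_gompertz(tt, predict(f1, tt), n_restarts = 30, seed = 10)
  expect_lte(f2$loss, f1$loss + 1e-6)
})

test_that("total growth agrees with integrating the growth rate", {
  p <- c(A = 5, mu = 1, lam = 3, A0 = 2)
  delta <- total_growth(p, 0, 127)
  # independent route: integrate dy/dt = mu * e * exp(u - exp(u))
  rate <- function(t) {
    u <- (p[["mu"]] * exp(1) / p[["A"]]) * (p[["lam"]] - t) + 1
    p[["mu"]] * exp(1) * exp(u - exp(u))
  }
  delta_int <- stats::integrate(rate, 0, 127, rel.tol = 1e-10)$value
  expect_equal(delta, delta_int, tolerance = 1e-6)
})

test_that("total growth limits behave", {
  # lag far beyond the window: nothing grows inside it
  expect_lt(total_growth(c(A = 5, mu = 1, lam = 11.9, A0 = 1), 0, 5), 1e-6)
  # full-range window recovers the amplitude
  expect_equal(total_growth(c(A = 5, mu = 1, lam = 3, A0 = 1),
                            -1e5, 1e5), 5)
  expect_error(total_growth(structure(list(retained = FALSE),
                                      class = "gompertz_fit")),
               "not retained")
})

test_that("ln-changes convert to doublings by log(2)", {
  expect_equal(round(doublings_from_delta_ln(1.48), 2), 2.14)
  expect_identical(doublings_from_delta_ln(0), 0)
  expect_equal(doublings_from_delta_ln(log(2)), 1)
  expect_error(doublings_from_delta_ln(NA), "finite")
})

test_that("time to capacity fraction matches its closed form", {
  p <- c(A = 10, mu = 1, lam = 2, A0 = 0)
  expect_equal(time_to_capacity_fraction(p, 0.8), 11.197, tolerance = 1e-3)
  # at q = exp(-e) the exponent collapses and t = lam exactly
  expect_equal(time_to_capacity_fraction(p, exp(-exp(1))), 2,
               tolerance = 1e-12)
  # forward consistency: the curve evaluated there sits at A0 + q * A
  for (q in c(0.2, 0.5, 0.8, 0.95)) {
    tq <- time_to_capacity_fraction(p, q)
    expect_equal(gompertz_ln(tq, p[["A"]], p[["mu"]], p[["lam"]],
                             p[["A0"]]), q * p[["A"]], tolerance = 1e-10)
  }
  expect_lt(time_to_capacity_fraction(p, 0.3),
            time_to_capacity_fraction(p, 0.9))
  expect_error(time_to_capacity_fraction(p, 1), "between")
  expect_error(time_to_capacity_fraction(c(A = 1, mu = 0, lam = 0,
                                           A0 = 0), 0.5), "never")
})

test_that("capacity fraction curve is the ECDF of per-taxon times", {
  fits <- list(c(A = 4, mu = 0.5, lam = 2, A0 = 1),
               c(A = 8, mu = 1.2, lam = 6, A0 = 0.5))
  tq <- sapply(fits, time_to_capacity_fraction, q = 0.8)
  grid <- sort(c(tq - 0.01, tq + 0.01, 0, 200))
  curve <- capacity_fraction_curve(fits, q = 0.8, times = grid)
  expect_equal(curve$fraction, ecdf(tq)(grid))
  expect_true(all(diff(curve$fraction) >= 0))
  expect_equal(curve$fraction[length(grid)], 1)
  # a single fit is a unit step at its own t(q)
  single <- capacity_fraction_curve(fits[1], q = 0.8,
                                    times = c(tq[1] - 1e-6, tq[1] + 1e-6))
  expect_equal(single$fraction, c(0, 1))
  expect_error(capacity_fraction_curve(list(), times = 1), "at least one")
})
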
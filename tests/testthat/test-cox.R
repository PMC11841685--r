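test_that("equal-risk partial likelihood has its closed form", {
  # three subjects, distinct times, all events, all scores zero:
  # risk sets shrink 3 -> 2 -> 1, so ll = -(ln 3 + ln 2 + ln 1)
  ll <- cox_partial_log_likelihood(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))
  expect_equal(ll, -log(6), tolerance = 1e-12)
})

test_that("tied event times match a hand-expanded Breslow sum", {
  # five subjects; times 1, 2, 2, 3, 4; events at 1, 2, 2, 4
  s <- c(0.5, -0.2, 0.3, 0.1, -0.4)
  time <- c(1, 2, 2, 3, 4)
  event <- c(1, 1, 1, 0, 1)
  w <- exp(s)
  hand <- (s[1] - log(sum(w))) +
    (s[2] + s[3] - 2 * log(w[2] + w[3] + w[4] + w[5])) +
    (s[5] - log(w[5]))
  expect_equal(cox_partial_log_likelihood(s, time, event), hand,
               tolerance = 1e-12)
  # Efron splits the tied pair's own hazard mass across the two events
  efron <- (s[1] - log(sum(w))) +
    (s[2] + s[3] - log(w[2] + w[3] + w[4] + w[5]) -
       log(w[2] + w[3] + w[4] + w[5] - 0.5 * (w[2] + w[3]))) +
    (s[5] - log(w[5]))
  expect_equal(cox_partial_log_likelihood(s, time, event, ties = "efron"),
               efron, tolerance = 1e-12)
})

test_that("partial likelihood is invariant to score shifts", {
  for (seed in 1:5) {
    inst <- random_instance(40, seed)
    s <- rnorm(40)
    base <- cox_partial_log_likelihood(s, inst$time, inst$event)
    expect_equal(cox_partial_log_likelihood(s + 17.3, inst$time, inst$event),
                 base, tolerance = 1e-8)
    expect_equal(cox_partial_log_likelihood(s - 250, inst$time, inst$event),
                 base, tolerance = 1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(cox_partial_log_likelihood(c(0, 0), c(1, 2), c(0, 0)), "no events")
  expect_error(cox_partial_log_likelihood(c(0, Inf), c(1, 2), c(1, 0)), "non-finite")
  expect_error(fit_linear_cox(matrix(1, 10, 1), 1:10, rep(1, 10)), "zero-variance")
})

test_that("analytic score-gradient matches finite differences", {
  inst <- random_instance(30, 11)
  s <- rnorm(30)
  g <- cox_pl_gradient(s, inst$time, inst$event)
  fd <- fd_gradient(function(x) cox_partial_log_likelihood(x, inst$time, inst$event), s)
  expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-6)
  # gradient components sum to zero (shift invariance)
  expect_lt(abs(sum(g)), 1e-10)
})

test_that("the Newton fitter agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(21)
  n <- 400
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
  psi <- drop(X %*% c(0.6, -0.4, 0.3))
  tt <- rexp(n, 0.02 * exp(psi))
  cc <- rexp(n, 0.01)
  y <- round(pmin(tt, cc), 1)          # rounding forces tied times
  y[y == 0] <- 0.05
  d <- as.integer(tt <= cc)
  for (ties in c("breslow", "efron")) {
    fit <- fit_linear_cox(X, y, d, ties = ties)
    ref <- survival::coxph(survival::Surv(y, d) ~ X, ties = ties)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$standard_errors),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-7)
  }
})

test_that("hazard ratios, CIs and p-values are mutually consistent", {
  set.seed(31)
  n <- 300
  X <- cbind(z = rnorm(n))
  y <- rexp(n, 0.05 * exp(0.5 * X[, 1]))
  fit <- fit_linear_cox(X, y, rep(1, n))
  expect_equal(fit$hazard_ratios, exp(fit$coefficients))
  expect_true(all(fit$ci_lower < fit$hazard_ratios &
                    fit$hazard_ratios < fit$ci_upper))
  z <- fit$coefficients / fit$standard_errors
  expect_equal(unname(fit$p_values), 2 * pnorm(-abs(unname(z))))
})

test_that("1-D fit matches grid-search maximization of the objective", {
  set.seed(41)
  n <- 50
  X <- cbind(x = rnorm(n))
  y <- rexp(n, 0.1 * exp(0.8 * X[, 1]))
  d <- rbinom(n, 1, 0.8); d[1] <- 1
  fit <- fit_linear_cox(X, y, d)
  obj <- function(b) cox_partial_log_likelihood(X[, 1] * b, y, d)
  grid <- seq(-3, 3, by = 0.01)
  b0 <- grid[which.max(vapply(grid, obj, numeric(1)))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  bhat <- fine[which.max(vapply(fine, obj, numeric(1)))]
  expect_lt(abs(fit$coefficients[[1]] - bhat), 1e-4)
})

test_that("separation is reported rather than silently diverging", {
  # perfectly separated binary covariate: event subjects all have x = 1
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  X <- cbind(x = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_linear_cox(X, time, event), "separation|converge")
})

test_that("Breslow baseline has its step-function properties", {
  # single event among n subjects with all scores zero: S0 jumps to exp(-1/n)
  n <- 8
  time <- seq_len(n)
  event <- c(1, rep(0, n - 1))
  b <- breslow_baseline(rep(0, n), time, event)
  expect_equal(b$surv, exp(-1 / n), tolerance = 1e-12)
  expect_equal(b$time, 1)

  inst <- random_instance(60, 13)
  s <- rnorm(60)
  bl <- breslow_baseline(s, inst$time, inst$event)
  expect_true(all(diff(bl$surv) <= 1e-15))
  expect_true(all(bl$surv > 0 & bl$surv <= 1))
  expect_error(breslow_baseline(rep(0, 3), 1:3, rep(0, 3)), "no events")
})

test_that("baseline agrees with the survival package's Breslow estimator", {
  skip_if_not_installed("survival")
  set.seed(51)
  n <- 200
  x <- rnorm(n)
  y <- rexp(n, 0.05 * exp(0.5 * x))
  d <- rbinom(n, 1, 0.7); d[1] <- 1
  fit <- survival::coxph(survival::Surv(y, d) ~ x, ties = "breslow")
  sf <- survival::survfit(fit, newdata = data.frame(x = 0), ctype = 1)
  mine <- breslow_baseline(coef(fit) * x, y, d)
  at_events <- sf$time %in% mine$time
  expect_equal(mine$cumhaz, sf$cumhaz[at_events], tolerance = 1e-8)
})

test_that("survival_function raises the baseline to the relative risk", {
  inst <- random_instance(50, 17)
  s <- rnorm(50)
  bl <- breslow_baseline(s, inst$time, inst$event)
  expect_equal(survival_function(bl, 0)$surv, bl$surv, tolerance = 1e-12)
  # doubling exp(psi) squares the curve pointwise
  a <- survival_function(bl, log(1))$surv
  b <- survival_function(bl, log(2))$surv
  expect_equal(b, a^2, tolerance = 1e-10)
  # evaluation before the first event time is 1
  expect_equal(survival_function(bl, 1.3, times = min(bl$time) / 2)$surv, 1)
  # a no-event (empty) baseline gives the constant-1 curve for any score
  empty <- structure(list(time = numeric(0), hazard = numeric(0),
                          cumhaz = numeric(0), surv = numeric(0)),
                     class = "icu_baseline")
  expect_equal(survival_function(empty, 3, times = c(1, 10, 100))$surv,
               c(1, 1, 1))
})

test_that("concordance ordering of curves is invariant to hazard scaling", {
  inst <- random_instance(40, 19)
  s <- rnorm(40)
  bl <- breslow_baseline(s, inst$time, inst$event)
  s_a <- 0.3; s_b <- 1.1
  base_order <- survival_function(bl, s_a)$surv >= survival_function(bl, s_b)$surv
  # multiplying every exp(psi) by a constant = shifting every score
  shift_order <- survival_function(bl, s_a + 2)$surv >=
    survival_function(bl, s_b + 2)$surv
  expect_identical(base_order, shift_order)
  expect_true(all(base_order))
})
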
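test_that("smooth_abs matches its closed form and limits", {
  expect_equal(smooth_abs(0), 0)
  expect_equal(smooth_abs(0, deriv = 1), 0)
  expect_equal(smooth_abs(1, 1e-4), 0.999900005, tolerance = 1e-9)
  # epsilon -> 0 recovers |x|
  xs <- seq(-2, 2, by = 0.25)
  expect_true(all(abs(smooth_abs(xs, 1e-10) - abs(xs)) < 1e-9))
  expect_error(smooth_abs(1, epsilon = 0), "positive")
  expect_error(smooth_abs(1, epsilon = -1), "positive")
})

test_that("smooth_abs satisfies the sandwich and shape properties", {
  for (eps in c(1e-6, 1e-4, 1e-2)) {
    xs <- c(-5, -1, -0.01, -1e-5, 0, 1e-5, 0.01, 1, 5)
    a <- smooth_abs(xs, eps)
    expect_true(all(a >= 0))
    expect_true(all(abs(a - abs(xs)) <= eps + 1e-15))
    expect_equal(a, rev(a))  # even function
    a1 <- smooth_abs(xs, eps, deriv = 1)
    expect_true(all(a1 > -1 & a1 < 1))
    expect_true(all(smooth_abs(xs, eps, deriv = 2) > 0))
  }
})

test_that("penalty values match the printed piecewise forms", {
  lasso <- penalty_config("lasso")
  scad <- penalty_config("scad")
  # theta = 0 gives 0 for every family
  expect_equal(penalty_value(0, 0.5, lasso), 0)
  expect_equal(penalty_value(0, 0.5, scad), 0)
  # SCAD flat region: lambda^2 (a + 1) / 2
  expect_equal(penalty_value(5, 1, scad), 3.7^0 * 1^2 * (3.7 + 1) / 2,
               tolerance = 1e-6)
  expect_equal(penalty_value(5, 1, scad), 2.35, tolerance = 1e-6)
  # ALASSO = weighted LASSO: w = 1/|theta0| = 0.5, lambda = 0.3, theta = 1
  al <- penalty_config("alasso", "single",
                       weights = list(beta = 0.5, alpha = numeric(0)))
  lam <- expand_lambda(0.3, p = 1, q = 0, al)
  expect_equal(lam, c(0, 0.15, 0))
  expect_equal(penalty_value(1, lam[2], al), 0.15, tolerance = 1e-4)
  # evenness
  th <- c(0.01, 0.3, 1.2, 4)
  for (cfg in list(lasso, scad))
    expect_equal(penalty_value(th, 0.4, cfg), penalty_value(-th, 0.4, cfg))
  expect_error(penalty_value(1, -0.1, lasso), "nonnegative")
})

test_that("penalty derivatives match central finite differences", {
  h <- 1e-6
  for (family in c("lasso", "scad")) {
    cfg <- penalty_config(family)
    for (lam in c(0, 0.1, 1)) {
      for (th in c(-2, -0.5, -0.05, 0.02, 0.4, 1.5, 4)) {
        fd1 <- (penalty_value(th + h, lam, cfg) -
                penalty_value(th - h, lam, cfg)) / (2 * h)
        expect_equal(penalty_value(th, lam, cfg, deriv = 1), fd1,
                     tolerance = 1e-6,
                     label = sprintf("%s d1 at theta=%g lambda=%g", family, th, lam))
        fd2 <- (penalty_value(th + h, lam, cfg, deriv = 1) -
                penalty_value(th - h, lam, cfg, deriv = 1)) / (2 * h)
        expect_equal(penalty_value(th, lam, cfg, deriv = 2), fd2,
                     tolerance = 1e-5,
                     label = sprintf("%s d2 at theta=%g lambda=%g", family, th, lam))
      }
    }
  }
})

test_that("SCAD is continuous (value and slope) at both knots", {
  lam <- 0.4
  a <- 3.7
  cfg <- penalty_config("scad", epsilon = 1e-9)
  h <- 1e-7
  for (knot in c(lam, a * lam)) {
    expect_equal(penalty_value(knot - h, lam, cfg),
                 penalty_value(knot + h, lam, cfg), tolerance = 1e-6)
    expect_equal(penalty_value(knot - h, lam, cfg, deriv = 1),
                 penalty_value(knot + h, lam, cfg, deriv = 1), tolerance = 1e-5)
  }
  # smoothed form converges to the exact piecewise values as eps -> 0
  exact <- function(u) {
    if (u <= lam) lam * u
    else if (u < a * lam) (2 * a * lam * u - u^2 - lam^2) / (2 * (a - 1))
    else lam^2 * (a + 1) / 2
  }
  for (u in c(0.1, lam, 0.8, a * lam, 2))
    expect_equal(penalty_value(u, lam, cfg), exact(u), tolerance = 1e-7)
})

test_that("adaptive weights invert unpenalized estimates and saturate", {
  fake <- structure(list(
    converged = TRUE,
    lambda = rep(0, 6),
    coefficients_std = list(beta = c(0.1, 2, -0.25), alpha = c(0, 0, 4))),
    class = "mpr")
  w <- make_adaptive_weights(fake)
  expect_equal(w$beta, c(0.5, 4))
  expect_equal(w$alpha, c(1e6, 0.25))  # exact zero saturates at the cap
  w2 <- make_adaptive_weights(fake, weight_cap = 10)
  expect_equal(w2$alpha[1], 10)
  fake$converged <- FALSE
  expect_error(make_adaptive_weights(fake), "converged")
  fake$converged <- TRUE
  fake$lambda <- rep(0.1, 6)
  expect_error(make_adaptive_weights(fake), "unpenalized")
})

test_that("expand_lambda lays out per-coefficient tuning parameters", {
  single <- penalty_config("lasso", "single")
  sep <- penalty_config("lasso", "separate")
  expect_equal(expand_lambda(0.2, 2, 2, single), c(0, 0.2, 0.2, 0, 0.2, 0.2))
  expect_equal(expand_lambda(c(0.1, 0.4), 1, 1, sep), c(0, 0.1, 0, 0.4))
  # separate with equal values reduces to the single expansion
  expect_equal(expand_lambda(c(0.3, 0.3), 3, 2, sep),
               expand_lambda(0.3, 3, 2, single))
  expect_error(expand_lambda(c(0.1, 0.2), 2, 2, single), "1 tuning")
  expect_error(expand_lambda(0.1, 2, 2, sep), "2 tuning")
  expect_error(expand_lambda(-0.1, 2, 2, single), "nonnegative")
})

test_that("penalty_config validates its invariants", {
  expect_error(penalty_config("scad", scad_a = 2), "greater than 2")
  expect_error(penalty_config("lasso", epsilon = 0), "positive")
  expect_error(penalty_config("alasso"), "weights")
  expect_error(penalty_config("lasso", weights = list(beta = 1, alpha = 1)),
               "alasso")
  expect_error(penalty_config("alasso",
                              weights = list(beta = -1, alpha = 1)),
               "nonnegative")
  expect_error(penalty_config("alasso", weight_cap = 10,
                              weights = list(beta = 100, alpha = 1)),
               "weight_cap")
})
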
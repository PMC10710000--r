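# The central correctness oracle: analytic score and information against
# finite differences of an independently coded penalized objective.
test_that("gradient and information match finite differences of the objective", {
  d <- make_test_data(n = 30, p = 2, q = 2, seed = 21)
  set.seed(22)
  theta <- rnorm(6, sd = 0.4)
  cases <- list(
    list(cfg = NULL, lam = rep(0, 6), family = "lasso"),
    list(cfg = penalty_config("lasso", "single"), lam = NULL, raw = 0.05,
         family = "lasso"),
    list(cfg = penalty_config("scad", "single"), lam = NULL, raw = 0.1,
         family = "scad"),
    list(cfg = penalty_config("alasso", "separate",
                              weights = list(beta = c(2, 0.5),
                                             alpha = c(1.5, 3))),
         lam = NULL, raw = c(0.08, 0.15), family = "lasso"))
  for (cs in cases) {
    lam_vec <- if (is.null(cs$lam))
      expand_lambda(cs$raw, d$p, d$q, cs$cfg) else cs$lam
    si <- mpr_score_info(theta[1:3], theta[4:6], d,
                         lambda = lam_vec, config = cs$cfg)
    f <- function(th) ref_objective(th, d, lam_vec, cs$family)
    expect_equal(si$objective, f(theta), tolerance = 1e-10)
    g_fd <- num_grad(f, theta)
    expect_equal(si$gradient, g_fd, tolerance = 1e-5,
                 label = paste("gradient", cs$family))
    H_fd <- -num_hess(f, theta)
    expect_equal(si$information, H_fd, tolerance = 1e-4,
                 label = paste("information", cs$family))
    # unpenalized information from finite differences of l0
    f0 <- function(th) ref_objective(th, d, rep(0, 6), "lasso")
    expect_equal(si$information0, -num_hess(f0, theta), tolerance = 1e-4)
  }
})

test_that("the exponential submodel score reduces to X'(delta - tau t)", {
  d <- make_test_data(n = 40, p = 2, q = 2, seed = 30)
  beta <- c(-0.3, 0.2, 0.1)
  si <- mpr_score_info(beta, c(0, 0, 0), d)  # gamma = 1 for all subjects
  tau <- exp(drop(d$X %*% beta))
  expect_equal(si$gradient0[1:3],
               unname(drop(crossprod(d$X, d$status - tau * d$time))),
               tolerance = 1e-10)
})

test_that("unpenalized fit is a stationary point and is idempotent", {
  d <- make_test_data(n = 150, p = 2, q = 2, seed = 31)
  f <- fit_unpenalized(d)
  expect_true(f$converged)
  expect_lt(f$gradient_norm, 1e-5)
  expect_equal(f$edf, 6)  # exactly p + q + 2
  expect_equal(f$bic, -2 * f$loglik + 6 * log(d$n))
  # refitting from the solution does not move
  init <- unlist(f$coefficients_std, use.names = FALSE)
  f2 <- fit_unpenalized(d, init = init)
  expect_lte(f2$n_iter, 2)
  expect_equal(unlist(f2$coefficients_std), unlist(f$coefficients_std),
               tolerance = 1e-8)
})

test_that("lambda = 0 penalized fit coincides with the unpenalized MLE", {
  d <- make_test_data(n = 120, p = 2, q = 1, seed = 32)
  un <- fit_unpenalized(d)
  cfg <- penalty_config("lasso", "single")
  pz <- fit_penalized(d, 0, cfg)
  expect_equal(unlist(pz$coefficients_std), unlist(un$coefficients_std),
               tolerance = 1e-8)
  # sandwich covariance reduces to the inverse observed information exactly
  expect_equal(pz$vcov_std, un$vcov_std, tolerance = 1e-12)
  si <- mpr_score_info(un$coefficients_std$beta, un$coefficients_std$alpha, d)
  expect_equal(un$vcov_std, solve(si$information0),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(pz$edf, d$p + d$q + 2)
})

test_that("penalized fits are stationary points of the smoothed objective", {
  d <- make_test_data(n = 200, p = 3, q = 3, seed = 33,
                      beta = c(-0.5, 0.6, 0, -0.4), alpha = c(0.2, 0, 0.3, 0))
  cfg <- penalty_config("lasso", "single")
  ctl <- mpr_control(final_tol = 1e-9, final_max_iter = 2000)
  f <- fit_penalized(d, 0.05, cfg, control = ctl)
  expect_true(f$converged)
  expect_lt(f$gradient_norm, 1e-5)
  # ascent: penalized objective at the solution >= at the (unpenalized) init
  un <- fit_unpenalized(d)
  si0 <- mpr_score_info(un$coefficients_std$beta, un$coefficients_std$alpha,
                        d, lambda = 0.05, config = cfg)
  expect_gte(f$objective, si0$objective)
})

test_that("a huge lasso penalty empties both active sets and edf -> 2", {
  d <- make_test_data(n = 150, p = 3, q = 2, seed = 34,
                      beta = c(-0.5, 0.8, -0.6, 0.4), alpha = c(0.2, 0.3, -0.2))
  cfg <- penalty_config("lasso", "single")
  f <- fit_penalized(d, 1e3, cfg)
  expect_true(f$converged)
  expect_false(any(f$active$scale))
  expect_false(any(f$active$shape))
  expect_lt(abs(f$edf - 2), 0.05)
  # shrinkage reduces reported variance (typical, not universal): selected-out
  # coefficients have collapsed sandwich variances and the average penalized
  # variance does not increase on this dataset
  fm <- fit_penalized(d, 0.3, cfg)
  f0 <- fit_penalized(d, 0, cfg)
  slopes <- c(2:4, 6:7)
  inact <- slopes[c(!fm$active$scale, !fm$active$shape)]
  expect_true(length(inact) > 0)
  expect_true(all(diag(fm$vcov_std)[inact] < 0.1 * diag(f0$vcov_std)[inact]))
  expect_lt(mean(diag(fm$vcov_std)[slopes] / diag(f0$vcov_std)[slopes]), 1)
})

test_that("effective df decreases monotonically along an increasing lambda path", {
  d <- make_test_data(n = 150, p = 2, q = 2, seed = 35)
  cfg <- penalty_config("lasso", "single")
  path <- c(0, 0.005, 0.02, 0.05, 0.1, 0.3, 1, 10)
  edfs <- vapply(path, function(l) fit_penalized(d, l, cfg)$edf, numeric(1))
  expect_true(all(diff(edfs) <= 1e-6))
  expect_equal(edfs[1], 6)
})

test_that("alasso with unit weights is identical to the lasso", {
  d <- make_test_data(n = 120, p = 2, q = 2, seed = 36)
  la <- penalty_config("lasso", "single")
  al <- penalty_config("alasso", "single",
                       weights = list(beta = c(1, 1), alpha = c(1, 1)))
  f1 <- fit_penalized(d, 0.08, la)
  f2 <- fit_penalized(d, 0.08, al)
  expect_identical(unlist(f1$coefficients_std), unlist(f2$coefficients_std))
})

test_that("standardize-and-backtransform equals fitting on original units", {
  set.seed(37)
  n <- 200
  x <- cbind(a = rnorm(n, 5, 2), b = rnorm(n, -1, 0.5))
  tau <- exp(-1 + 0.2 * x[, 1] - 0.5 * x[, 2])
  gam <- exp(0.3 - 0.05 * x[, 1])
  tt <- (-log(runif(n)) / tau)^(1 / gam)
  d_std <- mpr_data(tt, rep(1, n), x)
  d_raw <- mpr_data(tt, rep(1, n), x, standardize = FALSE)
  f_std <- fit_unpenalized(d_std)
  f_raw <- fit_unpenalized(d_raw)
  expect_equal(unlist(f_std$coefficients), unlist(f_raw$coefficients),
               tolerance = 1e-6)
  expect_equal(f_std$vcov, f_raw$vcov, tolerance = 1e-4)
  expect_equal(f_std$loglik, f_raw$loglik, tolerance = 1e-8)
})

test_that("sandwich SEs of active coefficients track the oracle information", {
  # for an unpenalized fit the reported SE must equal sqrt(diag(I0^-1))
  d <- make_test_data(n = 300, p = 2, q = 2, seed = 38)
  f <- fit_unpenalized(d)
  si <- mpr_score_info(f$coefficients_std$beta, f$coefficients_std$alpha, d)
  V <- unstd_vcov_for_test(solve(si$information0), d)
  expect_equal(unname(c(f$se$beta, f$se$alpha)), sqrt(diag(V)),
               tolerance = 1e-8)
})
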
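write_sim_csv <- function(n = 150, seed = 60, path = tempfile(fileext = ".csv")) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  grp <- sample(c("lo", "hi"), n, replace = TRUE)
  tau <- exp(-0.8 + 0.7 * x1)
  gam <- exp(0.2 - 0.25 * x2)
  tt <- (-log(runif(n)) / tau)^(1 / gam)
  cc <- runif(n, 0, quantile(tt, 0.8) * 2)
  df <- data.frame(time = pmin(tt, cc), status = as.numeric(tt <= cc),
                   x1 = x1, x2 = x2, grp = grp)
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_survival_data builds a standardized dataset with dummies", {
  path <- write_sim_csv()
  md <- read_survival_data(path, scale = c("x1", "grp"), shape = "x2")
  expect_s3_class(md, "mpr_data")
  expect_equal(md$p, 2)  # x1 + one dummy for the two-level factor
  expect_equal(md$q, 1)
  expect_true(all(abs(colMeans(md$X[, -1, drop = FALSE])) < 1e-12))
  expect_equal(unname(apply(md$X[, -1, drop = FALSE], 2, sd)), c(1, 1))
  expect_equal(unname(md$X[, 1]), rep(1, md$n))
})

test_that("reader errors name the offending column or row", {
  path <- write_sim_csv()
  expect_error(read_survival_data(path, scale = "nope"),
               class = "mpr_config_error")
  expect_error(read_survival_data("no-such-file.csv", scale = "x1"),
               class = "mpr_config_error")
  df <- read.csv(path)
  df$status[3] <- 2
  p2 <- tempfile(fileext = ".csv")
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_survival_data(p2, scale = "x1"), "binary")
  df <- read.csv(path)
  df$x1[5] <- NA
  write.csv(df, p2, row.names = FALSE)
  expect_error(read_survival_data(p2, scale = "x1"), "row 5")
})

test_that("mpr_run_fit writes a consistent, re-parsable coefficient report", {
  path <- write_sim_csv(n = 200, seed = 61)
  out <- file.path(tempdir(), "fit_out")
  cfg <- list(input = list(path = path, scale = c("x1", "x2"),
                           shape = c("x1", "x2")),
              penalty = list(family = "lasso", structure = "single"),
              tuning = list(pop_size = 8, max_gen = 10),
              seed = 3, output_dir = out)
  fit <- mpr_run_fit(cfg)
  expect_true(all(file.exists(file.path(out, c("coefficients.csv", "fit.json",
                                               "config_resolved.json",
                                               "run.log")))))
  tab <- read.csv(file.path(out, "coefficients.csv"))
  # round-trip: full-precision columns re-parse to the in-memory values
  expect_equal(tab$estimate,
               unname(unlist(fit$coefficients)), tolerance = 1e-12)
  expect_equal(tab$std_error, unname(unlist(fit$se)), tolerance = 1e-12)
  info <- jsonlite::read_json(file.path(out, "fit.json"), simplifyVector = TRUE)
  # single structure: exactly one lambda; report BIC reproduces Eq.-style
  # arithmetic from its own df and loglik fields
  expect_length(info$lambda, 1)
  expect_equal(info$bic, -2 * info$loglik + info$edf * log(info$n),
               tolerance = 1e-8)
  # resolved config re-runs to the same result
  fit2 <- mpr_run_fit(file.path(out, "config_resolved.json"))
  expect_equal(unlist(fit2$coefficients), unlist(fit$coefficients))
})

test_that("mpr_run_fit with separate tuning reports two lambdas", {
  path <- write_sim_csv(n = 150, seed = 62)
  out <- file.path(tempdir(), "fit_out2")
  fit <- mpr_run_fit(list(input = list(path = path, scale = c("x1", "x2")),
                          penalty = list(family = "alasso",
                                         structure = "separate"),
                          tuning = list(pop_size = 8, max_gen = 8),
                          seed = 4, output_dir = out))
  info <- jsonlite::read_json(file.path(out, "fit.json"), simplifyVector = TRUE)
  expect_length(info$lambda, 2)
  expect_true(all(info$lambda >= 0 & info$lambda <= 1))
})

test_that("mpr_run_simulate emits reproducible report tables", {
  out1 <- file.path(tempdir(), "sim1")
  out2 <- file.path(tempdir(), "sim2")
  cfg <- list(scenario = list(n = 200, n_covariates = 3, rho = 0.5,
                              beta = c(-1, -0.8, 0, 0.5),
                              alpha = c(0.4, 0.3, 0, 0),
                              censor_prop = 0.25, n_replicates = 3),
              penalties = list(list(family = "lasso", structure = "single")),
              tuning = list(pop_size = 8, max_gen = 8),
              seed = 5, output_dir = out1)
  mpr_run_simulate(cfg)
  sel <- read.csv(file.path(out1, "selection.csv"))
  expect_setequal(unique(sel$component), c("scale", "shape"))
  expect_true(all(c("C", "IC", "PT", "MSE") %in% names(sel)))
  inf <- read.csv(file.path(out1, "inference.csv"))
  expect_true(all(c("term", "truth", "mean", "SE", "SEE", "CP") %in% names(inf)))
  cfg$output_dir <- out2
  mpr_run_simulate(cfg)
  expect_identical(readLines(file.path(out1, "selection.csv")),
                   readLines(file.path(out2, "selection.csv")))
  expect_identical(readLines(file.path(out1, "inference.csv")),
                   readLines(file.path(out2, "inference.csv")))
})

test_that("malformed simulation scenarios are rejected before any computation", {
  expect_error(mpr_run_simulate(list(scenario = list(rho = 1),
                                     output_dir = tempdir())),
               class = "mpr_config_error")
})

test_that("mpr_run_diagnose writes adequacy points and a BIC surface", {
  # homogeneous Weibull, gamma = 2: adequacy line slope should be near 2
  set.seed(63)
  n <- 2000
  df <- data.frame(time = (-log(runif(n)))^(1 / 2), status = 1,
                   x1 = rnorm(n))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  out <- file.path(tempdir(), "diag_out")
  res <- mpr_run_diagnose(list(input = list(path = path, scale = "x1"),
                               grid = c(0.01, 0.05, 0.2),
                               output_dir = out))
  adeq <- read.csv(file.path(out, "adequacy.csv"))
  sl <- coef(lm(logH ~ logt, data = adeq))
  expect_lt(abs(sl[2] - 2), 0.1)
  surf <- read.csv(file.path(out, "bic_surface.csv"))
  expect_equal(nrow(surf), 3)
  expect_equal(surf$bic, -2 * surf$loglik + surf$df * log(n), tolerance = 1e-8)
  # no grid: surface step skipped with a notice
  out2 <- file.path(tempdir(), "diag_out2")
  expect_message(
    mpr_run_diagnose(list(input = list(path = path, scale = "x1"),
                          output_dir = out2, verbose = TRUE)),
    "skipping")
  expect_false(file.exists(file.path(out2, "bic_surface.csv")))
})

test_that("the CLI script is a well-formed thin wrapper", {
  script <- system.file("scripts", "mprselect-cli.R", package = "mprselect")
  expect_true(nzchar(script) && file.exists(script))
  code <- readLines(script)
  expect_true(any(grepl("mpr_run_fit", code)))
  expect_true(any(grepl("quit\\(status", code)))
})
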
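#' Simulation scenario for the Weibull MPR selection study
#'
#' Describes the data-generating process of the reference simulation design:
#' `n_covariates` marginally standard-normal covariates with AR(1) correlation
#' `rho^|j-k|` entering *both* regression components, Weibull event times
#' generated by inversion from the MPR model, and independent uniform
#' censoring `C ~ U(0, c*)` with `c*` calibrated so that the expected
#' censoring proportion equals `censor_prop`.  The default truth vectors are
#' the sparse design used throughout the reference study:
#' `beta = (-1.5, -1, 0, 0, 0, 0, 0, -0.8, 0.5, 0, 0)` and
#' `alpha = (0.5, 0.4, 0, 0, 0, 0.4, -0.2, 0, 0, 0, 0)` (intercepts first),
#' i.e. 7 true zeros in each component.
#'
#' @param n sample size per replicate.
#' @param n_covariates number of covariates (default 10).
#' @param rho AR(1) correlation between consecutive covariates (|rho| < 1).
#' @param beta,alpha true coefficient vectors including intercepts
#'   (length `n_covariates + 1`).
#' @param censor_prop target censoring proportion in `[0, 1)`; 0 disables
#'   censoring.
#' @param n_replicates default number of replicates for [mpr_sim_study()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return object of class `"mpr_scenario"`.
#' @export
mpr_scenario <- function(n = 1000, n_covariates = 10, rho = 0.5,
                         beta = c(-1.5, -1.0, 0, 0, 0, 0, 0, -0.8, 0.5, 0, 0),
                         alpha = c(0.5, 0.4, 0, 0, 0, 0.4, -0.2, 0, 0, 0, 0),
                         censor_prop = 0.25, n_replicates = 1000, seed = 1) {
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  if (censor_prop < 0 || censor_prop >= 1) stop("'censor_prop' must be in [0, 1)")
  if (n < 10) stop("'n' must be at least 10")
  if (length(beta) != n_covariates + 1L || length(alpha) != n_covariates + 1L)
    stop("'beta' and 'alpha' must have length n_covariates + 1 (intercept first)")
  structure(list(n = as.integer(n), n_covariates = as.integer(n_covariates),
                 rho = rho, beta = beta, alpha = alpha,
                 censor_prop = censor_prop,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "mpr_scenario")
}

#' @export
print.mpr_scenario <- function(x, ...) {
  cat(sprintf("Weibull MPR simulation scenario: n = %d, %d AR(1) covariates (rho = %g), %g%% censoring\n",
              x$n, x$n_covariates, x$rho, 100 * x$censor_prop))
  cat("  true beta: ", paste(format(x$beta), collapse = " "), "\n")
  cat("  true alpha:", paste(format(x$alpha), collapse = " "), "\n")
  invisible(x)
}

# AR(1) latent-recursion draw: marginally N(0,1), corr(x_j, x_k) = rho^|j-k|
ar1_covariates <- function(n, p, rho) {
  x <- matrix(rnorm(n * p), n, p)
  if (p > 1L)
    for (j in 2:p) x[, j] <- rho * x[, j - 1L] + sqrt(1 - rho^2) * x[, j]
  colnames(x) <- paste0("x", seq_len(p))
  x
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483629)
}

#' Calibrate the uniform censoring bound
#'
#' Finds `c*` such that `C ~ U(0, c*)` yields the scenario's target expected
#' censoring proportion, by root-finding on the censoring fraction of a large
#' Monte-Carlo pilot sample (whose seed is derived deterministically from the
#' scenario seed).
#'
#' @param scenario an [mpr_scenario()].
#' @param pilot_n pilot sample size.
#' @return the calibrated upper bound `c*` (or `Inf` when `censor_prop = 0`).
#' @export
censoring_bound <- function(scenario, pilot_n = 2e5) {
  stopifnot(inherits(scenario, "mpr_scenario"))
  if (scenario$censor_prop == 0) return(Inf)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(derive_seed(scenario$seed, 104729L))
  x <- ar1_covariates(pilot_n, scenario$n_covariates, scenario$rho)
  tau <- exp(scenario$beta[1L] + drop(x %*% scenario$beta[-1L]))
  gam <- exp(scenario$alpha[1L] + drop(x %*% scenario$alpha[-1L]))
  tt <- (-log(runif(pilot_n)) / tau)^(1 / gam)
  u <- runif(pilot_n)
  f <- function(cc) mean(tt > cc * u) - scenario$censor_prop
  hi <- quantile(tt, 0.99)
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e12)
      stop(sprintf("censoring calibration failed: even c* = %g leaves more than %.0f%% censored",
                   hi / 2, 100 * scenario$censor_prop))
  }
  uniroot(f, lower = 1e-10, upper = hi, tol = 1e-6 * hi)$root
}

#' Generate one simulated dataset
#'
#' Draws covariates, Weibull event times `T = (-log U / tau)^(1/gamma)` by
#' inversion, and uniform censoring times, returning the observed data.  The
#' same covariates enter the scale and shape designs.
#'
#' @param scenario an [mpr_scenario()].
#' @param seed seed for this replicate.
#' @param censor_upper optional precomputed [censoring_bound()] (computed on
#'   the fly when omitted, which is deterministic but slower in replicate
#'   loops).
#' @return data.frame with columns `time`, `status`, `x1..xp`; the scenario
#'   and the censoring bound are attached as attributes.
#' @export
mpr_simulate <- function(scenario, seed = scenario$seed, censor_upper = NULL) {
  stopifnot(inherits(scenario, "mpr_scenario"))
  if (is.null(censor_upper)) censor_upper <- censoring_bound(scenario)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  n <- scenario$n
  x <- ar1_covariates(n, scenario$n_covariates, scenario$rho)
  tau <- exp(scenario$beta[1L] + drop(x %*% scenario$beta[-1L]))
  gam <- exp(scenario$alpha[1L] + drop(x %*% scenario$alpha[-1L]))
  tt <- (-log(runif(n)) / tau)^(1 / gam)
  if (is.finite(censor_upper)) {
    cc <- runif(n, 0, censor_upper)
    time <- pmin(tt, cc)
    status <- as.numeric(tt <= cc)
  } else {
    time <- tt
    status <- rep(1, n)
  }
  out <- data.frame(time = time, status = status, x)
  attr(out, "scenario") <- scenario
  attr(out, "censor_upper") <- censor_upper
  out
}

#' Selection metrics for one replicate
#'
#' Compares the active set of the non-intercept coefficients of one component
#' with the truth: `C` counts true zeros correctly set to zero, `IC` counts
#' true non-zeros incorrectly set to zero, and `exact` flags exact support
#' recovery (`C` equals the number of true zeros *and* `IC = 0`).  For the
#' default scenario's oracle fit, `C = 7` and `IC = 0` by construction.
#'
#' @param active logical vector of selection flags for the non-intercept
#'   coefficients of one component.
#' @param truth numeric vector of true non-intercept coefficients.
#' @return named numeric vector `c(C, IC, exact)`.
#' @export
selection_metrics <- function(active, truth) {
  if (length(active) != length(truth))
    stop("'active' and 'truth' lengths differ")
  zero <- truth == 0
  C <- sum(!active[zero])
  IC <- sum(!active[!zero])
  c(C = C, IC = IC, exact = as.numeric(C == sum(zero) && IC == 0))
}

#' Covariate-weighted mean squared error
#'
#' `MSE = (estimate - truth)' S (estimate - truth)` where `S` is the sample
#' covariance matrix of the covariates of the same replicate (intercepts
#' excluded).
#'
#' @param estimate,truth non-intercept coefficient vectors (original scale).
#' @param S covariate sample covariance matrix.
#' @return a nonnegative number.
#' @export
mse_metric <- function(estimate, truth, S) {
  S <- as.matrix(S)
  m <- length(truth)
  if (length(estimate) != m || nrow(S) != m || ncol(S) != m)
    stop("dimension mismatch between estimates, truth and S")
  if (rcond(S) < 1e-12)
    stop("singular covariate covariance matrix (need more rows than covariates)")
  d <- estimate - truth
  drop(t(d) %*% S %*% d)
}

#' Inference metrics across replicates
#'
#' For each coefficient: mean estimate, empirical standard deviation across
#' replicates (SE), mean model-based standard error (SEE) and empirical
#' coverage (CP) of the nominal Wald interval `estimate +/- z * SEE`.  A
#' coefficient whose replicate was selected out (flagged inactive) has a
#' degenerate interval: it is counted as covering only when the true value is
#' 0.
#'
#' @param estimates replicates-by-coefficients matrix of estimates.
#' @param sees matching matrix of model-based standard errors.
#' @param truth true coefficient vector.
#' @param active optional logical matrix of selection flags (intercolumn
#'   `TRUE` for always-active coefficients); `NULL` treats everything as
#'   active.
#' @param level nominal confidence level.
#' @return data.frame with one row per coefficient: `term`, `truth`, `mean`,
#'   `bias`, `SE`, `SEE`, `CP`.
#' @export
inference_metrics <- function(estimates, sees, truth, active = NULL,
                              level = 0.95) {
  estimates <- as.matrix(estimates)
  sees <- as.matrix(sees)
  if (nrow(estimates) < 2L) stop("need at least 2 replicates")
  if (!all(dim(estimates) == dim(sees)) || ncol(estimates) != length(truth))
    stop("dimension mismatch")
  if (anyNA(sees)) stop("missing standard errors")
  z <- qnorm(1 - (1 - level) / 2)
  wald <- abs(sweep(estimates, 2L, truth)) <= z * sees
  if (!is.null(active)) {
    active <- as.matrix(active)
    degenerate <- sweep(!active, 2L, truth == 0, "&")
    cover <- ifelse(active, wald, degenerate)
  } else {
    cover <- wald
  }
  data.frame(term = colnames(estimates) %||% paste0("theta", seq_along(truth)),
             truth = truth,
             mean = colMeans(estimates),
             bias = colMeans(estimates) - truth,
             SE = apply(estimates, 2L, sd),
             SEE = colMeans(sees),
             CP = colMeans(cover),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_label <- function(cfg) paste(cfg$family, cfg$structure, sep = "_")

# fit the benchmarks and the requested penalties on one replicate
run_one_replicate <- function(scenario, seed, censor_upper, penalties, bounds,
                              control, de, include_benchmarks) {
  dat <- mpr_simulate(scenario, seed = seed, censor_upper = censor_upper)
  p <- scenario$n_covariates
  x <- as.matrix(dat[, paste0("x", seq_len(p)), drop = FALSE])
  md <- mpr_data(dat$time, dat$status, x)
  S <- cov(x)
  unpen <- fit_unpenalized(md, control = control)
  k <- 2L * (p + 1L)
  record <- function(est, se, act_scale, act_shape, lambda_raw, fit) {
    list(est = est, se = se,
         active = c(act_scale, act_shape),
         lambda = lambda_raw,
         bic = if (is.null(fit)) NA_real_ else fit$bic,
         edf = if (is.null(fit)) NA_real_ else fit$edf,
         converged = if (is.null(fit)) NA else fit$converged)
  }
  out <- list()
  if (include_benchmarks) {
    out$unpenalized <- record(
      unlist(unpen$coefficients, use.names = FALSE),
      unlist(unpen$se, use.names = FALSE),
      unpen$active$scale, unpen$active$shape, numeric(0), unpen)
    # oracle: unpenalized fit on the true support of each component
    bsup <- which(scenario$beta[-1L] != 0)
    asup <- which(scenario$alpha[-1L] != 0)
    md_o <- mpr_data(dat$time, dat$status,
                     x[, bsup, drop = FALSE], x[, asup, drop = FALSE])
    fo <- fit_unpenalized(md_o, control = control)
    est <- se <- numeric(k)
    est[c(1L, 1L + bsup)] <- fo$coefficients$beta
    est[p + 1L + c(1L, 1L + asup)] <- fo$coefficients$alpha
    se[c(1L, 1L + bsup)] <- fo$se$beta
    se[p + 1L + c(1L, 1L + asup)] <- fo$se$alpha
    act_s <- seq_len(p) %in% bsup
    act_a <- seq_len(p) %in% asup
    out$oracle <- record(est, se, act_s, act_a, numeric(0), fo)
  }
  weights <- NULL
  for (i in seq_along(penalties)) {
    pen <- penalties[[i]]
    if (pen$family == "alasso" && is.null(weights))
      weights <- make_adaptive_weights(unpen)
    cfg <- penalty_config(pen$family, pen$structure,
                          weights = if (pen$family == "alasso") weights)
    tun <- select_lambda_de(md, cfg, bounds = bounds, unpenalized = unpen,
                            control = control,
                            de = de_control(pop_size = de$pop_size,
                                            max_gen = de$max_gen, F = de$F,
                                            CR = de$CR, tol = de$tol,
                                            patience = de$patience,
                                            seed = derive_seed(seed, 7000L + i)))
    fit <- tun$best_fit
    out[[config_label(cfg)]] <- record(
      unlist(fit$coefficients, use.names = FALSE),
      unlist(fit$se, use.names = FALSE),
      fit$active$scale, fit$active$shape, tun$lambda_star, fit)
  }
  list(fits = out, S = S)
}

#' Replicated simulation study
#'
#' Runs the full selection/inference study: for each replicate a dataset is
#' generated, the unpenalized and oracle benchmark models are fitted, and each
#' requested penalty is tuned by BIC/differential evolution and refitted.
#' Selection metrics (C, IC, PT, MSE) are aggregated per component and
#' inference metrics (mean estimate, SE, SEE, CP) per coefficient.  Replicate
#' seeds are derived from the scenario's master seed by a counter scheme, so
#' serial and parallel runs give identical results.
#'
#' @param scenario an [mpr_scenario()].
#' @param penalties list of penalty requests, each a list with elements
#'   `family` and `structure`, e.g.
#'   `list(list(family = "alasso", structure = "separate"))`.
#' @param n_replicates number of replicates (defaults to the scenario's).
#' @param bounds tuning search box per dimension.
#' @param control an [mpr_control()].
#' @param de a [de_control()] (its seed field is ignored; per-replicate DE
#'   seeds are derived internally).
#' @param include_benchmarks also fit the unpenalized (worst-case) and oracle
#'   (best-case) benchmark models.
#' @param cores parallelize over replicates with this many forked workers
#'   (identical results for any value).
#' @param max_fail_frac abort when more than this fraction of replicates fail.
#' @param verbose print progress.
#' @return object of class `"mpr_sim_report"`: `selection` and `inference`
#'   data.frames, raw per-replicate results in `raw`, failure count, and the
#'   scenario.
#' @export
mpr_sim_study <- function(scenario,
                          penalties = list(list(family = "alasso",
                                                structure = "separate")),
                          n_replicates = NULL, bounds = c(0, 1),
                          control = mpr_control(), de = de_control(),
                          include_benchmarks = TRUE, cores = 1L,
                          max_fail_frac = 0.1, verbose = FALSE) {
  stopifnot(inherits(scenario, "mpr_scenario"))
  R <- n_replicates %||% scenario$n_replicates
  cstar <- censoring_bound(scenario)
  seeds <- vapply(seq_len(R), function(r) derive_seed(scenario$seed, r), integer(1L))
  worker <- function(r) {
    res <- tryCatch(
      run_one_replicate(scenario, seeds[r], cstar, penalties, bounds,
                        control, de, include_benchmarks),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "replicate_failure"))
    if (verbose && r %% 10 == 0) message("replicate ", r, " done")
    res
  }
  raw <- if (cores > 1L) {
    parallel::mclapply(seq_len(R), worker, mc.cores = cores)
  } else {
    lapply(seq_len(R), worker)
  }
  failed <- vapply(raw, inherits, logical(1L), "replicate_failure")
  if (mean(failed) > max_fail_frac)
    stop(sprintf("%d/%d replicates failed (first message: %s)",
                 sum(failed), R, raw[[which(failed)[1L]]]$message))
  raw_ok <- raw[!failed]
  aggregate_sim_report(scenario, raw_ok, sum(failed))
}

aggregate_sim_report <- function(scenario, raw, n_failed) {
  p <- scenario$n_covariates
  labels <- names(raw[[1L]]$fits)
  terms <- c(paste0("beta", 0:p), paste0("alpha", 0:p))
  truth <- c(scenario$beta, scenario$alpha)
  sel_rows <- list()
  inf_rows <- list()
  raw_out <- list()
  for (lb in labels) {
    est <- t(vapply(raw, function(r) r$fits[[lb]]$est, numeric(2L * (p + 1L))))
    se <- t(vapply(raw, function(r) r$fits[[lb]]$se, numeric(2L * (p + 1L))))
    act <- t(vapply(raw, function(r) r$fits[[lb]]$active, logical(2L * p)))
    colnames(est) <- colnames(se) <- terms
    mse_s <- vapply(seq_along(raw), function(i)
      mse_metric(est[i, 2:(p + 1L)], scenario$beta[-1L], raw[[i]]$S), numeric(1L))
    mse_a <- vapply(seq_along(raw), function(i)
      mse_metric(est[i, (p + 3L):(2L * p + 2L)], scenario$alpha[-1L], raw[[i]]$S),
      numeric(1L))
    sm_s <- t(apply(act[, seq_len(p), drop = FALSE], 1L, selection_metrics,
                    truth = scenario$beta[-1L]))
    sm_a <- t(apply(act[, p + seq_len(p), drop = FALSE], 1L, selection_metrics,
                    truth = scenario$alpha[-1L]))
    sel_rows[[lb]] <- data.frame(
      penalty = lb, component = c("scale", "shape"), n = scenario$n,
      C = c(mean(sm_s[, "C"]), mean(sm_a[, "C"])),
      IC = c(mean(sm_s[, "IC"]), mean(sm_a[, "IC"])),
      PT = c(mean(sm_s[, "exact"]), mean(sm_a[, "exact"])),
      MSE = c(mean(mse_s), mean(mse_a)))
    act_full <- cbind(TRUE, act[, seq_len(p), drop = FALSE],
                      TRUE, act[, p + seq_len(p), drop = FALSE])
    im <- inference_metrics(est, se, truth, active = act_full)
    im <- cbind(penalty = lb, im)
    inf_rows[[lb]] <- im
    raw_out[[lb]] <- list(
      est = est, se = se, active = act,
      lambda = lapply(raw, function(r) r$fits[[lb]]$lambda),
      bic = vapply(raw, function(r) r$fits[[lb]]$bic, numeric(1L)),
      edf = vapply(raw, function(r) r$fits[[lb]]$edf, numeric(1L)),
      converged = vapply(raw, function(r) isTRUE(r$fits[[lb]]$converged),
                         logical(1L)),
      mse_scale = mse_s, mse_shape = mse_a,
      selection_scale = sm_s, selection_shape = sm_a)
  }
  structure(list(selection = do.call(rbind, c(sel_rows, make.row.names = FALSE)),
                 inference = do.call(rbind, c(inf_rows, make.row.names = FALSE)),
                 raw = raw_out, scenario = scenario,
                 n_replicates = length(raw), n_failed = n_failed),
            class = "mpr_sim_report")
}

#' @export
print.mpr_sim_report <- function(x, digits = 3, ...) {
  cat(sprintf("Simulation study: %d replicates (%d failed), n = %d, %g%% target censoring\n\n",
              x$n_replicates, x$n_failed, x$scenario$n,
              100 * x$scenario$censor_prop))
  cat("Selection metrics (C = correct zeros, IC = incorrect zeros, PT = exact support):\n")
  sel <- x$selection
  sel[, c("C", "IC", "PT", "MSE")] <- round(sel[, c("C", "IC", "PT", "MSE")], digits)
  print(sel, row.names = FALSE)
  cat("\n(inference metrics in $inference)\n")
  invisible(x)
}
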
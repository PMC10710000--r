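#' BIC of a fitted model
#'
#' `BIC(lambda) = -2 l0(theta_hat) + df * log(n)` where `l0` is the
#' *unpenalized* log-likelihood evaluated at the penalized estimates and `df`
#' the effective degrees of freedom `tr[I^-1 I0]`.  A non-converged fit gets
#' `+Inf` so that optimizers discard it.
#'
#' @param fit a fitted `"mpr"` object.
#' @return a single number (possibly `Inf`).
#' @export
mpr_bic <- function(fit) {
  stopifnot(inherits(fit, "mpr"))
  if (!isTRUE(fit$converged)) return(Inf)
  -2 * fit$loglik + fit$edf * log(fit$n)
}

#' Differential-evolution settings
#'
#' @param pop_size population size; default `max(15, 10 * dim)`.
#' @param max_gen maximum number of generations.
#' @param F mutation factor of the rand/1 scheme.
#' @param CR binomial crossover probability.
#' @param tol,patience early stop when the best objective value improves by
#'   less than `tol` over `patience` consecutive generations.
#' @param seed optional integer seed making the optimization reproducible.
#' @return list of class `"de_control"`.
#' @export
de_control <- function(pop_size = NULL, max_gen = 100L, F = 0.8, CR = 0.9,
                       tol = 1e-4, patience = 10L, seed = NULL) {
  stopifnot(max_gen >= 1, F > 0, CR >= 0, CR <= 1, tol >= 0, patience >= 1)
  structure(list(pop_size = pop_size, max_gen = as.integer(max_gen), F = F,
                 CR = CR, tol = tol, patience = as.integer(patience),
                 seed = seed),
            class = "de_control")
}

#' Differential-evolution minimizer (rand/1/bin)
#'
#' Population-based stochastic global minimizer over a box: mutation
#' `v = x_r1 + F (x_r2 - x_r3)`, binomial crossover with probability `CR`, and
#' greedy selection.  The initial population is uniform over the box except
#' that the first member sits at the lower corner (for tuning-parameter use
#' this guarantees a candidate with essentially no penalty, so the selected
#' objective can never beat the unpenalized model by less than the tolerance).
#' Non-finite objective values are treated as `+Inf`.
#'
#' @param fn objective function taking a numeric vector of length `length(lower)`.
#' @param lower,upper bounds of the search box.
#' @param control a [de_control()].
#' @return list with `par`, `value`, `history` (one row per generation:
#'   generation, best parameters, best value), `n_eval`, `population` and
#'   `pop_values` at exit.
#' @export
de_optimize <- function(fn, lower, upper, control = de_control()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (!is.null(control$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(control$seed)
  }
  np <- if (is.null(control$pop_size)) max(15L, 10L * d) else as.integer(control$pop_size)
  np <- max(np, 4L)
  # mixed initial spread: half the population uniform over the box, half
  # log-uniform.  BIC tuning surfaces typically have their basin within a few
  # hundredths of the box width from the origin, which a purely uniform draw
  # of ~15 members rarely samples; the uniform half keeps coverage of wide
  # basins elsewhere.
  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                np, d)
  logi <- seq_len(np) %% 2L == 0L
  pop[logi, ] <- matrix(10^runif(sum(logi) * d, -3, 0), sum(logi), d) *
    rep(upper - lower, each = sum(logi)) + rep(lower, each = sum(logi))
  pop[1L, ] <- lower  # near-zero-penalty member
  val <- apply(pop, 1L, function(p) {
    v <- fn(p); if (is.finite(v)) v else Inf
  })
  n_eval <- np
  hist <- vector("list", control$max_gen + 1L)
  best <- which.min(val)
  hist[[1L]] <- c(generation = 0, pop[best, ], value = val[best])
  stall <- 0L
  gen <- 0L
  for (gen in seq_len(control$max_gen)) {
    prev_best <- min(val)
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3L)
      v <- pop[r[1L], ] + control$F * (pop[r[2L], ] - pop[r[3L], ])
      # bounce-back: out-of-box components are resampled between the violated
      # bound and the base vector (hard clamping makes the bounds absorbing
      # and can collapse the population onto a boundary)
      low <- v < lower
      if (any(low))
        v[low] <- lower[low] + runif(sum(low)) * (pop[r[1L], low] - lower[low])
      high <- v > upper
      if (any(high))
        v[high] <- upper[high] - runif(sum(high)) * (upper[high] - pop[r[1L], high])
      v <- pmin(pmax(v, lower), upper)
      jr <- sample.int(d, 1L)
      cross <- runif(d) < control$CR
      cross[jr] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tv <- fn(trial)
      if (!is.finite(tv)) tv <- Inf
      n_eval <- n_eval + 1L
      if (tv <= val[i]) {
        pop[i, ] <- trial
        val[i] <- tv
      }
    }
    best <- which.min(val)
    hist[[gen + 1L]] <- c(generation = gen, pop[best, ], value = val[best])
    stall <- if (prev_best - val[best] < control$tol) stall + 1L else 0L
    if (stall >= control$patience) break
  }
  hist <- do.call(rbind, hist[!vapply(hist, is.null, logical(1L))])
  hist <- as.data.frame(hist)
  names(hist) <- c("generation", paste0("par", seq_len(d)), "value")
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], history = hist,
       n_eval = n_eval, population = pop, pop_values = val)
}

tuning_objective <- function(data, config, control, init_theta) {
  function(lambda_raw) {
    fit <- tryCatch(
      fit_penalized(data, lambda_raw, config, init = init_theta,
                    control = control, final = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    mpr_bic(fit)
  }
}

finalize_tuning <- function(data, config, control, init_theta, lambda_star,
                            bic_star, history, n_eval, bounds) {
  best_fit <- fit_penalized(data, lambda_star, config, init = init_theta,
                            control = control, final = TRUE)
  structure(list(lambda_star = lambda_star, best_fit = best_fit,
                 bic_star = mpr_bic(best_fit), bic_search = bic_star,
                 history = history, n_eval = n_eval, bounds = bounds),
            class = "mpr_tuning")
}

#' @export
print.mpr_tuning <- function(x, ...) {
  cat("Tuning-parameter selection by BIC\n")
  cat("  lambda* =", paste(format(x$lambda_star, digits = 4), collapse = ", "),
      "  BIC =", format(x$bic_star, digits = 7), "\n")
  cat("  inner fits evaluated:", x$n_eval, "\n")
  invisible(x)
}

#' Select tuning parameters by differential evolution
#'
#' Minimizes `BIC(lambda)` over the tuning box.  Each candidate lambda is
#' evaluated by a penalized Newton fit started from the unpenalized estimates
#' (the reference algorithm; a warm-start option exists in [mpr_control()]).
#' The BIC surface is typically multi-modal because the effective df drops
#' sharply whenever a coefficient crosses into the active set, so a global
#' optimizer is used rather than a local one; a grid search is available as
#' [select_lambda_grid()].  The winning lambda is refitted at the strict final
#' tolerances.
#'
#' @param data an [mpr_data()].
#' @param config a [penalty_config()] (for the ALASSO it must already carry
#'   the adaptive weights).
#' @param bounds numeric of length 2 `c(lo, hi)` applied to each dimension, or
#'   a 2-row matrix with one column per dimension.  Default `[0, 1]` per
#'   dimension on the standardized scale.
#' @param unpenalized optional precomputed unpenalized `"mpr"` fit (used for
#'   initialization); computed if omitted.
#' @param control an [mpr_control()].
#' @param de a [de_control()].
#' @return object of class `"mpr_tuning"`: `lambda_star`, `best_fit`,
#'   `bic_star`, `history`, `n_eval`, `bounds`.
#' @export
select_lambda_de <- function(data, config, bounds = c(0, 1),
                             unpenalized = NULL, control = mpr_control(),
                             de = de_control()) {
  stopifnot(inherits(data, "mpr_data"), inherits(config, "penalty_config"))
  d <- if (config$structure == "single") 1L else 2L
  bm <- if (is.matrix(bounds)) bounds else matrix(rep(bounds, d), 2L, d)
  if (any(bm[1L, ] < 0)) stop("tuning-parameter bounds must be nonnegative")
  if (is.null(unpenalized)) unpenalized <- fit_unpenalized(data, control = control)
  init_theta <- unlist(unpenalized$coefficients_std, use.names = FALSE)
  fn <- tuning_objective(data, config, control, init_theta)
  if (all(bm[1L, ] == bm[2L, ])) {  # degenerate box: single evaluation
    lam <- bm[1L, ]
    return(finalize_tuning(data, config, control, init_theta, lam, fn(lam),
                           history = NULL, n_eval = 1L, bounds = bm))
  }
  opt <- de_optimize(fn, bm[1L, ], bm[2L, ], control = de)
  if (!is.finite(opt$value))
    stop("no tuning candidate produced a converged fit; widen the bounds or relax the control settings")
  finalize_tuning(data, config, control, init_theta, opt$par, opt$value,
                  opt$history, opt$n_eval, bm)
}

#' Select tuning parameters by grid search
#'
#' Exhaustive BIC evaluation over a user grid; also returns the full BIC
#' surface (lambda, effective df, log-likelihood, BIC) for diagnostics and
#' plotting.
#'
#' @param data an [mpr_data()].
#' @param config a [penalty_config()].
#' @param grid numeric vector (single tuning parameter) or a matrix /
#'   data.frame with one column per tuning dimension.
#' @param unpenalized,control as in [select_lambda_de()].
#' @return object of class `"mpr_tuning"` with an additional `surface`
#'   data.frame.
#' @export
select_lambda_grid <- function(data, config, grid, unpenalized = NULL,
                               control = mpr_control()) {
  stopifnot(inherits(data, "mpr_data"), inherits(config, "penalty_config"))
  d <- if (config$structure == "single") 1L else 2L
  G <- as.matrix(grid)
  if (ncol(G) != d)
    stop(sprintf("grid has %d column(s) but the structure needs %d", ncol(G), d))
  if (nrow(G) == 0L) stop("empty tuning grid")
  if (is.null(unpenalized)) unpenalized <- fit_unpenalized(data, control = control)
  init_theta <- unlist(unpenalized$coefficients_std, use.names = FALSE)
  rows <- vector("list", nrow(G))
  vals <- numeric(nrow(G))
  for (i in seq_len(nrow(G))) {
    fit <- tryCatch(
      fit_penalized(data, G[i, ], config, init = init_theta,
                    control = control, final = FALSE),
      error = function(e) NULL)
    vals[i] <- if (is.null(fit)) Inf else mpr_bic(fit)
    rows[[i]] <- data.frame(t(G[i, ]),
                            df = if (is.null(fit)) NA_real_ else fit$edf,
                            loglik = if (is.null(fit)) NA_real_ else fit$loglik,
                            bic = vals[i])
  }
  surface <- do.call(rbind, rows)
  names(surface)[seq_len(d)] <- if (d == 1L) "lambda" else c("lambda_beta", "lambda_alpha")
  best <- which.min(vals)
  if (!is.finite(vals[best]))
    stop("no grid point produced a converged fit")
  out <- finalize_tuning(data, config, control, init_theta, G[best, ],
                         vals[best], history = NULL, n_eval = nrow(G),
                         bounds = apply(G, 2L, range))
  out$surface <- surface
  out
}
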
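#' Penalized Weibull multi-parameter regression
#'
#' Fits the Weibull MPR survival model
#' \deqn{h(t)=\tau\gamma t^{\gamma-1},\qquad
#'   \log\tau_i=x_i'\beta,\quad \log\gamma_i=z_i'\alpha,}
#' optionally with LASSO, SCAD or adaptive-LASSO penalized likelihood for
#' simultaneous variable selection in both regression components.  Covariates
#' are standardized internally for penalization and coefficients are reported
#' on the original scale.  When `lambda` is not supplied, the tuning
#' parameter(s) are selected by minimizing the effective-df BIC with a
#' differential-evolution global optimizer.
#'
#' The model formula uses a two-part right-hand side separated by `|`: the
#' first part gives the scale (`beta`) covariates, the second the shape
#' (`alpha`) covariates, e.g.
#' `Surv(time, status) ~ age + trt | trt + sex`.  Without a bar the same
#' covariates enter both components.  The left-hand side is a
#' [survival::Surv()] object (right censoring only).
#'
#' @param formula model formula as described above.
#' @param data data.frame holding the variables.
#' @param penalty `"none"` (unpenalized maximum likelihood), `"lasso"`,
#'   `"scad"` or `"alasso"`.
#' @param structure `"single"` for one tuning parameter shared by both
#'   components, `"separate"` for component-specific `lambda_beta`,
#'   `lambda_alpha`.
#' @param lambda optional fixed tuning parameter(s) (length 1 or 2 according
#'   to `structure`); when `NULL` they are selected by BIC/differential
#'   evolution over `bounds`.
#' @param bounds search box for the tuning parameters, per dimension.
#' @param weights optional adaptive weights for `penalty = "alasso"` (list
#'   with `beta`, `alpha`); computed from the unpenalized fit when omitted.
#' @param scad_a,epsilon,weight_cap penalty hyper-parameters, see
#'   [penalty_config()].
#' @param control an [mpr_control()].
#' @param de a [de_control()]; set `de$seed` for a reproducible search.
#' @return An object of class `"mpr"` with components including
#'   `coefficients` (list `beta`, `alpha`, original scale),
#'   `coefficients_std`, `vcov` (sandwich covariance, original scale), `se`,
#'   `loglik` (unpenalized log-likelihood at the estimates), `edf`, `bic`,
#'   `lambda`/`lambda_raw`, `active` (selection flags for the non-intercept
#'   coefficients), `converged`, `n_iter`, and for tuned fits `tuning` (an
#'   `"mpr_tuning"` object).  Methods: [print()], [summary()], [coef()],
#'   [vcov()], [logLik()], [predict()], [hazard_ratio()].
#' @examples
#' set.seed(42)
#' sc <- mpr_scenario(n = 300, n_covariates = 3,
#'                    beta = c(-1, 0.8, 0, 0), alpha = c(0.3, 0, 0.4, 0),
#'                    censor_prop = 0.2)
#' d <- mpr_simulate(sc, seed = 1)
#' f <- mpr(survival::Surv(time, status) ~ x1 + x2 + x3, data = d,
#'          penalty = "alasso", structure = "separate",
#'          de = de_control(max_gen = 20, seed = 7))
#' summary(f)
#' @export
mpr <- function(formula, data, penalty = c("none", "lasso", "scad", "alasso"),
                structure = c("single", "separate"), lambda = NULL,
                bounds = c(0, 1), weights = NULL, scad_a = 3.7,
                epsilon = 1e-4, weight_cap = 1e6,
                control = mpr_control(), de = de_control()) {
  penalty <- match.arg(penalty)
  structure <- match.arg(structure)
  cl <- match.call()
  parts <- parse_mpr_formula(formula, data)
  md <- mpr_data(parts$time, parts$status, parts$x, parts$z)
  unpen <- fit_unpenalized(md, control = control)
  if (penalty == "none") {
    fit <- unpen
  } else {
    if (penalty == "alasso" && is.null(weights))
      weights <- make_adaptive_weights(unpen, weight_cap = weight_cap)
    cfg <- penalty_config(penalty, structure, scad_a = scad_a,
                          epsilon = epsilon,
                          weights = if (penalty == "alasso") weights,
                          weight_cap = weight_cap)
    if (!is.null(lambda)) {
      fit <- fit_penalized(md, lambda, cfg, init = unpen, control = control)
    } else {
      tun <- select_lambda_de(md, cfg, bounds = bounds, unpenalized = unpen,
                              control = control, de = de)
      fit <- tun$best_fit
      fit$tuning <- tun
    }
  }
  fit$call <- cl
  fit$formula <- formula
  fit$terms <- parts$terms
  fit$xlevels <- parts$xlevels
  fit$unpenalized_loglik <- unpen$loglik
  fit$unpenalized_bic <- unpen$bic
  fit
}

# split `lhs ~ scale | shape` and build covariate matrices via model.matrix
parse_mpr_formula <- function(formula, data) {
  rhs <- formula[[3L]]
  if (is.call(rhs) && identical(rhs[[1L]], as.name("|"))) {
    f_scale <- formula
    f_scale[[3L]] <- rhs[[2L]]
    f_shape <- formula
    f_shape[[3L]] <- rhs[[3L]]
  } else {
    f_scale <- f_shape <- formula
  }
  mf <- model.frame(f_scale, data, na.action = stats::na.fail)
  y <- model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the response must be a survival::Surv(time, status) object")
  if (attr(y, "type") != "right")
    stop("only right-censored survival data are supported")
  mm <- function(f) {
    tt <- terms(f, data = data)
    m <- model.frame(delete.response(tt), data)
    M <- model.matrix(delete.response(tt), m)
    list(x = M[, colnames(M) != "(Intercept)", drop = FALSE],
         terms = tt, xlevels = stats::.getXlevels(delete.response(tt), m))
  }
  sc <- mm(f_scale)
  sh <- mm(f_shape)
  list(time = y[, 1L], status = y[, 2L],
       x = if (ncol(sc$x)) sc$x else NULL,
       z = if (ncol(sh$x)) sh$x else NULL,
       terms = list(scale = sc$terms, shape = sh$terms),
       xlevels = list(scale = sc$xlevels, shape = sh$xlevels))
}

#' @export
print.mpr <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat(sprintf("Weibull MPR model (%s penalty%s), n = %d\n",
              x$family,
              if (x$family == "none") "" else paste0(", ", x$penalty$structure, " tuning"),
              x$n))
  if (length(x$lambda_raw))
    cat("  lambda =", paste(format(x$lambda_raw, digits = digits), collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.4f, effective df %.2f, BIC %.4f\n",
              x$loglik, x$edf, x$bic))
  cat("\nScale (beta):\n")
  print(round(x$coefficients$beta, digits))
  cat("Shape (alpha):\n")
  print(round(x$coefficients$alpha, digits))
  if (x$family != "none")
    cat(sprintf("\nSelected: %d/%d scale, %d/%d shape covariates\n",
                sum(x$active$scale), length(x$active$scale),
                sum(x$active$shape), length(x$active$shape)))
  if (!x$converged)
    cat("WARNING: the fit did not converge\n")
  invisible(x)
}

#' @export
summary.mpr <- function(object, ...) {
  tab <- function(est, se, act) {
    z <- est / ifelse(se > 0, se, NA)
    data.frame(estimate = est, std_error = se, z = z,
               p_value = 2 * pnorm(-abs(z)),
               active = c(TRUE, act),
               row.names = names(est))
  }
  out <- list(call = object$call, family = object$family,
              structure = if (!is.null(object$penalty)) object$penalty$structure,
              lambda = object$lambda_raw,
              scale = tab(object$coefficients$beta, object$se$beta,
                          object$active$scale),
              shape = tab(object$coefficients$alpha, object$se$alpha,
                          object$active$shape),
              loglik = object$loglik, edf = object$edf, bic = object$bic,
              n = object$n, converged = object$converged,
              n_iter = object$n_iter)
  class(out) <- "summary.mpr"
  out
}

#' @export
print.summary.mpr <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) { cat("Call:\n"); print(x$call); cat("\n") }
  star <- function(tb) {
    sig <- ifelse(is.na(tb$p_value), "", ifelse(tb$p_value < 0.05, "*", ""))
    cbind(round(tb[, 1:4], digits), active = tb$active, ` ` = sig)
  }
  cat(sprintf("Weibull MPR model, %s penalty, n = %d\n\n", x$family, x$n))
  cat("Scale component (log tau):\n")
  print(star(x$scale))
  cat("\nShape component (log gamma):\n")
  print(star(x$shape))
  if (length(x$lambda))
    cat("\nlambda =", paste(format(x$lambda, digits = digits), collapse = ", "), "\n")
  cat(sprintf("log-likelihood %.4f, effective df %.2f, BIC %.4f\n",
              x$loglik, x$edf, x$bic))
  if (!x$converged) cat("WARNING: the fit did not converge\n")
  invisible(x)
}

#' @export
coef.mpr <- function(object, component = c("both", "scale", "shape"),
                     standardized = FALSE, ...) {
  component <- match.arg(component)
  cf <- if (standardized) object$coefficients_std else object$coefficients
  switch(component,
         both = cf,
         scale = cf$beta,
         shape = cf$alpha)
}

#' @export
vcov.mpr <- function(object, standardized = FALSE, ...) {
  if (standardized) object$vcov_std else object$vcov
}

#' @export
logLik.mpr <- function(object, ...) {
  structure(object$loglik, df = object$edf, nobs = object$n, class = "logLik")
}

#' Predictions from a fitted Weibull MPR model
#'
#' @param object a fitted `"mpr"` model (built through [mpr()] with a
#'   formula, for `newdata` support).
#' @param newdata data.frame of covariate values to predict for (required).
#' @param times evaluation time(s) for hazard/survival type predictions.
#' @param type `"tau"`, `"gamma"` (distributional parameters), `"hazard"`,
#'   `"cumhazard"` or `"survival"`.
#' @param ... unused.
#' @return numeric vector (matrix if several `times`).
#' @export
predict.mpr <- function(object, newdata, times = NULL,
                        type = c("tau", "gamma", "hazard", "cumhazard",
                                 "survival"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) stop("'newdata' is required")
  if (is.null(object$terms)) stop("predict needs a model fitted via mpr(formula, ...)")
  mm <- function(tt, xlev) {
    m <- model.frame(delete.response(tt), newdata, xlev = xlev)
    M <- model.matrix(delete.response(tt), m)
    M[, colnames(M) != "(Intercept)", drop = FALSE]
  }
  xs <- mm(object$terms$scale, object$xlevels$scale)
  zs <- mm(object$terms$shape, object$xlevels$shape)
  bt <- object$coefficients$beta
  at <- object$coefficients$alpha
  tau <- exp(bt[1L] + if (ncol(xs)) drop(xs %*% bt[-1L]) else 0)
  gam <- exp(at[1L] + if (ncol(zs)) drop(zs %*% at[-1L]) else 0)
  if (type == "tau") return(tau)
  if (type == "gamma") return(gam)
  if (is.null(times)) stop(sprintf("type '%s' needs 'times'", type))
  f <- switch(type, hazard = weibull_hazard, cumhazard = weibull_cumhaz,
              survival = weibull_survival)
  out <- vapply(times, function(t) f(t, tau, gam), numeric(length(tau)))
  if (length(times) == 1L) drop(out) else out
}
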
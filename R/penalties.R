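#' Smoothed absolute value
#'
#' Differentiable surrogate for `|x|`: `a(x) = sqrt(x^2 + epsilon^2) - epsilon`.
#' As `epsilon -> 0`, `a(x) -> |x|`, and `|a(x) - |x|| <= epsilon` for every x.
#' Substituting `a()` for the absolute value inside the LASSO/SCAD/ALASSO
#' penalties makes the penalized log-likelihood twice differentiable so that
#' Newton-type optimization applies.
#'
#' @param x numeric vector.
#' @param epsilon positive smoothing constant; the default `1e-4` keeps the
#'   surrogate within `1e-4` of `|x|` everywhere.
#' @param deriv order of derivative: 0 (value), 1 (`x / sqrt(x^2 + eps^2)`,
#'   a smooth signum) or 2 (`eps^2 / (eps^2 + x^2)^{3/2}`, strictly positive).
#' @return numeric vector of the same length as `x`.
#' @examples
#' smooth_abs(0)                       # exactly 0
#' smooth_abs(1) - abs(1)              # within 1e-4
#' smooth_abs(c(-2, 2), deriv = 1)     # odd, in (-1, 1)
#' @export
smooth_abs <- function(x, epsilon = 1e-4, deriv = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  s <- sqrt(x^2 + epsilon^2)
  switch(as.character(deriv),
    "0" = s - epsilon,
    "1" = x / s,
    "2" = epsilon^2 / s^3,
    stop("'deriv' must be 0, 1 or 2"))
}

#' Penalty configuration
#'
#' Bundles the penalty family and its hyper-parameters.  Three families are
#' supported: `"lasso"` (`J(u) = lambda * u`), `"scad"` (the piecewise
#' quadratic-spline penalty with knot parameter `a`, flat at
#' `lambda^2 (a + 1) / 2` beyond `a * lambda`) and `"alasso"` (LASSO rescaled
#' per coefficient by adaptive weights, typically `1 / |unpenalized estimate|`).
#' `structure` chooses between one tuning parameter shared by the scale and
#' shape components or a separate one for each ("single" vs "separate").
#' Intercepts are never penalized.
#'
#' @param family `"lasso"`, `"scad"` or `"alasso"`.
#' @param structure `"single"` (one lambda) or `"separate"` (`lambda_beta`,
#'   `lambda_alpha`).
#' @param scad_a SCAD knot parameter, must exceed 2; default 3.7, the value
#'   with well-established practical performance.
#' @param epsilon smoothing constant passed to [smooth_abs()].
#' @param weights for `"alasso"` only: list with components `beta` and `alpha`,
#'   nonnegative weight vectors for the non-intercept scale and shape
#'   coefficients (see [make_adaptive_weights()]).  Must be absent for the
#'   non-adaptive families.
#' @param weight_cap upper bound applied to adaptive weights so that a
#'   near-zero unpenalized estimate yields a large-but-finite weight.
#' @return an object of class `"penalty_config"`.
#' @export
penalty_config <- function(family = c("lasso", "scad", "alasso"),
                           structure = c("single", "separate"),
                           scad_a = 3.7, epsilon = 1e-4,
                           weights = NULL, weight_cap = 1e6) {
  family <- match.arg(family)
  structure <- match.arg(structure)
  if (!is.numeric(scad_a) || length(scad_a) != 1L || scad_a <= 2)
    stop("'scad_a' must be a single number greater than 2")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  if (!is.numeric(weight_cap) || length(weight_cap) != 1L || weight_cap <= 0)
    stop("'weight_cap' must be a single positive number")
  if (family == "alasso") {
    if (is.null(weights))
      stop("family 'alasso' requires adaptive 'weights' (see make_adaptive_weights)")
    if (!is.list(weights) || !all(c("beta", "alpha") %in% names(weights)))
      stop("'weights' must be a list with components 'beta' and 'alpha'")
    for (w in weights[c("beta", "alpha")]) {
      if (any(!is.finite(w)) || any(w < 0))
        stop("adaptive weights must be finite and nonnegative")
      if (any(w > weight_cap))
        stop("adaptive weights exceed 'weight_cap'")
    }
  } else if (!is.null(weights)) {
    stop("'weights' are only meaningful for family 'alasso'")
  }
  structure(list(family = family, structure = structure, scad_a = scad_a,
                 epsilon = epsilon, weights = weights,
                 weight_cap = weight_cap),
            class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  cat("Penalty configuration:", x$family,
      sprintf("(%s tuning parameter%s)", x$structure,
              if (x$structure == "separate") "s" else ""), "\n")
  if (x$family == "scad") cat("  scad_a =", x$scad_a, "\n")
  cat("  smoothing epsilon =", format(x$epsilon), "\n")
  if (!is.null(x$weights))
    cat("  adaptive weights: ", length(x$weights$beta), " scale, ",
        length(x$weights$alpha), " shape\n", sep = "")
  invisible(x)
}

#' Penalty value and derivatives for one coefficient
#'
#' Evaluates `J_lambda(a(theta))`, the smoothed penalty contribution of a
#' single coefficient, or its first/second derivative with respect to `theta`.
#' `lambda` is the *effective* per-coefficient tuning parameter: for the
#' adaptive LASSO the adaptive weight has already been folded in (see
#' [expand_lambda()]), so the ALASSO evaluates through the LASSO form.
#'
#' @param theta numeric vector of coefficient values.
#' @param lambda nonnegative effective tuning parameter(s), recycled against
#'   `theta`.
#' @param config a [penalty_config()].
#' @param deriv 0, 1 or 2.
#' @return numeric vector.
#' @export
penalty_value <- function(theta, lambda, config, deriv = 0) {
  stopifnot(inherits(config, "penalty_config"))
  if (any(lambda < 0)) stop("'lambda' must be nonnegative")
  n <- max(length(theta), length(lambda))
  theta <- rep_len(theta, n)
  lambda <- rep_len(lambda, n)
  eps <- config$epsilon
  u <- smooth_abs(theta, eps)
  u1 <- smooth_abs(theta, eps, deriv = 1)
  u2 <- smooth_abs(theta, eps, deriv = 2)
  if (config$family == "scad") {
    a <- config$scad_a
    J <- Jp <- Jpp <- numeric(n)
    lo <- u <= lambda
    mid <- u > lambda & u < a * lambda
    hi <- u >= a * lambda & lambda > 0
    J[lo] <- lambda[lo] * u[lo]
    Jp[lo] <- lambda[lo]
    J[mid] <- (2 * a * lambda[mid] * u[mid] - u[mid]^2 - lambda[mid]^2) /
      (2 * (a - 1))
    Jp[mid] <- (a * lambda[mid] - u[mid]) / (a - 1)
    Jpp[mid] <- -1 / (a - 1)
    J[hi] <- lambda[hi]^2 * (a + 1) / 2
  } else {
    J <- lambda * u
    Jp <- lambda
    Jpp <- 0
  }
  zero <- lambda == 0
  out <- switch(as.character(deriv),
    "0" = J,
    "1" = Jp * u1,
    "2" = Jpp * u1^2 + Jp * u2,
    stop("'deriv' must be 0, 1 or 2"))
  out[zero] <- 0
  out
}

#' Adaptive-LASSO weights from an unpenalized fit
#'
#' Computes `w_j = min(1 / |theta_hat_0j|, weight_cap)` for each non-intercept
#' coefficient, where `theta_hat_0j` are unpenalized estimates on the
#' standardized covariate scale (so that weighting and penalization share one
#' scale convention).  A coefficient estimated at exactly zero saturates at
#' `weight_cap`, which still forces it to zero at any positive lambda.
#'
#' @param fit a converged unpenalized [mpr()] fit.
#' @param weight_cap upper bound for the weights.
#' @return list with numeric components `beta` (length p) and `alpha`
#'   (length q).
#' @export
make_adaptive_weights <- function(fit, weight_cap = 1e6) {
  stopifnot(inherits(fit, "mpr"))
  if (!isTRUE(fit$converged))
    stop("adaptive weights require a *converged* unpenalized fit")
  if (any(fit$lambda != 0))
    stop("adaptive weights must be computed from an unpenalized fit")
  b <- fit$coefficients_std$beta[-1L]
  a <- fit$coefficients_std$alpha[-1L]
  cap <- function(x) pmin(1 / abs(x), weight_cap)
  list(beta = cap(b), alpha = cap(a))
}

#' Expand tuning parameters to a per-coefficient vector
#'
#' Maps the raw tuning parameter(s) onto the full coefficient vector
#' `(beta_0, beta_1, ..., beta_p, alpha_0, alpha_1, ..., alpha_q)`.  Intercept
#' slots always carry 0 (intercepts are not penalized).  With
#' `structure = "single"` the single value fills both components; with
#' `"separate"`, `raw[1]` fills the scale slots and `raw[2]` the shape slots.
#' For the adaptive LASSO the component lambdas are further multiplied by the
#' adaptive weights in `config`.
#'
#' @param raw numeric vector of length 1 (`single`) or 2 (`separate`).
#' @param p,q number of non-intercept scale and shape covariates.
#' @param config a [penalty_config()]; its `structure` (and, for the ALASSO,
#'   its `weights`) drive the expansion.
#' @return numeric vector of length `p + q + 2`.
#' @export
expand_lambda <- function(raw, p, q, config) {
  stopifnot(inherits(config, "penalty_config"))
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("tuning parameters must be finite and nonnegative")
  need <- if (config$structure == "single") 1L else 2L
  if (length(raw) != need)
    stop(sprintf("structure '%s' needs %d tuning parameter(s), got %d",
                 config$structure, need, length(raw)))
  lb <- if (need == 1L) raw else raw[1L]
  la <- if (need == 1L) raw else raw[2L]
  wb <- rep(1, p)
  wa <- rep(1, q)
  if (config$family == "alasso") {
    if (length(config$weights$beta) != p || length(config$weights$alpha) != q)
      stop("adaptive weight lengths do not match the design (p, q)")
    wb <- config$weights$beta
    wa <- config$weights$alpha
  }
  c(0, lb * wb, 0, la * wa)
}
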
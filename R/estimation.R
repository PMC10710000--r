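#' Control parameters for the Newton-Raphson fitting loop
#'
#' @param max_iter maximum inner iterations during tuning-parameter search.
#' @param tol convergence threshold on the infinity norm of the parameter
#'   update during tuning-parameter search.
#' @param final_max_iter,final_tol stricter settings used for the final
#'   (reported) fit at the selected tuning parameters and for unpenalized
#'   fits.
#' @param clip bound on linear predictors before exponentiation; exceeding it
#'   is counted and reported via a warning (never silent).
#' @param zero_threshold absolute value (standardized scale) below which a
#'   coefficient is declared selected-out.  The smoothed penalty never
#'   produces exact zeros: shrunk coefficients land at the order of the
#'   smoothing constant (1e-4), so the default 1e-3 separates cleanly.
#' @param zero_inactive_cov zero out covariance rows/columns of de-selected
#'   coefficients (the Fan-Li reporting convention).  Default `FALSE`:
#'   the sandwich covariance is reported as computed.
#' @param warm_start start each tuning-candidate fit from the previous
#'   solution instead of the unpenalized estimates.  Off by default, matching
#'   the reference algorithm (each inner solve starts at the unpenalized
#'   estimates).
#' @return list of class `"mpr_control"`.
#' @export
mpr_control <- function(max_iter = 300L, tol = 1e-5,
                        final_max_iter = 1000L, final_tol = 1e-6,
                        clip = 50, zero_threshold = 1e-3,
                        zero_inactive_cov = FALSE, warm_start = FALSE) {
  stopifnot(max_iter >= 1, tol > 0, final_max_iter >= 1, final_tol > 0,
            clip > 0, zero_threshold > 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 final_max_iter = as.integer(final_max_iter),
                 final_tol = final_tol, clip = clip,
                 zero_threshold = zero_threshold,
                 zero_inactive_cov = isTRUE(zero_inactive_cov),
                 warm_start = isTRUE(warm_start)),
            class = "mpr_control")
}

family_code <- function(config) {
  if (is.null(config)) 0L else if (config$family == "scad") 1L else 0L
}

split_lambda <- function(lambda_vec, data) {
  list(beta = lambda_vec[seq_len(data$p + 1L)],
       alpha = lambda_vec[data$p + 1L + seq_len(data$q + 1L)])
}

#' Score vector and information matrices of the penalized likelihood
#'
#' Returns the gradient of the penalized log-likelihood
#' (`X'U_beta - n V_beta` stacked over `Z'U_alpha - n V_alpha`), the penalized
#' information matrix `I(theta) = I0(theta) + diag(n Sigma_beta, n
#' Sigma_alpha)` assembled from the `W` weight matrices, and the unpenalized
#' observed information `I0(theta)`.  With all tuning parameters zero these
#' reduce to the score and observed information of the plain Weibull MPR
#' likelihood.
#'
#' @param beta,alpha coefficients on the scale of the stored designs.
#' @param data an [mpr_data()].
#' @param lambda per-coefficient tuning vector of length `p + q + 2` (zero
#'   intercept slots), or the raw 1-/2-vector to be expanded through `config`;
#'   `NULL` means unpenalized.
#' @param config a [penalty_config()] (required when `lambda` is non-null and
#'   raw).
#' @param control an [mpr_control()].
#' @return list with `gradient`, `gradient0`, `information`, `information0`,
#'   `loglik`, `objective`.
#' @export
mpr_score_info <- function(beta, alpha, data, lambda = NULL, config = NULL,
                           control = mpr_control()) {
  stopifnot(inherits(data, "mpr_data"))
  k <- data$p + data$q + 2L
  if (is.null(lambda)) {
    lambda <- rep(0, k)
  } else if (length(lambda) != k) {
    if (is.null(config))
      stop("raw 'lambda' needs a 'config' to be expanded per coefficient")
    lambda <- expand_lambda(lambda, data$p, data$q, config)
  }
  if (lambda[1L] != 0 || lambda[data$p + 2L] != 0)
    stop("intercept slots of 'lambda' must be zero")
  eps <- if (is.null(config)) 1e-4 else config$epsilon
  sa <- if (is.null(config)) 3.7 else config$scad_a
  lam <- split_lambda(lambda, data)
  d <- cpp_mpr_derivs(data$X, data$Z, data$time, data$status,
                      lam$beta, lam$alpha, family_code(config), sa, eps,
                      control$clip, c(beta, alpha), 2L)
  if (any(!is.finite(d$information)))
    stop("non-finite entries in the information matrix")
  list(gradient = drop(d$gradient), gradient0 = drop(d$gradient0),
       information = d$information, information0 = d$information0,
       loglik = d$loglik, objective = d$objective)
}

# generalized inverse via SVD, used only when the information is singular
ginv_sym <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

safe_inverse <- function(M, label = "information matrix") {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    warning(sprintf("singular %s: using a pseudo-inverse", label))
    out <- ginv_sym(M)
  }
  out
}

# effective degrees of freedom: tr[I(theta)^-1 I0(theta)]
compute_edf <- function(I, I0, lambda_vec) {
  if (all(lambda_vec == 0)) return(nrow(I0))
  M <- tryCatch(solve(I, I0), error = function(e) ginv_sym(I) %*% I0)
  sum(diag(M))
}

# sandwich covariance I^-1 I0 I^-1 (standardized scale); exact I0^-1 when
# unpenalized
compute_sandwich <- function(I, I0, lambda_vec) {
  if (all(lambda_vec == 0)) {
    V <- safe_inverse(I0)
  } else {
    Iinv <- safe_inverse(I)
    V <- Iinv %*% I0 %*% Iinv
  }
  (V + t(V)) / 2
}

# assemble the fitted-model object from the optimizer output
build_mpr_fit <- function(data, res, lambda_vec, lambda_raw, config, control) {
  pb <- data$p + 1L
  qb <- data$q + 1L
  theta <- drop(res$theta)
  bnames <- colnames(data$X)
  anames <- colnames(data$Z)
  beta_std <- setNames(theta[seq_len(pb)], bnames)
  alpha_std <- setNames(theta[pb + seq_len(qb)], anames)
  V_std <- compute_sandwich(res$information, res$information0, lambda_vec)
  orig <- unstandardize_theta(theta, data)
  V_orig <- unstandardize_vcov(V_std, data)
  active_scale <- abs(beta_std[-1L]) > control$zero_threshold
  active_shape <- abs(alpha_std[-1L]) > control$zero_threshold
  if (control$zero_inactive_cov) {
    drop_idx <- c(which(!c(TRUE, active_scale)), pb + which(!c(TRUE, active_shape)))
    V_std[drop_idx, ] <- 0; V_std[, drop_idx] <- 0
    V_orig[drop_idx, ] <- 0; V_orig[, drop_idx] <- 0
  }
  dimnames(V_std) <- dimnames(V_orig) <-
    list(c(bnames, anames), c(bnames, anames))
  edf <- compute_edf(res$information, res$information0, lambda_vec)
  ll <- res$loglik
  se_all <- sqrt(pmax(diag(V_orig), 0))
  if (res$n_clip > 0)
    warning(sprintf("linear predictor clipped at +/-%g in %d evaluations",
                    control$clip, res$n_clip))
  structure(list(
    coefficients = list(beta = setNames(orig$beta, bnames),
                        alpha = setNames(orig$alpha, anames)),
    coefficients_std = list(beta = beta_std, alpha = alpha_std),
    vcov = V_orig, vcov_std = V_std,
    se = list(beta = setNames(se_all[seq_len(pb)], bnames),
              alpha = setNames(se_all[pb + seq_len(qb)], anames)),
    loglik = ll, objective = res$objective,
    edf = edf, bic = -2 * ll + edf * log(data$n),
    lambda = lambda_vec, lambda_raw = lambda_raw,
    penalty = config,
    family = if (is.null(config)) "none" else config$family,
    active = list(scale = active_scale, shape = active_shape),
    n_iter = res$n_iter, converged = isTRUE(res$converged),
    gradient_norm = max(abs(res$gradient)),
    n_clip = res$n_clip,
    data = data, control = control, n = data$n),
    class = "mpr")
}

default_init <- function(data) {
  # exponential special case: intercept-only, gamma = 1 gives tau = sum(d)/sum(t)
  c(log(sum(data$status) / sum(data$time)), rep(0, data$p),
    rep(0, data$q + 1L))
}

#' Unpenalized maximum likelihood fit
#'
#' Maximizes the Weibull MPR log-likelihood by Newton-Raphson with
#' step-halving.  The covariance is the inverse observed information and the
#' effective degrees of freedom equal `p + q + 2`.
#'
#' @param data an [mpr_data()].
#' @param init optional starting value for `c(beta, alpha)` (standardized
#'   scale); defaults to the intercept-only exponential estimate.
#' @param control an [mpr_control()].
#' @return an object of class `"mpr"` (see [mpr()]).
#' @export
fit_unpenalized <- function(data, init = NULL, control = mpr_control()) {
  stopifnot(inherits(data, "mpr_data"))
  k <- data$p + data$q + 2L
  if (data$n <= k)
    warning(sprintf("n = %d is not larger than the parameter count %d; the fit may be unstable",
                    data$n, k))
  if (is.null(init)) init <- default_init(data)
  zl <- split_lambda(rep(0, k), data)
  res <- cpp_mpr_newton(data$X, data$Z, data$time, data$status,
                        zl$beta, zl$alpha, 0L, 3.7, 1e-4, control$clip,
                        init, control$final_max_iter, control$final_tol)
  if (!isTRUE(res$converged))
    warning(sprintf("unpenalized fit did not converge in %d iterations (last step %.2e)",
                    control$final_max_iter, res$last_step))
  build_mpr_fit(data, res, rep(0, k), numeric(0), NULL, control)
}

#' Penalized fit at fixed tuning parameters
#'
#' Iteratively solves the penalized Newton-Raphson system starting from the
#' unpenalized estimates (the reference algorithm's initialization), using
#' step-halving to enforce ascent of the penalized objective.  Standard errors
#' come from the sandwich formula `I^-1 I0 I^-1` evaluated at the solution.
#'
#' @param data an [mpr_data()].
#' @param lambda_raw tuning parameter(s): length 1 for `structure = "single"`,
#'   length 2 (`lambda_beta`, `lambda_alpha`) for `"separate"`.
#' @param config a [penalty_config()].
#' @param init starting value, typically the unpenalized estimates (computed
#'   if omitted).
#' @param control an [mpr_control()].
#' @param final use the stricter final convergence settings (default); the
#'   tuning loop passes `FALSE` for speed.
#' @return an object of class `"mpr"`.
#' @export
fit_penalized <- function(data, lambda_raw, config, init = NULL,
                          control = mpr_control(), final = TRUE) {
  stopifnot(inherits(data, "mpr_data"), inherits(config, "penalty_config"))
  lambda_vec <- expand_lambda(lambda_raw, data$p, data$q, config)
  if (is.null(init)) init <- fit_unpenalized(data, control = control)
  if (inherits(init, "mpr"))
    init <- unlist(init$coefficients_std, use.names = FALSE)
  lam <- split_lambda(lambda_vec, data)
  res <- cpp_mpr_newton(data$X, data$Z, data$time, data$status,
                        lam$beta, lam$alpha, family_code(config),
                        config$scad_a, config$epsilon, control$clip, init,
                        if (final) control$final_max_iter else control$max_iter,
                        if (final) control$final_tol else control$tol)
  build_mpr_fit(data, res, lambda_vec, lambda_raw, config, control)
}

#' Effective degrees of freedom of a fit
#'
#' `tr[I(theta)^-1 I0(theta)]`, the complexity term of the tuning BIC.  Equals
#' `p + q + 2` exactly for an unpenalized fit and decreases towards 2 (the two
#' unpenalized intercepts) as the tuning parameters grow.
#'
#' @param fit a fitted `"mpr"` object.
#' @return a single number in `(0, p + q + 2]`.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "mpr"))
  fit$edf
}
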
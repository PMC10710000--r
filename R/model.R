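#' Weibull MPR log-likelihood
#'
#' Evaluates the unpenalized log-likelihood of the Weibull multi-parameter
#' regression model,
#' \deqn{\ell_0(\theta)=\sum_i \delta_i\{\log\tau_i+\log\gamma_i+
#'   (\gamma_i-1)\log t_i\}-\tau_i t_i^{\gamma_i},}
#' with \eqn{\tau_i=\exp(x_i'\beta)} and \eqn{\gamma_i=\exp(z_i'\alpha)}.
#' A censored subject contributes exactly \eqn{\log S(t_i)=-\tau_i
#' t_i^{\gamma_i}}.
#'
#' @param beta scale coefficients (length p + 1, intercept first), on the
#'   scale of the designs stored in `data` (standardized by default).
#' @param alpha shape coefficients (length q + 1).
#' @param data an [mpr_data()] object.
#' @return the log-likelihood (a single number).
#' @export
mpr_loglik <- function(beta, alpha, data) {
  stopifnot(inherits(data, "mpr_data"))
  if (length(beta) != data$p + 1L || length(alpha) != data$q + 1L)
    stop(sprintf("coefficient lengths (%d, %d) do not match the designs (%d, %d)",
                 length(beta), length(alpha), data$p + 1L, data$q + 1L))
  if (any(!is.finite(c(beta, alpha))))
    stop("non-finite coefficients")
  z <- rep(0, data$p + data$q + 2L)
  d <- cpp_mpr_derivs(data$X, data$Z, data$time, data$status,
                      z[seq_len(data$p + 1L)], z[data$p + 1L + seq_len(data$q + 1L)],
                      0L, 3.7, 1e-4, 50, c(beta, alpha), 0L)
  d$loglik
}

#' Weibull hazard, cumulative hazard and survival
#'
#' `weibull_hazard()` returns \eqn{h(t)=\tau\gamma t^{\gamma-1}},
#' `weibull_cumhaz()` returns \eqn{H(t)=\tau t^{\gamma}} and
#' `weibull_survival()` returns \eqn{S(t)=\exp(-\tau t^{\gamma})}.
#' Arguments are recycled.
#'
#' @param t positive time(s).
#' @param tau,gamma positive scale and shape parameters.
#' @return numeric vector.
#' @export
weibull_hazard <- function(t, tau, gamma) {
  if (any(t <= 0)) stop("'t' must be strictly positive")
  if (any(tau <= 0) || any(gamma <= 0)) stop("'tau' and 'gamma' must be positive")
  tau * gamma * t^(gamma - 1)
}

#' @rdname weibull_hazard
#' @export
weibull_cumhaz <- function(t, tau, gamma) {
  if (any(t <= 0)) stop("'t' must be strictly positive")
  tau * t^gamma
}

#' @rdname weibull_hazard
#' @export
weibull_survival <- function(t, tau, gamma) exp(-weibull_cumhaz(t, tau, gamma))

#' Hazard ratio for a one-unit (or `delta`-unit) covariate increment
#'
#' In the Weibull MPR model the hazard ratio between two subjects who differ
#' by `delta` units in one covariate (present in the scale and/or shape
#' component, all other covariates equal) is
#' \deqn{HR(t)=\exp\{\delta(\beta_1+\alpha_1)\}\,
#'   t^{\gamma_{ref}\{\exp(\delta\alpha_1)-1\}},}
#' where \eqn{\gamma_{ref}=\exp(z_{ref}'\alpha)} is the shape parameter at the
#' reference covariate profile.  When the shape coefficient is zero this is
#' the familiar time-constant proportional-hazards ratio
#' \eqn{\exp(\delta\beta_1)}.
#'
#' The default method takes the two coefficients and the reference shape
#' directly; the `mpr` method extracts them from a fitted model, using the
#' column means of the shape covariates as the reference profile (a
#' representative-profile convention; with standardized covariates this is the
#' shape intercept).
#'
#' @param object coefficients or a fitted [mpr()] model.
#' @param ... passed between methods.
#' @return numeric vector of hazard ratios, one per `t`.
#' @export
hazard_ratio <- function(object, ...) UseMethod("hazard_ratio")

#' @rdname hazard_ratio
#' @param beta1,alpha1 scale and shape coefficients of the covariate (use 0
#'   when the covariate is absent from a component).
#' @param t positive evaluation time(s); irrelevant when `alpha1 = 0`.
#' @param gamma_ref shape parameter at the reference profile.
#' @param delta size of the covariate increment.
#' @export
hazard_ratio.default <- function(object, alpha1 = 0, t = 1, gamma_ref = 1,
                                 delta = 1, beta1 = object, ...) {
  if (any(t <= 0)) stop("'t' must be strictly positive")
  if (gamma_ref <= 0) stop("'gamma_ref' must be positive")
  exp(delta * (beta1 + alpha1)) * t^(gamma_ref * (exp(delta * alpha1) - 1))
}

#' @rdname hazard_ratio
#' @param covariate name (or index among non-intercept terms) of the covariate.
#' @param profile optional named list / vector of shape covariate values
#'   defining the reference profile (original units); defaults to column means.
#' @export
hazard_ratio.mpr <- function(object, covariate, t = 1, delta = 1,
                             profile = NULL, ...) {
  cf <- coef(object)
  bnames <- names(cf$beta)[-1L]
  anames <- names(cf$alpha)[-1L]
  if (is.numeric(covariate)) covariate <- union(bnames, anames)[covariate]
  if (!covariate %in% c(bnames, anames))
    stop(sprintf("covariate '%s' appears in neither component", covariate))
  b1 <- if (covariate %in% bnames) unname(cf$beta[covariate]) else 0
  a1 <- if (covariate %in% anames) unname(cf$alpha[covariate]) else 0
  # reference shape: column means of the shape covariates in original units,
  # with the incremented covariate held at its profile value
  zbar <- object$data$center_z
  if (length(zbar) == 0L) {
    gref <- exp(unname(cf$alpha[1L]))
  } else {
    if (!is.null(profile)) {
      profile <- unlist(profile)
      keep <- intersect(names(profile), names(zbar))
      zbar[keep] <- profile[keep]
    }
    gref <- exp(unname(cf$alpha[1L] + sum(cf$alpha[-1L] * zbar)))
  }
  hazard_ratio.default(b1, alpha1 = a1, t = t, gamma_ref = gref, delta = delta)
}

#' Kaplan-Meier points for the Weibull adequacy check
#'
#' For a homogeneous Weibull model `log H(t) = log tau + gamma * log t`, so a
#' plot of `log Hhat(t)` against `log t` should be close to a straight line
#' with slope `gamma`.  This computes `Hhat(t) = -log Shat_KM(t)` at the
#' distinct event times, with pointwise confidence bounds obtained from the
#' Greenwood standard error on the cumulative-hazard scale (delta method on
#' `log H`).  Points where the Kaplan-Meier estimate has dropped to 0, or
#' where `Hhat = 0`, are dropped (their logarithm is undefined).
#'
#' @param time,status right-censored survival data (events coded 1).
#' @param conf_level confidence level for the pointwise bounds.
#' @return data.frame with columns `time`, `logt`, `logH`, `lower`, `upper`,
#'   `n_risk`, `n_event`.
#' @export
km_log_cumhaz <- function(time, status, conf_level = 0.95) {
  if (sum(status) == 0)
    stop("all observations are censored: the cumulative hazard estimate is identically 0")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, conf.type = "none")
  keep <- sf$n.event > 0 & sf$surv > 0
  S <- sf$surv[keep]
  H <- -log(S)
  se_H <- sf$std.err[keep]  # Greenwood SE on the cumulative-hazard scale
  keep2 <- H > 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(time = sf$time[keep][keep2],
             logt = log(sf$time[keep][keep2]),
             logH = log(H[keep2]),
             lower = log(H[keep2]) - z * se_H[keep2] / H[keep2],
             upper = log(H[keep2]) + z * se_H[keep2] / H[keep2],
             n_risk = sf$n.risk[keep][keep2],
             n_event = sf$n.event[keep][keep2])
}
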
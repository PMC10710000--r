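#' Survival dataset for Weibull MPR modelling
#'
#' Validates and packages right-censored survival data together with the two
#' design matrices: `x` enters the hazard scale (`log tau = x' beta`) and `z`
#' the hazard shape (`log gamma = z' alpha`).  Non-intercept columns are
#' internally standardized (mean 0, sd 1) so that penalization does not depend
#' on measurement units; the centering/scaling constants are retained so that
#' fitted coefficients can be reported on the original scale.
#'
#' @param time positive survival/censoring times.
#' @param status event indicator, 1 = event, 0 = right-censored.
#' @param x numeric matrix (or data.frame) of scale covariates, one row per
#'   subject, *without* an intercept column (it is added internally).  `NULL`
#'   gives an intercept-only scale component.
#' @param z shape covariates, same convention; defaults to `x` (shared
#'   covariates in both components).
#' @param standardize standardize non-intercept columns internally (default).
#'   `FALSE` keeps original units (centering 0, scaling 1); penalized fitting
#'   should only be done on the standardized scale.
#' @return object of class `"mpr_data"`: list with elements `time`, `status`,
#'   `X`, `Z` (standardized designs including the leading column of ones),
#'   `n`, `p`, `q` and the standardization constants
#'   (`center_x`, `scale_x`, `center_z`, `scale_z`).
#' @export
mpr_data <- function(time, status, x = NULL, z = x, standardize = TRUE) {
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (anyNA(time) || anyNA(status))
    stop("missing values in 'time' or 'status'")
  bad <- which(time <= 0)
  if (length(bad))
    stop(sprintf("non-positive survival time at row %d (t = %g); log(t) is undefined",
                 bad[1L], time[bad[1L]]))
  if (!all(status %in% c(0, 1)))
    stop("'status' must be 0 (censored) or 1 (event)")
  n <- length(time)
  if (length(status) != n)
    stop("'time' and 'status' lengths differ")
  std <- function(m, what) {
    if (is.null(m))
      return(list(M = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                  center = numeric(0), scale = numeric(0)))
    m <- as.matrix(m)
    if (!is.numeric(m)) stop(sprintf("'%s' must be numeric", what))
    if (anyNA(m)) stop(sprintf("missing values in '%s'", what))
    if (nrow(m) != n)
      stop(sprintf("'%s' has %d rows but there are %d subjects", what, nrow(m), n))
    if (is.null(colnames(m)))
      colnames(m) <- paste0(what, seq_len(ncol(m)))
    if (standardize) {
      ctr <- colMeans(m)
      scl <- apply(m, 2L, sd)
      if (any(scl == 0))
        stop(sprintf("constant column '%s' in '%s' cannot be standardized",
                     colnames(m)[which(scl == 0)[1L]], what))
    } else {
      ctr <- rep(0, ncol(m))
      scl <- rep(1, ncol(m))
    }
    ms <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
    list(M = cbind("(Intercept)" = 1, ms), center = ctr, scale = scl)
  }
  sx <- std(x, "x")
  sz <- std(z, "z")
  structure(list(time = time, status = status,
                 X = sx$M, Z = sz$M,
                 n = n, p = ncol(sx$M) - 1L, q = ncol(sz$M) - 1L,
                 center_x = sx$center, scale_x = sx$scale,
                 center_z = sz$center, scale_z = sz$scale,
                 standardized = standardize),
            class = "mpr_data")
}

#' @export
print.mpr_data <- function(x, ...) {
  cat(sprintf("Weibull MPR survival dataset: n = %d, events = %d (%.1f%% censored)\n",
              x$n, sum(x$status), 100 * mean(1 - x$status)))
  cat(sprintf("  scale covariates: %d, shape covariates: %d%s\n", x$p, x$q,
              if (isTRUE(x$standardized)) " (standardized internally)" else ""))
  invisible(x)
}

# Jacobian of the original-scale coefficients with respect to the
# standardized-scale ones, for one component:
#   slope_orig_j = slope_std_j / s_j
#   intercept_orig = intercept_std - sum_j slope_std_j * m_j / s_j
component_jacobian <- function(center, scale) {
  k <- length(center)
  A <- diag(c(1, if (k) 1 / scale), k + 1L)
  if (k) A[1L, -1L] <- -center / scale
  A
}

# theta (std scale, c(beta, alpha)) -> original-scale list(beta, alpha)
unstandardize_theta <- function(theta, data) {
  pb <- data$p + 1L
  A <- component_jacobian(data$center_x, data$scale_x)
  B <- component_jacobian(data$center_z, data$scale_z)
  list(beta = drop(A %*% theta[seq_len(pb)]),
       alpha = drop(B %*% theta[pb + seq_len(data$q + 1L)]))
}

# covariance matrix on the standardized scale -> original scale
unstandardize_vcov <- function(V, data) {
  A <- component_jacobian(data$center_x, data$scale_x)
  B <- component_jacobian(data$center_z, data$scale_z)
  J <- rbind(cbind(A, matrix(0, nrow(A), ncol(B))),
             cbind(matrix(0, nrow(B), ncol(A)), B))
  J %*% V %*% t(J)
}
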
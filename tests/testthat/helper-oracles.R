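# Independent oracles used across the test files.  Everything here is plain,
# slow R written directly from the model definitions -- none of it calls the
# package's fitting internals.

# generic survival log-likelihood: sum delta*log h(t) - H(t) with
# h(t) = tau*gamma*t^(gamma-1), H(t) = tau*t^gamma
ref_loglik <- function(beta, alpha, time, status, X, Z) {
  tau <- exp(drop(X %*% beta))
  gam <- exp(drop(Z %*% alpha))
  h <- tau * gam * time^(gam - 1)
  H <- tau * time^gam
  sum(status * log(h) - H)
}

# smoothed penalty written out longhand (value only)
ref_penalty <- function(theta, lambda, family, scad_a = 3.7, eps = 1e-4) {
  u <- sqrt(theta^2 + eps^2) - eps
  if (family == "scad") {
    out <- numeric(length(u))
    for (i in seq_along(u)) {
      l <- lambda[i]
      if (l == 0) next
      out[i] <- if (u[i] <= l) l * u[i]
      else if (u[i] < scad_a * l)
        (2 * scad_a * l * u[i] - u[i]^2 - l^2) / (2 * (scad_a - 1))
      else l^2 * (scad_a + 1) / 2
    }
    out
  } else {
    lambda * u
  }
}

# full penalized objective (standardized-scale inputs)
ref_objective <- function(theta, data, lambda_vec, family, scad_a = 3.7,
                          eps = 1e-4) {
  pb <- data$p + 1L
  beta <- theta[seq_len(pb)]
  alpha <- theta[pb + seq_len(data$q + 1L)]
  ll <- ref_loglik(beta, alpha, data$time, data$status, data$X, data$Z)
  ll - data$n * sum(ref_penalty(theta, lambda_vec, family, scad_a, eps))
}

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- replace(numeric(length(x)), j, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# central finite-difference Hessian of a scalar function
num_hess <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- replace(numeric(k), i, h)
      ej <- replace(numeric(k), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# back-transform a standardized-scale covariance to original units, written
# out longhand from the linear map slope_orig = slope_std / s,
# intercept_orig = intercept_std - sum(slope_std * m / s)
unstd_vcov_for_test <- function(V, data) {
  jac <- function(m, s) {
    k <- length(m)
    A <- diag(c(1, if (k) 1 / s), k + 1)
    if (k) A[1, -1] <- -m / s
    A
  }
  A <- jac(data$center_x, data$scale_x)
  B <- jac(data$center_z, data$scale_z)
  J <- rbind(cbind(A, matrix(0, nrow(A), ncol(B))),
             cbind(matrix(0, nrow(B), ncol(A)), B))
  J %*% V %*% t(J)
}

# small random Weibull MPR dataset (inversion sampling, optionally censored)
make_test_data <- function(n = 60, p = 2, q = 2, seed = 1,
                           beta = c(-0.5, 0.6, -0.4)[seq_len(p + 1)],
                           alpha = c(0.2, -0.3, 0.25)[seq_len(q + 1)],
                           censor = 0.2, standardize = TRUE) {
  set.seed(seed)
  k <- max(p, q, 1)
  x <- matrix(rnorm(n * k), n, k)
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  X <- cbind(1, x[, seq_len(p), drop = FALSE])
  Z <- cbind(1, x[, seq_len(q), drop = FALSE])
  tau <- exp(drop(X %*% beta))
  gam <- exp(drop(Z %*% alpha))
  tt <- (-log(runif(n)) / tau)^(1 / gam)
  if (censor > 0) {
    cc <- runif(n, 0, quantile(tt, 1 - censor) * 2)
    time <- pmin(tt, cc)
    status <- as.numeric(tt <= cc)
  } else {
    time <- tt
    status <- rep(1, n)
  }
  mpr_data(time, status,
           if (p > 0) x[, seq_len(p), drop = FALSE],
           if (q > 0) x[, seq_len(q), drop = FALSE],
           standardize = standardize)
}
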
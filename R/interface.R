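#' Read right-censored survival data from delimited text
#'
#' Reads a CSV/TSV file with a header, validates the declared columns and
#' builds an [mpr_data()] object.  Categorical covariates (character/factor
#' columns) are one-hot encoded against their first (reference) level; every
#' dummy is standardized and penalized individually.
#'
#' @param path file path; the separator defaults to tab for `.tsv`/`.txt` and
#'   comma otherwise.
#' @param time,status names of the time and event-indicator columns.
#' @param scale character vector of covariate names for the scale component;
#'   `NULL` gives an intercept-only component.
#' @param shape covariate names for the shape component; defaults to `scale`.
#' @param sep field separator, overriding the extension-based default.
#' @param na_string token(s) read as missing (rows with missing values in the
#'   used columns are rejected with a message).
#' @return an [mpr_data()] object; the raw data.frame is attached as
#'   attribute `"frame"`.
#' @export
read_survival_data <- function(path, time = "time", status = "status",
                               scale = NULL, shape = scale, sep = NULL,
                               na_string = "NA") {
  if (!file.exists(path)) stop(config_error(sprintf("input file not found: %s", path)))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, na.strings = na_string,
                 stringsAsFactors = FALSE, check.names = FALSE)
  used <- unique(c(time, status, scale, shape))
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop(config_error(sprintf("column(s) not found in %s: %s", path,
                              paste(missing_cols, collapse = ", "))))
  if (anyNA(df[used])) {
    bad <- which(rowSums(is.na(df[used])) > 0)[1L]
    stop(config_error(sprintf("missing value in row %d of the used columns", bad)))
  }
  st <- df[[status]]
  if (!all(st %in% c(0, 1)))
    stop(config_error(sprintf("status column '%s' must be binary 0/1", status)))
  encode <- function(cols) {
    if (is.null(cols) || !length(cols)) return(NULL)
    f <- stats::as.formula(paste("~", paste(sprintf("`%s`", cols), collapse = "+")))
    M <- model.matrix(f, df)
    M[, colnames(M) != "(Intercept)", drop = FALSE]
  }
  md <- mpr_data(df[[time]], st, encode(scale), encode(shape))
  attr(md, "frame") <- df
  md
}

config_error <- function(msg) {
  structure(class = c("mpr_config_error", "error", "condition"),
            list(message = msg, call = NULL))
}

convergence_error <- function(msg) {
  structure(class = c("mpr_convergence_error", "error", "condition"),
            list(message = msg, call = NULL))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(config_error(sprintf("config file not found: %s", config)))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop(config_error("the run configuration must be a list or a JSON file path"))
  config
}

resolve_defaults <- function(config, defaults) {
  out <- modifyList(defaults, config)
  out
}

default_fit_config <- function() {
  list(input = list(path = NULL, time = "time", status = "status",
                    scale = NULL, shape = NULL, sep = NULL, na_string = "NA"),
       penalty = list(family = "alasso", structure = "separate",
                      epsilon = 1e-4, scad_a = 3.7, weight_cap = 1e6,
                      zero_threshold = 1e-3),
       tuning = list(bounds = c(0, 1), pop_size = NULL, max_gen = 100,
                     F = 0.8, CR = 0.9, tol = 1e-4, patience = 10),
       lambda = NULL, seed = 1, output_dir = ".", standardized_output = FALSE,
       verbose = FALSE)
}

write_full_precision_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_resolved_config <- function(config, output_dir) {
  jsonlite::write_json(config, file.path(output_dir, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

run_log <- function(output_dir, lines) {
  writeLines(lines, file.path(output_dir, "run.log"))
}

#' Run a penalized fit from a configuration
#'
#' End-to-end driver: reads the data, fits the unpenalized model, computes
#' adaptive weights when needed, selects the tuning parameter(s) by
#' BIC/differential evolution, refits, and writes a coefficient report
#' (estimate, standard error, selection flag per component), a machine-
#' readable fit summary, the resolved configuration and a run log into the
#' output directory.
#'
#' @param config list or path to a JSON file; see the package vignette for
#'   the schema.  Minimal example: `list(input = list(path = "d.csv", scale =
#'   c("x1", "x2")), penalty = list(family = "lasso", structure = "single"),
#'   output_dir = "out")`.
#' @return (invisibly) the fitted `"mpr"` object.
#' @export
mpr_run_fit <- function(config) {
  config <- resolve_defaults(read_run_config(config), default_fit_config())
  inp <- config$input
  if (is.null(inp$path)) stop(config_error("input$path is required"))
  if (is.null(inp$shape)) inp$shape <- inp$scale
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  md <- read_survival_data(inp$path, inp$time, inp$status, inp$scale,
                           inp$shape, sep = inp$sep, na_string = inp$na_string)
  ctl <- mpr_control(zero_threshold = config$penalty$zero_threshold)
  unpen <- fit_unpenalized(md, control = ctl)
  fam <- config$penalty$family
  if (fam == "none") {
    fit <- unpen
  } else {
    weights <- if (fam == "alasso")
      make_adaptive_weights(unpen, config$penalty$weight_cap)
    cfg <- penalty_config(fam, config$penalty$structure,
                          scad_a = config$penalty$scad_a,
                          epsilon = config$penalty$epsilon,
                          weights = weights,
                          weight_cap = config$penalty$weight_cap)
    if (!is.null(config$lambda)) {
      fit <- fit_penalized(md, config$lambda, cfg, init = unpen, control = ctl)
    } else {
      tn <- config$tuning
      tun <- select_lambda_de(md, cfg, bounds = tn$bounds, unpenalized = unpen,
                              control = ctl,
                              de = de_control(pop_size = tn$pop_size,
                                              max_gen = tn$max_gen, F = tn$F,
                                              CR = tn$CR, tol = tn$tol,
                                              patience = tn$patience,
                                              seed = config$seed))
      fit <- tun$best_fit
      fit$tuning <- tun
    }
  }
  if (!fit$converged)
    stop(convergence_error("the final fit did not converge; see the run log"))
  std <- isTRUE(config$standardized_output)
  cf <- if (std) fit$coefficients_std else fit$coefficients
  se_std <- sqrt(pmax(diag(fit$vcov_std), 0))
  pb <- md$p + 1L
  se <- if (std)
    list(beta = se_std[seq_len(pb)], alpha = se_std[pb + seq_len(md$q + 1L)])
  else fit$se
  tab <- data.frame(
    component = rep(c("scale", "shape"), c(pb, md$q + 1L)),
    term = c(names(cf$beta), names(cf$alpha)),
    estimate = c(cf$beta, cf$alpha),
    std_error = c(se$beta, se$alpha),
    active = c(TRUE, fit$active$scale, TRUE, fit$active$shape))
  tab$z <- tab$estimate / ifelse(tab$std_error > 0, tab$std_error, NA)
  tab$p_value <- 2 * pnorm(-abs(tab$z))
  tab$significant_5pct <- !is.na(tab$p_value) & tab$p_value < 0.05
  write_full_precision_csv(tab, file.path(config$output_dir, "coefficients.csv"))
  jsonlite::write_json(
    list(penalty = fam, structure = config$penalty$structure,
         lambda = fit$lambda_raw, loglik = fit$loglik, edf = fit$edf,
         bic = fit$bic, n = fit$n, n_iter = fit$n_iter,
         converged = fit$converged, coefficient_scale = if (std) "standardized" else "original"),
    file.path(config$output_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  write_resolved_config(config, config$output_dir)
  run_log(config$output_dir, c(
    sprintf("mprselect fit: %s (%s)", fam, config$penalty$structure),
    sprintf("n = %d, p = %d, q = %d", md$n, md$p, md$q),
    sprintf("lambda* = %s", paste(format(fit$lambda_raw, digits = 8), collapse = ", ")),
    sprintf("loglik = %.6f, edf = %.4f, BIC = %.6f", fit$loglik, fit$edf, fit$bic),
    sprintf("converged = %s after %d iterations", fit$converged, fit$n_iter)))
  invisible(fit)
}

default_sim_config <- function() {
  list(scenario = list(n = 1000, n_covariates = 10, rho = 0.5,
                       beta = c(-1.5, -1.0, 0, 0, 0, 0, 0, -0.8, 0.5, 0, 0),
                       alpha = c(0.5, 0.4, 0, 0, 0, 0.4, -0.2, 0, 0, 0, 0),
                       censor_prop = 0.25, n_replicates = 100),
       penalties = list(list(family = "alasso", structure = "separate")),
       tuning = list(bounds = c(0, 1), pop_size = NULL, max_gen = 50,
                     F = 0.8, CR = 0.9, tol = 1e-4, patience = 10),
       seed = 1, cores = 1, output_dir = ".", save_raw = FALSE,
       verbose = FALSE)
}

#' Run a replicated simulation study from a configuration
#'
#' Wraps [mpr_sim_study()]: builds the scenario, runs all requested penalties
#' plus the unpenalized/oracle benchmarks, and writes `selection.csv` (C, IC,
#' PT, MSE per penalty and component), `inference.csv` (per-coefficient mean,
#' SE, SEE, CP), optionally the replicate-level raw estimates, and the
#' resolved configuration.  Identical seeds give identical files.
#'
#' @param config list or JSON path; see `default` fields in the vignette.
#' @return (invisibly) the `"mpr_sim_report"`.
#' @export
mpr_run_simulate <- function(config) {
  config <- resolve_defaults(read_run_config(config), default_sim_config())
  sc <- config$scenario
  scenario <- tryCatch(
    mpr_scenario(n = sc$n, n_covariates = sc$n_covariates, rho = sc$rho,
                 beta = sc$beta, alpha = sc$alpha,
                 censor_prop = sc$censor_prop,
                 n_replicates = sc$n_replicates, seed = config$seed),
    error = function(e) stop(config_error(conditionMessage(e))))
  penalties <- config$penalties
  if (!is.null(names(penalties)) && all(c("family", "structure") %in% names(penalties)))
    penalties <- list(penalties)  # JSON single object
  if (is.data.frame(penalties))
    penalties <- lapply(seq_len(nrow(penalties)),
                        function(i) as.list(penalties[i, ]))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  tn <- config$tuning
  rep <- mpr_sim_study(scenario, penalties = penalties,
                       bounds = tn$bounds,
                       de = de_control(pop_size = tn$pop_size,
                                       max_gen = tn$max_gen, F = tn$F,
                                       CR = tn$CR, tol = tn$tol,
                                       patience = tn$patience),
                       cores = config$cores, verbose = config$verbose)
  write_full_precision_csv(rep$selection, file.path(config$output_dir, "selection.csv"))
  write_full_precision_csv(rep$inference, file.path(config$output_dir, "inference.csv"))
  if (isTRUE(config$save_raw)) {
    long <- do.call(rbind, lapply(names(rep$raw), function(lb) {
      est <- rep$raw[[lb]]$est
      data.frame(penalty = lb,
                 replicate = rep(seq_len(nrow(est)), ncol(est)),
                 term = rep(colnames(est), each = nrow(est)),
                 estimate = as.vector(est),
                 std_error = as.vector(rep$raw[[lb]]$se))
    }))
    write_full_precision_csv(long, file.path(config$output_dir, "replicates.csv"))
  }
  write_resolved_config(config, config$output_dir)
  invisible(rep)
}

default_diag_config <- function() {
  list(input = list(path = NULL, time = "time", status = "status",
                    scale = NULL, shape = NULL, sep = NULL, na_string = "NA"),
       penalty = list(family = "lasso", structure = "single",
                      epsilon = 1e-4, scad_a = 3.7, weight_cap = 1e6,
                      zero_threshold = 1e-3),
       grid = NULL, conf_level = 0.95, seed = 1, output_dir = ".",
       verbose = FALSE)
}

#' Model diagnostics from a configuration
#'
#' Writes the Weibull adequacy table — Kaplan-Meier based `(log t, log H(t))`
#' points with confidence bounds, which should be near-linear (slope = shape)
#' under a homogeneous Weibull model — and, when a tuning grid is configured,
#' the BIC surface table (lambda, effective df, log-likelihood, BIC per grid
#' point).
#'
#' @param config list or JSON path with `input`, optional `penalty` + `grid`,
#'   `conf_level`, `output_dir`.
#' @return (invisibly) a list with the adequacy table and the BIC surface (or
#'   `NULL`).
#' @export
mpr_run_diagnose <- function(config) {
  config <- resolve_defaults(read_run_config(config), default_diag_config())
  inp <- config$input
  if (is.null(inp$path)) stop(config_error("input$path is required"))
  if (is.null(inp$shape)) inp$shape <- inp$scale
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  md <- read_survival_data(inp$path, inp$time, inp$status, inp$scale,
                           inp$shape, sep = inp$sep, na_string = inp$na_string)
  if (sum(md$status) == 0)
    stop(config_error("all observations are censored; the adequacy check needs events"))
  adequacy <- km_log_cumhaz(md$time, md$status, conf_level = config$conf_level)
  write_full_precision_csv(adequacy, file.path(config$output_dir, "adequacy.csv"))
  surface <- NULL
  if (!is.null(config$grid) && length(config$grid)) {
    fam <- config$penalty$family
    unpen <- fit_unpenalized(md)
    weights <- if (fam == "alasso") make_adaptive_weights(unpen, config$penalty$weight_cap)
    cfg <- penalty_config(fam, config$penalty$structure,
                          scad_a = config$penalty$scad_a,
                          epsilon = config$penalty$epsilon, weights = weights,
                          weight_cap = config$penalty$weight_cap)
    grid <- config$grid
    if (is.list(grid) && !is.data.frame(grid)) grid <- do.call(cbind, grid)
    tun <- select_lambda_grid(md, cfg, grid, unpenalized = unpen)
    surface <- tun$surface
    write_full_precision_csv(surface, file.path(config$output_dir, "bic_surface.csv"))
  } else if (isTRUE(config$verbose)) {
    message("no tuning grid configured; skipping the BIC surface table")
  }
  write_resolved_config(config, config$output_dir)
  invisible(list(adequacy = adequacy, surface = surface))
}
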
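#' Configure the synthetic-data generator
#'
#' Covariates are generated by a Gaussian-copula-style construction: latent
#' standard-normal deviates with a prescribed correlation matrix are
#' transformed marginally into continuous, zero-inflated, log-normal,
#' exponential, binary (latent thresholding) and three-level ordinal
#' variables; each ordinal factor expands into two dummy design columns.
#' The default configuration ([default_sim_config()]) emulates a typical
#' medical observational study with 15 latent variables yielding 17 design
#' columns, of which X1..X8 carry nonzero true coefficients.
#'
#' @param variables List of marginal specifications; each element is a list
#'   with `dist` in `"normal"`, `"zinormal"`, `"lognormal"`, `"exponential"`,
#'   `"binary"`, `"ordinal3"` plus its parameters (see the default config
#'   for the shapes).
#' @param latent_cor Positive-definite latent correlation matrix with unit
#'   diagonal, one row per variable (not per design column).
#' @param beta Named numeric vector of true coefficients, one per design
#'   column; zeros mark non-predictors.
#' @param sigma_eps Residual SD of the linear outcome.
#' @param family Outcome family for [simulate_outcome()].
#' @param logistic_intercept,cox_baseline_hazard,cox_censoring_rate Extra
#'   outcome parameters for the logistic and Cox families.
#' @return A `sim_config` object.
#' @export
sim_config <- function(variables, latent_cor, beta,
                       sigma_eps = 1,
                       family = c("linear", "logistic", "cox"),
                       logistic_intercept = 0,
                       cox_baseline_hazard = 0.1,
                       cox_censoring_rate = 0.05) {
  family <- match.arg(family)
  nv <- length(variables)
  latent_cor <- as.matrix(latent_cor)
  if (!isTRUE(all.equal(dim(latent_cor), c(nv, nv))))
    stop("latent_cor must be ", nv, " x ", nv)
  if (max(abs(latent_cor - t(latent_cor))) > 1e-8 ||
      max(abs(diag(latent_cor) - 1)) > 1e-8)
    stop("latent_cor must be symmetric with unit diagonal")
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("latent_cor is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  cols <- design_colnames(variables)
  beta <- beta[cols]
  if (anyNA(beta)) stop("beta must name every design column: ",
                        paste(setdiff(cols, names(beta)), collapse = ", "))
  structure(list(variables = variables, latent_cor = latent_cor,
                 beta = beta, sigma_eps = sigma_eps, family = family,
                 logistic_intercept = logistic_intercept,
                 cox_baseline_hazard = cox_baseline_hazard,
                 cox_censoring_rate = cox_censoring_rate,
                 columns = cols),
            class = "sim_config")
}

design_colnames <- function(variables) {
  unlist(lapply(variables, function(v)
    if (v$dist == "ordinal3") v$columns else v$column), use.names = FALSE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d latent variables -> %d design columns, family %s\n",
              length(x$variables), length(x$columns), x$family))
  cat(sprintf("predictors: %s\n",
              paste(names(x$beta)[x$beta != 0], collapse = ", ")))
  cat(sprintf("sigma_eps = %.4f\n", x$sigma_eps))
  invisible(x)
}

# Marginal transform of one latent standard-normal column.
transform_latent <- function(z, v) {
  switch(v$dist,
    normal = v$mean + v$sd * z,
    zinormal = v$scale * pmax(z - stats::qnorm(v$prop_zero), 0),
    lognormal = exp(v$meanlog + v$sdlog * z),
    exponential = stats::qexp(stats::pnorm(z), rate = v$rate),
    binary = as.numeric(z > stats::qnorm(1 - v$p)),
    ordinal3 = {
      # category probabilities v$probs; coding "cumulative" gives
      # I(level >= 2), I(level = 3); "level" gives I(level = 2), I(level = 3)
      c1 <- stats::qnorm(v$probs[1L])
      c2 <- stats::qnorm(v$probs[1L] + v$probs[2L])
      lev <- 1L + (z > c1) + (z > c2)
      if (v$coding == "cumulative") cbind(as.numeric(lev >= 2L),
                                          as.numeric(lev == 3L))
      else cbind(as.numeric(lev == 2L), as.numeric(lev == 3L))
    },
    stop("unknown marginal distribution: ", v$dist))
}

#' Generate covariates from a simulation configuration
#'
#' Draws `n` latent multivariate-normal rows with the configured
#' correlation matrix and applies the marginal transforms, yielding the
#' design columns (ordinal factors contribute their two dummies).
#'
#' @param n Sample size.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with one column per design variable.
#' @export
simulate_covariates <- function(n, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, nrow(config$latent_cor)),
                     Sigma = config$latent_cor)
  Z <- matrix(Z, nrow = n)   # n = 1 edge case
  out <- vector("list", length(config$variables))
  for (i in seq_along(config$variables)) {
    v <- config$variables[[i]]
    tr <- transform_latent(Z[, i], v)
    if (v$dist == "ordinal3") {
      out[[i]] <- stats::setNames(list(tr[, 1L], tr[, 2L]), v$columns)
    } else {
      out[[i]] <- stats::setNames(list(drop(tr)), v$column)
    }
  }
  tibble::as_tibble(unlist(out, recursive = FALSE))
}

#' Generate an outcome for a covariate table
#'
#' Linear family: `Y = X beta + eps`, `eps ~ N(0, sigma_eps^2)`.
#' Logistic: `P(Y = 1) = expit(intercept + X beta)`.
#' Cox: exponential event times with hazard
#' `h0 * exp(X beta)` and independent exponential censoring.
#'
#' @param X Covariate table whose columns match `names(config$beta)`.
#' @inheritParams simulate_covariates
#' @return A tibble with column `y` (linear/logistic) or `time`/`event` (cox).
#' @export
simulate_outcome <- function(X, config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(colnames(X), names(config$beta)))
    stop("columns of X do not match the configured coefficients")
  set.seed(seed)
  n <- nrow(X)
  lp <- as.numeric(as.matrix(X) %*% config$beta)
  switch(config$family,
    linear = tibble::tibble(y = lp + stats::rnorm(n, 0, config$sigma_eps)),
    logistic = {
      pr <- stats::plogis(config$logistic_intercept + lp)
      tibble::tibble(y = stats::rbinom(n, 1L, pr))
    },
    cox = {
      t_event <- stats::rexp(n) / (config$cox_baseline_hazard * exp(lp))
      t_cens <- stats::rexp(n, rate = config$cox_censoring_rate)
      tibble::tibble(time = pmin(t_event, t_cens),
                     event = as.numeric(t_event <= t_cens))
    })
}

#' Simulate a complete dataset
#'
#' @inheritParams simulate_covariates
#' @return A tibble: outcome column(s) followed by the design columns.
#' @examples
#' d <- simulate_dataset(200, default_sim_config(), seed = 1)
#' dim(d)
#' @export
simulate_dataset <- function(n, config, seed = 1) {
  X <- simulate_covariates(n, config, seed = mix_seed(seed, 1L))
  y <- simulate_outcome(X, config, seed = mix_seed(seed, 2L))
  dplyr::bind_cols(y, X)
}

#' Calibrate the residual SD to a target R-squared
#'
#' Chooses `sigma_eps` so that the population R-squared of the linear
#' outcome equals `r2`, using the empirical variance of the linear
#' predictor on a large simulated sample:
#' `sigma_eps = sd(X beta) * sqrt((1 - r2) / r2)`.
#'
#' @inheritParams simulate_covariates
#' @param r2 Target proportion of outcome variance explained.
#' @param n Calibration sample size.
#' @return The input config with `sigma_eps` replaced.
#' @export
calibrate_noise_sd <- function(config, r2 = 0.47, n = 1e5, seed = 1) {
  stopifnot(r2 > 0, r2 < 1)
  X <- simulate_covariates(n, config, seed = seed)
  s <- stats::sd(as.numeric(as.matrix(X) %*% config$beta))
  config$sigma_eps <- s * sqrt((1 - r2) / r2)
  config
}

#' Write a simulated dataset with a metadata sidecar
#'
#' @param data Tibble from [simulate_dataset()].
#' @param path CSV output path; the sidecar is written to `<path>.meta.json`.
#' @param config,seed The generating configuration and seed, recorded in the
#'   sidecar together with a hash of the configuration.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(data, path, config, seed) {
  readr::write_csv(data, path)
  meta <- list(
    n = nrow(data), seed = seed,
    family = config$family, sigma_eps = config$sigma_eps,
    beta = as.list(config$beta),
    config_hash = sum(as.numeric(config$latent_cor)) + sum(config$beta)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
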
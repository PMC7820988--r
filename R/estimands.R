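# Simulation engine: approximate the estimands of the four stability
# measures over Q independently simulated datasets, and benchmark their
# resampling estimators against those estimands.

# One simulated dataset -> global OLS fit + backward elimination, on the
# sufficient-statistic path.  Returns padded beta_hat, beta_tilde, selection.
sim_one_linear <- function(n, config, alpha, seed) {
  d <- simulate_dataset(n, config, seed = seed)
  X <- as.matrix(d[, config$columns, drop = FALSE])
  y <- d$y
  X1 <- cbind(1, X)
  XtX <- crossprod(X1)
  Xty <- crossprod(X1, y)
  yty <- sum(y * y)
  p <- ncol(X)
  tc <- as.list(seq_len(p) + 1L)
  glob <- fast_ols(XtX, Xty, yty, n)
  be <- fast_be(XtX, Xty, yty, n, tc, alpha)
  list(beta_hat = be$beta, beta_tilde = glob$beta, se_tilde = glob$se,
       selected = be$selected)
}

#' Approximate the estimands of the stability measures by simulation
#'
#' Simulates `Q` datasets of size `n` from `config`, applies backward
#' elimination with level `alpha` to each, and evaluates the estimands:
#' per design column the probability of selection (VIF) and the root mean
#' squared difference ratio
#' `sqrt(sum_q (beta_hat_jq - beta_j)^2 / Q) / sqrt(sum_q (beta_tilde_jq - beta_j)^2 / Q)`;
#' for predictors the relative conditional bias
#' `sum_q beta_hat_jq / (beta_j VIF_j Q) - 1` (undefined for true zero
#' coefficients); and the probability that exactly the true model is
#' selected (MSF).  Only the linear family is supported by the simulation
#' engine; each design column is its own term.
#'
#' @param config A [sim_config()] with `family = "linear"`.
#' @param n Sample size of each simulated dataset.
#' @param Q Number of simulated datasets.
#' @param alpha Backward-elimination level.
#' @param seed Master seed; dataset `q` uses a derived substream.
#' @param cores Parallel workers over datasets (results are independent of
#'   the worker count).
#' @return An `estimand_table` tibble: `column`, `true_beta`, `predictor`,
#'   `vif`, `vif_mc_se`, `rcb`, `rcb_mc_se`, `rmsdr`.  Attributes:
#'   `msf_true`, `msf_true_mc_se`, `true_model`, `Q`, `n`, `alpha`,
#'   `n_dropped` (datasets on which the selector failed).
#' @examples
#' \donttest{
#' et <- approximate_estimands(default_sim_config(), n = 300, Q = 50, seed = 1)
#' attr(et, "msf_true")
#' }
#' @export
approximate_estimands <- function(config, n, Q = 1000, alpha = 0.157,
                                  seed = 1, cores = 1) {
  stopifnot(inherits(config, "sim_config"), Q >= 2)
  if (config$family != "linear")
    stop("the simulation engine supports the linear family")
  runs <- sim_apply(seq_len(Q), cores, function(q)
    tryCatch(sim_one_linear(n, config, alpha, mix_seed(seed, q)),
             error = function(e) NULL))
  ok <- !vapply(runs, is.null, TRUE)
  runs <- runs[ok]
  Qe <- length(runs)
  beta_hat <- do.call(rbind, lapply(runs, `[[`, "beta_hat"))
  beta_til <- do.call(rbind, lapply(runs, `[[`, "beta_tilde"))
  sel <- do.call(rbind, lapply(runs, `[[`, "selected"))
  beta <- config$beta
  p <- length(beta)
  J <- which(beta != 0)
  vif_e <- colMeans(sel)
  hit <- apply(sel, 1L, function(s) all(s[J]) && !any(s[-J]))
  msf_e <- mean(hit)
  rcb_e <- rcb_mc <- rep(NA_real_, p)
  for (j in J) {
    if (vif_e[j] > 0) {
      rcb_e[j] <- sum(beta_hat[, j]) / (beta[j] * vif_e[j] * Qe) - 1
      r <- beta_hat[sel[, j], j] / beta[j]
      if (length(r) > 1L) rcb_mc[j] <- stats::sd(r) / sqrt(length(r))
    }
  }
  num <- sqrt(colMeans((beta_hat - matrix(beta, Qe, p, byrow = TRUE))^2))
  den <- sqrt(colMeans((beta_til - matrix(beta, Qe, p, byrow = TRUE))^2))
  out <- tibble::tibble(
    column = names(beta),
    true_beta = unname(beta),
    predictor = seq_len(p) %in% J,
    vif = unname(vif_e),
    vif_mc_se = sqrt(vif_e * (1 - vif_e) / Qe),
    rcb = rcb_e,
    rcb_mc_se = rcb_mc,
    rmsdr = unname(num / den)
  )
  structure(out, class = c("estimand_table", class(out)),
            msf_true = msf_e,
            msf_true_mc_se = sqrt(msf_e * (1 - msf_e) / Qe),
            true_model = names(beta)[J],
            Q = Qe, n = n, alpha = alpha, n_dropped = Q - Qe)
}

sim_apply <- function(ix, cores, fun) {
  if (cores > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(ix, fun, mc.cores = cores)
  else lapply(ix, fun)
}

# Resampling estimates of all four measures for one simulated dataset and
# one plan, on the sufficient-statistic path.
estimate_measures_fast <- function(X, y, alpha, plan, true_model_idx) {
  n <- nrow(X)
  p <- ncol(X)
  X1 <- cbind(1, X)
  tc <- as.list(seq_len(p) + 1L)
  glob <- fast_ols(crossprod(X1), crossprod(X1, y), sum(y * y), n)
  idx_sets <- draw_indices(n, plan)
  coefs <- matrix(NA_real_, plan$B, p)
  sel <- matrix(NA, plan$B, p)
  ok <- logical(plan$B)
  for (b in seq_len(plan$B)) {
    ix <- idx_sets[[b]]
    Xb <- X1[ix, , drop = FALSE]
    yb <- y[ix]
    r <- tryCatch(fast_be(crossprod(Xb), crossprod(Xb, yb), sum(yb * yb),
                          length(ix), tc, alpha),
                  error = function(e) NULL)
    if (is.null(r)) next
    coefs[b, ] <- r$beta
    sel[b, ] <- r$selected
    ok[b] <- TRUE
  }
  coefs <- coefs[ok, , drop = FALSE]
  sel <- sel[ok, , drop = FALSE]
  B <- nrow(sel)
  vif_b <- colMeans(sel)
  msf_b <- mean(apply(sel, 1L, function(s)
    all(s[true_model_idx]) && !any(s[-true_model_idx])))
  rcb_b <- rep(NA_real_, p)
  nz <- which(vif_b > 0 & glob$beta != 0)
  rcb_b[nz] <- colSums(coefs[, nz, drop = FALSE]) /
    (glob$beta[nz] * vif_b[nz] * B) - 1
  rmsdr_b <- sqrt(colMeans((coefs - matrix(glob$beta, B, p, byrow = TRUE))^2)) /
    glob$se
  list(vif = vif_b, msf = msf_b, rcb = rcb_b, rmsdr = rmsdr_b,
       n_failed = sum(!ok))
}

#' Benchmark resampling estimators of the stability measures
#'
#' For each of `Q` simulated datasets, draws a resampling ensemble of size
#' `B` under every plan, estimates VIF, MSF (of the true model), RCB and
#' RMSDR, and summarises the estimates against their simulation-approximated
#' estimands: mean and RMSE for the frequencies (VIF, MSF), median bias and
#' median absolute bias for RCB and RMSDR, with Monte-Carlo standard errors
#' of the means.
#'
#' @inheritParams approximate_estimands
#' @param B Resamples per dataset and plan.
#' @param schemes Character vector from `"bootstrap"`, `"s0.5"`, `"s0.632"`,
#'   `"s0.8"` (subsampling proportions 0.5, floor(0.632 N)/N, 0.8).
#' @param estimands Optional precomputed [approximate_estimands()] table;
#'   computed at the same `n` if missing.
#' @return A `performance_table` tibble: `measure`, `scheme`, `column`
#'   (`NA` for MSF), `estimand`, `mean`, `mc_se`, `rmse`, `median_bias`,
#'   `median_abs_bias`.  Attributes `Q`, `B`, `n`, `alpha`.
#' @export
evaluate_estimators <- function(config, n, Q = 200, B = 200,
                                schemes = c("bootstrap", "s0.5", "s0.632", "s0.8"),
                                alpha = 0.157, seed = 1, estimands = NULL,
                                cores = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$family != "linear")
    stop("the simulation engine supports the linear family")
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.null(estimands))
    estimands <- approximate_estimands(config, n, Q = max(Q, 500),
                                       alpha = alpha,
                                       seed = mix_seed(seed, 900001L))
  beta <- config$beta
  p <- length(beta)
  Jidx <- which(beta != 0)

  make_plan <- function(scheme, q) {
    sd_q <- mix_seed(seed, 7L * q + match(scheme, schemes))
    if (scheme == "bootstrap") resample_plan("bootstrap", B = B, seed = sd_q)
    else resample_plan("subsample", B = B,
                       proportion = as.numeric(sub("^s", "", scheme)),
                       seed = sd_q)
  }
  per_q <- sim_apply(seq_len(Q), cores, function(q) {
    d <- tryCatch(simulate_dataset(n, config, seed = mix_seed(seed, 500000L + q)),
                  error = function(e) NULL)
    if (is.null(d)) return(NULL)
    X <- as.matrix(d[, config$columns, drop = FALSE])
    lapply(stats::setNames(schemes, schemes), function(sc)
      tryCatch(estimate_measures_fast(X, d$y, alpha, make_plan(sc, q), Jidx),
               error = function(e) NULL))
  })
  per_q <- per_q[!vapply(per_q, is.null, TRUE)]
  Qe <- length(per_q)

  summarise_scheme <- function(sc) {
    runs <- lapply(per_q, `[[`, sc)
    keep <- !vapply(runs, is.null, TRUE)
    runs <- runs[keep]
    vifs <- do.call(rbind, lapply(runs, `[[`, "vif"))
    msfs <- vapply(runs, `[[`, 1, "msf")
    rcbs <- do.call(rbind, lapply(runs, `[[`, "rcb"))
    rmsd <- do.call(rbind, lapply(runs, `[[`, "rmsdr"))
    rows <- list()
    rows$msf <- tibble::tibble(
      measure = "msf", scheme = sc, column = NA_character_,
      estimand = attr(estimands, "msf_true"),
      mean = mean(msfs), mc_se = stats::sd(msfs) / sqrt(length(msfs)),
      rmse = sqrt(mean((msfs - attr(estimands, "msf_true"))^2)),
      median_bias = NA_real_, median_abs_bias = NA_real_)
    rows$vif <- tibble::tibble(
      measure = "vif", scheme = sc, column = estimands$column,
      estimand = estimands$vif,
      mean = colMeans(vifs),
      mc_se = apply(vifs, 2L, stats::sd) / sqrt(nrow(vifs)),
      rmse = sqrt(colMeans((vifs - matrix(estimands$vif, nrow(vifs), p,
                                          byrow = TRUE))^2)),
      median_bias = NA_real_, median_abs_bias = NA_real_)
    dev_rcb <- rcbs - matrix(estimands$rcb, nrow(rcbs), p, byrow = TRUE)
    rows$rcb <- tibble::tibble(
      measure = "rcb", scheme = sc, column = estimands$column,
      estimand = estimands$rcb,
      mean = colMeans(rcbs, na.rm = TRUE),
      mc_se = apply(rcbs, 2L, stats::sd, na.rm = TRUE) /
        sqrt(colSums(!is.na(rcbs))),
      rmse = NA_real_,
      median_bias = apply(dev_rcb, 2L, stats::median, na.rm = TRUE),
      median_abs_bias = apply(abs(dev_rcb), 2L, stats::median, na.rm = TRUE))
    dev_rm <- rmsd - matrix(estimands$rmsdr, nrow(rmsd), p, byrow = TRUE)
    rows$rmsdr <- tibble::tibble(
      measure = "rmsdr", scheme = sc, column = estimands$column,
      estimand = estimands$rmsdr,
      mean = colMeans(rmsd, na.rm = TRUE),
      mc_se = apply(rmsd, 2L, stats::sd, na.rm = TRUE) / sqrt(nrow(rmsd)),
      rmse = NA_real_,
      median_bias = apply(dev_rm, 2L, stats::median, na.rm = TRUE),
      median_abs_bias = apply(abs(dev_rm), 2L, stats::median, na.rm = TRUE))
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(lapply(schemes, summarise_scheme))
  structure(out, class = c("performance_table", class(out)),
            Q = Qe, B = B, n = n, alpha = alpha, estimands = estimands)
}
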
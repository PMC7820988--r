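#' Full stability assessment of a selected model
#'
#' End-to-end stability report for backward elimination on one dataset:
#' fits the global model, runs the selector on the original data, builds
#' two resampling ensembles and assembles the per-term report.  Following
#' the operating characteristics of the measures, inclusion-type measures
#' (VIF, MSF, pairwise inclusion) are estimated from a subsampling ensemble
#' with m = floor(N/2) and bias/variance-type measures (RCB, RMSDR, SF)
#' from a bootstrap ensemble; both default to `B` resamples and can be
#' overridden via `plan_inclusion`/`plan_bias`.
#'
#' @inheritParams backward_eliminate
#' @param B Number of resamples for both default plans.
#' @param seed Master seed; the two ensembles use substreams derived from it.
#' @param plan_inclusion,plan_bias Optional [resample_plan()]s replacing the
#'   defaults (subsample S_0.5 and bootstrap).
#' @param selector Optional custom selector (see [resample_select()]).
#' @return A `stability_report`.  `tidy()` returns the per-column table
#'   (global estimate/SE, VIF, selected estimate/SE, RMSDR, RCB x 100, SF,
#'   SE of SF), sorted by decreasing VIF; `glance()` the run summary.
#'   Attributes carry the ranked model frequencies ([top_models()]) and the
#'   pairwise inclusion matrix.
#' @examples
#' set.seed(42)
#' d <- data.frame(x1 = rnorm(120), x2 = rnorm(120), x3 = rnorm(120))
#' d$y <- d$x1 + 0.3 * d$x2 + rnorm(120)
#' rep <- stability(d, y ~ x1 + x2 + x3, family = "linear", B = 50, seed = 1)
#' tidy(rep)
#' @export
stability <- function(data, formula,
                      family = c("linear", "logistic", "cox"),
                      alpha = 0.157, forced = NULL, test = c("wald", "lr"),
                      B = 1000, seed = 1,
                      plan_inclusion = NULL, plan_bias = NULL,
                      selector = NULL) {
  family <- match.arg(family)
  test <- match.arg(test)
  plan_inclusion <- plan_inclusion %||%
    resample_plan("subsample", B = B, proportion = 0.5,
                  seed = mix_seed(seed, 1L))
  plan_bias <- plan_bias %||%
    resample_plan("bootstrap", B = B, seed = mix_seed(seed, 2L))

  be <- backward_eliminate(data, formula, family, alpha = alpha,
                           forced = forced, test = test)
  ens_inc <- resample_select(data, formula, family, plan_inclusion,
                             alpha = alpha, forced = forced, test = test,
                             selector = selector)
  ens_bias <- resample_select(data, formula, family, plan_bias,
                              alpha = alpha, forced = forced, test = test,
                              selector = selector)
  global <- ens_inc$global

  vt <- vif(ens_inc)
  check_report_invariants(ens_inc, vt)
  rc <- rcb(ens_bias, global)
  rm <- rmsdr(ens_bias, global)
  sfs <- shrinkage_factor(rc$rcb, rc$se_rcb)

  term_of <- character(length(ens_inc$columns))
  for (tm in names(ens_inc$term_cols)) term_of[ens_inc$term_cols[[tm]]] <- tm
  se_glob <- sqrt(diag(global$vcov))[ens_inc$columns]
  sel_est <- be$coefficients[ens_inc$columns]
  sel_se <- rep(NA_real_, length(ens_inc$columns))
  sel_cols <- names(be$fit$coefficients)
  sel_se[match(sel_cols, ens_inc$columns)] <- sqrt(diag(be$fit$vcov))[sel_cols]
  sel_est[!(term_of %in% be$selected)] <- NA_real_

  tab <- tibble::tibble(
    term = term_of,
    column = ens_inc$columns,
    estimate_global = unname(global$coefficients[ens_inc$columns]),
    se_global = unname(se_glob),
    vif = vt$vif[match(term_of, vt$term)] * 100,
    estimate_selected = unname(sel_est),
    se_selected = sel_se,
    rmsdr = rm$rmsdr,
    rcb_100 = rc$rcb * 100,
    sf = sfs$sf,
    se_sf = sfs$se_sf,
    rcb_caveat = rc$caveat | !(term_of %in% be$selected)
  )
  # Sort terms by decreasing VIF, keeping a term's columns adjacent and in
  # design order; ties keep the original term order.
  ord <- order(-tab$vif, match(tab$term, ens_inc$terms))
  tab <- tab[ord, ]

  structure(list(
    table = tab,
    selected = be$selected,
    trace = be$trace,
    top_models = top_models(ens_inc, k = 10),
    msf_selected = msf(ens_inc, be$selected),
    pairwise = pairwise_inclusion(ens_inc),
    plans = list(inclusion = plan_inclusion, bias = plan_bias),
    failures = c(inclusion = ens_inc$n_failed, bias = ens_bias$n_failed),
    alpha = alpha, family = family, seed = seed,
    n = ens_inc$n, terms = ens_inc$terms, forced = forced
  ), class = "stability_report")
}

# Invariants asserted on every run: MSFs over distinct selected models
# partition the ensemble, and each model frequency is bounded by the VIF of
# every included term and by 1 - VIF of every excluded term.
check_report_invariants <- function(ens, vt) {
  tm <- top_models(ens, k = Inf)
  stopifnot(abs(sum(tm$msf) - 1) < 1e-12)
  for (i in seq_len(nrow(tm))) {
    inset <- if (tm$model[i] == "(empty model)") character(0)
             else strsplit(tm$model[i], " + ", fixed = TRUE)[[1L]]
    vin <- vt$vif[vt$term %in% inset]
    vout <- vt$vif[!vt$term %in% inset]
    if (length(vin)) stopifnot(tm$msf[i] <= min(vin) + 1e-12)
    if (length(vout)) stopifnot(tm$msf[i] <= min(1 - vout) + 1e-12)
  }
  invisible(TRUE)
}

#' @export
print.stability_report <- function(x, digits = 3, ...) {
  cat(sprintf("<stability_report> %s model, N = %d, alpha = %.3g, seed = %d\n",
              x$family, x$n, x$alpha, x$seed))
  cat(sprintf("selected model (MSF %.1f%%): %s\n", 100 * x$msf_selected,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  pl <- x$plans$inclusion
  cat(sprintf(
    "ensembles: VIF/MSF from %s (B = %d), RCB/RMSDR from %s (B = %d); failures %d/%d\n",
    if (pl$scheme == "subsample") sprintf("subsample S_%g", pl$proportion)
    else "bootstrap", pl$B,
    if (x$plans$bias$scheme == "subsample")
      sprintf("subsample S_%g", x$plans$bias$proportion) else "bootstrap",
    x$plans$bias$B, x$failures[1], x$failures[2]))
  print(as.data.frame(x$table), digits = digits, row.names = FALSE)
  if (any(x$table$rcb_caveat, na.rm = TRUE))
    cat("note: RCB/SF rows of unselected terms describe apparent",
        "non-predictors; interpret with caution\n")
  invisible(x)
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$table

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_terms = length(x$terms),
    n_selected = length(x$selected),
    alpha = x$alpha,
    family = x$family,
    msf_selected = x$msf_selected,
    B_inclusion = x$plans$inclusion$B,
    B_bias = x$plans$bias$B,
    failed_inclusion = unname(x$failures["inclusion"]),
    failed_bias = unname(x$failures["bias"]),
    seed = x$seed
  )
}

#' Write a stability report to CSV and JSON
#'
#' The CSV holds the per-column table in report order; the JSON adds the
#' ranked model frequencies, the pairwise inclusion matrix and the run
#' metadata (seed, plans, failure counts) needed to reproduce the run.
#' Files are written atomically (temporary file, then rename), so a failed
#' run never leaves a partial output.
#'
#' @param x A `stability_report`.
#' @param csv,json Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_stability <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "stability_report"))
  if (!is.null(csv)) {
    tmp <- paste0(csv, ".tmp")
    readr::write_csv(x$table, tmp)
    file.rename(tmp, csv)
  }
  if (!is.null(json)) {
    payload <- list(
      family = x$family, n = x$n, alpha = x$alpha, seed = x$seed,
      selected = x$selected,
      msf_selected = x$msf_selected,
      table = x$table,
      top_models = x$top_models,
      pairwise_inclusion = list(terms = rownames(x$pairwise),
                                matrix = unname(x$pairwise)),
      plans = lapply(x$plans, unclass),
      failures = as.list(x$failures),
      trace = x$trace
    )
    tmp <- paste0(json, ".tmp")
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, json)
  }
  invisible(x)
}
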
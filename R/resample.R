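#' Define a resampling plan
#'
#' A plan describes how index sets are drawn from the original data:
#' `"bootstrap"` draws `N` observations with replacement; `"subsample"`
#' draws `floor(proportion * N)` observations without replacement.  The
#' customary subsampling proportions are 0.5, 0.632 (the limiting
#' probability that an observation appears in a bootstrap resample) and
#' 0.8.
#'
#' Index draws are seeded per resample from the plan seed, so increasing
#' `B` later extends an ensemble without changing the earlier resamples.
#'
#' @param scheme `"subsample"` or `"bootstrap"`.
#' @param B Number of resamples.
#' @param proportion Subsampling fraction m/N (ignored for the bootstrap).
#' @param seed Integer seed for the index draws.
#' @return A `resample_plan` object.
#' @examples
#' resample_plan("subsample", B = 500, proportion = 0.632, seed = 7)
#' @export
resample_plan <- function(scheme = c("subsample", "bootstrap"), B = 1000,
                          proportion = 0.5, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(B), B >= 1, is.numeric(seed))
  if (scheme == "subsample" &&
      (!is.numeric(proportion) || proportion <= 0 || proportion >= 1))
    stop("subsample proportion must lie strictly between 0 and 1")
  structure(list(scheme = scheme, B = as.integer(B),
                 proportion = if (scheme == "subsample") proportion else NA_real_,
                 seed = as.integer(seed)),
            class = "resample_plan")
}

#' @export
print.resample_plan <- function(x, ...) {
  lab <- if (x$scheme == "bootstrap") "bootstrap (N with replacement)"
         else sprintf("subsample S_%g (m = floor(%g N), without replacement)",
                      x$proportion, x$proportion)
  cat(sprintf("<resample_plan> %s, B = %d, seed = %d\n", lab, x$B, x$seed))
  invisible(x)
}

#' Draw resampling index sets
#'
#' @param n Number of observations in the original dataset.
#' @param plan A [resample_plan()].
#' @return A list of `B` integer vectors (multisets for the bootstrap).
#' @export
draw_indices <- function(n, plan) {
  stopifnot(inherits(plan, "resample_plan"), n >= 2)
  if (plan$scheme == "subsample") {
    m <- floor(plan$proportion * n)
    if (m <= 0 || m >= n) stop("subsample size m must satisfy 0 < m < N")
  }
  lapply(seq_len(plan$B), function(b) {
    set.seed(mix_seed(plan$seed, b))
    if (plan$scheme == "bootstrap") sample.int(n, n, replace = TRUE)
    else sample.int(n, floor(plan$proportion * n))
  })
}

#' Run a selector on every resample
#'
#' Applies a variable-selection procedure independently to each resampled
#' dataset and collects the zero-padded coefficient vectors and selected
#' term sets.  The default selector is [backward_eliminate()] with the
#' given `alpha`/`forced`/`test`; any function `data -> be_fit` satisfying
#' the same contract may be supplied instead (e.g. a Lasso wrapper).
#' Resamples on which the selector fails (singular design, non-convergence)
#' are excluded from all downstream measures and counted; more than 50%
#' failures aborts.
#'
#' For the linear family with the default selector, resamples are processed
#' via a sufficient-statistic path that is algebraically identical to the
#' formula interface but orders of magnitude faster.
#'
#' @inheritParams backward_eliminate
#' @param plan A [resample_plan()].
#' @param selector Optional custom selector, a `function(data)` returning an
#'   object with elements `selected` and zero-padded `coefficients` (such as
#'   a `be_fit`).
#' @return A `selection_ensemble`: coefficient matrix (successful resamples
#'   by design columns), logical selection matrix (resamples by terms),
#'   failure count, the plan and the global-model fit on the original data.
#' @export
resample_select <- function(data, formula,
                            family = c("linear", "logistic", "cox"),
                            plan, alpha = 0.157, forced = NULL,
                            test = c("wald", "lr"), selector = NULL) {
  family <- match.arg(family)
  test <- match.arg(test)
  stopifnot(inherits(plan, "resample_plan"))
  spec <- build_spec(data, formula, family)
  global <- refit_spec(spec, spec$term_labels)
  idx_sets <- draw_indices(spec$n, plan)
  nt <- length(spec$term_labels)
  p <- length(spec$columns)

  use_fast <- is.null(selector) && family == "linear" && test == "wald"
  coefs <- matrix(NA_real_, plan$B, p, dimnames = list(NULL, spec$columns))
  sel <- matrix(NA, plan$B, nt, dimnames = list(NULL, spec$term_labels))
  ok <- logical(plan$B)

  if (use_fast) {
    X1 <- cbind(`(Intercept)` = 1, spec$X)
    yv <- as.numeric(spec$y)
    tc <- lapply(spec$term_cols, function(ix) ix + 1L)
    forced_idx <- match(forced, spec$term_labels)
    for (b in seq_len(plan$B)) {
      idx <- idx_sets[[b]]
      Xb <- X1[idx, , drop = FALSE]
      yb <- yv[idx]
      res <- tryCatch(
        fast_be(crossprod(Xb), crossprod(Xb, yb), sum(yb * yb), length(idx),
                tc, alpha, forced_idx),
        error = function(e) NULL)
      if (is.null(res)) next
      coefs[b, ] <- res$beta
      sel[b, ] <- res$selected
      ok[b] <- TRUE
    }
  } else {
    sel_fun <- selector %||% function(d)
      backward_eliminate(d, formula, family, alpha = alpha,
                         forced = forced, test = test)
    for (b in seq_len(plan$B)) {
      d_b <- data[idx_sets[[b]], , drop = FALSE]
      res <- tryCatch(sel_fun(d_b), error = function(e) NULL)
      if (is.null(res)) next
      cf <- res$coefficients[spec$columns]
      if (anyNA(cf)) next
      coefs[b, ] <- cf
      sel[b, ] <- spec$term_labels %in% res$selected
      ok[b] <- TRUE
    }
  }
  n_fail <- sum(!ok)
  if (n_fail > plan$B / 2)
    stop(sprintf("selector failed on %d of %d resamples; resampling aborted",
                 n_fail, plan$B))
  structure(list(
    coefficients = coefs[ok, , drop = FALSE],
    selected = sel[ok, , drop = FALSE],
    n_failed = n_fail,
    plan = plan,
    terms = spec$term_labels,
    term_cols = spec$term_cols,
    columns = spec$columns,
    global = global,
    alpha = alpha, forced = forced, family = family,
    n = spec$n
  ), class = "selection_ensemble")
}

#' @export
print.selection_ensemble <- function(x, ...) {
  cat(sprintf("<selection_ensemble> %s, %d successful resamples (%d failed)\n",
              x$family, nrow(x$selected), x$n_failed))
  print(x$plan)
  invisible(x)
}
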
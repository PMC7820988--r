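#' Backward elimination with a significance-level stopping rule
#'
#' Starts from the global model containing every term of `formula`, then
#' iteratively drops the least significant non-forced term (largest p-value
#' `>= alpha`) and refits, until every remaining non-forced term has
#' `p < alpha` or only forced terms remain.  `alpha = 0.157` makes 1-df
#' elimination approximately equivalent to dropping terms while the AIC
#' improves (the p-value at which removing a 1-df term leaves the AIC
#' unchanged is `P(chisq_1 > 2) = 0.157`); [be_aic()] is an alias for this
#' choice.  With `alpha >= 1` no term is ever eliminated and the global
#' model is returned.
#'
#' Coefficients of eliminated terms are reported as exact zeros, so the
#' padded coefficient vector always has one entry per design column of the
#' global model.  Ties in the largest p-value are broken by dropping the
#' term occurring later in the formula.
#'
#' @inheritParams fit_model
#' @param alpha Stopping significance level in (0, 1]; default `0.157`.
#' @param forced Character vector of terms never eliminated.  The intercept
#'   (linear/logistic) is always retained.
#' @param test `"wald"` (default) or `"lr"` elimination tests.
#' @return An object of class `be_fit`: `selected` (term labels),
#'   `coefficients` (zero-padded, one per design column), `fit` (final
#'   `ss_fit`), and `trace`, a tibble of `(step, term, p.value)` in
#'   elimination order.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rnorm(80), x1 = rnorm(80), x2 = rnorm(80))
#' d$y <- d$y + d$x1
#' backward_eliminate(d, y ~ x1 + x2, family = "linear")
#' @export
backward_eliminate <- function(data, formula,
                               family = c("linear", "logistic", "cox"),
                               alpha = 0.157, forced = NULL,
                               test = c("wald", "lr")) {
  family <- match.arg(family)
  test <- match.arg(test)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  spec <- build_spec(data, formula, family)
  bad <- setdiff(forced, spec$term_labels)
  if (length(bad)) stop("forced term(s) not in formula: ", paste(bad, collapse = ", "))
  be_on_spec(spec, alpha, forced, test)
}

# Elimination loop on a prepared spec (shared with the resampling engine).
be_on_spec <- function(spec, alpha, forced = NULL, test = "wald") {
  included <- spec$term_labels
  trace <- list()
  step <- 0L
  fit <- NULL
  repeat {
    fit <- tryCatch(refit_spec(spec, included), error = function(e) e)
    if (inherits(fit, "error")) {
      err <- simpleError(sprintf("refit failed after %d elimination(s): %s",
                                 step, conditionMessage(fit)))
      err$trace <- dplyr::bind_rows(trace)
      stop(err)
    }
    if (alpha >= 1) break            # selection disabled: keep the global model
    candidates <- setdiff(included, forced)
    if (!length(candidates)) break
    pv <- term_pvalues(fit, candidates, type = test)
    if (all(pv$p.value < alpha)) break
    mx <- max(pv$p.value)
    drop_term <- pv$term[max(which(pv$p.value == mx))]  # tie: later position
    step <- step + 1L
    trace[[step]] <- tibble::tibble(step = step, term = drop_term, p.value = mx)
    included <- setdiff(included, drop_term)
  }
  padded <- stats::setNames(numeric(length(spec$columns)), spec$columns)
  padded[names(fit$coefficients)] <- fit$coefficients
  structure(list(
    selected = included,
    coefficients = padded,
    intercept = fit$intercept,
    fit = fit,
    trace = if (length(trace)) dplyr::bind_rows(trace)
            else tibble::tibble(step = integer(), term = character(),
                                p.value = numeric()),
    alpha = alpha, forced = forced, test = test,
    terms = spec$term_labels, term_cols = spec$term_cols,
    columns = spec$columns, family = spec$family
  ), class = "be_fit")
}

#' Backward elimination at the AIC-equivalent level
#'
#' Convenience wrapper for [backward_eliminate()] with `alpha = 0.157`, the
#' significance level at which eliminating a 1-df term is approximately
#' equivalent to improving the AIC.
#'
#' @inheritParams backward_eliminate
#' @export
be_aic <- function(data, formula, family = c("linear", "logistic", "cox"),
                   forced = NULL, test = c("wald", "lr")) {
  backward_eliminate(data, formula, family, alpha = 0.157,
                     forced = forced, test = test)
}

#' @export
print.be_fit <- function(x, ...) {
  cat(sprintf("<be_fit> %s model, alpha = %.3g\n", x$family, x$alpha))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
                   else "(none)", "\n")
  if (nrow(x$trace)) {
    cat("eliminated (in order):\n")
    print(as.data.frame(x$trace), row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a backward-elimination fit
#'
#' One row per design column of the global model, with the zero-padded
#' post-selection estimate and, for selected columns, the model-based
#' standard error from the final refit.
#'
#' @param x A `be_fit`.
#' @param ... Unused.
#' @method tidy be_fit
#' @export
tidy.be_fit <- function(x, ...) {
  term_of <- character(length(x$columns))
  for (tm in names(x$term_cols)) term_of[x$term_cols[[tm]]] <- tm
  se <- rep(NA_real_, length(x$columns))
  sel_cols <- names(x$fit$coefficients)
  se[match(sel_cols, x$columns)] <-
    sqrt(diag(x$fit$vcov))[sel_cols]
  tibble::tibble(
    column = x$columns,
    term = term_of,
    estimate = unname(x$coefficients),
    std.error = se,
    selected = term_of %in% x$selected
  )
}

#' @method glance be_fit
#' @export
glance.be_fit <- function(x, ...) {
  tibble::tibble(
    n = x$fit$n,
    n_terms = length(x$terms),
    n_selected = length(x$selected),
    n_eliminated = nrow(x$trace),
    alpha = x$alpha,
    aic = x$fit$aic,
    logLik = x$fit$loglik,
    converged = x$fit$converged
  )
}
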
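#' Fit a linear, logistic or Cox model with term bookkeeping
#'
#' Fits the model defined by `formula` by maximum (partial) likelihood and
#' records, for every term on the right-hand side, which design-matrix
#' columns it owns.  A *term* is one entry of the formula: a numeric column
#' contributes one design column, a factor or matrix column contributes a
#' group of columns that is always kept or dropped jointly by
#' [backward_eliminate()].
#'
#' @param data A data frame.  Missing values are rejected.
#' @param formula Model formula.  For `family = "cox"` the left-hand side
#'   must be a [survival::Surv()] object, e.g. `Surv(time, status) ~ age + sbp`.
#' @param family One of `"linear"`, `"logistic"`, `"cox"`.
#' @param terms Optional character vector of term labels to include
#'   (a subset of the formula's terms); default: all.
#' @return An object of class `ss_fit` with components `coefficients`
#'   (covariate coefficients, named by design column), `intercept`,
#'   `vcov`, `loglik`, `aic`, `converged`, `separation`, and the underlying
#'   `lm`/`glm`/`coxph` fit in `$fit`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4), x = c(0, 0, 1, 1))
#' f <- fit_model(d, y ~ x, family = "linear")
#' coef(f$fit)
#' @export
fit_model <- function(data, formula, family = c("linear", "logistic", "cox"),
                      terms = NULL) {
  family <- match.arg(family)
  spec <- build_spec(data, formula, family)
  refit_spec(spec, terms %||% spec$term_labels)
}

# Parse formula + data once: global design matrix, term -> column map.
build_spec <- function(data, formula, family) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- stats::terms(mf)
  term_labels <- attr(tt, "term.labels")
  if (length(term_labels) < 1L) stop("formula must contain at least one covariate term")
  mm <- stats::model.matrix(tt, mf)
  assign <- attr(mm, "assign")
  cov_cols <- which(assign > 0L)
  columns <- colnames(mm)[cov_cols]
  term_cols <- lapply(seq_along(term_labels), function(j) {
    match(colnames(mm)[assign == j], columns)
  })
  names(term_cols) <- term_labels
  y <- stats::model.response(mf)
  if (family == "cox" && !inherits(y, "Surv"))
    stop("family = \"cox\" requires a survival::Surv() response")
  if (family == "logistic") {
    yv <- as.numeric(y)
    if (!all(yv %in% c(0, 1))) stop("logistic family requires a 0/1 outcome")
  }
  n <- nrow(mm)
  p <- length(columns)
  if (n < p + 2L) stop(sprintf("need N >= p + 2 observations (N = %d, p = %d)", n, p))
  list(
    data = data, formula = formula, family = family,
    lhs = deparse(formula[[2L]]),
    term_labels = term_labels, term_cols = term_cols,
    columns = columns, X = mm[, cov_cols, drop = FALSE], y = y, n = n
  )
}

# Refit on a subset of terms; returns an ss_fit.
refit_spec <- function(spec, included) {
  stopifnot(all(included %in% spec$term_labels))
  rhs <- if (length(included)) quote_term(included) else "1"
  fml <- stats::reformulate(rhs, response = spec$lhs, env = environment())
  separation <- FALSE
  fit <- switch(spec$family,
    linear = stats::lm(fml, data = spec$data),
    logistic = withCallingHandlers(
      stats::glm(fml, data = spec$data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      }),
    cox = survival::coxph(fml, data = spec$data, ties = "efron",
                          control = survival::coxph.control(iter.max = 100,
                                                            eps = 1e-9))
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular design: coefficients not estimable for terms ",
                      paste(included, collapse = ", "))
  has_int <- spec$family != "cox"
  cov_names <- setdiff(names(cf), "(Intercept)")
  beta <- cf[cov_names]
  converged <- switch(spec$family,
    linear = TRUE,
    logistic = isTRUE(fit$converged) && !separation,
    cox = is.null(fit$info) || !isTRUE(fit$info$flag > 0)
  )
  if (spec$family == "logistic" && any(abs(beta) > 1e3)) separation <- TRUE
  ll <- if (spec$family == "cox") fit$loglik[length(fit$loglik)]
        else as.numeric(stats::logLik(fit))
  structure(list(
    fit = fit, family = spec$family, spec = spec,
    included_terms = included,
    coefficients = beta,
    intercept = if (has_int) unname(cf["(Intercept)"]) else NULL,
    vcov = stats::vcov(fit),
    sigma = if (spec$family == "linear") stats::sigma(fit) else NULL,
    df.residual = stats::df.residual(fit),
    loglik = ll,
    aic = stats::AIC(fit),
    converged = converged && !separation,
    separation = separation,
    n = spec$n
  ), class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> %s model, N = %d, terms: %s\n", x$family, x$n,
              paste(x$included_terms, collapse = ", ")))
  print(stats::coef(x$fit))
  invisible(x)
}

#' Term-level tests for a fitted model
#'
#' Computes one p-value per term of a fitted model.  Single-column terms use
#' the two-sided Wald test (t reference with residual degrees of freedom for
#' the linear family, standard normal otherwise).  Multi-column terms use the
#' quadratic-form Wald statistic against an F reference (linear) or a
#' chi-square with one degree of freedom per column (logistic/Cox).
#' A likelihood-ratio variant is available via `type = "lr"`.
#'
#' @param fit An `ss_fit` from [fit_model()].
#' @param terms Terms to test; default: all currently included.
#' @param type `"wald"` (default) or `"lr"`.
#' @return A tibble with columns `term`, `df`, `statistic`, `p.value`.
#' @export
term_pvalues <- function(fit, terms = NULL, type = c("wald", "lr")) {
  stopifnot(inherits(fit, "ss_fit"))
  type <- match.arg(type)
  terms <- terms %||% fit$included_terms
  bad <- setdiff(terms, fit$included_terms)
  if (length(bad)) stop("term(s) not in fit: ", paste(bad, collapse = ", "))
  rows <- lapply(terms, function(tm) {
    cols <- fit$spec$columns[fit$spec$term_cols[[tm]]]
    if (type == "wald") {
      b <- fit$coefficients[cols]
      V <- fit$vcov[cols, cols, drop = FALSE]
      W <- drop(crossprod(b, solve(V, b)))
      df1 <- length(cols)
      if (fit$family == "linear") {
        stat <- W / df1
        p <- stats::pf(stat, df1, fit$df.residual, lower.tail = FALSE)
      } else {
        stat <- W
        p <- stats::pchisq(stat, df1, lower.tail = FALSE)
      }
    } else {
      reduced <- refit_spec(fit$spec, setdiff(fit$included_terms, tm))
      df1 <- length(cols)
      stat <- 2 * (fit$loglik - reduced$loglik)
      p <- stats::pchisq(stat, df1, lower.tail = FALSE)
    }
    tibble::tibble(term = tm, df = length(cols), statistic = stat, p.value = p)
  })
  dplyr::bind_rows(rows)
}
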
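# Sufficient-statistic backward elimination for the linear family.
#
# The simulation and resampling engines run backward elimination tens of
# thousands of times on row-resampled versions of one design matrix.  For
# ordinary least squares every refit only needs the cross-products X'X, X'y
# and y'y of the resample, so they are formed once per resample and every
# elimination step is a small Cholesky solve.  Estimates, standard errors
# and Wald F/t p-values are algebraically identical to lm(); tests assert
# the equivalence against the formula interface.

# XtX/Xty include the intercept in position 1.  term_cols indexes the
# covariate columns 2..p+1.  Returns selection, padded coefficients and the
# elimination trace; errors on singular designs.
fast_be <- function(XtX, Xty, yty, n, term_cols, alpha, forced = integer(0)) {
  nt <- length(term_cols)
  included <- rep(TRUE, nt)
  trace_term <- integer(0)
  trace_p <- numeric(0)
  repeat {
    cols <- c(1L, unlist(term_cols[included], use.names = FALSE))
    R <- tryCatch(chol(XtX[cols, cols, drop = FALSE]), error = function(e) e)
    if (inherits(R, "error")) stop("singular design in resample")
    b <- Xty[cols]
    beta <- backsolve(R, forwardsolve(t(R), b))
    rss <- yty - sum(beta * b)
    dfres <- n - length(cols)
    if (dfres <= 0) stop("no residual degrees of freedom")
    if (alpha >= 1) break
    inv <- chol2inv(R)
    sigma2 <- max(rss, 0) / dfres
    cand <- which(included)
    cand <- setdiff(cand, forced)
    if (!length(cand)) break
    lens <- lengths(term_cols[cand])
    if (all(lens == 1L)) {       # vectorised single-column Wald t tests
      idx <- match(unlist(term_cols[cand], use.names = FALSE), cols)
      f <- beta[idx]^2 / (sigma2 * diag(inv)[idx])
      pv <- stats::pf(f, 1, dfres, lower.tail = FALSE)
    } else {
      pv <- vapply(cand, function(tm) {
        idx <- match(term_cols[[tm]], cols)
        bt <- beta[idx]
        Vt <- sigma2 * inv[idx, idx, drop = FALSE]
        W <- drop(crossprod(bt, solve(Vt, bt)))
        df1 <- length(idx)
        stats::pf(W / df1, df1, dfres, lower.tail = FALSE)
      }, 1)
    }
    if (all(pv < alpha)) break
    mx <- max(pv)
    drop_tm <- cand[max(which(pv == mx))]    # tie: later position
    trace_term <- c(trace_term, drop_tm)
    trace_p <- c(trace_p, mx)
    included[drop_tm] <- FALSE
  }
  # final state: beta/cols from last iteration
  p <- length(Xty) - 1L
  padded <- numeric(p)
  sel_cols <- cols[-1L]
  padded[sel_cols - 1L] <- beta[-1L]
  inv <- chol2inv(R)
  sigma2 <- max(rss, 0) / dfres
  se <- rep(NA_real_, p)
  se[sel_cols - 1L] <- sqrt(sigma2 * diag(inv))[-1L]
  list(selected = included, beta = padded, se = se,
       intercept = beta[1L], sigma2 = sigma2, dfres = dfres,
       trace_term = trace_term, trace_p = trace_p)
}

# Global (no-selection) OLS from cross-products: coefficients and SEs.
fast_ols <- function(XtX, Xty, yty, n) {
  R <- chol(XtX)
  beta <- backsolve(R, forwardsolve(t(R), Xty))
  rss <- yty - sum(beta * Xty)
  dfres <- n - length(Xty)
  inv <- chol2inv(R)
  sigma2 <- max(rss, 0) / dfres
  list(beta = beta[-1L], intercept = beta[1L],
       se = sqrt(sigma2 * diag(inv))[-1L],
       sigma2 = sigma2, rss = rss, dfres = dfres)
}
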
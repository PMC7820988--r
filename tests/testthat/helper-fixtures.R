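# Fixtures and independent oracles used across the suite.

# Small linear dataset with named covariates x1..xk; beta recycled/padded.
make_linear_data <- function(n = 60, k = 5, beta = c(1, 0.5), sd = 1,
                             seed = 1, rho = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  if (rho != 0) {
    z <- rnorm(n)
    X <- sqrt(1 - rho) * X + sqrt(rho) * z
  }
  colnames(X) <- paste0("x", seq_len(k))
  b <- rep(0, k)
  b[seq_along(beta)] <- beta
  d <- as.data.frame(X)
  d$y <- as.numeric(X %*% b) + rnorm(n, 0, sd)
  d
}

# Independent backward-elimination oracle: formula refits with lm() and
# nested-model anova() F tests only (no shared code with the package path).
oracle_be <- function(data, response, covs, alpha) {
  included <- covs
  trace <- character(0)
  repeat {
    if (!length(included)) break
    full <- lm(reformulate(included, response), data = data)
    ps <- vapply(included, function(tm) {
      red <- lm(reformulate(setdiff(included, tm) %:% "1", response),
                data = data)
      anova(red, full)[2, "Pr(>F)"]
    }, 1)
    if (all(ps < alpha)) break
    mx <- max(ps)
    drop_tm <- included[max(which(ps == mx))]
    trace <- c(trace, drop_tm)
    included <- setdiff(included, drop_tm)
  }
  list(selected = included, trace = trace)
}
`%:%` <- function(x, y) if (length(x)) x else y

# Minimal hand-built selection ensemble for arithmetic checks of the
# stability measures.
fake_ensemble <- function(sel, coefs, beta_tilde, se_tilde,
                          terms = colnames(sel)) {
  p <- ncol(coefs)
  columns <- colnames(coefs) %||% paste0("c", seq_len(p))
  colnames(coefs) <- columns
  term_cols <- split(seq_len(p), rep(seq_along(terms),
                                     times = p / length(terms)))
  names(term_cols) <- terms
  vc <- diag(se_tilde^2, p)
  dimnames(vc) <- list(columns, columns)
  structure(list(
    coefficients = coefs,
    selected = matrix(as.logical(sel), nrow(sel), length(terms),
                      dimnames = list(NULL, terms)),
    n_failed = 0L,
    plan = resample_plan("bootstrap", B = nrow(sel), seed = 1),
    terms = terms, term_cols = term_cols, columns = columns,
    global = list(coefficients = setNames(beta_tilde, columns), vcov = vc),
    alpha = 0.157, forced = NULL, family = "linear", n = 100L
  ), class = "selection_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny independent-covariate config for fast simulation tests.
toy_config <- function(k_pred = 3, k_null = 2, beta = 0.5, sigma = 1) {
  k <- k_pred + k_null
  vars <- lapply(seq_len(k), function(i)
    list(dist = "normal", mean = 0, sd = 1, column = paste0("x", i)))
  b <- setNames(c(rep(beta, k_pred), rep(0, k_null)), paste0("x", seq_len(k)))
  sim_config(vars, diag(k), b, sigma_eps = sigma)
}
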
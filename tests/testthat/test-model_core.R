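test_that("linear fit reproduces group means and the normal equations", {
  d <- data.frame(y = c(1, 2, 3, 4), x = c(0, 0, 1, 1))
  f <- fit_model(d, y ~ x, family = "linear")
  expect_equal(f$intercept, 1.5)
  expect_equal(unname(f$coefficients["x"]), 2.0)

  d2 <- make_linear_data(n = 80, k = 4, beta = c(1, -0.5, 0.25), seed = 7)
  f2 <- fit_model(d2, y ~ x1 + x2 + x3 + x4, family = "linear")
  X <- cbind(1, as.matrix(d2[paste0("x", 1:4)]))
  beta_ne <- solve(crossprod(X), crossprod(X, d2$y))  # normal equations
  expect_equal(unname(c(f2$intercept, f2$coefficients)),
               unname(drop(beta_ne)), tolerance = 1e-8)
})

test_that("logistic slope is zero under sign-flip symmetry of the data", {
  d <- data.frame(x = c(-1, -1, 1, 1), y = c(0, 1, 1, 0))
  f <- fit_model(d, y ~ x, family = "logistic")
  expect_equal(unname(f$coefficients["x"]), 0, tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("cox coefficient equals the grid-search partial-likelihood argmax", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  status = rep(1, 6),
                  x = c(0.5, -0.2, 0.3, -0.5, 0.1, -0.1))
  f <- fit_model(d, survival::Surv(time, status) ~ x, family = "cox")
  # oracle: maximise the partial likelihood directly (no ties present)
  neg_log_pl <- function(b) {
    ord <- order(d$time)
    x <- d$x[ord]
    -sum(vapply(seq_along(x), function(i)
      b * x[i] - log(sum(exp(b * x[i:length(x)]))), 1))
  }
  b_star <- optimize(neg_log_pl, c(-10, 10), tol = 1e-9)$minimum
  expect_equal(unname(f$coefficients["x"]), b_star, tolerance = 1e-5)
})

test_that("Wald term tests match their reference distributions", {
  d <- make_linear_data(n = 50, k = 3, beta = c(0.8), seed = 3)
  f <- fit_model(d, y ~ x1 + x2 + x3, family = "linear")
  sm <- summary(f$fit)$coefficients
  pv <- term_pvalues(f)
  expect_equal(pv$p.value, unname(sm[paste0("x", 1:3), 4]), tolerance = 1e-12)

  # multi-column term: quadratic-form Wald against a chi-square integration
  # oracle (logistic family, 2-df factor)
  set.seed(11)
  d2 <- data.frame(g = factor(sample(c("a", "b", "c"), 300, TRUE)))
  d2$y <- rbinom(300, 1, plogis(0.5 * (d2$g == "b") - 0.4 * (d2$g == "c")))
  f2 <- fit_model(d2, y ~ g, family = "logistic")
  pv2 <- term_pvalues(f2)
  expect_equal(pv2$df, 2)
  p_oracle <- integrate(function(x) dchisq(x, 2), pv2$statistic, Inf,
                        rel.tol = 1e-10)$value
  expect_equal(pv2$p.value, p_oracle, tolerance = 1e-7)
})

test_that("dropping a 1-df term changes AIC by about z^2 - 2 at large N", {
  d <- make_linear_data(n = 4000, k = 3, beta = c(1, 0.04), seed = 5)
  f_full <- fit_model(d, y ~ x1 + x2 + x3, family = "linear")
  z <- f_full$coefficients["x2"] /
    sqrt(diag(f_full$vcov))[["x2"]]
  f_red <- fit_model(d, y ~ x1 + x2 + x3, family = "linear",
                     terms = c("x1", "x3"))
  expect_equal(f_red$aic - f_full$aic, unname(z^2) - 2, tolerance = 0.02)
})

test_that("likelihood-ratio tests agree with Wald tests at large N", {
  d <- make_linear_data(n = 2000, k = 3, beta = c(0.5, 0.1), seed = 9)
  f <- fit_model(d, y ~ x1 + x2 + x3, family = "linear")
  pw <- term_pvalues(f, type = "wald")
  pl <- term_pvalues(f, type = "lr")
  expect_equal(pw$p.value, pl$p.value, tolerance = 0.02)
  # likelihood of a nested logistic model never exceeds the full model's
  d$yb <- as.numeric(d$y > 0)
  fb <- fit_model(d, yb ~ x1 + x2 + x3, family = "logistic")
  fb_red <- fit_model(d, yb ~ x1 + x2 + x3, family = "logistic",
                      terms = c("x1"))
  expect_gte(fb$loglik, fb_red$loglik)
})

test_that("degenerate inputs are rejected", {
  d <- make_linear_data(n = 30, k = 2, seed = 1)
  d$x3 <- d$x1                                        # exact collinearity
  expect_error(fit_model(d, y ~ x1 + x2 + x3, family = "linear"), "singular")
  d_small <- d[1:3, ]
  expect_error(fit_model(d_small, y ~ x1 + x2 + x3, family = "linear"),
               "N >= p")
  d_na <- d; d_na$x1[5] <- NA
  expect_error(fit_model(d_na, y ~ x1 + x2, family = "linear"))
  expect_error(fit_model(d, y ~ x1, family = "cox"), "Surv")
  expect_error(term_pvalues(fit_model(d, y ~ x1, family = "linear"), "x9"),
               "not in fit")
})

test_that("logistic separation is flagged rather than silently reported", {
  d <- data.frame(x = c(-(10:1), 1:10) / 2,
                  y = rep(c(0, 1), each = 10))
  f <- fit_model(d, y ~ x, family = "logistic")
  expect_true(f$separation)
  expect_false(f$converged)
})
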
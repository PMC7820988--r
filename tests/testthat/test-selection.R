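test_that("alpha = 1 disables elimination and returns the global model", {
  d <- make_linear_data(n = 40, k = 4, beta = 0, seed = 2)
  be <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4, family = "linear",
                           alpha = 1)
  expect_setequal(be$selected, paste0("x", 1:4))
  glob <- fit_model(d, y ~ x1 + x2 + x3 + x4, family = "linear")
  expect_equal(be$coefficients[names(glob$coefficients)], glob$coefficients)
  expect_equal(nrow(be$trace), 0)
})

test_that("a tiny alpha eliminates pure-noise covariates down to forced terms", {
  d <- make_linear_data(n = 200, k = 5, beta = 0, seed = 4)
  be <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4 + x5, family = "linear",
                           alpha = 1e-12, forced = "x2")
  expect_identical(be$selected, "x2")
  expect_equal(nrow(be$trace), 4)
  # elimination order matches the independent oracle path
  orc <- oracle_be(d, "y", paste0("x", 1:5), 1e-12)
  expect_identical(setdiff(be$trace$term, orc$trace), character(0))
})

test_that("selection matches an independently coded naive oracle", {
  for (s in 1:12) {
    d <- make_linear_data(n = 60, k = 5,
                          beta = runif(2, -0.6, 0.6), sd = 1,
                          seed = 100 + s)
    be <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4 + x5,
                             family = "linear", alpha = 0.157)
    orc <- oracle_be(d, "y", paste0("x", 1:5), 0.157)
    expect_setequal(be$selected, orc$selected)
    expect_identical(be$trace$term, orc$trace)
  }
})

test_that("trace p-values exceed alpha and final p-values fall below it", {
  d <- make_linear_data(n = 80, k = 6, beta = c(1, 0.4), seed = 6)
  be <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4 + x5 + x6,
                           family = "linear", alpha = 0.157)
  expect_true(all(be$trace$p.value >= 0.157))
  if (length(be$selected))
    expect_true(all(term_pvalues(be$fit)$p.value < 0.157))
})

test_that("exact p-value ties are broken towards the later term", {
  # orthogonal design with both slopes exactly zero: both p-values are
  # exactly 1, so the later term must leave first at each step
  XtX <- diag(c(8, 4, 4))
  Xty <- c(2, 0, 0)
  res <- selstab:::fast_be(XtX, Xty, yty = 6, n = 8,
                           term_cols = list(2L, 3L), alpha = 0.157)
  expect_identical(res$trace_term, c(2L, 1L))
  expect_equal(res$trace_p, c(1, 1))
})

test_that("selection is invariant to positive rescaling of a covariate", {
  d <- make_linear_data(n = 70, k = 4, beta = c(0.8, 0.3), seed = 8)
  be1 <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4, family = "linear")
  d2 <- d; d2$x2 <- d2$x2 * 1000
  be2 <- backward_eliminate(d2, y ~ x1 + x2 + x3 + x4, family = "linear")
  expect_identical(be1$selected, be2$selected)
  expect_identical(be1$trace$term, be2$trace$term)
  expect_equal(be1$trace$p.value, be2$trace$p.value, tolerance = 1e-9)
})

test_that("padded coefficients are exactly zero iff the term was eliminated", {
  d <- make_linear_data(n = 60, k = 5, beta = c(1), seed = 10)
  be <- backward_eliminate(d, y ~ x1 + x2 + x3 + x4 + x5, family = "linear",
                           alpha = 0.05)
  sel_cols <- unlist(lapply(be$selected, function(tm)
    be$columns[be$term_cols[[tm]]]))
  expect_true(all(be$coefficients[setdiff(be$columns, sel_cols)] == 0))
  expect_true(all(be$coefficients[sel_cols] != 0))
  td <- tidy(be)
  expect_identical(td$estimate == 0, !td$selected)
})

test_that("factor terms are tested and eliminated jointly", {
  set.seed(21)
  d <- data.frame(g = factor(sample(letters[1:3], 150, TRUE)),
                  x1 = rnorm(150))
  d$y <- d$x1 + rnorm(150)
  be <- backward_eliminate(d, y ~ x1 + g, family = "linear", alpha = 0.157)
  td <- tidy(be)
  g_rows <- td[td$term == "g", ]
  expect_equal(nrow(g_rows), 2)          # two dummies, one term
  expect_length(unique(g_rows$selected), 1)
})

test_that("be_aic is backward elimination at level 0.157", {
  d <- make_linear_data(n = 90, k = 4, beta = c(0.7), seed = 12)
  expect_identical(be_aic(d, y ~ x1 + x2 + x3 + x4, family = "linear")$selected,
                   backward_eliminate(d, y ~ x1 + x2 + x3 + x4,
                                      family = "linear",
                                      alpha = 0.157)$selected)
})

test_that("backward elimination works for logistic and Cox families", {
  set.seed(31)
  n <- 250
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$yb <- rbinom(n, 1, plogis(1.2 * d$x1))
  be_l <- backward_eliminate(d, yb ~ x1 + x2 + x3, family = "logistic",
                             alpha = 0.157)
  expect_true("x1" %in% be_l$selected)

  d$t <- rexp(n, exp(0.9 * d$x1))
  d$ev <- rbinom(n, 1, 0.9)
  be_c <- backward_eliminate(d, survival::Surv(t, ev) ~ x1 + x2 + x3,
                             family = "cox", alpha = 0.157)
  expect_true("x1" %in% be_c$selected)
  expect_null(be_c$intercept)
})
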
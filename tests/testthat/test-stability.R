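# Arithmetic of the four measures on hand-built ensembles, then their
# invariance properties on real resampling ensembles.

test_that("VIF is the fraction of resamples selecting the term", {
  ens <- fake_ensemble(sel = cbind(a = c(1, 0, 1, 1), b = c(0, 0, 0, 0)),
                       coefs = cbind(a = c(1, 0, 1, 1), b = numeric(4)),
                       beta_tilde = c(1, 1), se_tilde = c(0.1, 0.1))
  v <- vif(ens)
  expect_equal(v$vif[v$term == "a"], 0.75)
  expect_equal(v$vif[v$term == "b"], 0)
})

test_that("MSF counts exact model matches and partitions the ensemble", {
  sel <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))   # AB, AB, A, B
  ens <- fake_ensemble(sel = sel, coefs = sel * 1.0,
                       beta_tilde = c(1, 1), se_tilde = c(0.1, 0.1),
                       terms = c("A", "B"))
  expect_equal(msf(ens, c("A", "B")), 0.5)
  expect_equal(msf(ens, "A"), 0.25)
  expect_equal(msf(ens, character(0)), 0)
  tm <- top_models(ens, k = 10)
  expect_equal(sum(tm$msf), 1)
  expect_equal(tm$model[1], "A + B")
  # single repeated model
  ens1 <- fake_ensemble(sel = matrix(1, 5, 2), coefs = matrix(1, 5, 2),
                        beta_tilde = c(1, 1), se_tilde = c(0.1, 0.1),
                        terms = c("A", "B"))
  expect_equal(msf(ens1, c("A", "B")), 1)
  expect_equal(nrow(top_models(ens1)), 1)
})

test_that("RCB arithmetic matches the padded-sum definition", {
  ens <- fake_ensemble(sel = cbind(x = c(1, 1, 0, 0)),
                       coefs = cbind(x = c(2.5, 2.5, 0, 0)),
                       beta_tilde = 2, se_tilde = 0.5, terms = "x")
  r <- rcb(ens)
  expect_equal(r$rcb, 5 / (2 * 0.5 * 4) - 1)   # = 0.25
  expect_equal(r$n_selected, 2L)
  # estimates equal to the global estimate whenever selected -> RCB = 0
  ens0 <- fake_ensemble(sel = cbind(x = c(1, 0, 1)),
                        coefs = cbind(x = c(2, 0, 2)),
                        beta_tilde = 2, se_tilde = 0.5, terms = "x")
  expect_equal(rcb(ens0)$rcb, 0)
  # never selected -> undefined, with explanation
  ensNA <- fake_ensemble(sel = cbind(x = c(0, 0)),
                         coefs = cbind(x = c(0, 0)),
                         beta_tilde = 2, se_tilde = 0.5, terms = "x")
  rNA <- rcb(ensNA)
  expect_true(is.na(rNA$rcb))
  expect_match(rNA$note, "never selected")
})

test_that("RMSDR arithmetic includes zeros and normalises by the global SE", {
  ens <- fake_ensemble(sel = cbind(x = c(1, 1)),
                       coefs = cbind(x = c(1.5, 0.5)),
                       beta_tilde = 1, se_tilde = 0.5, terms = "x")
  expect_equal(rmsdr(ens)$rmsdr, 1.0)
  ens0 <- fake_ensemble(sel = cbind(x = rep(1, 4)),
                        coefs = cbind(x = rep(3, 4)),
                        beta_tilde = 3, se_tilde = 0.5, terms = "x")
  expect_equal(rmsdr(ens0)$rmsdr, 0)
})

test_that("shrinkage factors reproduce the published arithmetic", {
  sf <- shrinkage_factor(c(9.984, 44.691, 0) / 100)
  expect_equal(round(sf$sf, 3), c(0.909, 0.691, 1))
  # delta-method SE and undefined region
  sf2 <- shrinkage_factor(0.25, se = 0.1)
  expect_equal(sf2$se_sf, 0.1 / 1.25^2)
  expect_true(is.na(shrinkage_factor(-1.5)$sf))
})

test_that("pairwise inclusion frequencies obey the subset bounds", {
  sel <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0), c(0, 1, 1))
  ens <- fake_ensemble(sel = sel, coefs = sel * 1.0,
                       beta_tilde = rep(1, 3), se_tilde = rep(0.1, 3),
                       terms = c("A", "B", "C"))
  M <- pairwise_inclusion(ens)
  v <- vif(ens)$vif
  expect_equal(unname(diag(M)), v)
  for (i in 1:3) for (j in 1:3)
    expect_lte(M[i, j], min(v[i], v[j]))
  # always-selected pair has pairwise frequency 1
  ens1 <- fake_ensemble(sel = matrix(1, 4, 2), coefs = matrix(1, 4, 2),
                        beta_tilde = c(1, 1), se_tilde = c(0.1, 0.1),
                        terms = c("A", "B"))
  expect_equal(unname(pairwise_inclusion(ens1)), matrix(1, 2, 2))
})

test_that("the two RCB computations agree to 1e-12 on a real ensemble", {
  d <- make_linear_data(n = 100, k = 4, beta = c(1, 0.5, 0.2), seed = 37)
  ens <- resample_select(d, y ~ x1 + x2 + x3 + x4, family = "linear",
                         resample_plan("bootstrap", B = 150, seed = 3),
                         alpha = 0.157)
  r <- rcb(ens)   # internal stopifnot compares both forms at 1e-12
  csel <- ens$coefficients[, "x1"][ens$selected[, "x1"]]
  alt <- mean(csel / ens$global$coefficients[["x1"]]) - 1
  expect_equal(r$rcb[r$column == "x1"], alt, tolerance = 1e-12)
})

test_that("all stability measures are invariant to covariate rescaling", {
  d <- make_linear_data(n = 90, k = 4, beta = c(0.8, 0.3), seed = 41)
  d2 <- d; d2$x1 <- d2$x1 * 250; d2$x3 <- d2$x3 / 40
  plan <- resample_plan("subsample", B = 120, proportion = 0.5, seed = 5)
  e1 <- resample_select(d, y ~ x1 + x2 + x3 + x4, family = "linear", plan,
                        alpha = 0.157)
  e2 <- resample_select(d2, y ~ x1 + x2 + x3 + x4, family = "linear", plan,
                        alpha = 0.157)
  expect_identical(e1$selected, e2$selected)
  expect_equal(vif(e1)$vif, vif(e2)$vif)
  expect_equal(rcb(e1)$rcb, rcb(e2)$rcb, tolerance = 1e-9)
  expect_equal(rmsdr(e1)$rmsdr, rmsdr(e2)$rmsdr, tolerance = 1e-9)
  expect_equal(unname(pairwise_inclusion(e1)), unname(pairwise_inclusion(e2)))
})

test_that("stability() assembles a coherent report", {
  d <- make_linear_data(n = 150, k = 5, beta = c(1.2, 0.6), seed = 43)
  rep <- stability(d, y ~ x1 + x2 + x3 + x4 + x5, family = "linear",
                   B = 80, seed = 9)
  tab <- tidy(rep)
  expect_true(all(diff(tab$vif) <= 1e-9))          # sorted by VIF desc
  expect_true(all(tab$vif >= 0 & tab$vif <= 100))
  expect_lte(sum(rep$top_models$msf), 1 + 1e-12)
  expect_true(all(c("estimate_global", "se_global", "vif", "rmsdr",
                    "rcb_100", "sf", "se_sf") %in% names(tab)))
  g <- glance(rep)
  expect_equal(g$n, 150)
  expect_equal(g$msf_selected, rep$msf_selected)
  # alpha = 1: everything always selected
  rep1 <- stability(d, y ~ x1 + x2 + x3, family = "linear", alpha = 1,
                    B = 30, seed = 2)
  expect_true(all(tidy(rep1)$vif == 100))
  expect_equal(rep1$msf_selected, 1)
})

test_that("report files are byte-identical across reruns with one seed", {
  d <- make_linear_data(n = 80, k = 3, beta = c(1), seed = 47)
  out <- withr::local_tempdir()
  run <- function(tag) {
    rep <- stability(d, y ~ x1 + x2 + x3, family = "linear", B = 40, seed = 4)
    write_stability(rep, csv = file.path(out, paste0(tag, ".csv")),
                    json = file.path(out, paste0(tag, ".json")))
  }
  run("a"); run("b")
  expect_identical(readLines(file.path(out, "a.csv")),
                   readLines(file.path(out, "b.csv")))
  expect_identical(readLines(file.path(out, "a.json")),
                   readLines(file.path(out, "b.json")))
})
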
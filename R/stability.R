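#' Variable inclusion frequencies
#'
#' Fraction of successful resamples in which each term was selected.  A
#' multi-column term (factor, matrix) counts once however many design
#' columns it owns.
#'
#' @param ens A `selection_ensemble` from [resample_select()].
#' @param terms Optional subset of terms.
#' @return A tibble with columns `term` and `vif` (a frequency in \[0, 1\]).
#' @export
vif <- function(ens, terms = NULL) {
  stopifnot(inherits(ens, "selection_ensemble"))
  terms <- terms %||% ens$terms
  stopifnot(all(terms %in% ens$terms))
  tibble::tibble(term = terms,
                 vif = unname(colMeans(ens$selected)[terms]))
}

#' Model selection frequencies
#'
#' `msf()` returns the fraction of resamples in which *exactly* the given
#' set of terms was selected; `top_models()` ranks the distinct selected
#' sets by frequency (ties broken by first occurrence in the ensemble).
#' Frequencies over all distinct selected models sum to one.
#'
#' @param ens A `selection_ensemble`.
#' @param model Character vector of term names (order irrelevant).
#' @export
msf <- function(ens, model) {
  stopifnot(inherits(ens, "selection_ensemble"))
  stopifnot(all(model %in% ens$terms))
  want <- ens$terms %in% model
  mean(apply(ens$selected, 1L, function(s) all(s == want)))
}

#' @rdname msf
#' @param k Number of models to return.
#' @return `top_models()`: a tibble with `model` (term names joined by
#'   `" + "`), `msf`, and `first_seen` (resample index of first occurrence).
#' @export
top_models <- function(ens, k = 10) {
  stopifnot(inherits(ens, "selection_ensemble"))
  keys <- apply(ens$selected, 1L, function(s)
    paste(ens$terms[s], collapse = " + "))
  keys[keys == ""] <- "(empty model)"
  tab <- table(keys)
  first <- vapply(names(tab), function(kk) min(which(keys == kk)), 1L)
  out <- tibble::tibble(model = names(tab),
                        msf = as.numeric(tab) / length(keys),
                        first_seen = first)
  out <- out[order(-out$msf, out$first_seen), ]
  utils::head(out, k)
}

# per-column inclusion indicator (column inherits its term's selection)
col_selected <- function(ens) {
  term_of <- integer(length(ens$columns))
  for (j in seq_along(ens$terms)) term_of[ens$term_cols[[j]]] <- j
  ens$selected[, term_of, drop = FALSE]
}

#' Relative conditional bias
#'
#' For each design column, the mean ratio of the post-selection estimate to
#' the global-model estimate, conditional on selection, minus one:
#' `RCB_j = sum_b beta_hat_jb / (beta_tilde_j * VIF_j * B) - 1`.  Values
#' above 0 indicate that the coefficient is overestimated when selected,
#' values below 0 underestimation.  Both the padded-sum form and the
#' conditional-mean form are computed and asserted equal.  Columns never
#' selected get `NA` with an explanation in the `note` column; columns of
#' terms not selected on the original data are flagged (`caveat`), since
#' there the measure mirrors the behaviour of an apparent non-predictor.
#'
#' @param ens A `selection_ensemble`.
#' @param global Global-model `ss_fit`; defaults to the one stored in `ens`.
#' @return Tibble: `column`, `term`, `n_selected`, `rcb`, `se_rcb`, `caveat`,
#'   `note`.  The standard error is the sample SD of the conditional ratios
#'   divided by the square root of the number of selecting resamples.
#' @export
rcb <- function(ens, global = ens$global) {
  stopifnot(inherits(ens, "selection_ensemble"))
  beta_tilde <- global$coefficients[ens$columns]
  csel <- col_selected(ens)
  B <- nrow(csel)
  term_of <- character(length(ens$columns))
  for (tm in names(ens$term_cols)) term_of[ens$term_cols[[tm]]] <- tm
  out <- lapply(seq_along(ens$columns), function(j) {
    nsel <- sum(csel[, j])
    if (nsel == 0L) {
      return(tibble::tibble(column = ens$columns[j], term = term_of[j],
                            n_selected = 0L, rcb = NA_real_, se_rcb = NA_real_,
                            caveat = TRUE,
                            note = "never selected; RCB undefined"))
    }
    v <- nsel / B
    rcb1 <- unname(sum(ens$coefficients[, j]) / (beta_tilde[j] * v * B) - 1)
    ratios <- ens$coefficients[csel[, j], j] / beta_tilde[j]
    rcb2 <- mean(ratios) - 1
    stopifnot(abs(rcb1 - rcb2) <= 1e-12 * max(1, abs(rcb1)))
    se <- if (nsel > 1L) stats::sd(ratios) / sqrt(nsel) else NA_real_
    tibble::tibble(column = ens$columns[j], term = term_of[j],
                   n_selected = as.integer(nsel), rcb = rcb1, se_rcb = se,
                   caveat = FALSE, note = NA_character_)
  })
  dplyr::bind_rows(out)
}

#' Root mean squared difference ratio
#'
#' Square root of the mean squared difference between the zero-padded
#' post-selection estimates and the global-model estimate, divided by the
#' global model-based standard error:
#' `RMSDR_j = sqrt(sum_b (beta_hat_jb - beta_tilde_j)^2 / B) / se_tilde_j`.
#' Non-selection contributes exact zeros to the numerator.  Values above 1
#' flag selection-induced error inflation, below 1 a reduction.
#'
#' @inheritParams rcb
#' @return Tibble: `column`, `term`, `rmsdr`.
#' @export
rmsdr <- function(ens, global = ens$global) {
  stopifnot(inherits(ens, "selection_ensemble"))
  beta_tilde <- global$coefficients[ens$columns]
  se_tilde <- sqrt(diag(global$vcov))[ens$columns]
  stopifnot(all(se_tilde > 0))
  term_of <- character(length(ens$columns))
  for (tm in names(ens$term_cols)) term_of[ens$term_cols[[tm]]] <- tm
  num <- sqrt(colMeans((ens$coefficients -
                          matrix(beta_tilde, nrow(ens$coefficients),
                                 length(beta_tilde), byrow = TRUE))^2))
  tibble::tibble(column = ens$columns, term = term_of,
                 rmsdr = unname(num / se_tilde))
}

#' Shrinkage factor from a relative conditional bias
#'
#' `SF = (1 + RCB)^-1`, a multiplicative correction for selection-induced
#' overestimation, with a delta-method standard error
#' `SE_SF = SE_RCB / (1 + RCB)^2`.  Undefined (`NA`) for `RCB <= -1`.
#'
#' @param rcb Numeric vector of relative conditional biases (not x100).
#' @param se Optional standard errors of `rcb`.
#' @return Tibble with columns `sf` and `se_sf`.
#' @examples
#' shrinkage_factor(c(0.09984, 0.44691))  # 0.909, 0.691
#' @export
shrinkage_factor <- function(rcb, se = NULL) {
  sf <- ifelse(!is.na(rcb) & rcb > -1, 1 / (1 + rcb), NA_real_)
  se_sf <- if (is.null(se)) rep(NA_real_, length(rcb)) else se / (1 + rcb)^2
  se_sf[is.na(sf)] <- NA_real_
  tibble::tibble(sf = sf, se_sf = se_sf)
}

#' Pairwise inclusion frequencies
#'
#' Matrix whose (i, j) entry is the fraction of resamples selecting both
#' term i and term j; the diagonal holds the variable inclusion
#' frequencies.  Every off-diagonal entry is bounded by the smaller of the
#' two VIFs.
#'
#' @param ens A `selection_ensemble`.
#' @return A symmetric numeric matrix with term dimnames.
#' @export
pairwise_inclusion <- function(ens) {
  stopifnot(inherits(ens, "selection_ensemble"))
  S <- ens$selected * 1
  crossprod(S) / nrow(S)
}
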
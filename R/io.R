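#' Read a rectangular dataset for stability analysis
#'
#' CSV with a header row; any missing value is rejected (no imputation is
#' performed by this package).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort_config(paste("data file not found:", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (anyNA(d)) abort_config("dataset contains missing values; impute or drop before analysis")
  d
}

# Validate a run configuration (list or YAML path) and normalise defaults.
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a list or a YAML file path")
  req <- c("data", "family")
  miss <- setdiff(req, names(config))
  if (length(miss)) abort_config(paste("config misses fields:",
                                       paste(miss, collapse = ", ")))
  if (!config$family %in% c("linear", "logistic", "cox"))
    abort_config("family must be linear, logistic or cox")
  if (config$family == "cox") {
    if (is.null(config$time) || is.null(config$event))
      abort_config("cox family requires 'time' and 'event' outcome columns")
  } else if (is.null(config$outcome)) {
    abort_config("linear/logistic family requires an 'outcome' column")
  }
  config$alpha <- config$alpha %||% 0.157
  if (config$alpha <= 0 || config$alpha > 1)
    abort_config("alpha must lie in (0, 1]")
  config$B <- config$B %||% 1000
  config$seed <- config$seed %||% 1
  config$proportion_inclusion <- config$proportion_inclusion %||% 0.5
  config$forced <- config$forced %||% NULL
  config
}

#' Assess model stability from a run configuration
#'
#' End-user entry point mirroring the YAML/CLI interface: reads the data,
#' builds the term structure, runs [stability()] and optionally writes the
#' CSV/JSON report files.  Configuration fields: `data` (CSV path),
#' `family`, `outcome` (or `time` + `event` for Cox), optional `terms`
#' (named list mapping a term name to one or more data columns; columns of
#' one term are selected jointly), `alpha`, `forced`, `B`,
#' `proportion_inclusion`, `seed`, `out_csv`, `out_json`.
#' Defaults: subsampling with m = floor(N/2) for VIF/MSF, bootstrap for
#' RCB/RMSDR, B = 1000 each.
#'
#' @param config A list or path to a YAML file.
#' @param data Optional data frame overriding `config$data`.
#' @return The [stability()] report (files written as side effect if
#'   `out_csv`/`out_json` are configured).
#' @export
assess_stability <- function(config, data = NULL) {
  cfg <- validate_run_config(config)
  d <- data %||% read_dataset(cfg$data)
  if (anyNA(d)) abort_config("dataset contains missing values")

  outcome_cols <- if (cfg$family == "cox") c(cfg$time, cfg$event) else cfg$outcome
  miss <- setdiff(outcome_cols, names(d))
  if (length(miss)) abort_config(paste("outcome column(s) not in data:",
                                       paste(miss, collapse = ", ")))
  covar_cols <- setdiff(names(d), outcome_cols)

  # Terms: named groups of columns; a multi-column term becomes a matrix
  # column so the whole group is tested and eliminated jointly.
  if (!is.null(cfg$terms)) {
    bad <- setdiff(unlist(cfg$terms), covar_cols)
    if (length(bad)) abort_config(paste("term column(s) not in data:",
                                        paste(bad, collapse = ", ")))
    used <- unlist(cfg$terms)
    if (anyDuplicated(used))
      abort_config("every column may belong to at most one term")
    d2 <- d[, outcome_cols, drop = FALSE]
    for (tm in names(cfg$terms)) {
      cols <- cfg$terms[[tm]]
      d2[[tm]] <- if (length(cols) == 1L) d[[cols]]
                  else as.matrix(d[, cols, drop = FALSE])
    }
    term_labels <- names(cfg$terms)
    d <- d2
  } else {
    term_labels <- covar_cols
  }
  lhs <- if (cfg$family == "cox")
    sprintf("survival::Surv(%s, %s)", cfg$time, cfg$event) else cfg$outcome
  fml <- stats::as.formula(paste(lhs, "~",
                                 paste(quote_term(term_labels), collapse = " + ")))
  rep <- stability(d, fml, family = cfg$family, alpha = cfg$alpha,
                   forced = cfg$forced, B = cfg$B, seed = cfg$seed,
                   plan_inclusion = resample_plan(
                     "subsample", B = cfg$B,
                     proportion = cfg$proportion_inclusion,
                     seed = mix_seed(cfg$seed, 1L)))
  write_stability(rep, csv = cfg$out_csv, json = cfg$out_json)
  rep
}
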
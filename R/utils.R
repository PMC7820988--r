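# internal helpers

# Deterministic substream seed: resample b / simulated dataset q gets its own
# seed derived from the user's master seed, so ensembles can be extended
# without repeating earlier draws and parallel execution is order-independent.
# Kept strictly below 2^31 - 1.
mix_seed <- function(seed, i) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69069 + as.numeric(i) * 104729) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quote a term label so it survives reformulate() when non-syntactic
quote_term <- function(x) {
  ifelse(make.names(x) == x, x, paste0("`", x, "`"))
}

abort_config <- function(msg) {
  stop(structure(class = c("selstab_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
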
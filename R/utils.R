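# Internal helpers: argument checking and reproducible seed derivation.

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric, got %s.", name,
                  paste(utils::head(x, 3), collapse = ", ")),
          class = "coralscreen_config_error")
  }
  if (any(x < min) || any(x > max)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, min, max),
          class = "coralscreen_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")),
          class = "coralscreen_data_error")
  }
  invisible(df)
}

# Derive a stage-specific 31-bit seed from a root seed and a label so that
# independent pipeline stages never share RNG streams.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- rlang::`%||%`
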
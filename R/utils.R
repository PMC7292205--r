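# Internal helpers shared across modules.

# Half-up rounding for display, matching the convention used in clinical
# reporting (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical subtype label sets.
coo_levels <- c("ABC", "GCB", "UNC")
binary_levels <- c("GCB", "non-GCB")

stop_coodx <- function(msg, ..., class = "coodx_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop_coodx("%s is missing required column(s): %s", what,
               paste(miss, collapse = ", "),
               class = "coodx_validation_error")
  }
}

normalize_gene <- function(x) toupper(trimws(x))
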
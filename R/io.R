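#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited expression table with genes in rows and samples in
#' columns: the first column holds gene symbols and the header row holds
#' sample identifiers. This is the orientation used by GEO series matrices;
#' a transposed file is a hard error (detected via duplicate/invalid ids),
#' never silently auto-corrected.
#'
#' @param path Path to a TSV (default) or CSV file.
#' @param dialect `"tsv"` or `"csv"`.
#'
#' @return A tibble with first column `gene` (unique, whitespace-trimmed,
#'   upper-cased symbols) and one numeric column per sample. Values are on a
#'   log-like or -dCt scale; all values must be finite.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(gene = c("BCL6", "BATF"), s1 = c(1, 2),
#'                                 s2 = c(0.5, -1)), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  # minimal name repair so duplicate sample columns are caught, not renamed
  raw <- suppressWarnings(
    reader(path, col_types = readr::cols(), progress = FALSE,
           show_col_types = FALSE, name_repair = "minimal"))
  if (ncol(raw) < 2) {
    stop_coodx("expression file must have a gene column and >=1 sample column",
               class = "coodx_parse_error")
  }
  names(raw)[1] <- "gene"
  raw$gene <- normalize_gene(raw$gene)
  as_expression_matrix(raw)
}

#' Validate a gene-by-sample expression tibble
#'
#' Enforces the expression-matrix contract used throughout the package:
#' a `gene` first column with unique symbols, unique sample columns, and
#' finite numeric values.
#'
#' @param x A data frame whose first column is `gene` and remaining columns
#'   are per-sample numeric expression values.
#' @return The validated tibble.
#' @export
as_expression_matrix <- function(x) {
  # duplicate sample columns must be caught before any tidy reshaping
  samples <- names(x)[names(x) != "gene"]
  if (anyDuplicated(samples)) {
    stop_coodx("duplicate sample id(s): %s",
               paste(unique(samples[duplicated(samples)]), collapse = ", "),
               class = "coodx_validation_error")
  }
  x <- as_tibble(x)
  assert_cols(x, "gene", "expression matrix")
  x <- dplyr::relocate(x, "gene")
  x$gene <- normalize_gene(x$gene)
  dup_g <- unique(x$gene[duplicated(x$gene)])
  if (length(dup_g) > 0) {
    stop_coodx("duplicate gene id(s): %s", paste(dup_g, collapse = ", "),
               class = "coodx_validation_error")
  }
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop_coodx("non-numeric expression value in column '%s' (row %s)",
                 s, ifelse(is.na(bad), "?", bad),
                 class = "coodx_parse_error")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop_coodx("non-finite expression value(s) in column '%s'", s,
                 class = "coodx_validation_error")
    }
  }
  x
}

# Extract the numeric matrix (genes x samples) from an expression tibble.
expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene
  m
}

#' Read a long-format qPCR Ct table
#'
#' Reads replicate-level Ct measurements with columns `sample_id`, `gene`,
#' `replicate`, `ct`. The qPCR sentinel `"Undetermined"` (no amplification
#' within the run) is stored as `NA`, not treated as an error; Ct values
#' outside the plausible cycle range (0, 45] are rejected.
#'
#' @param path Path to a CSV file (TSV also accepted via `dialect`).
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A tibble with columns `sample_id`, `gene`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE, show_col_types = FALSE)
  assert_cols(raw, c("sample_id", "gene", "replicate", "ct"), "Ct table")
  ct_chr <- trimws(raw$ct)
  undet <- !is.na(ct_chr) & toupper(ct_chr) == "UNDETERMINED"
  ct <- suppressWarnings(as.numeric(ct_chr))
  bad_parse <- which(is.na(ct) & !undet & !is.na(ct_chr) & ct_chr != "")
  if (length(bad_parse) > 0) {
    stop_coodx("non-numeric ct value '%s' at data row %d",
               ct_chr[bad_parse[1]], bad_parse[1], class = "coodx_parse_error")
  }
  ct[undet] <- NA_real_
  out_of_range <- which(!is.na(ct) & (ct <= 0 | ct > 45))
  if (length(out_of_range) > 0) {
    stop_coodx("ct value %s at data row %d outside plausible range (0, 45]",
               format(ct[out_of_range[1]]), out_of_range[1],
               class = "coodx_validation_error")
  }
  tibble(
    sample_id = raw$sample_id,
    gene = normalize_gene(raw$gene),
    replicate = as.integer(raw$replicate),
    ct = ct
  )
}

#' Write and read subtype call sets
#'
#' `write_coo_calls()` writes a call set as TSV with columns `sample_id`,
#' `p_ABC`, `p_GCB`, `call`, `binary_call`; `read_coo_calls()` reads it back,
#' so that write-then-read is the identity.
#'
#' @param calls A call-set tibble as produced by [coo_call()]: columns
#'   `sample_id`, `p_ABC`, `p_GCB`, `call`, `binary_call`.
#' @param path Output (or input) file path.
#' @return `write_coo_calls()` returns `path` invisibly; `read_coo_calls()`
#'   returns the call-set tibble.
#' @export
write_coo_calls <- function(calls, path) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) {
    stop_coodx("refusing to write an empty call set",
               class = "coodx_validation_error")
  }
  readr::write_tsv(calls[, c("sample_id", "p_ABC", "p_GCB", "call",
                             "binary_call")], path)
  invisible(path)
}

#' @rdname write_coo_calls
#' @export
read_coo_calls <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    p_ABC = readr::col_double(),
    p_GCB = readr::col_double(),
    call = readr::col_character(),
    binary_call = readr::col_character()
  ), progress = FALSE)
  validate_calls(raw)
}

validate_calls <- function(calls) {
  calls <- as_tibble(calls)
  assert_cols(calls, c("sample_id", "p_ABC", "p_GCB", "call", "binary_call"),
              "call set")
  if (nrow(calls) > 0) {
    if (any(calls$p_ABC < 0 | calls$p_ABC > 1 | calls$p_GCB < 0 |
              calls$p_GCB > 1)) {
      stop_coodx("call probabilities must lie in [0, 1]",
                 class = "coodx_validation_error")
    }
    if (any(abs(calls$p_ABC + calls$p_GCB - 1) > 1e-6)) {
      stop_coodx("p_ABC + p_GCB must sum to 1", class = "coodx_validation_error")
    }
    if (!all(calls$call %in% coo_levels)) {
      stop_coodx("calls must be ABC, GCB or UNC", class = "coodx_validation_error")
    }
    if (!all(calls$binary_call %in% binary_levels)) {
      stop_coodx("binary calls must be GCB or non-GCB",
                 class = "coodx_validation_error")
    }
  }
  calls
}
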
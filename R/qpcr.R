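#' Aggregate qPCR replicates into per-(sample, gene) mean Ct values
#'
#' Triplicate Ct measurements are reduced to a single mean per sample and
#' gene under a replicate-concordance rule: if the spread (max - min) of the
#' available replicates exceeds `max_spread` cycles, the replicate farthest
#' from the median is dropped and the remaining pair re-tested; if the pair
#' still disagrees by more than `max_spread`, the measurement is flagged as
#' failed rather than averaged. Missing replicates (e.g. "Undetermined"
#' wells) are ignored; a measurement with no usable replicate fails.
#'
#' @param ct Long Ct tibble with columns `sample_id`, `gene`, `replicate`,
#'   `ct` (see [read_ct_table()]).
#' @param max_spread Maximum tolerated replicate spread in cycles.
#' @return A tibble with columns `sample_id`, `gene`, `mean_ct`,
#'   `n_replicates` (replicates used), `qc_pass` (logical) and `qc_reason`.
#' @export
aggregate_replicates <- function(ct, max_spread = 0.5) {
  assert_cols(ct, c("sample_id", "gene", "replicate", "ct"), "Ct table")
  if (max_spread < 0) {
    stop_coodx("max_spread must be >= 0", class = "coodx_validation_error")
  }
  dup <- ct |>
    dplyr::filter(!is.na(.data$replicate)) |>
    dplyr::count(.data$sample_id, .data$gene, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_coodx("duplicate replicate index for sample '%s', gene '%s'",
               dup$sample_id[1], dup$gene[1], class = "coodx_validation_error")
  }
  ct |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::summarise(res = list(aggregate_one(.data$ct, max_spread)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
}

# Concordance rule for one (sample, gene) replicate set.
aggregate_one <- function(ct, max_spread) {
  ct <- ct[!is.na(ct)]
  if (length(ct) == 0) {
    return(list(mean_ct = NA_real_, n_replicates = 0L, qc_pass = FALSE,
                qc_reason = "all replicates missing"))
  }
  if (diff(range(ct)) > max_spread && length(ct) >= 3) {
    drop <- which.max(abs(ct - median(ct)))
    ct <- ct[-drop]
  }
  if (diff(range(ct)) > max_spread) {
    return(list(mean_ct = NA_real_, n_replicates = length(ct),
                qc_pass = FALSE, qc_reason = "replicate spread exceeds limit"))
  }
  list(mean_ct = mean(ct), n_replicates = length(ct), qc_pass = TRUE,
       qc_reason = NA_character_)
}

#' Normalize mean Ct values to -dCt expression
#'
#' For each sample, dCt of a target gene is its mean Ct minus the unweighted
#' mean Ct of the three housekeeping genes; the stored expression value is
#' -dCt, which increases with transcript abundance. A sample whose
#' housekeeping genes are not all measurable is failed wholesale — without a
#' valid normalizer no target value on that sample is interpretable.
#'
#' @param mean_ct Output of [aggregate_replicates()].
#' @param panel A [coo_panel()] naming target and housekeeping genes.
#' @return A list with `expression` (gene-by-sample tibble of -dCt values
#'   for passing samples, target genes only), `qc` (per-(sample, gene)
#'   flags for target genes) and `sample_qc` (per-sample housekeeping
#'   status: `sample_id`, `hk_mean_ct`, `hk_pass`).
#' @export
delta_ct <- function(mean_ct, panel = coo_panel()) {
  assert_cols(mean_ct, c("sample_id", "gene", "mean_ct", "qc_pass"),
              "aggregated Ct table")
  targets <- panel_targets(panel)
  hk <- panel_housekeeping(panel)

  hk_tbl <- mean_ct |>
    dplyr::filter(.data$gene %in% hk) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hk_mean_ct = mean(.data$mean_ct[.data$qc_pass]),
      hk_pass = sum(.data$qc_pass) == length(hk),
      .groups = "drop"
    )
  all_samples <- unique(mean_ct$sample_id)
  absent <- setdiff(all_samples, hk_tbl$sample_id)
  if (length(absent) > 0) {
    hk_tbl <- dplyr::bind_rows(
      hk_tbl, tibble(sample_id = absent, hk_mean_ct = NA_real_,
                     hk_pass = FALSE))
  }

  qc <- mean_ct |>
    dplyr::filter(.data$gene %in% targets) |>
    dplyr::left_join(hk_tbl, by = "sample_id") |>
    dplyr::mutate(
      neg_delta_ct = dplyr::if_else(
        .data$qc_pass & .data$hk_pass,
        -(.data$mean_ct - .data$hk_mean_ct), NA_real_),
      qc_pass = .data$qc_pass & .data$hk_pass
    ) |>
    dplyr::select("sample_id", "gene", "mean_ct", "neg_delta_ct", "qc_pass")

  pass_samples <- hk_tbl$sample_id[hk_tbl$hk_pass]
  expr <- qc |>
    dplyr::filter(.data$sample_id %in% pass_samples) |>
    dplyr::select("sample_id", "gene", "neg_delta_ct") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "neg_delta_ct") |>
    dplyr::arrange(match(.data$gene, targets))

  list(expression = expr, qc = qc, sample_qc = hk_tbl)
}

#' Per-sample quality control on normalized qPCR data
#'
#' A sample fails if any housekeeping gene failed replicate concordance, or
#' if more than `max_failed_genes` target genes failed. The tolerated
#' number of failed targets is a laboratory acceptance setting, not a
#' biological constant; it is exposed and recorded in the output.
#'
#' @param delta Output of [delta_ct()].
#' @param max_failed_genes Maximum tolerated failed target genes.
#' @return A tibble with `sample_id`, `n_failed_genes`, `hk_pass`,
#'   `sample_pass` and the `max_failed_genes` setting used.
#' @export
sample_qc <- function(delta, max_failed_genes = 3) {
  stopifnot(is.list(delta), !is.null(delta$qc), !is.null(delta$sample_qc))
  delta$qc |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_failed_genes = sum(!.data$qc_pass), .groups = "drop") |>
    dplyr::left_join(delta$sample_qc[, c("sample_id", "hk_pass")],
                     by = "sample_id") |>
    dplyr::mutate(
      sample_pass = .data$hk_pass & .data$n_failed_genes <= max_failed_genes,
      max_failed_genes = max_failed_genes
    )
}
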
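#' @importFrom ggplot2 ggplot aes geom_step geom_point geom_line geom_tile
#'   labs scale_fill_gradient2 theme_minimal facet_wrap geom_col
NULL

#' Plot Kaplan-Meier curves
#'
#' @param object A `coo_km` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot coo_km
autoplot.coo_km <- function(object, ...) {
  # prepend S(0) = 1 per group so every curve starts at the origin
  origin <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  ggplot(object, aes(x = .data$time, y = .data$surv,
                     colour = .data$group)) +
    geom_step(data = dplyr::bind_rows(origin, object[, c("group", "time",
                                                         "surv")])) +
    geom_point(data = dplyr::filter(object, .data$n_censor > 0),
               shape = 3, size = 1.5) +
    labs(x = "Time (months)", y = "Overall survival", colour = NULL) +
    ggplot2::ylim(0, 1) +
    theme_minimal()
}

#' Plot the feature-elimination trajectory
#'
#' Shows how many genes survive each elimination round and the score of the
#' weakest survivor, a quick read on whether the planted or biological
#' signal separates from the noise floor.
#'
#' @param object An `rfe_trace` from [run_rfe()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot rfe_trace
autoplot.rfe_trace <- function(object, ...) {
  per_round <- object$trace |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     min_score = min(.data$score), .groups = "drop")
  ggplot(per_round, aes(x = .data$round, y = .data$n_genes)) +
    geom_line() +
    geom_point() +
    labs(x = "Elimination round", y = "Surviving genes") +
    theme_minimal()
}

#' Expression heatmap ordered by sample clustering
#'
#' Tile heatmap of the panel genes with samples ordered by complete-linkage
#' clustering on Pearson distance — the numeric content behind the
#' red/green subtype heatmaps conventional in expression profiling.
#'
#' @param expr Gene-by-sample expression tibble (typically restricted to
#'   the 32 panel genes).
#' @param calls Optional call set; when given, tiles are annotated by call
#'   via facetting order only (colors encode expression).
#' @return A ggplot.
#' @export
plot_expression_heatmap <- function(expr, calls = NULL) {
  dendro <- complete_linkage(pearson_distance(expr, axis = "samples"))
  sample_order <- dendro$hclust$labels[dendro$hclust$order]
  long <- tidyr::pivot_longer(expr, -"gene", names_to = "sample_id",
                              values_to = "value")
  long$sample_id <- factor(long$sample_id, levels = sample_order)
  long$gene <- factor(long$gene, levels = rev(expr$gene))
  ggplot(long, aes(x = .data$sample_id, y = .data$gene,
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "green4", mid = "black", high = "red3") +
    labs(x = NULL, y = NULL, fill = "-ΔCt") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot calibrated subtype probabilities
#'
#' Samples ordered by GCB probability, colored by the three-way call, with
#' the call threshold marked — a waterfall view of how confidently each
#' sample is assigned.
#'
#' @param calls A call-set tibble from [coo_classify()] / [coo_call()].
#' @param threshold Call threshold to mark (default 0.75).
#' @return A ggplot.
#' @export
plot_call_probabilities <- function(calls, threshold = 0.75) {
  assert_cols(calls, c("sample_id", "p_GCB", "call"), "call set")
  calls <- dplyr::arrange(calls, .data$p_GCB)
  calls$rank <- seq_len(nrow(calls))
  ggplot(calls, aes(x = .data$rank, y = .data$p_GCB, fill = .data$call)) +
    geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(threshold, 1 - threshold),
                        linetype = "dashed") +
    labs(x = "Samples (ordered)", y = "P(GCB)", fill = "Call") +
    theme_minimal()
}
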
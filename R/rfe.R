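#' Rank genes by linear-SVM weight magnitude
#'
#' Fits a linear max-margin classifier (soft-margin SVM at cost `C`) on
#' standardized expression and scores each gene by the squared weight it
#' receives in the decision function — the elimination criterion of
#' SVM-based recursive feature elimination. Standardization statistics are
#' computed on the supplied (training) samples only.
#'
#' @param expr Gene-by-sample expression tibble (see
#'   [as_expression_matrix()]).
#' @param labels Tibble with columns `sample_id` and `reference_label`
#'   (values `"ABC"`/`"GCB"`), or a character vector aligned with the
#'   sample columns of `expr`.
#' @param C Soft-margin cost parameter of the linear SVM.
#' @return A tibble with columns `gene` and `score` (squared weight),
#'   in the gene order of `expr`.
#' @export
rank_features <- function(expr, labels, C = 1) {
  xy <- align_labels(expr, labels)
  if (nlevels(droplevels(xy$y)) < 2) {
    stop_coodx("both classes must be present to rank features",
               class = "coodx_validation_error")
  }
  if (min(table(xy$y)) < 2) {
    stop_coodx("need >= 2 samples per class", class = "coodx_validation_error")
  }
  st <- standardize_fit(xy$X)
  fit <- fit_linear_svm(st$X, xy$y, C)
  tibble(gene = colnames(xy$X), score = as.numeric(fit$w)^2)
}

#' Recursive feature elimination with a linear SVM
#'
#' Starting from all genes, repeatedly fits a linear SVM, ranks genes by
#' squared weight, and drops the lowest-scoring fraction of the survivors
#' (at least one gene per round, never below `target_size`) until exactly
#' `target_size` genes remain. Score ties are broken by dropping the
#' lexicographically last gene id first, making the procedure deterministic.
#'
#' @inheritParams rank_features
#' @param target_size Number of genes to retain (default 32).
#' @param step_fraction Fraction of surviving genes eliminated per round.
#' @return An object of class `rfe_trace`: list with `final_genes`
#'   (character), `trace` (tibble: `round`, `gene`, `score`, `eliminated`)
#'   and `config`. `tidy()` returns the trace, `glance()` a one-row summary.
#' @export
run_rfe <- function(expr, labels, target_size = 32, step_fraction = 0.1,
                    C = 1) {
  if (step_fraction <= 0 || step_fraction >= 1) {
    stop_coodx("step_fraction must lie in (0, 1)",
               class = "coodx_validation_error")
  }
  if (target_size < 1) {
    stop_coodx("target_size must be >= 1", class = "coodx_validation_error")
  }
  genes <- expr$gene
  if (target_size > length(genes)) {
    stop_coodx("target_size (%d) exceeds number of genes (%d)",
               target_size, length(genes), class = "coodx_validation_error")
  }

  surviving <- sort(genes)
  rounds <- list()
  r <- 0L
  while (length(surviving) > target_size) {
    r <- r + 1L
    scores <- rank_features(expr[match(surviving, expr$gene), ], labels, C)
    n_drop <- min(ceiling(step_fraction * length(surviving)),
                  length(surviving) - target_size)
    # eliminate lowest scores; ties resolved against the lexicographically
    # last gene id
    ord <- order(scores$score, -xtfrm(scores$gene))
    dropped <- scores$gene[head(ord, n_drop)]
    rounds[[r]] <- dplyr::mutate(scores, round = r,
                                 eliminated = .data$gene %in% dropped)
    surviving <- sort(setdiff(surviving, dropped))
  }
  # terminal round: score the retained set, no elimination
  final_scores <- rank_features(expr[match(surviving, expr$gene), ], labels, C)
  rounds[[r + 1L]] <- dplyr::mutate(final_scores, round = r + 1L,
                                    eliminated = FALSE)

  structure(
    list(
      final_genes = surviving,
      trace = dplyr::bind_rows(rounds)[, c("round", "gene", "score",
                                           "eliminated")],
      config = list(target_size = target_size, step_fraction = step_fraction,
                    C = C)
    ),
    class = "rfe_trace"
  )
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf(
    "<rfe_trace> %d round(s): %d -> %d genes (step %.0f%%, C = %g)\n",
    max(x$trace$round), length(unique(x$trace$gene)), length(x$final_genes),
    100 * x$config$step_fraction, x$config$C))
  invisible(x)
}

#' @export
#' @method tidy rfe_trace
tidy.rfe_trace <- function(x, ...) x$trace

#' @export
#' @method glance rfe_trace
glance.rfe_trace <- function(x, ...) {
  tibble(
    n_rounds = max(x$trace$round),
    n_start = length(unique(x$trace$gene)),
    n_final = length(x$final_genes),
    step_fraction = x$config$step_fraction,
    C = x$config$C
  )
}

# --- shared linear-SVM plumbing ---------------------------------------------

# Align an expression tibble with subtype labels; returns samples-by-genes
# matrix X and a factor y with levels ABC, GCB.
align_labels <- function(expr, labels) {
  X <- t(expr_values(expr))
  if (is.data.frame(labels)) {
    assert_cols(labels, c("sample_id", "reference_label"), "labels")
    idx <- match(rownames(X), labels$sample_id)
    if (anyNA(idx)) {
      stop_coodx("no label for sample(s): %s",
                 paste(head(rownames(X)[is.na(idx)], 5), collapse = ", "),
                 class = "coodx_validation_error")
    }
    y <- labels$reference_label[idx]
  } else {
    if (length(labels) != nrow(X)) {
      stop_coodx("labels length (%d) != number of samples (%d)",
                 length(labels), nrow(X), class = "coodx_validation_error")
    }
    y <- as.character(labels)
  }
  if (!all(y %in% c("ABC", "GCB"))) {
    stop_coodx("labels must be 'ABC' or 'GCB'", class = "coodx_validation_error")
  }
  list(X = X, y = factor(y, levels = c("ABC", "GCB")))
}

# Column-wise standardization; zero-variance columns are centered and left
# at zero (they carry no information and receive zero weight).
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sdev, "/"), mean = mu, sd = sdev)
}

standardize_apply <- function(X, mu, sdev) {
  sweep(sweep(X, 2, mu), 2, sdev, "/")
}

# Linear SVM via e1071; weights oriented so a positive margin means GCB.
# Orientation is read off the decision-value column name rather than assumed
# from factor level order (e1071 orders classes by first appearance in y).
fit_linear_svm <- function(Xs, y, C) {
  fit <- e1071::svm(x = Xs, y = y, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  dv <- attr(predict(fit, Xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  positive <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (positive != "GCB") {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}
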
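#' Fit the cell-of-origin subtype classifier
#'
#' Trains a linear soft-margin SVM (cost `C`, default 1) on the panel genes
#' of standardized training expression, then calibrates the signed margin
#' into a GCB probability with a Platt-style sigmoid fitted on out-of-fold
#' margins from stratified cross-validation. Standardization statistics are
#' frozen from the training data and travel with the model, so a downstream
#' call is reproducible from the model artifact alone.
#'
#' @param expr Gene-by-sample expression tibble covering all panel genes
#'   (-dCt or log-scale values).
#' @param labels Tibble with `sample_id` and `reference_label`
#'   (`"ABC"`/`"GCB"`), or a character vector aligned with the sample
#'   columns.
#' @param panel A [coo_panel()]; its 32 target genes define the feature set.
#' @param C Soft-margin cost.
#' @param threshold Probability call threshold in (0.5, 1); a sample is
#'   assigned a subtype only when its class probability strictly exceeds
#'   this value (default 0.75).
#' @param n_folds Folds for the calibration margins.
#' @param seed Seed controlling fold assignment.
#'
#' @return An object of class `coo_model` with elements `genes`, `means`,
#'   `sds`, `weights`, `bias`, `calib_a`, `calib_b` (probability of GCB is
#'   `plogis(calib_a * margin + calib_b)` with `calib_a >= 0`), `threshold`,
#'   `C` and `calibration`.
#' @export
coo_fit <- function(expr, labels, panel = coo_panel(), C = 1,
                    threshold = 0.75, n_folds = 5, seed = 1) {
  if (threshold <= 0.5 || threshold >= 1) {
    stop_coodx("threshold must lie in (0.5, 1)",
               class = "coodx_validation_error")
  }
  genes <- panel_targets(panel)
  missing <- setdiff(genes, expr$gene)
  if (length(missing) > 0) {
    stop_coodx("expression data lacks panel gene(s): %s",
               paste(missing, collapse = ", "),
               class = "coodx_validation_error")
  }
  expr <- expr[match(genes, expr$gene), ]
  xy <- align_labels(expr, labels)
  if (nlevels(droplevels(xy$y)) < 2) {
    stop_coodx("both ABC and GCB labels are required",
               class = "coodx_validation_error")
  }

  st <- standardize_fit(xy$X)
  fit <- fit_linear_svm(st$X, xy$y, C)

  oof <- oof_margins(xy$X, xy$y, C, n_folds = n_folds, seed = seed)
  calib <- fit_platt(oof$margin, oof$y == "GCB")

  structure(
    list(
      genes = genes,
      means = setNames(as.numeric(st$mean), genes),
      sds = setNames(as.numeric(st$sd), genes),
      weights = setNames(fit$w, genes),
      bias = fit$b,
      calib_a = calib$a,
      calib_b = calib$b,
      threshold = threshold,
      C = C,
      calibration = sprintf("platt-sigmoid-%dfold", n_folds)
    ),
    class = "coo_model"
  )
}

# Out-of-fold margins from stratified cross-validation; each fold refits
# standardization and SVM on its training part only.
oof_margins <- function(X, y, C, n_folds = 5, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  margin <- numeric(length(y))
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
    st <- standardize_fit(X[tr, , drop = FALSE])
    f <- fit_linear_svm(st$X, droplevels(y[tr]), C)
    Xte <- standardize_apply(X[!tr, , drop = FALSE], st$mean, st$sd)
    margin[!tr] <- as.numeric(Xte %*% f$w) + f$b
  }
  list(margin = margin, y = y, fold = fold)
}

# Platt sigmoid: p(GCB) = plogis(a * margin + b), fitted by minimizing the
# cross-entropy against Platt's smoothed targets, with a >= 0 so that the
# probability is non-decreasing in the margin.
fit_platt <- function(margin, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  t <- ifelse(is_pos, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    p <- plogis(par[1] * margin + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  init <- c(1, 0)
  opt <- optim(init, nll, method = "L-BFGS-B",
               lower = c(0, -Inf), upper = c(Inf, Inf))
  list(a = opt$par[1], b = opt$par[2])
}

#' Predict subtype probabilities
#'
#' Applies a fitted [coo_fit()] model to new expression data. Every panel
#' gene must be present with a finite value; missing genes are an error —
#' the assay takes a no-imputation posture, failing loudly rather than
#' guessing.
#'
#' @param object A `coo_model`.
#' @param new_data Gene-by-sample expression tibble.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `margin`, `p_ABC`, `p_GCB`
#'   (`p_ABC + p_GCB = 1`; `p_GCB` non-decreasing in the margin).
#' @export
predict.coo_model <- function(object, new_data, ...) {
  missing <- setdiff(object$genes, new_data$gene)
  if (length(missing) > 0) {
    stop_coodx("new data lacks panel gene(s): %s",
               paste(missing, collapse = ", "),
               class = "coodx_validation_error")
  }
  m <- expr_values(new_data)[object$genes, , drop = FALSE]
  if (anyNA(m) || any(!is.finite(m))) {
    stop_coodx("non-finite expression value(s) in panel genes; no imputation",
               class = "coodx_validation_error")
  }
  Xs <- standardize_apply(t(m), object$means, object$sds)
  margin <- as.numeric(Xs %*% object$weights) + object$bias
  p_gcb <- plogis(object$calib_a * margin + object$calib_b)
  tibble(sample_id = colnames(m), margin = margin,
         p_ABC = 1 - p_gcb, p_GCB = p_gcb)
}

#' Three-way subtype call from calibrated probabilities
#'
#' A sample is called GCB when `p_GCB` strictly exceeds the threshold, ABC
#' when `p_ABC` strictly exceeds it, and unclassified (UNC) otherwise; a
#' probability exactly at the threshold yields UNC. Also appends the
#' binary GCB / non-GCB collapse (see [collapse_binary()]).
#'
#' @param probs Tibble with columns `p_ABC` and `p_GCB` (e.g. from
#'   [predict.coo_model()]).
#' @param threshold Call threshold in (0.5, 1), default 0.75.
#' @return `probs` with columns `call` (`"ABC"`/`"GCB"`/`"UNC"`) and
#'   `binary_call` (`"GCB"`/`"non-GCB"`) appended.
#' @export
coo_call <- function(probs, threshold = 0.75) {
  assert_cols(probs, c("p_ABC", "p_GCB"), "probability table")
  if (threshold <= 0.5 || threshold >= 1) {
    stop_coodx("threshold must lie in (0.5, 1)",
               class = "coodx_validation_error")
  }
  if (any(probs$p_ABC < 0 | probs$p_GCB < 0 |
            abs(probs$p_ABC + probs$p_GCB - 1) > 1e-9)) {
    stop_coodx("invalid probability vector(s)",
               class = "coodx_validation_error")
  }
  call <- dplyr::case_when(
    probs$p_GCB > threshold ~ "GCB",
    probs$p_ABC > threshold ~ "ABC",
    .default = "UNC"
  )
  dplyr::mutate(probs, call = call, binary_call = collapse_binary(call))
}

#' Collapse three-way calls to the GCB / non-GCB axis
#'
#' GCB stays GCB; ABC and unclassified calls become non-GCB. This is the
#' deterministic conversion used when comparing against the Hans
#' immunohistochemistry surrogate, which only resolves GCB vs non-GCB.
#'
#' @param call Character vector of `"ABC"`, `"GCB"` or `"UNC"` calls.
#' @return Character vector of `"GCB"` / `"non-GCB"`.
#' @export
collapse_binary <- function(call) {
  bad <- setdiff(unique(call), coo_levels)
  if (length(bad) > 0) {
    stop_coodx("unknown subtype label(s): %s", paste(bad, collapse = ", "),
               class = "coodx_validation_error")
  }
  ifelse(call == "GCB", "GCB", "non-GCB")
}

#' Classify samples end to end
#'
#' Convenience wrapper: predict probabilities with a fitted model, then
#' apply the three-way call rule at the model's threshold.
#'
#' @param expr Gene-by-sample expression tibble.
#' @param model A `coo_model`.
#' @return A call-set tibble: `sample_id`, `p_ABC`, `p_GCB`, `call`,
#'   `binary_call` (plus the raw `margin`).
#' @export
coo_classify <- function(expr, model) {
  coo_call(predict(model, expr), threshold = model$threshold)
}

#' Cross-validated subtype prediction accuracy
#'
#' Stratified k-fold cross-validation of the panel classifier: each fold is
#' predicted by a model (standardization + SVM) fitted on the remaining
#' folds, and a sample is counted correct when the sign of its margin
#' matches its reference label. Used for null-calibration checks and
#' performance estimates without a held-out set.
#'
#' @inheritParams coo_fit
#' @return A list with `predictions` (tibble: `sample_id`,
#'   `reference_label`, `margin`, `predicted`, `fold`) and `accuracy`.
#' @export
coo_cv <- function(expr, labels, panel = coo_panel(), C = 1, n_folds = 5,
                   seed = 1) {
  genes <- panel_targets(panel)
  missing <- setdiff(genes, expr$gene)
  if (length(missing) > 0) {
    stop_coodx("expression data lacks panel gene(s): %s",
               paste(missing, collapse = ", "),
               class = "coodx_validation_error")
  }
  expr <- expr[match(genes, expr$gene), ]
  xy <- align_labels(expr, labels)
  oof <- oof_margins(xy$X, xy$y, C, n_folds = n_folds, seed = seed)
  predicted <- ifelse(oof$margin > 0, "GCB", "ABC")
  preds <- tibble(
    sample_id = rownames(xy$X),
    reference_label = as.character(xy$y),
    margin = oof$margin,
    predicted = predicted,
    fold = oof$fold
  )
  list(predictions = preds,
       accuracy = mean(preds$predicted == preds$reference_label))
}

# --- serialization -----------------------------------------------------------

#' Write and read classifier model artifacts
#'
#' The model file is JSON carrying the panel gene order, standardization
#' statistics, linear weights and bias, sigmoid calibration and call
#' threshold, so a subtype call is reproducible from the single artifact.
#'
#' @param model A `coo_model`.
#' @param path File path.
#' @return `write_coo_model()` returns `path` invisibly; `read_coo_model()`
#'   the restored `coo_model`.
#' @export
write_coo_model <- function(model, path) {
  stopifnot(inherits(model, "coo_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coo_model
#' @export
read_coo_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    genes = as.character(raw$genes),
    means = setNames(as.numeric(raw$means), raw$genes),
    sds = setNames(as.numeric(raw$sds), raw$genes),
    weights = setNames(as.numeric(raw$weights), raw$genes),
    bias = as.numeric(raw$bias),
    calib_a = as.numeric(raw$calib_a),
    calib_b = as.numeric(raw$calib_b),
    threshold = as.numeric(raw$threshold),
    C = as.numeric(raw$C),
    calibration = as.character(raw$calibration)
  )
  structure(model, class = "coo_model")
}

#' @export
print.coo_model <- function(x, ...) {
  cat(sprintf(
    "<coo_model> %d-gene linear classifier (C = %g, threshold = %g, %s)\n",
    length(x$genes), x$C, x$threshold, x$calibration))
  invisible(x)
}

#' @export
#' @method tidy coo_model
tidy.coo_model <- function(x, ...) {
  tibble(gene = x$genes, mean = unname(x$means), sd = unname(x$sds),
         weight = unname(x$weights))
}

#' @export
#' @method glance coo_model
glance.coo_model <- function(x, ...) {
  tibble(n_genes = length(x$genes), bias = x$bias, calib_a = x$calib_a,
         calib_b = x$calib_b, threshold = x$threshold, C = x$C,
         calibration = x$calibration)
}
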
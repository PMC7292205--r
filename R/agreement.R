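#' Cross-tabulate two call sets
#'
#' Builds the confusion matrix between an assay's calls (rows) and a
#' reference method's calls (columns) over the samples callable by both.
#' Samples present in only one set are excluded and counted in a drop log
#' rather than silently discarded.
#'
#' @param calls_a,calls_b Data frames with a `sample_id` column and a call
#'   column (assay A in rows, reference B in columns).
#' @param call_col Name of the call column in both inputs (default
#'   `"call"`).
#' @return An object of class `coo_confusion`: list with `table` (integer
#'   matrix, rows = A, columns = B), `n`, `dropped_a`, `dropped_b`.
#'   `tidy()` returns the counts in long form.
#' @export
coo_confusion <- function(calls_a, calls_b, call_col = "call") {
  for (nm in list(list(calls_a, "calls_a"), list(calls_b, "calls_b"))) {
    assert_cols(nm[[1]], c("sample_id", call_col), nm[[2]])
  }
  shared <- intersect(calls_a$sample_id, calls_b$sample_id)
  if (length(shared) == 0) {
    stop_coodx("no shared sample ids between the two call sets",
               class = "coodx_validation_error")
  }
  a <- calls_a[[call_col]][match(shared, calls_a$sample_id)]
  b <- calls_b[[call_col]][match(shared, calls_b$sample_id)]
  labels <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = labels), factor(b, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(labels, labels))
  structure(
    list(
      table = m,
      n = length(shared),
      dropped_a = setdiff(calls_a$sample_id, shared),
      dropped_b = setdiff(calls_b$sample_id, shared)
    ),
    class = "coo_confusion"
  )
}

#' @export
print.coo_confusion <- function(x, ...) {
  cat(sprintf("<coo_confusion> %d samples callable by both (%d / %d dropped)\n",
              x$n, length(x$dropped_a), length(x$dropped_b)))
  m <- cbind(x$table, Subtotal = rowSums(x$table))
  m <- rbind(m, Subtotal = colSums(m))
  print(m)
  invisible(x)
}

#' @export
#' @method tidy coo_confusion
tidy.coo_confusion <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$table), stringsAsFactors = FALSE)) |>
    setNames(c("call_a", "call_b", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' Overall percent agreement with a Wilson confidence interval
#'
#' The fraction of samples on the confusion-matrix diagonal, with a Wilson
#' score interval at the requested level.
#'
#' @param conf A [coo_confusion()].
#' @param ci_level Confidence level, default 0.95.
#' @return A one-row tibble: `statistic`, `estimate`, `successes`, `n`,
#'   `conf_low`, `conf_high`, `ci_level`.
#' @export
overall_agreement <- function(conf, ci_level = 0.95) {
  stopifnot(inherits(conf, "coo_confusion"))
  m <- conf$table
  total <- sum(m)
  if (total == 0) {
    stop_coodx("empty confusion matrix", class = "coodx_validation_error")
  }
  agree <- sum(diag(m))
  ci <- wilson_ci(agree, total, ci_level)
  tibble(statistic = "overall_agreement", estimate = agree / total,
         successes = as.integer(agree), n = as.integer(total),
         conf_low = ci$lower, conf_high = ci$upper, ci_level = ci_level)
}

#' Positive and negative percent agreement against a reference
#'
#' For a 2x2 confusion matrix with the reference method on the columns:
#' PPA is the fraction of reference-positive samples that the assay also
#' calls positive, NPA the analogue for reference-negative samples —
#' sensitivity/specificity analogues when the comparator is a reference
#' method rather than ground truth. An empty reference class leaves that
#' statistic flagged as undefined rather than propagating NaN.
#'
#' @param conf A [coo_confusion()] over two labels.
#' @param positive The positive label (default `"GCB"`).
#' @param ci_level Confidence level for the Wilson intervals.
#' @return A two-row tibble (`statistic` = `"ppa"`, `"npa"`) with
#'   `estimate`, `successes`, `n`, `conf_low`, `conf_high`, `defined`.
#' @export
ppa_npa <- function(conf, positive = "GCB", ci_level = 0.95) {
  stopifnot(inherits(conf, "coo_confusion"))
  m <- conf$table
  labels <- rownames(m)
  if (length(labels) != 2 || !positive %in% labels) {
    stop_coodx("PPA/NPA require a 2x2 confusion matrix containing '%s'",
               positive, class = "coodx_validation_error")
  }
  negative <- setdiff(labels, positive)
  one <- function(stat, lab) {
    n_ref <- sum(m[, lab])
    if (n_ref == 0) {
      return(tibble(statistic = stat, estimate = NA_real_,
                    successes = NA_integer_, n = 0L, conf_low = NA_real_,
                    conf_high = NA_real_, defined = FALSE))
    }
    s <- m[lab, lab]
    ci <- wilson_ci(s, n_ref, ci_level)
    tibble(statistic = stat, estimate = s / n_ref,
           successes = as.integer(s), n = as.integer(n_ref),
           conf_low = ci$lower, conf_high = ci$upper, defined = TRUE)
  }
  dplyr::bind_rows(one("ppa", positive), one("npa", negative))
}

#' Wilson score interval for a binomial proportion
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `> 0`.
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble with `lower` and `upper`.
#' @examples
#' wilson_ci(209, 215)
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop_coodx("n must be > 0", class = "coodx_validation_error")
  if (successes < 0 || successes > n) {
    stop_coodx("successes must lie in [0, n]", class = "coodx_validation_error")
  }
  ci <- suppressWarnings(
    prop.test(successes, n, conf.level = level, correct = FALSE))$conf.int
  tibble(lower = ci[1], upper = ci[2])
}

#' Exact McNemar comparison of two assays against a shared reference
#'
#' Given per-sample correctness indicators of two assays judged against the
#' same reference, tests whether one assay agrees with the reference more
#' often than the other using the exact McNemar construction: conditioning
#' on the discordant pairs (`b` = A correct / B wrong, `c` = A wrong /
#' B correct), `b` is Binomial(b + c, 1/2) under the null, and the p-value
#' is the two-sided exact binomial tail.
#'
#' @param agree_a,agree_b Logical vectors (same length, same sample order):
#'   whether each assay's call matched the reference for each sample.
#' @return A one-row tibble with `b`, `c`, `n_discordant` and `p_value`
#'   (p = 1 when there are no discordant pairs).
#' @export
compare_paired_agreement <- function(agree_a, agree_b) {
  if (length(agree_a) != length(agree_b)) {
    stop_coodx("agreement vectors differ in length (%d vs %d)",
               length(agree_a), length(agree_b),
               class = "coodx_validation_error")
  }
  if (anyNA(agree_a) || anyNA(agree_b)) {
    stop_coodx("agreement indicators must not be missing",
               class = "coodx_validation_error")
  }
  b <- sum(agree_a & !agree_b)
  cc <- sum(!agree_a & agree_b)
  p <- if (b + cc == 0) 1 else binom.test(b, b + cc, p = 0.5)$p.value
  tibble(b = as.integer(b), c = as.integer(cc),
         n_discordant = as.integer(b + cc), p_value = p)
}
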
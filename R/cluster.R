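#' Pearson-correlation distance between expression profiles
#'
#' Distance `d = 1 - r` where `r` is Pearson's correlation between two
#' profiles, computed across samples (for gene profiles) or across genes
#' (for sample profiles). Ranges over \[0, 2\]: identical shape gives 0,
#' perfect anti-correlation gives 2. Constant profiles have undefined
#' correlation and are rejected by name.
#'
#' @param expr Gene-by-sample expression tibble.
#' @param axis `"samples"` (default, cluster the samples) or `"genes"`.
#' @return A symmetric numeric matrix with zero diagonal and profile ids as
#'   dimnames.
#' @export
pearson_distance <- function(expr, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  m <- expr_values(expr)
  if (axis == "genes") m <- t(m)
  # profiles are now columns of m
  if (nrow(m) < 2) {
    stop_coodx("need >= 2 observations per profile to correlate",
               class = "coodx_validation_error")
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop_coodx("constant profile(s) have no defined correlation: %s",
               paste(head(colnames(m)[sds == 0], 5), collapse = ", "),
               class = "coodx_validation_error")
  }
  d <- 1 - cor(m)
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' maximum pairwise distance between their members, so merge heights are
#' non-decreasing.
#'
#' @param d Symmetric distance matrix (e.g. from [pearson_distance()]) or a
#'   `dist` object.
#' @return An object of class `coo_dendrogram` wrapping the `hclust` fit;
#'   `tidy()` returns one row per merge (`step`, `height`, `size`),
#'   [cut_clusters()] extracts flat cluster memberships.
#' @export
complete_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
      stop_coodx("distance matrix must be symmetric",
                 class = "coodx_validation_error")
    }
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) {
    stop_coodx("d must be a distance matrix or dist object",
               class = "coodx_validation_error")
  }
  h <- hclust(d, method = "complete")
  structure(list(hclust = h, labels = h$labels), class = "coo_dendrogram")
}

#' @export
print.coo_dendrogram <- function(x, ...) {
  cat(sprintf("<coo_dendrogram> complete linkage, %d leaves\n",
              length(x$hclust$order)))
  invisible(x)
}

#' @export
#' @method tidy coo_dendrogram
tidy.coo_dendrogram <- function(x, ...) {
  h <- x$hclust
  sizes <- integer(length(h$height))
  count <- function(i) if (i < 0) 1L else sizes[i]
  for (k in seq_along(h$height)) {
    sizes[k] <- count(h$merge[k, 1]) + count(h$merge[k, 2])
  }
  tibble(step = seq_along(h$height), height = h$height, size = sizes)
}

#' Cut a dendrogram into k flat clusters
#'
#' @param dendro A [complete_linkage()] result.
#' @param k Number of clusters.
#' @return A tibble with `id` (leaf label) and `cluster`.
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(inherits(dendro, "coo_dendrogram"))
  cl <- stats::cutree(dendro$hclust, k = k)
  tibble(id = names(cl), cluster = as.integer(cl))
}
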
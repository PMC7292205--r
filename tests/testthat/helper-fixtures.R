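# Shared fixtures and independent oracles for the test suite.

# Small synthetic cohort used by several module tests.
tiny_cohort <- function(seed = 1, n = 30, effect = 2, noise_genes = 10,
                        replicate_sd = 0.2) {
  spec <- cohort_spec(n_abc = n, n_gcb = n, n_noise_genes = noise_genes,
                      effect_size = effect, replicate_sd = replicate_sd,
                      seed = seed)
  simulate_cohort(spec)
}

# Expand printed confusion-matrix counts into two per-sample call sets
# sharing sample ids, so the agreement module recomputes the published
# statistics from sample-level data.
calls_from_counts <- function(counts) {
  # counts: matrix with rownames = assay-A labels, colnames = reference labels
  a <- character()
  b <- character()
  for (i in rownames(counts)) {
    for (j in colnames(counts)) {
      k <- counts[i, j]
      a <- c(a, rep(i, k))
      b <- c(b, rep(j, k))
    }
  }
  ids <- sprintf("V%04d", seq_along(a))
  list(a = tibble::tibble(sample_id = ids, call = a),
       b = tibble::tibble(sample_id = ids, call = b))
}

# Printed validation counts: assay rows x reference columns.
table5_set1 <- matrix(c(142, 4, 2, 67), nrow = 2, byrow = TRUE,
                      dimnames = list(c("GCB", "ABC"), c("GCB", "ABC")))
table5_set2 <- matrix(c(210, 2, 27, 212), nrow = 2, byrow = TRUE,
                      dimnames = list(c("GCB", "ABC"), c("GCB", "ABC")))
table6_assay <- matrix(c(30, 5, 4, 72), nrow = 2, byrow = TRUE,
                       dimnames = list(c("GCB", "non-GCB"),
                                       c("GCB", "non-GCB")))
table6_ihc <- matrix(c(25, 16, 9, 61), nrow = 2, byrow = TRUE,
                     dimnames = list(c("GCB", "non-GCB"),
                                     c("GCB", "non-GCB")))

# Closed-form Wilson score interval, independent of the implementation path.
wilson_closed_form <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = centre - half, upper = centre + half)
}

# Naive complete-linkage agglomeration: at each step merge the pair of
# clusters with the smallest maximum pairwise member distance.
complete_linkage_oracle <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dij <- max(D[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Two-group log-rank statistic tabulated directly from the
# observed-minus-expected construction with hypergeometric variance.
logrank_oracle_2group <- function(time, event, group) {
  g1 <- unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == g1)
    d_t <- sum(time == t & event)
    d1_t <- sum(time == t & event & group == g1)
    o_minus_e <- o_minus_e + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  o_minus_e^2 / v
}

# Rand index between two flat partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
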
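test_that("Pearson distance matches the definition", {
  expr <- tibble::tibble(
    gene = c("G1", "G2", "G3", "G4"),
    a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1)
  )
  d <- pearson_distance(expr, axis = "samples")
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0)          # perfectly correlated
  expect_equal(d["a", "c"], 2)          # perfectly anti-correlated
  # brute-force formula oracle on random profiles
  set.seed(19)
  m <- matrix(rnorm(30), 10)
  colnames(m) <- c("x", "y", "z")
  expr2 <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%d", 1:10)),
                            tibble::as_tibble(m))
  d2 <- pearson_distance(expr2, axis = "samples")
  r_oracle <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(d2["x", "y"], 1 - r_oracle(m[, 1], m[, 2]), tolerance = 1e-12)
  expect_equal(d2["y", "z"], 1 - r_oracle(m[, 2], m[, 3]), tolerance = 1e-12)
})

test_that("constant profiles are rejected by name", {
  expr <- tibble::tibble(gene = c("G1", "G2"), a = c(1, 2), b = c(1, 5),
                         flat = c(3, 3))
  expect_error(pearson_distance(expr, axis = "samples"), "flat",
               class = "coodx_validation_error")
})

test_that("complete linkage reproduces a hand-traced merge sequence", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 5
  d["B", "C"] <- d["C", "B"] <- 4
  dendro <- complete_linkage(d)
  expect_equal(dendro$hclust$height, c(1, 5))
  td <- tidy(dendro)
  expect_equal(td$height, c(1, 5))
  expect_equal(td$size, c(2L, 3L))
})

test_that("equal distances merge at a common height", {
  n <- 5
  d <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(d) <- 0
  dendro <- complete_linkage(d)
  expect_equal(dendro$hclust$height, rep(1, n - 1))
})

test_that("merge heights match brute-force agglomeration on random inputs", {
  set.seed(29)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    p <- matrix(rnorm(n * 4), n)
    D <- as.matrix(dist(p))
    dendro <- complete_linkage(D)
    expect_equal(dendro$hclust$height, complete_linkage_oracle(D),
                 tolerance = 1e-10)
  }
})

test_that("asymmetric distance input is rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(complete_linkage(d), class = "coodx_validation_error")
})

test_that("two planted classes are recovered by cutting the dendrogram", {
  spec <- cohort_spec(n_abc = 30, n_gcb = 30, n_noise_genes = 0,
                      effect_size = 3, seed = 13)
  ex <- simulate_expression(spec)
  dendro <- complete_linkage(pearson_distance(ex$expression,
                                              axis = "samples"))
  cl <- cut_clusters(dendro, k = 2)
  truth <- ex$annotations$reference_label[match(cl$id,
                                                ex$annotations$sample_id)]
  expect_gt(rand_index(cl$cluster, as.integer(factor(truth))), 0.9)
})

test_that("Kaplan-Meier estimates match hand computation", {
  # all events at distinct times
  km <- km_curve(tibble::tibble(survival_time = c(1, 2, 3),
                                event = c(TRUE, TRUE, TRUE)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # one event among four, the rest censored later
  km <- km_curve(tibble::tibble(survival_time = c(2, 3, 4, 5),
                                event = c(TRUE, FALSE, FALSE, FALSE)))
  expect_equal(km$surv[km$time == 2], 3 / 4)
  # no events: survival stays at 1
  km <- km_curve(tibble::tibble(survival_time = c(1, 2, 3),
                                event = c(FALSE, FALSE, FALSE)))
  expect_true(all(km$surv == 1))
  expect_error(km_curve(tibble::tibble(survival_time = numeric(),
                                       event = logical())),
               class = "coodx_validation_error")
})

test_that("without censoring the KM curve equals the empirical survival", {
  set.seed(37)
  tt <- round(rexp(40, 0.1), 2)
  km <- km_curve(tibble::tibble(survival_time = tt, event = TRUE))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(tt > km$time[i]))
  }
})

test_that("the log-rank statistic matches a hand tabulation", {
  # textbook-scale two-arm fixture with ties and censoring
  df <- tibble::tibble(
    survival_time = c(3, 5, 5, 8, 10, 12, 14, 18, 20, 24,
                      2, 4, 6, 6, 9, 11, 13, 15, 21, 22),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
              TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    group = rep(c("A", "B"), each = 10)
  )
  got <- logrank_test(df, group = "group")
  want <- logrank_oracle_2group(df$survival_time, df$event, df$group)
  expect_equal(got$statistic, want, tolerance = 1e-10)
  expect_equal(got$df, 1L)

  # identical groups: statistic 0, p = 1
  same <- tibble::tibble(survival_time = rep(c(1, 2, 3, 4), 2),
                         event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
                         group = rep(c("A", "B"), each = 4))
  lr <- logrank_test(same, group = "group")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  expect_error(logrank_test(dplyr::mutate(same, group = "A"),
                            group = "group"),
               class = "coodx_validation_error")
})

test_that("the log-rank statistic ignores group label names", {
  set.seed(41)
  df <- tibble::tibble(
    survival_time = rexp(60, 0.05),
    event = runif(60) < 0.7,
    group = sample(c("x", "y", "z"), 60, replace = TRUE)
  )
  base <- logrank_test(df, group = "group")
  relabel <- c(x = "z", y = "x", z = "y")
  perm <- logrank_test(dplyr::mutate(df, group = unname(relabel[group])),
                       group = "group")
  expect_equal(base$statistic, perm$statistic, tolerance = 1e-12)
  expect_equal(base$df, perm$df)
})

test_that("a doubled hazard is detected with high power", {
  hits <- 0
  for (seed in 1:20) {
    spec <- cohort_spec(n_abc = 100, n_gcb = 100, hazard_abc = 0.04,
                        hazard_gcb = 0.02, seed = seed)
    ex <- simulate_expression(spec)
    ann <- simulate_ihc_survival(spec, ex$annotations)$annotations
    lr <- logrank_test(ann, group = "reference_label")
    hits <- hits + (lr$p_value < 0.05)
  }
  expect_gte(hits / 20, 0.9)
})
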
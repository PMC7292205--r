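# A separable one-dimensional problem embedded in the 32-gene panel: the
# first panel gene carries the signal, the rest are flat noise.
separable_fixture <- function(n_per_class = 20, seed = 1, sd = 0.01) {
  set.seed(seed)
  panel <- coo_panel()
  genes <- panel$gene[panel$role == "target"]
  y <- rep(c("ABC", "GCB"), each = n_per_class)
  ids <- sprintf("s%03d", seq_along(y))
  m <- matrix(rnorm(length(genes) * length(y), 0, sd), length(genes),
              dimnames = list(genes, ids))
  m[1, ] <- ifelse(y == "GCB", 1, -1) + rnorm(length(y), 0, sd)
  list(
    expr = dplyr::bind_cols(tibble::tibble(gene = genes),
                            tibble::as_tibble(m)),
    labels = tibble::tibble(sample_id = ids, reference_label = y)
  )
}

test_that("a separable toy is classified perfectly with confident calls", {
  fx <- separable_fixture(n_per_class = 20, seed = 1)
  model <- coo_fit(fx$expr, fx$labels, seed = 1)
  calls <- coo_classify(fx$expr, model)
  expect_equal(calls$call, fx$labels$reference_label)
  expect_true(all(calls$p_GCB[fx$labels$reference_label == "GCB"] > 0.75))
  expect_true(all(calls$p_ABC[fx$labels$reference_label == "ABC"] > 0.75))
  # cross-check: a simple threshold on the signal gene also separates
  v <- as.numeric(fx$expr[1, -1])
  expect_equal(mean((v > 0) == (fx$labels$reference_label == "GCB")), 1)
})

test_that("swapping class labels negates the decision function", {
  fx <- separable_fixture(n_per_class = 15, seed = 2, sd = 0.3)
  m1 <- coo_fit(fx$expr, fx$labels, seed = 1)
  swapped <- dplyr::mutate(fx$labels, reference_label = ifelse(
    reference_label == "ABC", "GCB", "ABC"))
  m2 <- coo_fit(fx$expr, swapped, seed = 1)
  expect_equal(unname(m2$weights), unname(-m1$weights), tolerance = 1e-6)
  expect_equal(m2$bias, -m1$bias, tolerance = 1e-6)
})

test_that("missing panel genes and non-finite values are hard errors", {
  fx <- separable_fixture(n_per_class = 10, seed = 3, sd = 0.3)
  expect_error(coo_fit(fx$expr[-1, ], fx$labels),
               class = "coodx_validation_error")
  model <- coo_fit(fx$expr, fx$labels, seed = 1)
  expect_error(predict(model, fx$expr[-5, ]),
               class = "coodx_validation_error")
  single <- dplyr::mutate(fx$labels, reference_label = "GCB")
  expect_error(coo_fit(fx$expr, single), class = "coodx_validation_error")
})

test_that("probabilities are coherent and monotone in the margin", {
  co <- tiny_cohort(seed = 9, n = 50, noise_genes = 0)
  model <- coo_fit(co$expression, co$annotations, seed = 1)
  probs <- predict(model, co$expression)
  expect_true(all(abs(probs$p_ABC + probs$p_GCB - 1) < 1e-9))
  ord <- order(probs$margin)
  expect_true(all(diff(probs$p_GCB[ord]) >= 0))

  # pushing a sample along the weight direction never lowers p_GCB
  x <- coodx:::expr_values(co$expression)[model$genes, 1]
  direction <- model$weights * model$sds
  shifted <- sapply(c(0, 1, 2, 4), function(k) {
    e <- tibble::tibble(gene = model$genes, s = x + k * direction)
    names(e)[2] <- "s"
    predict(model, e)$p_GCB
  })
  expect_true(all(diff(shifted) >= 0))
})

test_that("calibration assigns high probability to the true class", {
  train <- simulate_expression(cohort_spec(n_abc = 100, n_gcb = 100,
                                           n_noise_genes = 0,
                                           effect_size = 2, seed = 9))
  model <- coo_fit(train$expression, train$annotations, seed = 9)
  test <- simulate_expression(cohort_spec(n_abc = 100, n_gcb = 100,
                                          n_noise_genes = 0,
                                          effect_size = 2, seed = 10))
  probs <- predict(model, test$expression)
  truth <- test$annotations$reference_label
  p_true <- ifelse(truth == "GCB", probs$p_GCB, probs$p_ABC)
  expect_gt(mean(p_true), 0.8)
})

test_that("a boundary sample gets a near-even probability", {
  # symmetric training data; a sample at the panel-wise class midpoint has
  # margin ~0 and its calibrated probability stays near one half
  train <- simulate_expression(cohort_spec(n_abc = 100, n_gcb = 100,
                                           n_noise_genes = 0,
                                           effect_size = 2, seed = 12))
  model <- coo_fit(train$expression, train$annotations, seed = 12)
  mid <- tibble::tibble(gene = model$genes, mid = unname(model$means))
  p <- predict(model, mid)
  expect_lt(abs(p$p_GCB - 0.5), 0.2)
})

test_that("the three-way call rule applies strict threshold inequalities", {
  probs <- tibble::tibble(p_ABC = c(0.10, 0.40, 0.25, 0.80, 0.249),
                          p_GCB = c(0.90, 0.60, 0.75, 0.20, 0.751))
  calls <- coo_call(probs, threshold = 0.75)
  expect_equal(calls$call, c("GCB", "UNC", "UNC", "ABC", "GCB"))
  expect_equal(calls$binary_call,
               c("GCB", "non-GCB", "non-GCB", "non-GCB", "GCB"))
})

test_that("binary collapse maps exactly as specified", {
  expect_equal(collapse_binary(c("GCB", "ABC", "UNC")),
               c("GCB", "non-GCB", "non-GCB"))
  expect_error(collapse_binary("weird"), class = "coodx_validation_error")
})

test_that("the unclassified fraction is non-decreasing in the threshold", {
  co <- tiny_cohort(seed = 21, n = 60, noise_genes = 0)
  model <- coo_fit(co$expression, co$annotations, seed = 1)
  probs <- predict(model, co$expression)
  uncs <- sapply(seq(0.51, 0.99, by = 0.04), function(th) {
    mean(coo_call(probs, threshold = th)$call == "UNC")
  })
  expect_true(all(diff(uncs) >= 0))
})

test_that("model JSON serialization reproduces probabilities to 1e-12", {
  co <- tiny_cohort(seed = 5, n = 30, noise_genes = 0)
  model <- coo_fit(co$expression, co$annotations, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_coo_model(model, path)
  back <- read_coo_model(path)
  set.seed(99)
  random_expr <- dplyr::bind_cols(
    tibble::tibble(gene = model$genes),
    tibble::as_tibble(matrix(rnorm(32 * 100), 32,
                             dimnames = list(NULL, sprintf("r%03d", 1:100)))))
  p1 <- predict(model, random_expr)
  p2 <- predict(back, random_expr)
  expect_lt(max(abs(p1$p_GCB - p2$p_GCB)), 1e-12)
})

test_that("tidy and glance summarize fitted models", {
  co <- tiny_cohort(seed = 6, n = 20, noise_genes = 0)
  model <- coo_fit(co$expression, co$annotations, seed = 1)
  td <- tidy(model)
  expect_equal(nrow(td), 32L)
  expect_named(td, c("gene", "mean", "sd", "weight"))
  gl <- glance(model)
  expect_equal(gl$n_genes, 32L)
  expect_equal(gl$threshold, 0.75)
  expect_gte(gl$calib_a, 0)
})
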
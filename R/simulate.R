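#' Specify a synthetic DLBCL cohort
#'
#' Parameters of the synthetic-cohort generator used for testing and
#' benchmarking the assay pipeline. The generative model is deliberately
#' simple: two-class Gaussian expression with unit variance, so that a
#' linear max-margin classifier is consistent for the planted signal.
#'
#' Defaults mirror the training cohort the assay was derived on: 167 ABC and
#' 183 GCB samples, 468 non-informative genes alongside the 32-gene panel,
#' and a one-standard-deviation effect of 2 for each panel gene in its
#' overexpressing class. Survival defaults give ABC patients twice the event
#' hazard of GCB patients (medians roughly 23 vs 46 months), the direction
#' and magnitude of outcome separation expected for R-CHOP-treated cohorts.
#'
#' @param n_abc,n_gcb Samples per subtype.
#' @param n_noise_genes Number of non-informative genes drawn i.i.d.
#'   standard normal in both classes.
#' @param effect_size Mean shift (in SD units) of each panel gene in its
#'   overexpressing class.
#' @param batch_shift Additive offset applied to every gene of samples in
#'   the second of two alternating batches; 0 disables batch structure.
#' @param replicate_sd SD (cycles) of qPCR replicate noise.
#' @param base_ct Baseline cycle threshold; cancels in dCt normalization.
#' @param hazard_abc,hazard_gcb Exponential event rates (per month).
#' @param censor_max Upper bound of the independent Uniform(0, censor_max)
#'   censoring time (months).
#' @param ihc_noise SD (percentage points) of noise on IHC marker
#'   percentages; drives crossover of Hans calls across classes.
#' @param seed Integer seed; identical specs give byte-identical cohorts.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_abc = 167, n_gcb = 183, n_noise_genes = 468,
                        effect_size = 2, batch_shift = 0,
                        replicate_sd = 0.2, base_ct = 25,
                        hazard_abc = 0.030, hazard_gcb = 0.015,
                        censor_max = 84, ihc_noise = 10, seed = 1) {
  spec <- list(
    n_abc = as.integer(n_abc), n_gcb = as.integer(n_gcb),
    n_noise_genes = as.integer(n_noise_genes),
    effect_size = effect_size, batch_shift = batch_shift,
    replicate_sd = replicate_sd, base_ct = base_ct,
    hazard_abc = hazard_abc, hazard_gcb = hazard_gcb,
    censor_max = censor_max, ihc_noise = ihc_noise,
    seed = as.integer(seed)
  )
  if (spec$n_abc < 0 || spec$n_gcb < 0 || spec$n_noise_genes < 0) {
    stop_coodx("sample and gene counts must be >= 0",
               class = "coodx_validation_error")
  }
  if (spec$n_abc + spec$n_gcb == 0) {
    stop_coodx("cohort must contain at least one sample",
               class = "coodx_validation_error")
  }
  if (spec$effect_size < 0 || spec$replicate_sd < 0) {
    stop_coodx("effect_size and replicate_sd must be >= 0",
               class = "coodx_validation_error")
  }
  if (spec$hazard_abc <= 0 || spec$hazard_gcb <= 0) {
    stop_coodx("hazards must be > 0", class = "coodx_validation_error")
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate two-class expression data with a planted gene panel
#'
#' Each panel gene is drawn Normal(`effect_size`, 1) in its overexpressing
#' class and Normal(0, 1) otherwise; noise genes are Normal(0, 1)
#' everywhere. With `batch_shift != 0`, samples alternate between two
#' batches and the second batch receives a constant additive offset on all
#' genes.
#'
#' @param spec A [cohort_spec()].
#' @param panel A [coo_panel()]; its 32 target genes are the planted signal.
#' @return A list with `expression` (gene-by-sample tibble, 32 +
#'   `n_noise_genes` rows) and `annotations` (tibble with `sample_id`,
#'   `reference_label`, `batch`).
#' @export
simulate_expression <- function(spec, panel = coo_panel()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_abc + spec$n_gcb
  labels <- c(rep("ABC", spec$n_abc), rep("GCB", spec$n_gcb))
  sample_ids <- sprintf("S%04d", seq_len(n))

  targets <- panel[panel$role == "target", ]
  noise_ids <- if (spec$n_noise_genes > 0) {
    sprintf("NOISE%04d", seq_len(spec$n_noise_genes))
  } else character()
  genes <- c(targets$gene, noise_ids)

  m <- matrix(rnorm(length(genes) * n), nrow = length(genes),
              dimnames = list(genes, sample_ids))
  for (i in seq_len(nrow(targets))) {
    up <- labels == targets$subtype[i]
    m[i, up] <- m[i, up] + spec$effect_size
  }

  batch <- rep(NA_character_, n)
  if (spec$batch_shift != 0) {
    batch <- rep(c("B1", "B2"), length.out = n)
    m[, batch == "B2"] <- m[, batch == "B2"] + spec$batch_shift
  }

  expr <- dplyr::bind_cols(tibble(gene = genes), as_tibble(m))
  list(
    expression = as_expression_matrix(expr),
    annotations = tibble(sample_id = sample_ids, reference_label = labels,
                         batch = batch)
  )
}

#' Simulate replicate-level qPCR Ct measurements
#'
#' Inverts the -dCt convention: for every sample and panel target gene,
#' three replicate Ct values are drawn as `base_ct - expression +
#' Normal(0, replicate_sd)`. Housekeeping genes have expression 0 by
#' construction, so their Ct fluctuates around `base_ct` and the dCt
#' normalization recovers the planted expression.
#'
#' @param spec A [cohort_spec()].
#' @param expr Gene-by-sample expression tibble containing all panel target
#'   genes.
#' @param panel A [coo_panel()].
#' @return A long Ct tibble with columns `sample_id`, `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_ct <- function(spec, expr, panel = coo_panel()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  targets <- panel_targets(panel)
  hk <- panel_housekeeping(panel)
  missing <- setdiff(targets, expr$gene)
  if (length(missing) > 0) {
    stop_coodx("expression matrix lacks panel gene(s): %s",
               paste(missing, collapse = ", "),
               class = "coodx_validation_error")
  }
  samples <- names(expr)[-1]
  e <- expr_values(expr)[targets, , drop = FALSE]
  # housekeeping rows at expression 0
  e <- rbind(e, matrix(0, nrow = length(hk), ncol = ncol(e),
                       dimnames = list(hk, samples)))
  grid <- tidyr::expand_grid(
    sample_id = samples, gene = rownames(e), replicate = 1:3
  )
  grid$ct <- spec$base_ct - e[cbind(grid$gene, grid$sample_id)] +
    rnorm(nrow(grid), 0, spec$replicate_sd)
  grid[order(match(grid$sample_id, samples), match(grid$gene, rownames(e)),
             grid$replicate), ]
}

#' Simulate IHC marker percentages and survival outcomes
#'
#' IHC: GCB samples draw CD10 percentages around 60% and MUM1 around 10%;
#' ABC samples draw CD10 around 10% and MUM1 around 70%; BCL6 is high in
#' both. Gaussian noise with SD `ihc_noise` (clamped to \[0, 100\]) drives
#' crossover, so at `ihc_noise = 0` the Hans tree reproduces the true
#' binary labels exactly. Survival: event times are exponential with the
#' class hazard, censored by an independent Uniform(0, `censor_max`) time.
#'
#' @param spec A [cohort_spec()].
#' @param annotations Tibble with `sample_id` and `reference_label`
#'   (`"ABC"`/`"GCB"`).
#' @return A list with `ihc` (tibble: `sample_id`, `cd10_pct`, `bcl6_pct`,
#'   `mum1_pct`) and `annotations` (input plus `survival_time` in months and
#'   logical `event`).
#' @export
simulate_ihc_survival <- function(spec, annotations) {
  stopifnot(inherits(spec, "cohort_spec"))
  assert_cols(annotations, c("sample_id", "reference_label"), "annotations")
  set.seed(spec$seed + 2L)
  n <- nrow(annotations)
  gcb <- annotations$reference_label == "GCB"

  clamp <- function(x) pmin(100, pmax(0, x))
  noise <- function() rnorm(n, 0, spec$ihc_noise)
  ihc <- tibble(
    sample_id = annotations$sample_id,
    cd10_pct = clamp(ifelse(gcb, 60, 10) + noise()),
    bcl6_pct = clamp(ifelse(gcb, 60, 50) + noise()),
    mum1_pct = clamp(ifelse(gcb, 10, 70) + noise())
  )

  hazard <- ifelse(gcb, spec$hazard_gcb, spec$hazard_abc)
  t_event <- rexp(n, rate = hazard)
  t_censor <- runif(n, 0, spec$censor_max)
  annotations$survival_time <- pmin(t_event, t_censor)
  annotations$event <- t_event <= t_censor
  list(ihc = ihc, annotations = annotations)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_expression()], [simulate_ct()]
#' and [simulate_ihc_survival()].
#'
#' @inheritParams simulate_expression
#' @return A list with `expression`, `ct`, `ihc` and `annotations`.
#' @export
simulate_cohort <- function(spec, panel = coo_panel()) {
  ex <- simulate_expression(spec, panel)
  ct <- simulate_ct(spec, ex$expression, panel)
  iv <- simulate_ihc_survival(spec, ex$annotations)
  list(expression = ex$expression, ct = ct, ihc = iv$ihc,
       annotations = iv$annotations)
}
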
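#' The 32-gene cell-of-origin panel
#'
#' Returns the gene panel used by the DLBCL cell-of-origin assay: 32 target
#' genes, 16 overexpressed in the ABC subtype and 16 in the GCB subtype,
#' plus the three housekeeping genes (IPO8, PGK1, TFRC) used for qPCR
#' normalization.
#'
#' @param target_genes Optional replacement panel: a data frame with columns
#'   `gene` and `subtype` (values `"ABC"` or `"GCB"`). Defaults to the
#'   published 32-gene panel.
#' @param housekeeping_genes Character vector of housekeeping gene symbols.
#'
#' @return An object of class `coo_panel`: a tibble with columns `gene`,
#'   `subtype` (`"ABC"`/`"GCB"` for targets, `"HK"` for housekeeping) and
#'   `role` (`"target"`/`"housekeeping"`).
#'
#' @examples
#' panel <- coo_panel()
#' dplyr::count(panel, subtype)
#' @export
coo_panel <- function(target_genes = NULL,
                      housekeeping_genes = c("IPO8", "PGK1", "TFRC")) {
  if (is.null(target_genes)) {
    target_genes <- default_panel_targets()
  }
  target_genes <- as_tibble(target_genes)
  assert_cols(target_genes, c("gene", "subtype"), "target panel")
  target_genes <- dplyr::mutate(
    target_genes,
    gene = normalize_gene(.data$gene),
    subtype = as.character(.data$subtype)
  )
  housekeeping_genes <- normalize_gene(housekeeping_genes)

  if (anyDuplicated(target_genes$gene)) {
    stop_coodx("duplicate target gene(s): %s",
               paste(unique(target_genes$gene[duplicated(target_genes$gene)]),
                     collapse = ", "),
               class = "coodx_validation_error")
  }
  if (!all(target_genes$subtype %in% c("ABC", "GCB"))) {
    stop_coodx("target subtype labels must be 'ABC' or 'GCB'",
               class = "coodx_validation_error")
  }
  n_dir <- table(factor(target_genes$subtype, levels = c("ABC", "GCB")))
  if (nrow(target_genes) != 32L || any(n_dir != 16L)) {
    stop_coodx(
      "panel must contain 32 target genes, 16 per subtype (got %d ABC, %d GCB)",
      n_dir[["ABC"]], n_dir[["GCB"]], class = "coodx_validation_error")
  }
  if (length(housekeeping_genes) != 3L || anyDuplicated(housekeeping_genes)) {
    stop_coodx("exactly 3 distinct housekeeping genes are required",
               class = "coodx_validation_error")
  }
  if (length(intersect(target_genes$gene, housekeeping_genes)) > 0) {
    stop_coodx("housekeeping genes must not overlap the target panel",
               class = "coodx_validation_error")
  }

  panel <- dplyr::bind_rows(
    dplyr::mutate(target_genes, role = "target"),
    tibble(gene = housekeeping_genes, subtype = "HK", role = "housekeeping")
  )
  class(panel) <- c("coo_panel", class(panel))
  panel
}

# Published panel: 16 ABC-overexpressed and 16 GCB-overexpressed genes.
default_panel_targets <- function() {
  tibble(
    gene = c(
      "GPR183", "IGHM", "P2RX5", "CCL22", "FCMR", "SH3BP5", "JADE3", "BATF",
      "BLNK", "DOCK10", "AICDA", "TOX2", "MIR155HG", "NLRP7", "FAM129C",
      "MPEG1",
      "BCL6", "CR2", "LMO2", "LRMP", "MME", "MYBL1", "RGS13", "TUBB2A",
      "UCHL1", "XIST", "CILP", "CD83", "STAG3", "RGCC", "VPREB3", "HOPX"
    ),
    subtype = rep(c("ABC", "GCB"), each = 16L)
  )
}

#' @export
print.coo_panel <- function(x, ...) {
  cat("<coo_panel> 32 target genes (16 ABC, 16 GCB), 3 housekeeping\n")
  NextMethod()
}

panel_targets <- function(panel) panel$gene[panel$role == "target"]
panel_housekeeping <- function(panel) panel$gene[panel$role == "housekeeping"]
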
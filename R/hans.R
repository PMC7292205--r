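#' Hans immunohistochemistry surrogate classifier
#'
#' Applies the Hans decision tree to CD10, BCL6 and MUM1 percent-positivity
#' values. A marker is positive when its percentage is at or above the
#' cutoff (default 30% of tumor cells staining). The tree: CD10+ is GCB;
#' CD10-/BCL6- is non-GCB; CD10-/BCL6+/MUM1+ is non-GCB;
#' CD10-/BCL6+/MUM1- is GCB.
#'
#' @param ihc Data frame with columns `cd10_pct`, `bcl6_pct`, `mum1_pct`
#'   (percent tumor cells staining, each in \[0, 100\]); an optional
#'   `sample_id` column is carried through.
#' @param cutoff Positivity cutoff in percent, in (0, 100); exactly at the
#'   cutoff counts as positive.
#' @return `ihc` as a tibble with marker positivity columns (`cd10_pos`,
#'   `bcl6_pos`, `mum1_pos`) and `hans_call` (`"GCB"`/`"non-GCB"`)
#'   appended.
#' @examples
#' hans_call(tibble::tibble(cd10_pct = 40, bcl6_pct = 0, mum1_pct = 0))
#' @export
hans_call <- function(ihc, cutoff = 30) {
  ihc <- as_tibble(ihc)
  assert_cols(ihc, c("cd10_pct", "bcl6_pct", "mum1_pct"), "IHC table")
  if (cutoff <= 0 || cutoff >= 100) {
    stop_coodx("positivity cutoff must lie in (0, 100)",
               class = "coodx_validation_error")
  }
  pcts <- ihc[, c("cd10_pct", "bcl6_pct", "mum1_pct")]
  if (anyNA(pcts)) {
    stop_coodx("IHC marker value(s) missing; Hans call is not evaluable",
               class = "coodx_validation_error")
  }
  if (any(pcts < 0 | pcts > 100)) {
    stop_coodx("IHC percentages must lie in [0, 100]",
               class = "coodx_validation_error")
  }
  dplyr::mutate(
    ihc,
    cd10_pos = .data$cd10_pct >= cutoff,
    bcl6_pos = .data$bcl6_pct >= cutoff,
    mum1_pos = .data$mum1_pct >= cutoff,
    hans_call = dplyr::case_when(
      cd10_pos ~ "GCB",
      !bcl6_pos ~ "non-GCB",
      mum1_pos ~ "non-GCB",
      .default = "GCB"
    )
  )
}
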
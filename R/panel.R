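#' The 17-parameter biomarker panel
#'
#' Fixed, ordered identifiers of the 17 biological parameters carried at every
#' visit: 13 routine clinical laboratory parameters (with anti-dsDNA expressed
#' as fold above the assay's upper limit of normal) followed by 4 serum
#' cytokines/chemokines (MIF and the type I interferon-inducible chemokines
#' CCL2, CCL19 and CXCL10). All visit tables, summary vectors and design
#' matrices in this package use exactly this column order.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' parameter_panel()
parameter_panel <- function() {
  c("CRP", "C3", "C4", "Hb", "WCC", "platelets", "neutrophils",
    "lymphocytes", "ESR", "dsDNA_fold_ULN", "UPCR", "urine_WCC", "urine_RBC",
    "MIF", "CCL2", "CCL19", "CXCL10")
}

#' Indices of the cytokine parameters within the panel
#'
#' @return Integer vector of length 4 (positions of MIF, CCL2, CCL19, CXCL10).
#' @export
cytokine_indices <- function() {
  match(c("MIF", "CCL2", "CCL19", "CXCL10"), parameter_panel())
}
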
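#' Run the full tumor/normal pipeline on downloaded Xena matrices
#'
#' Reproduces a published-style tumor-vs-normal pathway comparison from
#' UCSC Xena exports of harmonized TCGA (primary tumor) and GTEx (normal)
#' expression: gene-by-sample TSVs storing `log2(TPM + 0.001)`. The files
#' are multi-gigabyte and must be downloaded by the user beforehand
#' (xenabrowser.net); this function only reads local paths. Values are
#' converted back to TPM, harmonized against the KB, and compared with
#' [compare_cohorts()].
#'
#' For the pancreatic comparison (178 primary tumors vs 165 normal
#' tissues) the reference fold changes are CHST3 4.0, CHST15 3.5, VCAN 4.8
#' and DCN 1.5; for breast, CHST3 decreases 3.4-fold. Dataset-version
#' drift in Xena can move these by more than rounding.
#'
#' @param tumor_path,normal_path Local TSVs (genes in rows, samples in
#'   columns, `log2(TPM + 0.001)` values).
#' @param kb A `gag_kb`; default packaged KB.
#' @param extra_genes Non-KB genes to carry through at gene level; default
#'   the proteoglycan core proteins VCAN and DCN.
#' @return A `gag_comparison` data frame (see [compare_cohorts()]).
#' @export
reproduce_xena_comparison <- function(tumor_path, normal_path,
                                      kb = load_kb(),
                                      extra_genes = c("VCAN", "DCN")) {
  for (p in c(tumor_path, normal_path)) {
    if (!file.exists(p))
      stop("Xena matrix not found: '", p, "'. Download the log2(TPM+0.001) ",
           "expression TSVs from xenabrowser.net first; they are not ",
           "shipped with the package.")
  }
  tumor <- read_tpm_table(tumor_path, orientation = "genes_in_rows",
                          xena_log = TRUE)
  normal <- read_tpm_table(normal_path, orientation = "genes_in_rows",
                           xena_log = TRUE)
  compare_cohorts(kb, tumor, normal, missing_policy = "PERMISSIVE",
                  extra_genes = intersect(extra_genes,
                                          intersect(rownames(tumor),
                                                    rownames(normal))))
}
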
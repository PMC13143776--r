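#' Reported cross-tabulations of the 75-patient IDC cohort
#'
#' Contingency tables of clinicopathological features reported for a
#' 75-patient invasive ductal carcinoma cohort, cross-tabulated by
#' molecular subtype and by IHC-derived YAP/NELFA expression groups.
#' These printed counts are the desk-reproducible part of the clinical
#' analysis: feeding them to [chi2_contingency()] recovers the reported
#' p-values exactly (which pins down the uncorrected Pearson variant).
#'
#' @return named list of count matrices: `grade_by_subtype` (tumor grade
#'   x subtype), `yap_by_grade`, `yap_by_node`, `yap_by_subtype`,
#'   `nelfa_by_menopause`, `joint_by_subtype` (four YAP x NELFA groups
#'   x subtype)
#' @export
cohort_contingency_tables <- function() {
  path <- system.file("extdata", "cohort_contingency.csv",
                      package = "nelfayap", mustWork = TRUE)
  long <- read.csv(path)
  lapply(split(long, long$table), function(d) {
    rows <- unique(d$row); cols <- unique(d$col)
    m <- matrix(0, length(rows), length(cols),
                dimnames = list(rows, cols))
    m[cbind(match(d$row, rows), match(d$col, cols))] <- d$count
    m
  })
}

#' Reported NELF-C degron pausing quantifications
#'
#' Promoter log2(ChIP/Input) occupancy and gene-body nascent-output
#' values for seven representative YAP-target genes, quantified from the
#' public NELF-C AID-degron ChIP-seq/PRO-seq dataset (GEO accession
#' GSE144786) before (NELF-C overexpressed) and after auxin-induced
#' degradation.  Ready-made input for [call_pausing()]: every gene shows
#' baseline retention, complete promoter loss and an output increase,
#' i.e. the coordinated-loss signature.
#'
#' @return data.frame with the [call_pausing()] quantification columns
#'   plus the gene's co-regulation annotation
#' @export
nelfc_degron_quantifications <- function() {
  path <- system.file("extdata", "nelfc_degron_quant.csv",
                      package = "nelfayap", mustWork = TRUE)
  read.csv(path)
}
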
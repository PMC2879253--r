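#' Published five-gene relapse signature for pediatric T-ALL
#'
#' The reference five-gene classifier (ABTB2, IL7R, LGALS8, PLAC8, FAM13A1)
#' with its reported Random-Forest ranks, mean linear array expression per
#' outcome class, R/CCR fold changes on both measurement platforms, and the
#' array-vs-qRT-PCR log2 Pearson correlation per gene.  These values
#' parameterize the default synthetic cohorts (fold changes, requantification
#' correlation targets).
#'
#' @return data.frame with one row per signature gene.
#' @export
reference_signature <- function() {
  read.delim(system.file("extdata", "five_gene_signature.tsv",
                         package = "tallgc"),
             stringsAsFactors = FALSE)
}

#' Published multi-cohort validation panel of the relapse classifiers
#'
#' Reported integer-percent performance metrics (accuracy, PPV, NPV,
#' sensitivity, specificity) and exact-test p-values for the five-gene
#' classifier and the three pathway classifiers across the Training,
#' Validation, COG 9404 and POG 8704 cohorts, including the pooled
#' "Combined" rows.  Together with the class sizes these rows reconstruct
#' uniquely into integer confusion tables (see [confusion_from_metrics()]),
#' which is how the package's round-trip checks recompute every cell.
#'
#' @return data.frame with one row per model/cohort combination.
#' @export
reference_performance <- function() {
  read.csv(system.file("extdata", "cohort_performance.csv",
                       package = "tallgc"),
           stringsAsFactors = FALSE, check.names = FALSE)
}
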
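#' Example clinical cohort of printed deformation indexes
#'
#' Per-patient anthropometric index values for an 18-infant example cohort
#' (8 initially healthy, 10 with diagnosed deformational plagiocephaly), as
#' printed in the clinical source: cranial perimeter `CP` (mm), cephalic
#' index `CI` (%), asymmetry indexes `AI`, `AAI`, `PAI` (mm), `OCLR` (%),
#' the initial and final labels, and which values the source marked as
#' outside the normal thresholds (`flag_*`).  Useful for exercising the
#' screening rules on real printed numbers.
#'
#' @return A data.frame with 18 rows.
#' @export
clinical_cohort <- function() {
  path <- system.file("extdata", "clinical_cohort_indexes.csv",
                      package = "craniosh", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
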
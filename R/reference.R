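#' Published reference cohort and performance tables
#'
#' Plain-text copies of the reference study's printed per-participant tables
#' (demographics, clinical examination, testing results for the two collection
#' waves) and model-performance tables, shipped under
#' `inst/extdata/cohort_tables`. They serve as fixture inputs: cohort
#' aggregates can be recomputed from the per-participant rows with
#' [summarize_cohort_rows()], and the performance rows anchor the
#' identified/predicted/detected percentage invariants.
#'
#' @param name one of `"dataset1_demographics"`, `"dataset2_demographics"`,
#'   `"dataset1_exam"`, `"dataset2_exam"`, `"dataset1_testing"`,
#'   `"dataset2_testing"`, `"model_performance"`, `"modified_performance"`.
#' @return a `data.frame`.
#' @examples
#' t6 <- reference_table("dataset1_testing")
#' attr(summarize_cohort_rows(t6), "mean")[["n_fog"]]  # 32.91
#' @export
reference_table <- function(name) {
  path <- system.file("extdata", "cohort_tables", paste0(name, ".tsv"),
                      package = "fogsentry", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
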
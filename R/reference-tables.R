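#' Published sarcoma reference tables
#'
#' Small plain-text tables transcribed from a published two-group
#' high-grade soft-tissue sarcoma multi-omics analysis (expression +
#' methylation, 13 cases vs 13 controls), shipped under `inst/extdata/`:
#'
#' * `"ranking"` -- 24 mined rules with their interestingness measures,
#'   relative closeness scores and ranks before/after multi-criteria
#'   optimization (rule strings as printed, including two rows whose item
#'   sign glyph was dropped in print).
#' * `"dynamic"`, `"apriori"`, `"eclat"` -- per-rule repeated 10-fold CV
#'   classification metrics for the top 10 rules of the dynamic-threshold
#'   miner and of the two static-threshold baselines (proportions, not
#'   percentages; one obvious misprint `0942` restored to `0.942`).
#'
#' These serve as worked-example inputs for the ranking and summary
#' operations; they are reference data, not package output.
#'
#' @param table which table to load.
#' @return data.frame.
#' @export
sarcoma_reference <- function(table = c("ranking", "dynamic", "apriori", "eclat")) {
  table <- match.arg(table)
  file <- switch(table,
                 ranking = "sarcoma_rules_ranking.tsv",
                 dynamic = "sarcoma_cv_dynamic.tsv",
                 apriori = "sarcoma_cv_apriori.tsv",
                 eclat = "sarcoma_cv_eclat.tsv")
  path <- system.file("extdata", file, package = "momarules", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
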
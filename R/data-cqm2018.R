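#' Published 2018 eCQM condition value-set counts
#'
#' A transcribed reference table of per-condition counts from a
#' published comparison of downloaded (list-based) versus
#' hierarchy-rule-derived SNOMED CT value sets for conditions
#' referenced by 2018 CMS high-priority eCQMs: concepts in the
#' downloaded list, concept references in the defining rule, concepts
#' in the full derived expansion, discrepancy counts in each
#' direction, measured or to-be-estimated creation times, and compiled
#' EHR clinical-term counts for each set.
#'
#' Eleven rows cover 10 conditions: pregnancy appears twice (a narrow
#' definition matched to the downloaded list's scope, and the broad
#' clinical definition), with the broad row flagged
#' `exclude_from_summary` so summary statistics count pregnancy once.
#' Clinical-term counts are `NA` for prostate cancer (not published).
#' `ext_minutes_measured` is non-`NA` only for the three conditions
#' whose extensional build was actually timed; the rest are estimated
#' from the linear time model.
#'
#' Feeding this table to [condition_metrics()] +
#' [summarize_comparison()] reproduces the published summary
#' statistics (e.g. median 21.5 vs 3 concepts to define, median
#' completeness ratio 3.3, median 35% of derived concepts present in
#' the downloaded lists).
#'
#' @return A tibble with the columns described above, ready for
#'   [condition_metrics()].
#' @examples
#' counts <- cqm2018_conditions()
#' summarize_comparison(condition_metrics(counts))
#' @export
cqm2018_conditions <- function() {
  path <- system.file("extdata", "cqm2018_conditions.tsv",
                      package = "phenovset", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    condition_name = readr::col_character(),
                    exclude_from_summary = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}
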
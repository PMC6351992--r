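as_id_set <- function(x) {
  if (inherits(x, "extensional_valueset")) x$concept_ids
  else unique(as.character(x))
}

#' Concept discrepancies between two enumerated value sets
#'
#' Counts concepts present in one set and not the other: the number only
#' in the downloaded list, the number only in the rule-derived list, and
#' their total (the size of the symmetric difference). A total of zero
#' means the two sets are identical.
#'
#' @param downloaded,derived [extensional_valueset()] objects or
#'   character vectors of concept ids.
#' @return A one-row tibble: `only_in_downloaded`, `only_in_derived`,
#'   `total`.
#' @export
diff_concepts <- function(downloaded, derived) {
  d <- as_id_set(downloaded)
  r <- as_id_set(derived)
  only_d <- length(setdiff(d, r))
  only_r <- length(setdiff(r, d))
  tibble(only_in_downloaded = only_d, only_in_derived = only_r,
         total = only_d + only_r)
}

#' Conciseness ratios: concepts needed to define a value set
#'
#' How many times more concepts an enumerated list needs than the
#' rule that defines the same phenotype:
#' `ratio_download = n_downloaded / n_intensional` and
#' `ratio_derived = n_derived / n_intensional`, each reported to 1
#' decimal (half away from zero). Vectorised over conditions.
#'
#' @param n_downloaded Concepts in the downloaded extensional list.
#' @param n_intensional Concept references in the defining rule (>= 1).
#' @param n_derived Concepts in the rule-derived extensional list.
#' @return A tibble: `ratio_download`, `ratio_derived`.
#' @examples
#' define_ratios(26, 2, 48)  # 13 and 24
#' @export
define_ratios <- function(n_downloaded, n_intensional, n_derived) {
  if (any(n_intensional < 1)) {
    abort("n_intensional must be >= 1 (a rule references at least one concept)",
          class = "phenovset_undefined_ratio")
  }
  tibble(
    ratio_download = round_half_up(n_downloaded / n_intensional, 1),
    ratio_derived = round_half_up(n_derived / n_intensional, 1)
  )
}

#' Concept-level completeness of a downloaded list
#'
#' `completeness_ratio` is the number of concepts in the rule-derived
#' set over the number in the downloaded set (1 decimal);
#' `percent_included` is the share of derived-set concepts present in
#' the downloaded set, as an integer percent. Inputs may be value sets,
#' id vectors, or bare counts.
#'
#' @param downloaded,derived [extensional_valueset()] objects, id
#'   vectors, or single non-negative counts.
#' @return A one-row tibble: `n_downloaded`, `n_derived`,
#'   `completeness_ratio`, `percent_included`.
#' @examples
#' completeness(12, 233)  # ratio 19.4, percent 5
#' @export
completeness <- function(downloaded, derived) {
  n_d <- if (is.numeric(downloaded)) as.numeric(downloaded) else length(as_id_set(downloaded))
  n_r <- if (is.numeric(derived)) as.numeric(derived) else length(as_id_set(derived))
  if (any(n_d < 1)) {
    abort("downloaded set is empty: completeness undefined",
          class = "phenovset_undefined_ratio")
  }
  if (any(n_r < 1)) {
    abort("derived set is empty: percent included undefined",
          class = "phenovset_undefined_ratio")
  }
  tibble(
    n_downloaded = n_d, n_derived = n_r,
    completeness_ratio = round_half_up(n_r / n_d, 1),
    percent_included = round_half_up(100 * n_d / n_r)
  )
}

#' Summarise one metric across conditions
#'
#' The per-table summary block: median (for an even number of
#' conditions, the mean of the two central order statistics), minimum,
#' maximum, range, and an "overall" cell that is either the plain sum
#' (count columns) or a ratio of sums (ratio/percent columns, computed
#' from unrounded numerator and denominator sums, times `scale`).
#'
#' The median across conditions — not the mean — is the primary central
#' tendency, so a single huge condition cannot dominate the summary.
#'
#' @param values Per-condition values (unrounded where applicable).
#' @param metric_name Label for the output row.
#' @param overall `"sum"` or `"ratio_of_sums"`.
#' @param numerators,denominators Required when
#'   `overall = "ratio_of_sums"`: per-condition numerator and
#'   denominator counts, summed before dividing.
#' @param scale Multiplier for the ratio-of-sums cell (100 for percent
#'   columns). Default 1.
#' @return A one-row tibble: `metric_name`, `overall`, `median`,
#'   `minimum`, `maximum`, `range`. Values are unrounded; apply
#'   display rounding downstream.
#' @examples
#' summarize_metric(c(5, 12, 8, 35, 99, 72, 26, 89, 12, 17),
#'                  "concepts to define (downloaded)")
#' @export
summarize_metric <- function(values, metric_name = "metric",
                             overall = c("sum", "ratio_of_sums"),
                             numerators = NULL, denominators = NULL,
                             scale = 1) {
  overall <- match.arg(overall)
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("no non-missing values to summarise", class = "phenovset_validation_error")
  }
  overall_value <- if (overall == "sum") {
    sum(values)
  } else {
    if (is.null(numerators) || is.null(denominators) ||
        length(numerators) != length(denominators)) {
      abort("ratio_of_sums needs numerators and denominators of equal length",
            class = "phenovset_validation_error")
    }
    ok <- !is.na(numerators) & !is.na(denominators)
    scale * sum(numerators[ok]) / sum(denominators[ok])
  }
  tibble(
    metric_name = metric_name,
    overall = overall_value,
    median = median(values),
    minimum = min(values),
    maximum = max(values),
    range = max(values) - min(values)
  )
}

#' Compare one condition's downloaded list against its hierarchy rule
#'
#' Runs the full per-condition pipeline: expand the rule over the
#' hierarchy, count concept discrepancies, compute conciseness and
#' completeness, compile the clinical terms reachable from each set and
#' compute term-level coverage. This is one row of the comparison
#' report.
#'
#' @param downloaded An [extensional_valueset()] (the list-based set).
#' @param rule An [intensional_valueset()] defining the same condition.
#' @param graph A [concept_graph()].
#' @param map Optional `term_map`; when `NULL` the term columns are
#'   `NA`.
#' @param condition_name Row label; defaults to the rule's
#'   `condition_label` or `name`.
#' @param exclude_from_summary Flag carried into the report: rows
#'   tagged `TRUE` are shown but left out of summary statistics (used
#'   for alternate definitions of a condition already counted once).
#' @return A one-row tibble of class `condition_comparison`.
#' @export
compare_condition <- function(downloaded, rule, graph, map = NULL,
                              condition_name = NULL,
                              exclude_from_summary = FALSE) {
  stopifnot(inherits(downloaded, "extensional_valueset"),
            inherits(rule, "intensional_valueset"))
  condition_name <- condition_name %||% rule$condition_label %||%
    rule$name %||% downloaded$name %||% "condition"
  derived <- expand_valueset(rule, graph)
  n_downloaded <- n_defining_concepts(downloaded)
  n_intensional <- n_defining_concepts(rule)
  n_derived <- n_defining_concepts(derived)
  ratios <- define_ratios(n_downloaded, n_intensional, n_derived)
  comp <- completeness(downloaded, derived)
  disc <- diff_concepts(downloaded, derived)
  if (!is.null(map)) {
    terms_d <- compile_terms(downloaded, map)
    terms_i <- compile_terms(derived, map)
    tc <- term_coverage(terms_d, terms_i)
  } else {
    tc <- tibble(n_terms_downloaded = NA_integer_,
                 n_terms_intensional = NA_integer_,
                 term_ratio = NA_real_, term_percent = NA_real_)
  }
  out <- tibble(
    condition_name = condition_name,
    n_downloaded = n_downloaded,
    n_intensional = n_intensional,
    n_derived = n_derived,
    ratio_to_define_download = ratios$ratio_download,
    ratio_to_define_derived = ratios$ratio_derived,
    completeness_ratio = comp$completeness_ratio,
    percent_concepts_included = comp$percent_included,
    disc_only_in_downloaded = disc$only_in_downloaded,
    disc_only_in_derived = disc$only_in_derived,
    disc_total = disc$total,
    n_terms_downloaded = tc$n_terms_downloaded,
    n_terms_intensional = tc$n_terms_intensional,
    term_ratio = tc$term_ratio,
    term_percent = tc$term_percent,
    exclude_from_summary = isTRUE(exclude_from_summary)
  )
  class(out) <- c("condition_comparison", class(out))
  out
}
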
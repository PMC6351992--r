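# which summary "overall" cell each metric gets, and how to recompute
# the unrounded per-condition value from the count columns
metric_spec <- function() {
  tibble::tribble(
    ~metric_name,                ~overall,        ~num,                  ~den,             ~scale, ~digits,
    "n_downloaded",              "sum",           NA,                    NA,               1,      0,
    "n_intensional",             "sum",           NA,                    NA,               1,      0,
    "ratio_to_define_download",  "ratio_of_sums", "n_downloaded",        "n_intensional",  1,      1,
    "n_derived",                 "sum",           NA,                    NA,               1,      0,
    "ratio_to_define_derived",   "ratio_of_sums", "n_derived",           "n_intensional",  1,      1,
    "ext_minutes",               "sum",           NA,                    NA,               1,      1,
    "int_minutes",               "sum",           NA,                    NA,               1,      0,
    "diff_minutes",              "sum",           NA,                    NA,               1,      1,
    "time_ratio",                "ratio_of_sums", "ext_minutes",         "int_minutes",    1,      1,
    "completeness_ratio",        "ratio_of_sums", "n_derived",           "n_downloaded",   1,      1,
    "percent_concepts_included", "ratio_of_sums", "n_downloaded",        "n_derived",      100,    0,
    "disc_total",                "sum",           NA,                    NA,               1,      0,
    "disc_only_in_downloaded",   "sum",           NA,                    NA,               1,      0,
    "disc_only_in_derived",      "sum",           NA,                    NA,               1,      0,
    "n_terms_downloaded",        "sum",           NA,                    NA,               1,      0,
    "n_terms_intensional",       "sum",           NA,                    NA,               1,      0,
    "term_ratio",                "ratio_of_sums", "n_terms_intensional", "n_terms_downloaded", 1,  1,
    "term_percent",              "ratio_of_sums", "n_terms_downloaded",  "n_terms_intensional", 100, 0
  )
}

#' Per-condition comparison metrics from a count table
#'
#' The tabular entry point to the comparison machinery: given one row
#' per condition of raw counts (set sizes, discrepancy counts, term
#' counts, creation times), computes every derived column of the
#' comparison report — conciseness ratios, completeness ratio and
#' percent, discrepancy total, term coverage, and creation times.
#'
#' Extensional creation time is the measured stopwatch time where one
#' is supplied (`ext_minutes_measured`) and otherwise estimated from
#' the linear time model at the derived-set size. The unrounded
#' estimate is kept (column `ext_minutes`) alongside the whole-minute
#' display value, because downstream medians and time ratios computed
#' from pre-rounded minutes drift visibly.
#'
#' @param counts A data frame with columns `condition_name`,
#'   `n_downloaded`, `n_intensional`, `n_derived`,
#'   `disc_only_in_downloaded`, `disc_only_in_derived`; optionally
#'   `ext_minutes_measured` (NA where not measured), `int_minutes`,
#'   `n_terms_downloaded`, `n_terms_intensional`,
#'   `exclude_from_summary`.
#' @param model A [time_model()] used for unmeasured extensional times
#'   (default [default_time_model()]).
#' @return A tibble of class `condition_comparison`, one row per
#'   condition, with rounded ratio/percent columns and both unrounded
#'   (`ext_minutes`, `diff_minutes`) and rounded
#'   (`ext_minutes_rounded`, `diff_minutes_rounded`) time columns.
#' @seealso [summarize_comparison()], [compare_condition()]
#' @export
condition_metrics <- function(counts, model = default_time_model()) {
  counts <- as_tibble(counts)
  req <- c("condition_name", "n_downloaded", "n_intensional", "n_derived",
           "disc_only_in_downloaded", "disc_only_in_derived")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols)) {
    abort(sprintf("count table: missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "phenovset_format_error")
  }
  opt_default <- list(ext_minutes_measured = NA_real_, int_minutes = NA_real_,
                      n_terms_downloaded = NA_real_, n_terms_intensional = NA_real_,
                      exclude_from_summary = FALSE)
  for (nm in names(opt_default)) {
    if (!nm %in% names(counts)) counts[[nm]] <- opt_default[[nm]]
  }
  ratios <- define_ratios(counts$n_downloaded, counts$n_intensional,
                          counts$n_derived)
  est <- predict_time(model, counts$n_derived)
  ext_minutes <- ifelse(is.na(counts$ext_minutes_measured),
                        est$minutes, counts$ext_minutes_measured)
  out <- mutate(
    counts,
    ratio_to_define_download = ratios$ratio_download,
    ratio_to_define_derived = ratios$ratio_derived,
    completeness_ratio = round_half_up(.data$n_derived / .data$n_downloaded, 1),
    percent_concepts_included = round_half_up(100 * .data$n_downloaded / .data$n_derived),
    disc_total = .data$disc_only_in_downloaded + .data$disc_only_in_derived,
    ext_minutes = ext_minutes,
    ext_minutes_rounded = round_half_up(ext_minutes),
    ext_time_measured = !is.na(.data$ext_minutes_measured),
    diff_minutes = ext_minutes - .data$int_minutes,
    diff_minutes_rounded = round_half_up(ext_minutes - .data$int_minutes),
    time_ratio = round_half_up(ext_minutes / .data$int_minutes, 1),
    term_ratio = round_half_up(.data$n_terms_intensional / .data$n_terms_downloaded, 1),
    term_percent = round_half_up(100 * .data$n_terms_downloaded / .data$n_terms_intensional)
  )
  class(out) <- c("condition_comparison", class(tibble()))
  out
}

#' Summary rows across conditions
#'
#' Builds the summary block of the comparison tables: for every metric,
#' the overall cell (sum for counts, ratio of unrounded sums for
#' ratio/percent columns), plus median, minimum, maximum and range of
#' the per-condition values. Conditions flagged `exclude_from_summary`
#' are left out (they are alternate definitions of a condition already
#' counted), and metrics missing for some conditions (e.g. term counts)
#' are summarised over the conditions that have them.
#'
#' Ratio and percent metrics are summarised from unrounded
#' per-condition values recomputed from the count columns, then the
#' summary itself can be display-rounded; summarising the pre-rounded
#' display values instead is subtly wrong (a median of rounded ratios
#' need not equal the rounded median).
#'
#' @param metrics Output of [condition_metrics()] (or
#'   [compare_condition()] rows plus time columns).
#' @return A tibble with columns `metric_name`, `overall`, `median`,
#'   `minimum`, `maximum`, `range`, `n_conditions`, `overall_kind`
#'   (`"sum"` or `"ratio_of_sums"`), and `digits` (the display precision
#'   conventionally used for that metric).
#' @export
summarize_comparison <- function(metrics) {
  metrics <- as_tibble(metrics)
  if ("exclude_from_summary" %in% names(metrics)) {
    metrics <- filter(metrics, !.data$exclude_from_summary)
  }
  spec <- metric_spec()
  spec <- spec[spec$metric_name %in% names(metrics) |
                 spec$overall == "ratio_of_sums", ]
  rows <- pmap(spec, function(metric_name, overall, num, den, scale, digits) {
    values <- if (overall == "ratio_of_sums") {
      if (!all(c(num, den) %in% names(metrics))) return(NULL)
      scale * metrics[[num]] / metrics[[den]]
    } else {
      metrics[[metric_name]]
    }
    if (is.null(values) || all(is.na(values))) return(NULL)
    out <- summarize_metric(
      values, metric_name = metric_name, overall = overall,
      numerators = if (overall == "ratio_of_sums") metrics[[num]],
      denominators = if (overall == "ratio_of_sums") metrics[[den]],
      scale = scale
    )
    out$n_conditions <- sum(!is.na(values))
    out$overall_kind <- overall
    out$digits <- digits
    out
  })
  list_rbind(rows[!vapply(rows, is.null, logical(1))])
}

#' Round a summary table to its display precision
#'
#' Applies each metric's conventional display precision (integer for
#' counts and percents, 1 decimal for ratios) to the unrounded summary
#' produced by [summarize_comparison()].
#'
#' @param summary_tbl Output of [summarize_comparison()].
#' @return The same tibble with `overall`, `median`, `minimum`,
#'   `maximum`, `range` rounded half away from zero at each row's
#'   `digits`.
#' @export
round_summary <- function(summary_tbl) {
  mutate(summary_tbl,
         across(c("overall", "minimum", "maximum", "range"),
                ~ round_half_up(.x, .data$digits)),
         # an even condition count makes medians of count/time columns end
         # in .5, so those medians keep at least one decimal; ratio and
         # percent medians stay at their column precision
         median = round_half_up(.data$median,
                                ifelse(.data$overall_kind == "sum",
                                       pmax(.data$digits, 1), .data$digits)))
}

#' Write the comparison report
#'
#' Writes the per-condition rows and the summary block as CSV and/or a
#' Markdown document. Footnotes flag conditions excluded from the
#' summary statistics, and note that the overall cell of ratio columns
#' is a ratio of sums (which can differ from other published overall
#' conventions).
#'
#' @param metrics Output of [condition_metrics()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"`, `"markdown"`, or `"both"` (default).
#' @param prefix File-name prefix, default `"report"`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(metrics, dir, format = c("both", "csv", "markdown"),
                         prefix = "report") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_tbl <- round_summary(summarize_comparison(metrics))
  files <- character()
  if (format %in% c("both", "csv")) {
    f1 <- file.path(dir, paste0(prefix, "_conditions.csv"))
    f2 <- file.path(dir, paste0(prefix, "_summary.csv"))
    readr::write_csv(as_tibble(metrics), f1, progress = FALSE)
    readr::write_csv(summary_tbl, f2, progress = FALSE)
    files <- c(files, f1, f2)
  }
  if (format %in% c("both", "markdown")) {
    f3 <- file.path(dir, paste0(prefix, ".md"))
    excluded <- if ("exclude_from_summary" %in% names(metrics)) {
      metrics$condition_name[metrics$exclude_from_summary]
    } else character()
    lines <- c(
      "# Value-set comparison report", "",
      "## Per-condition metrics", "",
      md_table(as_tibble(metrics)), "",
      "## Summary across conditions", "",
      md_table(summary_tbl), "",
      "Notes:", "",
      "- Overall cells of ratio/percent metrics are ratios of unrounded sums;",
      "  medians are computed from unrounded per-condition values.",
      if (length(excluded)) {
        sprintf("- Excluded from summary statistics: %s.",
                paste(excluded, collapse = ", "))
      }
    )
    writeLines(lines[!is.na(lines)], f3)
    files <- c(files, f3)
  }
  invisible(files)
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
    else ifelse(is.na(x), "", as.character(x))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Plot per-condition completeness
#'
#' Bar chart of the share of rule-derived content present in the
#' downloaded list, per condition, for concepts and (when available)
#' clinical terms — the at-a-glance view of how stale the enumerated
#' lists are.
#'
#' @param object A `condition_comparison` tibble
#'   (from [condition_metrics()] or [compare_condition()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.condition_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    select("condition_name", concepts = "percent_concepts_included",
           dplyr::any_of(c(terms = "term_percent"))) |>
    tidyr::pivot_longer(-"condition_name", names_to = "level",
                        values_to = "percent") |>
    filter(!is.na(.data$percent))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$condition_name, .data$percent),
    y = .data$percent, fill = .data$level
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Included in downloaded list (%)",
                  fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
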
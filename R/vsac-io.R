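#' Read a value-set export CSV
#'
#' Reads an enumerated value set from the export dialect used by
#' value-set repositories (VSAC-style "export value set results"): a
#' CSV with a header row and at least a code column; description, code
#' system, code system version, OID and value-set name columns are
#' used when present. Header names are matched case-insensitively and
#' ignoring spaces/underscores, since the public export layout has
#' varied across vintages.
#'
#' @param path Path to the CSV file.
#' @return An [extensional_valueset()] with provenance `"downloaded"`;
#'   OID and name are taken from the first data row when present.
#'   Duplicate codes are collapsed with a warning; a file with zero
#'   data rows yields an empty set with a warning.
#' @export
read_vsac_export <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  canon <- gsub("[ _]", "", tolower(names(df)))
  find_col <- function(...) {
    idx <- which(canon %in% c(...))
    if (length(idx)) df[[idx[1]]] else NULL
  }
  codes <- find_col("code", "conceptid", "sctid")
  if (is.null(codes)) {
    abort(sprintf("%s: no code column found", basename(path)),
          class = "phenovset_format_error")
  }
  if (length(codes) == 0) {
    warn(sprintf("%s: no data rows; returning an empty value set", basename(path)))
  }
  if (anyDuplicated(codes)) {
    warn(sprintf("%s: %d duplicate code row(s) collapsed",
                 basename(path), sum(duplicated(codes))))
  }
  first_value <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x[1]) || !nzchar(x[1])) NULL
    else x[1]
  }
  extensional_valueset(
    unique(codes), provenance = "downloaded",
    name = first_value(find_col("valuesetname", "name")),
    oid = first_value(find_col("oid", "valuesetoid")),
    code_system_version = first_value(find_col("codesystemversion"))
  )
}

#' Write a value-set export CSV
#'
#' Inverse of [read_vsac_export()]: one row per concept in
#' deterministic lexicographic code order, RFC 4180 quoting, columns
#' `code`, `description`, `code_system`, `code_system_version`, `oid`,
#' `value_set_name`. An empty set produces a header-only file.
#'
#' @param evs An [extensional_valueset()].
#' @param path Output path.
#' @param labels Optional named character vector (or `concept_graph`)
#'   supplying descriptions per code.
#' @return `path`, invisibly.
#' @export
write_vsac_export <- function(evs, path, labels = NULL) {
  stopifnot(inherits(evs, "extensional_valueset"))
  if (is_concept_graph(labels)) {
    labels <- setNames(labels$nodes$label, labels$nodes$concept_id)
  }
  codes <- sort(evs$concept_ids)
  desc <- if (is.null(labels)) codes else {
    ifelse(codes %in% names(labels), unname(labels[codes]), codes)
  }
  out <- tibble(
    code = codes,
    description = desc,
    code_system = rep("SNOMEDCT", length(codes)),
    code_system_version = rep(evs$code_system_version %||% "", length(codes)),
    oid = rep(evs$oid %||% "", length(codes)),
    value_set_name = rep(evs$name %||% "", length(codes))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the full comparison pipeline from a configuration file
#'
#' Drives the whole analysis for a set of conditions described in a
#' JSON configuration: load the hierarchy and term map, parse each
#' condition's rule, expand it, read the downloaded list, compute the
#' per-condition comparison row, attach creation times (measured from
#' the timing table where available, otherwise estimated from the time
#' model), and write the per-condition and summary report.
#'
#' Configuration fields (paths are resolved relative to the config
#' file):
#' \describe{
#'   \item{graph}{`{"edge_table": path}` or `{"rf2_concepts": path,
#'     "rf2_relationships": path}`.}
#'   \item{term_map}{Optional term-map TSV path.}
#'   \item{timing}{Optional timing-observations TSV path (see
#'     [read_timing_observations()]); measured rows are matched to
#'     conditions by `label` = condition name.}
#'   \item{time_model}{Either `{"slope": s, "intercept": b}` or
#'     `{"fit_from_timing": true}` to fit from the timing table;
#'     default is the package's built-in model.}
#'   \item{conditions}{Array of `{name, label, expression |
#'     rule_file, downloaded_csv, exclude_from_summary}`.}
#' }
#'
#' @param config_file Path to the JSON configuration.
#' @param out_dir Report output directory; default `"report"` next to
#'   the config file.
#' @param format Report format, `"both"`, `"csv"` or `"markdown"`.
#' @return Invisibly, a list with `metrics` (per-condition tibble),
#'   `summary` (summary tibble, display-rounded) and `files` (report
#'   paths written).
#' @export
run_pipeline <- function(config_file, out_dir = NULL,
                         format = c("both", "csv", "markdown")) {
  format <- match.arg(format)
  cfg <- jsonlite::read_json(config_file, simplifyVector = FALSE)
  base <- dirname(normalizePath(config_file))
  rel <- function(p) if (is.null(p)) NULL else {
    if (file.exists(p)) p else file.path(base, p)
  }
  out_dir <- out_dir %||% file.path(base, "report")

  graph <- if (!is.null(cfg$graph$edge_table)) {
    read_edge_table(rel(cfg$graph$edge_table))
  } else if (!is.null(cfg$graph$rf2_concepts)) {
    read_rf2_snapshot(rel(cfg$graph$rf2_concepts), rel(cfg$graph$rf2_relationships))
  } else {
    abort("config: `graph` needs either edge_table or rf2_concepts/rf2_relationships",
          class = "phenovset_format_error")
  }
  map <- if (!is.null(cfg$term_map)) read_term_map(rel(cfg$term_map))
  timing <- if (!is.null(cfg$timing)) read_timing_observations(rel(cfg$timing))
  model <- if (!is.null(cfg$time_model$slope)) {
    time_model(cfg$time_model$slope, cfg$time_model$intercept)
  } else if (isTRUE(cfg$time_model$fit_from_timing)) {
    if (is.null(timing)) {
      abort("config: fit_from_timing requires a `timing` table",
            class = "phenovset_format_error")
    }
    fit_time_model(filter(timing, .data$measured))
  } else {
    default_time_model()
  }

  if (length(cfg$conditions) == 0) {
    abort("config: no conditions listed", class = "phenovset_format_error")
  }
  rows <- lapply(cfg$conditions, function(cond) {
    label <- cond$label %||% cond$name %||% "condition"
    tryCatch({
      rule <- if (!is.null(cond$expression)) {
        parse_ecl(cond$expression, name = cond$name, condition_label = label)
      } else if (!is.null(cond$rule_file)) {
        read_rule_file(rel(cond$rule_file), name = cond$name,
                       condition_label = label)
      } else {
        abort("condition needs `expression` or `rule_file`",
              class = "phenovset_format_error")
      }
      downloaded <- read_vsac_export(rel(cond$downloaded_csv))
      inform(sprintf("condition '%s': rule %s, downloaded %d concepts",
                     label, format_ecl(rule),
                     length(downloaded$concept_ids)))
      compare_condition(downloaded, rule, graph, map,
                        condition_name = label,
                        exclude_from_summary = isTRUE(cond$exclude_from_summary))
    }, error = function(e) {
      abort(sprintf("condition '%s': %s", label, conditionMessage(e)),
            class = "phenovset_pipeline_error", parent = e)
    })
  }) |> list_rbind()

  # attach creation times: measured where the timing table has the
  # condition, otherwise estimated from the model at the relevant size
  est_int <- predict_time(model, rows$n_intensional)$minutes
  est_ext <- predict_time(model, rows$n_derived)$minutes
  meas <- if (!is.null(timing)) filter(timing, .data$measured) else NULL
  cond_names <- map_chr(cfg$conditions, function(cond) {
    cond$name %||% cond$label %||% "condition"
  })
  lookup <- function(labels) {
    if (is.null(meas)) return(rep(NA_real_, length(labels)))
    meas$minutes[match(labels, meas$label)]
  }
  # timing rows are matched by the condition's name or display label; a
  # bare label is an intensional build time, "<label> [extensional]" a
  # measured extensional build
  m_int <- dplyr::coalesce(lookup(cond_names), lookup(rows$condition_name),
                           lookup(paste0(cond_names, " [intensional]")))
  m_ext <- dplyr::coalesce(lookup(paste0(cond_names, " [extensional]")),
                           lookup(paste0(rows$condition_name, " [extensional]")))
  rows <- mutate(
    rows,
    int_minutes = ifelse(is.na(m_int), est_int, m_int),
    ext_minutes_measured = m_ext,
    ext_minutes = ifelse(is.na(m_ext), est_ext, m_ext),
    ext_minutes_rounded = round_half_up(.data$ext_minutes),
    ext_time_measured = !is.na(m_ext),
    diff_minutes = .data$ext_minutes - .data$int_minutes,
    diff_minutes_rounded = round_half_up(.data$diff_minutes),
    time_ratio = round_half_up(.data$ext_minutes / .data$int_minutes, 1)
  )
  class(rows) <- c("condition_comparison", class(tibble()))
  files <- write_report(rows, out_dir, format = format)
  invisible(list(
    metrics = rows,
    summary = round_summary(summarize_comparison(rows)),
    files = files
  ))
}

#' Read a rule file
#'
#' Either a plain-text ECL-lite file (one rule; `#` comment lines) or a
#' structured TSV with columns `name`, `condition_label`, `expression`
#' (first row used unless `which` selects another).
#'
#' @param path File path.
#' @param name,condition_label Overrides for the plain-text form.
#' @param which Row to take from a structured file (default 1).
#' @return An [intensional_valueset()].
#' @export
read_rule_file <- function(path, name = NULL, condition_label = NULL, which = 1L) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) {
    df <- read_tsv_strict(path, c("name", "condition_label", "expression"))
    if (which > nrow(df)) {
      abort(sprintf("%s: rule %d requested but file has %d",
                    basename(path), which, nrow(df)),
            class = "phenovset_lookup_error")
    }
    parse_ecl(df$expression[which],
              name = name %||% df$name[which],
              condition_label = condition_label %||% df$condition_label[which])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      abort(sprintf("%s: no rule expression found", basename(path)),
            class = "phenovset_parse_error")
    }
    parse_ecl(paste(lines, collapse = " "), name = name,
              condition_label = condition_label)
  }
}
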
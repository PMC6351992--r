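#' Read an RF2 snapshot concept hierarchy
#'
#' Loads the active is-a hierarchy from a pair of RF2 snapshot tables
#' (`sct2_Concept` and `sct2_Relationship` style, tab-separated with a
#' header row). Only rows with `active = 1` are kept, and only
#' relationship rows whose `typeId` is the is-a relationship type
#' (`116680003`) become edges, oriented `sourceId` (subtype, child) to
#' `destinationId` (supertype, parent). Counts of dropped inactive rows
#' are reported as a message.
#'
#' Only the snapshot dialect is supported; `effectiveTime` is ignored
#' beyond the `active` flag, since a value-set analysis pins a single
#' release.
#'
#' @param concept_path Path to the concept table. Required columns:
#'   `id`, `active`. A `term`/`label` column, if present, supplies labels.
#' @param relationship_path Path to the relationship table. Required
#'   columns: `sourceId`, `destinationId`, `typeId`, `active`.
#' @param isa_type_id The relationship `typeId` treated as is-a
#'   (default `"116680003"`).
#' @return A [concept_graph()].
#' @export
read_rf2_snapshot <- function(concept_path, relationship_path,
                              isa_type_id = "116680003") {
  concepts <- read_tsv_strict(concept_path, c("id", "active"))
  rels <- read_tsv_strict(relationship_path,
                          c("sourceId", "destinationId", "typeId", "active"))
  label_col <- intersect(c("term", "label"), names(concepts))[1]
  nodes <- tibble(
    concept_id = as.character(concepts$id),
    label = if (!is.na(label_col)) as.character(concepts[[label_col]])
            else as.character(concepts$id),
    active = as.integer(concepts$active) == 1L
  )
  isa <- filter(rels, as.character(.data$typeId) == isa_type_id)
  edges <- tibble(
    child_id = as.character(isa$sourceId),
    parent_id = as.character(isa$destinationId),
    active = as.integer(isa$active) == 1L
  )
  concept_graph(nodes, edges)
}

# readr-based TSV reader that insists on named columns
read_tsv_strict <- function(path, required) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(path), paste(missing_cols, collapse = ", ")),
          class = "phenovset_format_error")
  }
  df
}

#' Read a child/parent edge table
#'
#' A lightweight alternative to RF2 for fixtures and synthetic
#' hierarchies: a tab-separated table `child_id<TAB>parent_id[<TAB>label]`,
#' all rows treated as active. The optional third column labels the child
#' concept. The header row is auto-detected (the first field matching a
#' known header name such as `child_id`, `child` or `sourceId`); pass
#' `header` explicitly to override.
#'
#' @param path Path to the TSV file.
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @return A [concept_graph()]. Concepts are the union of child and
#'   parent ids; a self-loop row is an error.
#' @export
read_edge_table <- function(path, header = "auto") {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    abort(sprintf("%s: empty edge table", basename(path)),
          class = "phenovset_format_error")
  }
  if (identical(header, "auto")) {
    header <- tolower(raw[[1]][1]) %in%
      c("child_id", "child", "sourceid", "source_id", "subtype")
  }
  if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
  if (ncol(raw) < 2) {
    abort(sprintf("%s: edge table needs at least 2 columns", basename(path)),
          class = "phenovset_format_error")
  }
  edges <- tibble(child_id = raw[[1]], parent_id = raw[[2]])
  if (any(edges$child_id == edges$parent_id)) {
    abort("edge table contains a self-loop row (child = parent)",
          class = "phenovset_validation_error")
  }
  labels <- if (ncol(raw) >= 3) setNames(raw[[3]], raw[[1]]) else character()
  ids <- unique(c(edges$child_id, edges$parent_id))
  nodes <- tibble(
    concept_id = ids,
    label = ifelse(ids %in% names(labels) & !is.na(labels[ids]),
                   unname(labels[ids]), ids)
  )
  concept_graph(nodes, edges)
}

#' Write a concept graph as an edge table
#'
#' Inverse of [read_edge_table()]: writes `child_id`, `parent_id` and the
#' child's `label`, with a header row, in deterministic (sorted) order.
#' Isolated concepts (no parent and no child) cannot be represented in an
#' edge table and trigger a warning.
#'
#' @param graph A [concept_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  stopifnot(is_concept_graph(graph))
  isolated <- setdiff(graph$nodes$concept_id,
                      c(graph$edges$child_id, graph$edges$parent_id))
  if (length(isolated)) {
    warn(sprintf("%d isolated concept(s) not representable in an edge table",
                 length(isolated)))
  }
  out <- graph$edges |>
    left_join(rename(graph$nodes, child_id = "concept_id"), by = "child_id") |>
    arrange(.data$child_id, .data$parent_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
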
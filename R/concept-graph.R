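#' Build a concept polyhierarchy
#'
#' A `concept_graph` holds the active is-a ("supertype-subtype") portion of
#' a clinical concept hierarchy: a node table and a directed child-to-parent
#' edge table. SNOMED CT is the motivating terminology, so concept ids are
#' kept as opaque strings throughout (SCTIDs run past 15 digits and would be
#' mangled by doubles), but any acyclic child/parent table works.
#'
#' @param nodes A data frame with columns `concept_id` and optionally
#'   `label` and `active`. Inactive nodes are dropped.
#' @param edges A data frame with columns `child_id` and `parent_id`;
#'   optionally `active` (inactive edges are dropped).
#' @return An object of class `concept_graph` with elements `nodes`
#'   (tibble: `concept_id`, `label`), `edges` (tibble: `child_id`,
#'   `parent_id`) and `graph` (the underlying [igraph::igraph] object,
#'   edges directed child -> parent).
#' @details Validation is strict: duplicate concept ids, edges whose
#'   endpoints are missing from the node table, self-loops, and cycles are
#'   all errors. A cyclic "hierarchy" would make every descendant query
#'   meaningless, so cycles are never silently broken; the error message
#'   names the members of one offending cycle.
#' @seealso [read_rf2_snapshot()], [read_edge_table()], [descendants()]
#' @examples
#' g <- concept_graph(
#'   nodes = data.frame(concept_id = c("A", "B", "C", "D")),
#'   edges = data.frame(child_id = c("B", "C", "D", "D"),
#'                      parent_id = c("A", "A", "B", "C"))
#' )
#' descendants(g, "A")
#' @export
concept_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!"concept_id" %in% names(nodes)) {
    abort("`nodes` must have a `concept_id` column", class = "phenovset_format_error")
  }
  if (!all(c("child_id", "parent_id") %in% names(edges))) {
    abort("`edges` must have `child_id` and `parent_id` columns",
          class = "phenovset_format_error")
  }
  nodes$concept_id <- as.character(nodes$concept_id)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$concept_id
  all_ids <- nodes$concept_id
  n_inactive_nodes <- 0L
  if ("active" %in% names(nodes)) {
    keep <- as.logical(nodes$active)
    n_inactive_nodes <- sum(!keep)
    nodes <- nodes[keep, , drop = FALSE]
  }
  nodes <- select(nodes, "concept_id", "label")
  check_concept_ids(nodes$concept_id)
  if (anyDuplicated(nodes$concept_id)) {
    dup <- unique(nodes$concept_id[duplicated(nodes$concept_id)])
    abort(sprintf("duplicate concept ids: %s",
                  paste(head(dup, 10), collapse = ", ")),
          class = "phenovset_validation_error")
  }

  edges$child_id <- as.character(edges$child_id)
  edges$parent_id <- as.character(edges$parent_id)
  n_inactive_edges <- 0L
  if ("active" %in% names(edges)) {
    keep <- as.logical(edges$active)
    n_inactive_edges <- sum(!keep)
    edges <- edges[keep, , drop = FALSE]
  }
  edges <- select(edges, "child_id", "parent_id")
  # endpoints never seen in the concept table are a hard error;
  # edges touching inactive (dropped) concepts go with them
  unknown <- unique(c(setdiff(edges$child_id, all_ids),
                      setdiff(edges$parent_id, all_ids)))
  if (length(unknown)) {
    abort(sprintf("edge endpoints absent from concept table: %s",
                  paste(head(unknown, 10), collapse = ", ")),
          class = "phenovset_validation_error")
  }
  live <- edges$child_id %in% nodes$concept_id &
    edges$parent_id %in% nodes$concept_id
  n_inactive_edges <- n_inactive_edges + sum(!live)
  edges <- edges[live, , drop = FALSE]
  if (any(edges$child_id == edges$parent_id)) {
    abort("self-loop edges (child = parent) are not allowed",
          class = "phenovset_validation_error")
  }
  edges <- distinct(edges)

  g <- igraph::graph_from_data_frame(
    d = edges, directed = TRUE,
    vertices = rename(nodes, name = "concept_id")
  )
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(edges)
    abort(sprintf("is-a hierarchy contains a cycle: %s",
                  paste(cyc, collapse = " -> ")),
          class = "phenovset_cycle_error")
  }
  if (n_inactive_nodes + n_inactive_edges > 0) {
    inform(sprintf("dropped %d inactive concept(s) and %d inactive/orphaned edge(s)",
                   n_inactive_nodes, n_inactive_edges))
  }
  structure(
    list(nodes = nodes, edges = edges, graph = g),
    class = "concept_graph"
  )
}

# DFS for one concrete cycle, reported in the cycle error message
find_one_cycle <- function(edges) {
  adj <- split(edges$parent_id, edges$child_id)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    s <- state[[v]] %||% 0L
    if (s == 1L) {
      found <<- c(path[which(path == v)[1]:length(path)], v)
      return()
    }
    if (s == 2L) return()
    state[[v]] <- 1L
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) visit(w)
    path <<- path[-length(path)]
    state[[v]] <- 2L
  }
  for (v in unique(edges$child_id)) visit(v)
  found %||% character()
}

#' @export
print.concept_graph <- function(x, ...) {
  roots <- setdiff(x$nodes$concept_id, x$edges$child_id)
  cat(sprintf("<concept_graph: %d concepts, %d is-a edges, %d root(s)>\n",
              nrow(x$nodes), nrow(x$edges), length(roots)))
  invisible(x)
}

#' @export
format.concept_graph <- function(x, ...) {
  sprintf("<concept_graph: %d concepts, %d edges>", nrow(x$nodes), nrow(x$edges))
}

is_concept_graph <- function(x) inherits(x, "concept_graph")

assert_in_graph <- function(graph, ids, what = "concept id") {
  missing_ids <- setdiff(ids, graph$nodes$concept_id)
  if (length(missing_ids)) {
    abort(sprintf("unknown %s: %s", what,
                  paste(head(missing_ids, 10), collapse = ", ")),
          class = "phenovset_lookup_error")
  }
  invisible(TRUE)
}

#' Transitive descendant and ancestor queries
#'
#' `descendants()` returns every concept from which `root_id` is reachable
#' along child-to-parent is-a edges, i.e. the full subtype tree under a
#' concept; this closure is what turns a one-line hierarchy rule such as
#' "osteoporosis and all its descendants" into an enumerated value set.
#' `ancestors()` returns the supertypes of a concept (self excluded),
#' mainly for audit diagnostics.
#'
#' A concept on several paths (the hierarchy is a DAG, not a tree) is
#' returned once.
#'
#' @param graph A [concept_graph()].
#' @param root_id,concept_id A single concept id present in the graph.
#' @param include_self Should the root itself be part of the result
#'   (descendant-or-self, the ECL `<<` reading)? Default `TRUE`.
#' @return A sorted character vector of concept ids.
#' @examples
#' g <- concept_graph(
#'   nodes = data.frame(concept_id = c("A", "B", "C", "D")),
#'   edges = data.frame(child_id = c("B", "C", "D", "D"),
#'                      parent_id = c("A", "A", "B", "C"))
#' )
#' descendants(g, "A")                       # A B C D
#' descendants(g, "A", include_self = FALSE) # B C D
#' ancestors(g, "D")                         # A B C
#' @export
descendants <- function(graph, root_id, include_self = TRUE) {
  stopifnot(is_concept_graph(graph), length(root_id) == 1)
  root_id <- as.character(root_id)
  assert_in_graph(graph, root_id, "root concept id")
  res <- igraph::subcomponent(graph$graph, root_id, mode = "in")$name
  if (!include_self) res <- setdiff(res, root_id)
  sort(res)
}

#' @rdname descendants
#' @export
ancestors <- function(graph, concept_id) {
  stopifnot(is_concept_graph(graph), length(concept_id) == 1)
  concept_id <- as.character(concept_id)
  assert_in_graph(graph, concept_id)
  sort(setdiff(igraph::subcomponent(graph$graph, concept_id, mode = "out")$name,
               concept_id))
}
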
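ECL_SCOPES <- c("self_and_descendants", "descendants_only", "self_only")
SCOPE_PREFIX <- c(self_and_descendants = "<<", descendants_only = "<", self_only = "")

#' Construct an intensional (rule-based) value set
#'
#' An intensional value set defines a clinical phenotype by reference to
#' concept hierarchies rather than by enumerating codes: an ordered list
#' of include/exclude clauses, each naming one concept and a hierarchy
#' scope (`self_and_descendants`, `descendants_only`, or `self_only`).
#' Excludes are applied after all includes as a pure set difference
#' (Boolean AND NOT). Usually created via [parse_ecl()].
#'
#' @param clauses A data frame with columns `polarity` (`"include"` or
#'   `"exclude"`), `concept_id`, and `scope` (one of
#'   `self_and_descendants`, `descendants_only`, `self_only`).
#' @param name Optional value-set name.
#' @param condition_label Optional clinical condition label.
#' @return An object of class `intensional_valueset`.
#' @seealso [parse_ecl()], [format_ecl()], [expand_valueset()]
#' @export
intensional_valueset <- function(clauses, name = NULL, condition_label = NULL) {
  clauses <- as_tibble(clauses)
  req <- c("polarity", "concept_id", "scope")
  if (!all(req %in% names(clauses))) {
    abort("`clauses` needs columns polarity, concept_id, scope",
          class = "phenovset_format_error")
  }
  clauses <- select(clauses, dplyr::all_of(req))
  clauses$concept_id <- as.character(clauses$concept_id)
  if (nrow(clauses) == 0) {
    abort("a value-set rule needs at least one clause",
          class = "phenovset_validation_error")
  }
  if (!all(clauses$polarity %in% c("include", "exclude"))) {
    abort("clause polarity must be 'include' or 'exclude'",
          class = "phenovset_validation_error")
  }
  if (!all(clauses$scope %in% ECL_SCOPES)) {
    abort(sprintf("clause scope must be one of: %s",
                  paste(ECL_SCOPES, collapse = ", ")),
          class = "phenovset_validation_error")
  }
  if (!any(clauses$polarity == "include")) {
    abort("a value-set rule needs at least one include clause",
          class = "phenovset_validation_error")
  }
  check_concept_ids(clauses$concept_id)
  structure(
    list(name = name, condition_label = condition_label, clauses = clauses),
    class = "intensional_valueset"
  )
}

#' @export
print.intensional_valueset <- function(x, ...) {
  cat(sprintf("<intensional_valueset%s: %d clause(s)>\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$clauses)))
  cat(" ", format_ecl(x), "\n")
  invisible(x)
}

#' Construct an extensional (enumerated) value set
#'
#' An extensional value set is a flat list of concept ids with
#' provenance: `"downloaded"` for lists obtained from a value-set
#' repository (VSAC-style), `"derived"` for lists produced by expanding
#' an intensional rule over a hierarchy, `"synthetic"` for simulated
#' lists. Ids are deduplicated and stored sorted.
#'
#' @param concept_ids Character vector of concept ids.
#' @param name,oid,code_system_version Optional metadata.
#' @param provenance One of `"downloaded"`, `"derived"`, `"synthetic"`.
#' @return An object of class `extensional_valueset`.
#' @export
extensional_valueset <- function(concept_ids,
                                 provenance = c("downloaded", "derived", "synthetic"),
                                 name = NULL, oid = NULL,
                                 code_system_version = NULL) {
  provenance <- match.arg(provenance)
  concept_ids <- as.character(concept_ids)
  if (length(concept_ids)) check_concept_ids(concept_ids)
  structure(
    list(name = name, oid = oid, code_system_version = code_system_version,
         provenance = provenance,
         concept_ids = sort(unique(concept_ids))),
    class = "extensional_valueset"
  )
}

#' @export
print.extensional_valueset <- function(x, ...) {
  cat(sprintf("<extensional_valueset%s: %d concept(s), provenance '%s'>\n",
              if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
              length(x$concept_ids), x$provenance))
  invisible(x)
}

#' Parse a hierarchy rule expression
#'
#' Parses the small Expression Constraint Language subset used for
#' hierarchy-based value sets: `<<ID` means a concept and all its
#' descendants (descendant-or-self), `<ID` descendants only, a bare `ID`
#' the concept alone. Include terms are joined with `OR`; exclusions are
#' appended with `MINUS` (the Boolean "AND NOT"); every term after the
#' first `MINUS` is an exclusion. Parentheses, refinements and attribute
#' constraints are not supported.
#'
#' @param text A single rule expression, e.g.
#'   `"<<33449004 MINUS <<36217008"` ("personality disorder and
#'   descendants, excluding organic personality disorder and
#'   descendants").
#' @param name,condition_label Optional metadata passed through to
#'   [intensional_valueset()].
#' @return An [intensional_valueset()] whose clause order preserves the
#'   source order.
#' @examples
#' parse_ecl("<<64859006")   # a concept and all its subtypes
#' parse_ecl("<<33449004 MINUS <<36217008")
#' @export
parse_ecl <- function(text, name = NULL, condition_label = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    abort("empty rule expression", class = "phenovset_parse_error")
  }
  polarity <- "include"
  expect_term <- TRUE
  rows <- vector("list", length(tokens))
  k <- 0L
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (tok %in% c("OR", "MINUS")) {
      if (expect_term) {
        abort(sprintf("parse error at token %d ('%s'): operator where a concept reference was expected",
                      i, tok),
              class = "phenovset_parse_error")
      }
      if (tok == "MINUS") polarity <- "exclude"
      expect_term <- TRUE
      next
    }
    if (!expect_term) {
      abort(sprintf("parse error at token %d ('%s'): missing OR/MINUS operator",
                    i, tok),
            class = "phenovset_parse_error")
    }
    m <- regmatches(tok, regexec("^(<<|<)?([^<>\\s]+)$", tok))[[1]]
    if (length(m) == 0 || grepl("[<>()]", m[3])) {
      abort(sprintf("parse error at token %d: unrecognised token '%s'", i, tok),
            class = "phenovset_parse_error")
    }
    scope <- switch(m[2], "<<" = "self_and_descendants", "<" = "descendants_only",
                    "self_only")
    k <- k + 1L
    rows[[k]] <- tibble(polarity = polarity, concept_id = m[3], scope = scope)
    expect_term <- FALSE
  }
  if (expect_term) {
    abort("parse error: expression ends with a dangling operator",
          class = "phenovset_parse_error")
  }
  clauses <- list_rbind(rows[seq_len(k)])
  if (clauses$polarity[1] == "exclude") {
    abort("parse error at token 1: MINUS with no preceding include clause",
          class = "phenovset_parse_error")
  }
  intensional_valueset(clauses, name = name, condition_label = condition_label)
}

#' Serialize a rule back to its expression form
#'
#' Inverse of [parse_ecl()]: includes (in clause order) joined with
#' `OR`, each exclude appended with `MINUS`. `parse_ecl(format_ecl(x))`
#' reproduces `x`'s clause table exactly.
#'
#' @param ivs An [intensional_valueset()].
#' @return A single string.
#' @export
format_ecl <- function(ivs) {
  stopifnot(inherits(ivs, "intensional_valueset"))
  cl <- ivs$clauses
  term <- paste0(SCOPE_PREFIX[cl$scope], cl$concept_id)
  inc <- term[cl$polarity == "include"]
  exc <- term[cl$polarity == "exclude"]
  out <- paste(inc, collapse = " OR ")
  if (length(exc)) out <- paste(out, paste("MINUS", exc, collapse = " "))
  out
}

#' Expand a value set to its enumerated form
#'
#' Expansion turns a rule-based value set into the exactly-equivalent
#' enumerated list on a given hierarchy: the union of each include
#' clause's hierarchy closure minus the union of each exclude clause's
#' closure. This is the step a terminology server performs when
#' deriving a full extensional value set from an intensional rule.
#'
#' Expanding an already-extensional set is the identity (its list *is*
#' its meaning — a downloaded list carries no descendant semantics).
#'
#' @param x An [intensional_valueset()] or [extensional_valueset()].
#' @param graph A [concept_graph()]. Every clause concept must exist in
#'   it.
#' @param ... Unused.
#' @return An [extensional_valueset()] with provenance `"derived"` (or
#'   `x` itself when `x` is already extensional).
#' @examples
#' g <- concept_graph(
#'   nodes = data.frame(concept_id = c("A", "B", "C", "D")),
#'   edges = data.frame(child_id = c("B", "C", "D", "D"),
#'                      parent_id = c("A", "A", "B", "C"))
#' )
#' expand_valueset(parse_ecl("<<A MINUS <<C"), g)$concept_ids  # "A" "B"
#' @export
expand_valueset <- function(x, graph, ...) UseMethod("expand_valueset")

#' @export
expand_valueset.intensional_valueset <- function(x, graph, ...) {
  stopifnot(is_concept_graph(graph))
  cl <- x$clauses
  bad <- setdiff(unique(cl$concept_id), graph$nodes$concept_id)
  if (length(bad)) {
    abort(sprintf("rule%s references concept(s) missing from the hierarchy: %s",
                  if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
                  paste(head(bad, 10), collapse = ", ")),
          class = "phenovset_lookup_error")
  }
  closure <- function(id, scope) {
    switch(scope,
      self_and_descendants = descendants(graph, id, include_self = TRUE),
      descendants_only = descendants(graph, id, include_self = FALSE),
      self_only = id
    )
  }
  inc <- cl[cl$polarity == "include", ]
  exc <- cl[cl$polarity == "exclude", ]
  included <- unique(unlist(map2(inc$concept_id, inc$scope, closure)))
  excluded <- unique(unlist(map2(exc$concept_id, exc$scope, closure)))
  extensional_valueset(setdiff(included, excluded %||% character()),
                       provenance = "derived",
                       name = x$name)
}

#' @export
expand_valueset.extensional_valueset <- function(x, graph, ...) x

#' Number of concepts needed to define a value set
#'
#' The conciseness measure: for an intensional rule, the number of
#' concept references in the defining rule (duplicates counted as
#' written); for an extensional list, the number of enumerated concepts.
#'
#' @param x An [intensional_valueset()] or [extensional_valueset()].
#' @return A single integer.
#' @export
n_defining_concepts <- function(x) UseMethod("n_defining_concepts")

#' @export
n_defining_concepts.intensional_valueset <- function(x) nrow(x$clauses)

#' @export
n_defining_concepts.extensional_valueset <- function(x) length(x$concept_ids)
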
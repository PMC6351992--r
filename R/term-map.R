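#' Read a clinical-term-to-concept mapping
#'
#' EHRs let clinicians record diagnoses using a clinician-friendly
#' interface terminology whose terms are premapped, many-to-one, onto
#' standard hierarchy concepts. A term map is that mapping: each term id
#' maps to exactly one concept id, while a concept typically collects
#' many terms. The file format is a UTF-8 TSV with a header row and
#' columns `term_id`, `term_text`, `concept_id`.
#'
#' The one-concept-per-term constraint is enforced at load (a duplicate
#' `term_id` is an error) because compiled-term counts presume the
#' mapping is a function, not a relation.
#'
#' @param path Path to the TSV file.
#' @return A tibble of class `term_map` with columns `term_id`,
#'   `term_text`, `concept_id`.
#' @seealso [compile_terms()], [term_coverage()]
#' @export
read_term_map <- function(path) {
  df <- read_tsv_strict(path, c("term_id", "term_text", "concept_id"))
  term_map(df)
}

#' @rdname read_term_map
#' @param records A data frame with columns `term_id`, `term_text`,
#'   `concept_id` (for `term_map()`, the in-memory constructor).
#' @export
term_map <- function(records) {
  records <- as_tibble(records)
  req <- c("term_id", "term_text", "concept_id")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    abort(sprintf("term map: missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "phenovset_format_error")
  }
  records <- select(records, dplyr::all_of(req))
  records <- mutate(records, across(dplyr::everything(), as.character))
  if (nrow(records) > 0) {
    check_concept_ids(records$concept_id)
    check_concept_ids(records$term_id, "term_id")
    if (anyDuplicated(records$term_id)) {
      dup <- unique(records$term_id[duplicated(records$term_id)])
      abort(sprintf("duplicate term_id (a term must map to exactly one concept): %s",
                    paste(head(dup, 10), collapse = ", ")),
            class = "phenovset_validation_error")
    }
  }
  class(records) <- c("term_map", class(tibble()))
  records
}

#' Write a term map
#'
#' @param map A `term_map` (see [read_term_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(map, path) {
  stopifnot(inherits(map, "term_map"))
  readr::write_tsv(arrange(as_tibble(map), .data$term_id), path, progress = FALSE)
  invisible(path)
}

#' Compile the clinical terms covered by a concept set
#'
#' Emulates the EHR's compiled list: the terms a clinician could select
#' that would place a patient inside the phenotype defined by
#' `concept_ids`. Concepts absent from the map simply contribute no
#' terms; the result is monotone in `concept_ids`.
#'
#' @param concept_ids Character vector of concept ids, or an
#'   [extensional_valueset()].
#' @param map A `term_map`.
#' @return Sorted character vector of term ids.
#' @export
compile_terms <- function(concept_ids, map) {
  stopifnot(inherits(map, "term_map"))
  if (inherits(concept_ids, "extensional_valueset")) {
    concept_ids <- concept_ids$concept_ids
  }
  sort(unique(map$term_id[map$concept_id %in% as.character(concept_ids)]))
}

#' Term-level completeness of a downloaded list
#'
#' Compares the clinical terms compiled from a downloaded (list-based)
#' value set against those compiled from the corresponding rule-derived
#' set: the ratio of term counts (intensional over downloaded, 1
#' decimal) and the percentage of intensional-set terms covered by the
#' downloaded set (integer percent). Both roundings are half away from
#' zero.
#'
#' @param downloaded_terms,intensional_terms Character vectors of term
#'   ids (each must be non-empty).
#' @return A one-row tibble: `n_terms_downloaded`, `n_terms_intensional`,
#'   `term_ratio`, `term_percent`.
#' @examples
#' term_coverage(paste0("t", 1:485), paste0("t", 1:586))
#' @export
term_coverage <- function(downloaded_terms, intensional_terms) {
  n_d <- length(unique(downloaded_terms))
  n_i <- length(unique(intensional_terms))
  if (n_d == 0) {
    abort("downloaded term set is empty: term ratio undefined",
          class = "phenovset_undefined_ratio")
  }
  if (n_i == 0) {
    abort("intensional term set is empty: term percent undefined",
          class = "phenovset_undefined_ratio")
  }
  tibble(
    n_terms_downloaded = n_d,
    n_terms_intensional = n_i,
    term_ratio = round_half_up(n_i / n_d, 1),
    term_percent = round_half_up(100 * n_d / n_i)
  )
}
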
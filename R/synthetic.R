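#' Configuration for the synthetic terminology generator
#'
#' The generator produces SNOMED-like structures with the statistical
#' features the comparison pipeline assumes: a single-rooted,
#' multi-parent is-a DAG; a many-terms-to-one-concept clinical term
#' map; hierarchy rules of the shape seen in practice (one subtree
#' include, sometimes one child-subtree exclude); and "stale" downloaded
#' lists formed by dropping a fraction of the true descendants.
#'
#' Defaults mirror the scale of the published 10-condition comparison:
#' a few hundred concepts per study hierarchy, derived sets of tens to
#' hundreds of concepts, a mean of about 12 terms per concept, and a
#' degradation fraction of 0.65 (so a downloaded list retains ~35% of
#' the concepts in the corresponding full derived set, the median
#' retention observed for 2018 downloaded value sets).
#'
#' @param n_concepts Number of concepts in the hierarchy (>= 2).
#' @param extra_parent_probability Probability that a non-root concept
#'   receives a second parent (polyhierarchy density), in `[0, 1]`.
#' @param max_depth Maximum hierarchy depth.
#' @param terms_per_concept Mean of the shifted-Poisson terms-per-concept
#'   distribution (every concept gets at least one term; mean must be
#'   >= 1; a mean of exactly 1 gives one term per concept).
#' @param degradation_fraction Probability that a non-clause-root concept
#'   of the derived set is missing from the simulated downloaded list,
#'   in `[0, 1)`.
#' @param n_conditions Number of condition rules in a fixture bundle.
#' @param seed Integer seed; every generator output is a pure function
#'   of (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_concepts = 300,
                             extra_parent_probability = 0.15,
                             max_depth = 8,
                             terms_per_concept = 12,
                             degradation_fraction = 0.65,
                             n_conditions = 10,
                             seed = 1L) {
  stopifnot(n_concepts >= 2,
            extra_parent_probability >= 0, extra_parent_probability <= 1,
            max_depth >= 1,
            terms_per_concept >= 1,
            degradation_fraction >= 0, degradation_fraction < 1,
            n_conditions >= 1)
  structure(
    list(n_concepts = as.integer(n_concepts),
         extra_parent_probability = extra_parent_probability,
         max_depth = as.integer(max_depth),
         terms_per_concept = terms_per_concept,
         degradation_fraction = degradation_fraction,
         n_conditions = as.integer(n_conditions),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# SCTID-flavoured opaque digit ids: a fixed prefix keeps them
# recognisably synthetic, the index keeps them unique
synthetic_id <- function(i) sprintf("900%06d", i)

#' Generate a synthetic concept polyhierarchy
#'
#' Builds a single-rooted acyclic is-a graph: concepts are added in
#' sequence, each attached to one uniformly sampled existing parent
#' with depth below `max_depth`; with probability
#' `extra_parent_probability` a concept also receives a second parent,
#' sampled among existing concepts at a depth no greater than the first
#' parent's. Because every edge points from a newer concept to an older
#' one, acyclicity holds by construction.
#'
#' @param config A [synthetic_config()].
#' @return A [concept_graph()]; deterministic for a given config.
#' @export
generate_ontology <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_concepts
    ids <- synthetic_id(seq_len(n))
    depth <- integer(n)
    child <- character(0)
    parent <- character(0)
    for (i in seq_len(n)[-1]) {
      eligible <- which(depth[seq_len(i - 1)] < config$max_depth)
      p1 <- eligible[sample.int(length(eligible), 1)]
      depth[i] <- depth[p1] + 1L
      child <- c(child, ids[i])
      parent <- c(parent, ids[p1])
      if (runif(1) < config$extra_parent_probability) {
        # second parents only among shallower-or-equal, already-created
        # concepts: keeps the graph acyclic without rejection sampling
        cand <- setdiff(which(depth[seq_len(i - 1)] <= depth[p1]), p1)
        if (length(cand)) {
          p2 <- cand[sample.int(length(cand), 1)]
          child <- c(child, ids[i])
          parent <- c(parent, ids[p2])
        }
      }
    }
    concept_graph(
      nodes = tibble(concept_id = ids,
                     label = paste0("Synthetic concept ", ids)),
      edges = tibble(child_id = child, parent_id = parent)
    )
  })
}

#' Generate a synthetic clinical term map
#'
#' Every concept receives at least one clinician-selectable term; the
#' number of terms per concept is 1 + Poisson(mean - 1), emulating the
#' heavily many-to-one mapping of an EHR interface terminology onto its
#' reference hierarchy.
#'
#' @param graph A [concept_graph()].
#' @param config A [synthetic_config()] (uses `terms_per_concept` and
#'   `seed`).
#' @return A `term_map` tibble; deterministic for a given (graph,
#'   config).
#' @export
generate_term_map <- function(graph, config) {
  stopifnot(is_concept_graph(graph), inherits(config, "synthetic_config"))
  if (nrow(graph$nodes) == 0) {
    abort("cannot generate terms for an empty graph",
          class = "phenovset_validation_error")
  }
  with_seed(config$seed + 1L, {
    counts <- 1L + rpois(nrow(graph$nodes), config$terms_per_concept - 1)
    concept_id <- rep(graph$nodes$concept_id, counts)
    term_map(tibble(
      term_id = sprintf("T%07d", seq_along(concept_id)),
      term_text = paste0("Synthetic term ", seq_along(concept_id),
                         " for ", concept_id),
      concept_id = concept_id
    ))
  })
}

#' Sample a condition-defining hierarchy rule
#'
#' Emulates the shape of real phenotype rules: one include clause at an
#' internal concept with at least `min_descendants` descendants
#' (descendant-or-self scope), and with probability 1/2 an exclude
#' clause at one of its children (also descendant-or-self), i.e.
#' "condition X and subtypes, but not subtype Y".
#'
#' @param graph A [concept_graph()].
#' @param config A [synthetic_config()].
#' @param index Condition index (varies the seed so a bundle's
#'   conditions differ); default 1.
#' @param min_descendants Minimum strict-descendant count for the
#'   include root (default 5).
#' @return An [intensional_valueset()].
#' @export
sample_condition <- function(graph, config, index = 1L, min_descendants = 5L) {
  stopifnot(is_concept_graph(graph), inherits(config, "synthetic_config"))
  n_desc <- vapply(graph$nodes$concept_id,
                   function(id) length(descendants(graph, id, include_self = FALSE)),
                   integer(1))
  eligible <- graph$nodes$concept_id[n_desc >= min_descendants]
  if (length(eligible) == 0) {
    abort(sprintf("no concept has >= %d descendants", min_descendants),
          class = "phenovset_validation_error")
  }
  with_seed(config$seed + 100L + as.integer(index), {
    root <- eligible[sample.int(length(eligible), 1)]
    clauses <- tibble(polarity = "include", concept_id = root,
                      scope = "self_and_descendants")
    if (runif(1) < 0.5) {
      children <- graph$edges$child_id[graph$edges$parent_id == root]
      if (length(children)) {
        excl <- children[sample.int(length(children), 1)]
        clauses <- bind_rows(clauses,
                             tibble(polarity = "exclude", concept_id = excl,
                                    scope = "self_and_descendants"))
      }
    }
    intensional_valueset(clauses,
                         name = sprintf("synthetic_condition_%02d", index),
                         condition_label = sprintf("Synthetic condition %02d", index))
  })
}

#' Simulate a stale downloaded value set
#'
#' Degrades a full derived extensional set into the kind of incomplete
#' enumerated list seen in downloaded value-set exports: each concept
#' is independently dropped with probability `fraction`, except the
#' rule's clause-root concepts, which are always retained (inspected
#' downloaded sets invariably contain the condition's root concept).
#'
#' @param derived An [extensional_valueset()] (typically provenance
#'   `"derived"`).
#' @param fraction Drop probability in `[0, 1)`.
#' @param clause_roots Concept ids always retained; must all be members
#'   of `derived`.
#' @param seed Integer seed.
#' @return An [extensional_valueset()] with provenance `"synthetic"`.
#' @export
degrade_to_extensional <- function(derived, fraction, clause_roots, seed) {
  stopifnot(inherits(derived, "extensional_valueset"),
            fraction >= 0, fraction < 1)
  clause_roots <- as.character(clause_roots)
  missing_roots <- setdiff(clause_roots, derived$concept_ids)
  if (length(missing_roots)) {
    abort(sprintf("clause root(s) not in the derived set: %s",
                  paste(head(missing_roots, 10), collapse = ", ")),
          class = "phenovset_validation_error")
  }
  with_seed(seed, {
    drop <- runif(length(derived$concept_ids)) < fraction &
      !(derived$concept_ids %in% clause_roots)
    extensional_valueset(derived$concept_ids[!drop],
                         provenance = "synthetic",
                         name = derived$name,
                         oid = derived$oid)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a hierarchy, term map, `n_conditions` rules, degraded
#' downloaded lists (VSAC-dialect CSV), timing observations and a
#' pipeline configuration, and writes them all to `out_dir` in the
#' formats the package's loaders consume. The returned manifest also
#' carries the generator's ground truth (derived sizes, retained
#' fractions) so end-to-end tests can check that the pipeline recovers
#' it.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `files` (named paths), `config`, `truth` (a
#'   tibble: condition, expression, n_derived, n_downloaded), and
#'   `config_file` (path of the pipeline JSON config).
#' @export
make_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  graph <- generate_ontology(config)
  map <- generate_term_map(graph, config)

  files <- c(edges = file.path(out_dir, "edges.tsv"),
             term_map = file.path(out_dir, "term_map.tsv"),
             rules = file.path(out_dir, "rules.tsv"),
             timing = file.path(out_dir, "timing.tsv"))
  write_edge_table(graph, files[["edges"]])
  write_term_map(map, files[["term_map"]])

  truth <- vector("list", config$n_conditions)
  rule_rows <- vector("list", config$n_conditions)
  timing_rows <- vector("list", config$n_conditions)
  for (i in seq_len(config$n_conditions)) {
    rule <- sample_condition(graph, config, index = i)
    derived <- expand_valueset(rule, graph)
    roots <- rule$clauses$concept_id[rule$clauses$polarity == "include"]
    downloaded <- degrade_to_extensional(
      derived, config$degradation_fraction,
      clause_roots = intersect(roots, derived$concept_ids),
      seed = config$seed + 200L + i
    )
    csv <- file.path(out_dir, sprintf("downloaded_%02d.csv", i))
    write_vsac_export(
      extensional_valueset(downloaded$concept_ids, provenance = "downloaded",
                           name = rule$condition_label,
                           oid = sprintf("2.999.%d.%d", config$seed, i)),
      csv
    )
    files[[sprintf("downloaded_%02d", i)]] <- csv
    rule_rows[[i]] <- tibble(name = rule$name,
                             condition_label = rule$condition_label,
                             expression = format_ecl(rule))
    # stopwatch-style intensional build time from the reference cost
    # line plus small noise; keeps bundles realistic and re-fittable
    tm <- default_time_model()
    timing_rows[[i]] <- with_seed(config$seed + 300L + i, tibble(
      label = rule$name,
      n_concepts = n_defining_concepts(rule),
      minutes = round(pmax(0.5, tm$slope * n_defining_concepts(rule) +
                             tm$intercept + stats::rnorm(1, 0, 0.5)), 2),
      measured = 1L
    ))
    truth[[i]] <- tibble(
      condition = rule$condition_label,
      name = rule$name,
      expression = format_ecl(rule),
      n_derived = length(derived$concept_ids),
      n_downloaded = length(downloaded$concept_ids)
    )
  }
  readr::write_tsv(list_rbind(rule_rows), files[["rules"]], progress = FALSE)
  readr::write_tsv(list_rbind(timing_rows), files[["timing"]], progress = FALSE)

  truth <- list_rbind(truth)
  config_file <- file.path(out_dir, "pipeline_config.json")
  pipeline_cfg <- list(
    seed = config$seed,
    graph = list(edge_table = basename(files[["edges"]])),
    term_map = basename(files[["term_map"]]),
    timing = basename(files[["timing"]]),
    time_model = list(slope = 0.4177, intercept = 3.8707),
    conditions = lapply(seq_len(config$n_conditions), function(i) {
      list(name = truth$name[i],
           label = truth$condition[i],
           expression = truth$expression[i],
           downloaded_csv = basename(files[[sprintf("downloaded_%02d", i)]]),
           exclude_from_summary = FALSE)
    })
  )
  jsonlite::write_json(pipeline_cfg, config_file, auto_unbox = TRUE, pretty = TRUE)
  files[["pipeline_config"]] <- config_file
  list(files = files, config = config, truth = truth,
       config_file = config_file)
}
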
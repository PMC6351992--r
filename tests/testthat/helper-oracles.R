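# Independent oracles, deliberately written without touching the package's
# implementation paths (no igraph): plain fixpoint iteration over an edge
# data frame, set algebra on top of it, and closed-form least squares.

# all concepts from which `root` is reachable along child -> parent edges
oracle_descendants <- function(edges, root, include_self = TRUE) {
  res <- root
  repeat {
    more <- edges$child_id[edges$parent_id %in% res & !edges$child_id %in% res]
    if (length(more) == 0) break
    res <- c(res, unique(more))
  }
  if (!include_self) res <- setdiff(res, root)
  sort(res)
}

oracle_ancestors <- function(edges, id) {
  res <- id
  repeat {
    more <- edges$parent_id[edges$child_id %in% res & !edges$parent_id %in% res]
    if (length(more) == 0) break
    res <- c(res, unique(more))
  }
  sort(setdiff(res, id))
}

# expansion by brute-force reachability plus set algebra
oracle_expand <- function(clauses, edges) {
  closure <- function(id, scope) {
    switch(scope,
      self_and_descendants = oracle_descendants(edges, id, TRUE),
      descendants_only = oracle_descendants(edges, id, FALSE),
      self_only = id
    )
  }
  inc <- clauses[clauses$polarity == "include", ]
  exc <- clauses[clauses$polarity == "exclude", ]
  included <- unique(unlist(Map(closure, inc$concept_id, inc$scope)))
  excluded <- unique(unlist(Map(closure, exc$concept_id, exc$scope)))
  sort(setdiff(included, excluded))
}

# closed-form simple-regression normal equations
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

diamond_graph <- function() {
  concept_graph(
    nodes = data.frame(concept_id = c("A", "B", "C", "D")),
    edges = data.frame(child_id = c("B", "C", "D", "D"),
                       parent_id = c("A", "A", "B", "C"))
  )
}

# a mid-sized synthetic hierarchy shared across tests
test_graph <- function(n = 200, seed = 42, p2 = 0.3) {
  generate_ontology(synthetic_config(n_concepts = n,
                                     extra_parent_probability = p2,
                                     seed = seed))
}
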
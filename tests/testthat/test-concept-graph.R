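write_rf2_pair <- function(concepts, rels, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cp <- file.path(dir, "concepts.tsv")
  rp <- file.path(dir, "relationships.tsv")
  readr::write_tsv(concepts, cp, progress = FALSE)
  readr::write_tsv(rels, rp, progress = FALSE)
  list(concepts = cp, relationships = rp)
}

rf2_rel <- function(sourceId, destinationId, active = 1, typeId = "116680003") {
  tibble::tibble(id = as.character(seq_along(sourceId)), effectiveTime = "20170731",
                 active = active, moduleId = "m", sourceId = sourceId,
                 destinationId = destinationId, relationshipGroup = 0,
                 typeId = typeId, characteristicTypeId = "c", modifierId = "mo")
}

rf2_con <- function(id, active = 1) {
  tibble::tibble(id = id, effectiveTime = "20170731", active = active,
                 moduleId = "m", definitionStatusId = "d")
}

test_that("RF2 snapshot loading keeps only active concepts, is-a edges", {
  paths <- write_rf2_pair(
    rf2_con(c("R", "C", "D"), active = c(1, 1, 0)),
    rf2_rel(c("C", "D"), c("R", "R"))
  )
  g <- suppressMessages(read_rf2_snapshot(paths$concepts, paths$relationships))
  expect_setequal(g$nodes$concept_id, c("R", "C"))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$child_id, "C")

  # inactive relationship rows and non-is-a typeIds are dropped too
  paths2 <- write_rf2_pair(
    rf2_con(c("R", "C", "E")),
    rf2_rel(c("C", "E", "E"), c("R", "R", "C"),
            active = c(1, 0, 1), typeId = c("116680003", "116680003", "12345"))
  )
  g2 <- suppressMessages(read_rf2_snapshot(paths2$concepts, paths2$relationships))
  expect_equal(nrow(g2$edges), 1)
})

test_that("concepts with no relationships give an edgeless graph with singleton closures", {
  paths <- write_rf2_pair(rf2_con(c("X", "Y")), rf2_rel(character(), character()))
  g <- read_rf2_snapshot(paths$concepts, paths$relationships)
  expect_equal(nrow(g$edges), 0)
  expect_equal(descendants(g, "X"), "X")
  expect_equal(descendants(g, "X", include_self = FALSE), character(0))
})

test_that("missing required columns are reported by name", {
  dir <- withr::local_tempdir()
  readr::write_tsv(tibble::tibble(id = "1"), file.path(dir, "c.tsv"), progress = FALSE)
  readr::write_tsv(rf2_rel("1", "2"), file.path(dir, "r.tsv"), progress = FALSE)
  expect_error(read_rf2_snapshot(file.path(dir, "c.tsv"), file.path(dir, "r.tsv")),
               "active", class = "phenovset_format_error")
})

test_that("edge endpoints absent from the concept table are a validation error", {
  paths <- write_rf2_pair(rf2_con(c("R", "C")), rf2_rel("C", "GHOST"))
  expect_error(read_rf2_snapshot(paths$concepts, paths$relationships),
               "GHOST", class = "phenovset_validation_error")
})

test_that("edge tables load as all-active graphs and reject self-loops and cycles", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "edges.tsv")
  writeLines(c("B\tA", "C\tA", "D\tB", "D\tC"), p)
  g <- read_edge_table(p)
  expect_equal(nrow(g$nodes), 4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(descendants(g, "A"), c("A", "B", "C", "D"))

  writeLines(c("A\tB", "B\tA"), p)
  expect_error(read_edge_table(p), "cycle", class = "phenovset_cycle_error")

  writeLines(c("A\tA"), p)
  expect_error(read_edge_table(p), "self-loop", class = "phenovset_validation_error")
})

test_that("cycle errors name the members of one cycle", {
  err <- tryCatch(
    concept_graph(data.frame(concept_id = c("A", "B", "C")),
                  data.frame(child_id = c("A", "B", "C"),
                             parent_id = c("B", "C", "A"))),
    error = function(e) conditionMessage(e)
  )
  expect_match(err, "A")
  expect_match(err, "B")
  expect_match(err, "C")
})

test_that("generator fixtures round-trip through the edge-table reader", {
  dir <- withr::local_tempdir()
  g <- generate_ontology(synthetic_config(n_concepts = 50, seed = 7))
  p <- file.path(dir, "edges.tsv")
  write_edge_table(g, p)
  g2 <- read_edge_table(p)
  expect_setequal(g2$nodes$concept_id, g$nodes$concept_id)
  expect_equal(dplyr::arrange(g2$edges, child_id, parent_id),
               dplyr::arrange(g$edges, child_id, parent_id))
  # labels ride on child rows, so every non-root label survives the trip
  children <- sort(unique(g$edges$child_id))
  expect_equal(unname(setNames(g2$nodes$label, g2$nodes$concept_id)[children]),
               unname(setNames(g$nodes$label, g$nodes$concept_id)[children]))
})

test_that("descendant closure handles leaves and multi-parent dedup", {
  g <- diamond_graph()
  expect_equal(descendants(g, "D"), "D")
  expect_equal(descendants(g, "D", include_self = FALSE), character(0))
  # D reachable under A via both B and C but counted once
  expect_equal(descendants(g, "A"), c("A", "B", "C", "D"))
  expect_equal(ancestors(g, "A"), character(0))
  expect_equal(ancestors(g, "D"), c("A", "B", "C"))
  expect_error(descendants(g, "nope"), "nope", class = "phenovset_lookup_error")
  expect_error(ancestors(g, "nope"), "nope", class = "phenovset_lookup_error")
})

test_that("closure queries match the brute-force reachability oracle everywhere", {
  g <- test_graph(200, seed = 11)
  for (id in g$nodes$concept_id) {
    expect_equal(descendants(g, id), oracle_descendants(g$edges, id),
                 info = paste("descendants of", id))
    expect_equal(ancestors(g, id), oracle_ancestors(g$edges, id),
                 info = paste("ancestors of", id))
  }
})

test_that("descendants/ancestors duality holds exhaustively", {
  g <- test_graph(200, seed = 13)
  ids <- g$nodes$concept_id
  desc <- lapply(ids, function(i) descendants(g, i, include_self = FALSE))
  names(desc) <- ids
  anc <- lapply(ids, function(i) ancestors(g, i))
  names(anc) <- ids
  for (y in ids) {
    for (x in desc[[y]]) expect_true(y %in% anc[[x]])
  }
  for (x in ids) {
    for (y in anc[[x]]) expect_true(x %in% desc[[y]])
  }
})

test_that("closures are pure: repeated queries are identical and self is always present", {
  g <- test_graph(100, seed = 5)
  withr::local_seed(99)
  for (id in sample(g$nodes$concept_id, 10)) {
    d1 <- descendants(g, id)
    d2 <- descendants(g, id)
    expect_identical(d1, d2)
    expect_true(id %in% d1)
    expect_gte(length(d1), 1)
  }
})
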
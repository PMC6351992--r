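test_that("rule expressions parse into ordered clause tables", {
  r <- parse_ecl("<<33449004 MINUS <<36217008")
  expect_s3_class(r, "intensional_valueset")
  expect_equal(r$clauses$polarity, c("include", "exclude"))
  expect_equal(r$clauses$concept_id, c("33449004", "36217008"))
  expect_equal(r$clauses$scope, rep("self_and_descendants", 2))

  r1 <- parse_ecl("<<64859006")
  expect_equal(nrow(r1$clauses), 1)
  expect_equal(r1$clauses$polarity, "include")

  # the three scopes
  r3 <- parse_ecl("<<10 OR <20 OR 30")
  expect_equal(r3$clauses$scope,
               c("self_and_descendants", "descendants_only", "self_only"))
})

test_that("malformed expressions fail with positioned parse errors", {
  expect_error(parse_ecl("MINUS <<5"), "token 1", class = "phenovset_parse_error")
  expect_error(parse_ecl(""), "empty", class = "phenovset_parse_error")
  expect_error(parse_ecl("   "), "empty", class = "phenovset_parse_error")
  expect_error(parse_ecl("<<5 OR"), "dangling", class = "phenovset_parse_error")
  expect_error(parse_ecl("<<5 OR OR <<6"), class = "phenovset_parse_error")
  expect_error(parse_ecl("<<5 (6)"), class = "phenovset_parse_error")
  expect_error(parse_ecl("<<5 <<6"), "missing OR/MINUS",
               class = "phenovset_parse_error")
})

test_that("a rule needs at least one include clause", {
  expect_error(
    intensional_valueset(data.frame(polarity = "exclude", concept_id = "5",
                                    scope = "self_only")),
    "include", class = "phenovset_validation_error"
  )
})

test_that("serialization round-trips clause tables exactly", {
  r <- parse_ecl("<<33449004 MINUS <<36217008")
  expect_identical(parse_ecl(format_ecl(r))$clauses, r$clauses)

  incl8 <- paste(paste0("<<", 1:8), collapse = " OR ")
  expect_equal(lengths(regmatches(incl8, gregexpr(" OR ", incl8))), 7)
  expect_identical(parse_ecl(incl8)$clauses$concept_id, as.character(1:8))
})

test_that("random rules round-trip byte-identically after one normalization", {
  withr::local_seed(2024)
  for (i in 1:100) {
    n_inc <- sample(1:4, 1)
    n_exc <- sample(0:3, 1)
    clauses <- tibble::tibble(
      polarity = c(rep("include", n_inc), rep("exclude", n_exc)),
      concept_id = as.character(sample(1e5, n_inc + n_exc)),
      scope = sample(c("self_and_descendants", "descendants_only", "self_only"),
                     n_inc + n_exc, replace = TRUE)
    )
    txt <- format_ecl(intensional_valueset(clauses))
    normalized <- format_ecl(parse_ecl(txt))
    expect_identical(normalized, txt)
    expect_identical(parse_ecl(normalized)$clauses, parse_ecl(txt)$clauses)
  }
})

test_that("expansion applies descendant-or-self closures with set subtraction", {
  g <- diamond_graph()
  # leaf include
  expect_equal(expand_valueset(parse_ecl("<<D"), g)$concept_ids, "D")
  # D removed because reachable under the excluded C, though also under B
  expect_equal(expand_valueset(parse_ecl("<<A MINUS <<C"), g)$concept_ids,
               c("A", "B"))
  # descendants-only and self-only scopes
  expect_equal(expand_valueset(parse_ecl("<A"), g)$concept_ids, c("B", "C", "D"))
  expect_equal(expand_valueset(parse_ecl("A"), g)$concept_ids, "A")
  # provenance of a derived set
  expect_equal(expand_valueset(parse_ecl("<<A"), g)$provenance, "derived")
  # expanding an extensional set is the identity
  evs <- extensional_valueset(c("A", "D"), provenance = "downloaded")
  expect_identical(expand_valueset(evs, g), evs)
  # unknown clause concept
  expect_error(expand_valueset(parse_ecl("<<Z"), g), "Z",
               class = "phenovset_lookup_error")
})

random_rule <- function(g, n_inc, n_exc) {
  ids <- sample(g$nodes$concept_id, n_inc + n_exc)
  tibble::tibble(
    polarity = c(rep("include", n_inc), rep("exclude", n_exc)),
    concept_id = ids,
    scope = sample(c("self_and_descendants", "descendants_only", "self_only"),
                   n_inc + n_exc, replace = TRUE)
  )
}

test_that("expansion equals the brute-force set-algebra oracle on random rules", {
  g <- test_graph(200, seed = 21)
  withr::local_seed(77)
  for (i in 1:100) {
    clauses <- random_rule(g, sample(1:2, 1), sample(0:1, 1))
    ivs <- intensional_valueset(clauses)
    expect_equal(expand_valueset(ivs, g)$concept_ids,
                 oracle_expand(clauses, g$edges),
                 info = format_ecl(ivs))
  }
})

test_that("include clauses are monotone up, exclude clauses monotone down", {
  g <- test_graph(150, seed = 31)
  withr::local_seed(88)
  for (i in 1:25) {
    base <- random_rule(g, 1, 0)
    base_set <- expand_valueset(intensional_valueset(base), g)$concept_ids
    extra_inc <- dplyr::bind_rows(base, random_rule(g, 1, 0))
    bigger <- expand_valueset(intensional_valueset(extra_inc), g)$concept_ids
    expect_true(all(base_set %in% bigger))
    extra_exc <- dplyr::bind_rows(base, dplyr::mutate(random_rule(g, 1, 0),
                                                      polarity = "exclude"))
    smaller <- expand_valueset(intensional_valueset(extra_exc), g)$concept_ids
    expect_true(all(smaller %in% base_set))
  }
})

test_that("expansion invariants: size bound, idempotence, include containment", {
  g <- test_graph(150, seed = 41)
  withr::local_seed(55)
  for (i in 1:25) {
    clauses <- random_rule(g, sample(1:3, 1), 0)
    # size bound needs scopes that keep the referenced concept itself
    clauses$scope[clauses$scope == "descendants_only"] <- "self_and_descendants"
    ivs <- intensional_valueset(clauses)
    ex <- expand_valueset(ivs, g)
    # include-only rules expand to at least one concept per clause
    expect_gte(length(ex$concept_ids), n_defining_concepts(ivs))
    # idempotent through re-serialization
    expect_identical(expand_valueset(parse_ecl(format_ecl(ivs)), g)$concept_ids,
                     ex$concept_ids)
    # every expanded concept is a descendant-or-self of an include root
    roots_closure <- unique(unlist(lapply(clauses$concept_id,
                                          function(id) descendants(g, id))))
    expect_true(all(ex$concept_ids %in% roots_closure))
  }
})

test_that("concepts-to-define counts clauses as written and set cardinality", {
  expect_equal(n_defining_concepts(parse_ecl("<<33449004 MINUS <<36217008")), 2)
  # duplicates count as written in the rule...
  dup <- intensional_valueset(tibble::tibble(
    polarity = "include", concept_id = c("5", "5"),
    scope = "self_and_descendants"
  ))
  expect_equal(n_defining_concepts(dup), 2)
  # ...but are deduplicated at expansion
  g <- diamond_graph()
  dup2 <- intensional_valueset(tibble::tibble(
    polarity = "include", concept_id = c("A", "A"), scope = "self_and_descendants"
  ))
  expect_equal(expand_valueset(dup2, g)$concept_ids, c("A", "B", "C", "D"))
  expect_equal(n_defining_concepts(extensional_valueset(as.character(1:99),
                                                        provenance = "downloaded")),
               99)
  expect_equal(n_defining_concepts(extensional_valueset("7", provenance = "derived")),
               1)
})
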
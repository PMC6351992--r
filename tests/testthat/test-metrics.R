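test_that("concept discrepancies are exact set-difference counts", {
  down <- extensional_valueset(paste0("c", 1:5), provenance = "downloaded")
  der <- extensional_valueset(paste0("c", 1:27), provenance = "derived")
  d <- diff_concepts(down, der)
  expect_equal(d$only_in_downloaded, 0)
  expect_equal(d$only_in_derived, 22)
  expect_equal(d$total, 22)

  same <- diff_concepts(down, down)
  expect_equal(unlist(same), c(only_in_downloaded = 0, only_in_derived = 0,
                               total = 0))
})

test_that("discrepancies match a brute-force membership scan on random pairs", {
  withr::local_seed(6)
  for (i in 1:25) {
    a <- sample(paste0("k", 1:60), sample(5:40, 1))
    b <- sample(paste0("k", 1:60), sample(5:40, 1))
    d <- diff_concepts(a, b)
    expect_equal(d$only_in_downloaded, sum(!a %in% b))
    expect_equal(d$only_in_derived, sum(!b %in% a))
    expect_equal(d$total == 0, setequal(a, b))
  }
})

test_that("conciseness ratios reproduce published roundings", {
  r <- define_ratios(26, 2, 48)
  expect_equal(r$ratio_download, 13)
  expect_equal(r$ratio_derived, 24)
  r2 <- define_ratios(12, 3, 233)
  expect_equal(r2$ratio_download, 4)
  expect_equal(r2$ratio_derived, 77.7)
  for (k in c(1, 5, 40)) {
    expect_equal(unlist(define_ratios(k, k, k)),
                 c(ratio_download = 1, ratio_derived = 1))
  }
  expect_error(define_ratios(5, 0, 5), class = "phenovset_undefined_ratio")
})

test_that("completeness ratio and percent reproduce published roundings", {
  c1 <- completeness(12, 233)
  expect_equal(c1$completeness_ratio, 19.4)
  expect_equal(c1$percent_included, 5)
  c2 <- completeness(12, 19)
  expect_equal(c2$completeness_ratio, 1.6)
  expect_equal(c2$percent_included, 63)
  s <- extensional_valueset(paste0("c", 1:9), provenance = "downloaded")
  c3 <- completeness(s, s)
  expect_equal(c3$completeness_ratio, 1.0)
  expect_equal(c3$percent_included, 100)
  expect_error(completeness(0, 5), class = "phenovset_undefined_ratio")
})

test_that("percent and ratio are reciprocal before rounding", {
  withr::local_seed(8)
  for (i in 1:20) {
    n_d <- sample(1:400, 1)
    n_r <- sample(n_d:450, 1)
    expect_equal((n_r / n_d) * (100 * n_d / n_r), 100)
  }
})

test_that("metric summaries use the even-count median convention", {
  downloaded <- c(5, 12, 8, 35, 99, 72, 26, 89, 12, 17)
  s <- summarize_metric(downloaded, "concepts to define (downloaded)")
  expect_equal(s$median, 21.5)
  expect_equal(s$minimum, 5)
  expect_equal(s$maximum, 99)
  expect_equal(s$range, 94)
  expect_equal(s$overall, 375)

  ratios <- c(5.4, 19.4, 4.5, 4.5, 1.1, 2.1, 1.8, 5, 1.6, 1.2)
  expect_equal(summarize_metric(ratios)$median, 3.3)

  single <- summarize_metric(7)
  expect_equal(single$median, 7)
  expect_equal(single$minimum, 7)
  expect_equal(single$maximum, 7)
  expect_equal(single$range, 0)
})

test_that("summary of identical rows degenerates correctly", {
  s <- summarize_metric(rep(4.2, 6))
  expect_equal(s$overall, 6 * 4.2)
  expect_equal(s$median, 4.2)
  expect_equal(s$range, 0)
  s2 <- summarize_metric(rep(10, 3), overall = "ratio_of_sums",
                         numerators = rep(20, 3), denominators = rep(2, 3))
  expect_equal(s2$overall, 10)
  expect_error(summarize_metric(1:3, overall = "ratio_of_sums",
                                numerators = 1:3, denominators = 1:2),
               class = "phenovset_validation_error")
})

test_that("a full condition row recomposes its component metrics", {
  cfg <- synthetic_config(n_concepts = 250, seed = 17, terms_per_concept = 6)
  g <- generate_ontology(cfg)
  m <- generate_term_map(g, cfg)
  rule <- sample_condition(g, cfg, index = 2)
  derived <- expand_valueset(rule, g)
  roots <- rule$clauses$concept_id[rule$clauses$polarity == "include"]
  down_syn <- degrade_to_extensional(derived, 0.4, clause_roots = roots, seed = 99)
  downloaded <- extensional_valueset(down_syn$concept_ids, provenance = "downloaded")

  row <- compare_condition(downloaded, rule, g, m)
  expect_s3_class(row, "condition_comparison")
  expect_equal(row$n_downloaded, length(downloaded$concept_ids))
  expect_equal(row$n_intensional, nrow(rule$clauses))
  expect_equal(row$n_derived, length(derived$concept_ids))
  expect_equal(row$ratio_to_define_download,
               define_ratios(row$n_downloaded, row$n_intensional,
                             row$n_derived)$ratio_download)
  expect_equal(row$completeness_ratio,
               completeness(downloaded, derived)$completeness_ratio)
  expect_equal(row$percent_concepts_included,
               completeness(downloaded, derived)$percent_included)
  d <- diff_concepts(downloaded, derived)
  expect_equal(row$disc_total, d$total)
  tc <- term_coverage(compile_terms(downloaded, m), compile_terms(derived, m))
  expect_equal(row$term_ratio, tc$term_ratio)
  expect_equal(row$term_percent, tc$term_percent)
})

test_that("identical downloaded and derived sets give a perfect row", {
  g <- diamond_graph()
  m <- term_map(tibble::tibble(term_id = paste0("t", 1:8),
                               term_text = paste("term", 1:8),
                               concept_id = rep(c("A", "B", "C", "D"), 2)))
  rule <- parse_ecl("<<A", condition_label = "everything")
  derived <- expand_valueset(rule, g)
  downloaded <- extensional_valueset(derived$concept_ids, provenance = "downloaded")
  row <- compare_condition(downloaded, rule, g, m)
  expect_equal(row$disc_total, 0)
  expect_equal(row$percent_concepts_included, 100)
  expect_equal(row$term_percent, 100)
  expect_equal(row$completeness_ratio, 1)
})

test_that("degrading 65% of a large derived set yields ~35% concept retention", {
  cfg <- synthetic_config(n_concepts = 500, seed = 23,
                          extra_parent_probability = 0.1)
  g <- generate_ontology(cfg)
  sizes <- vapply(g$nodes$concept_id,
                  function(id) length(descendants(g, id)), integer(1))
  root <- g$nodes$concept_id[which.max(sizes)]
  rule <- intensional_valueset(tibble::tibble(
    polarity = "include", concept_id = root, scope = "self_and_descendants"
  ))
  derived <- expand_valueset(rule, g)
  n <- length(derived$concept_ids)
  expect_gte(n, 300)
  down <- degrade_to_extensional(derived, 0.65, clause_roots = root, seed = 7)
  pct <- 100 * length(down$concept_ids) / n
  # binomial sampling bound around the 35% target
  sd_pct <- 100 * sqrt(0.65 * 0.35 / n)
  expect_lt(abs(pct - 35), 3 * sd_pct + 100 / n)
})
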
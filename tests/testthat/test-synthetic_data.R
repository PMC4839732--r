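# Synthetic-data generators: determinism, constructive invariants and
# calibration of the stated defaults.

test_that("make_universe is deterministic with sizes in range", {
  c1 <- make_universe(n_genes = 500, n_pathways = 12,
                      size_range = c(5, 40), seed = 3)
  c2 <- make_universe(n_genes = 500, n_pathways = 12,
                      size_range = c(5, 40), seed = 3)
  expect_identical(c1$terms, c2$terms)
  expect_true(all(lengths(c1$terms) >= 5 & lengths(c1$terms) <= 40))
  expect_equal(length(c1$universe), 500L)
  expect_error(make_universe(n_genes = 100, size_range = c(2, 300)),
               "size_range")
})

test_that("overlap_fraction 0 keeps pathways disjoint while genes last", {
  coll <- make_universe(n_genes = 400, n_pathways = 8,
                        size_range = c(5, 30), overlap_fraction = 0,
                        seed = 4)
  all_members <- unlist(coll$terms)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("simulate_expression is reproducible and honours its knobs", {
  coll <- make_universe(n_genes = 300, n_pathways = 6,
                        size_range = c(5, 20), seed = 5)
  s1 <- simulate_expression(coll, names(coll$terms)[1], seed = 9)
  s2 <- simulate_expression(coll, names(coll$terms)[1], seed = 9)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_equal(s1$matrix$scale_tag, "linear")
  expect_true(all(s1$matrix$values >= 0))
  expect_error(simulate_expression(coll, "no_such_term"), "planted")
  expect_error(simulate_expression(coll, names(coll$terms)[1],
                                   responsive_fraction = 0), "\\(0, 1\\]")
  # low-expression genes exercise the RPKM floor
  expect_gt(length(s1$truth$low_genes), 0L)
  f <- filter_low_expression(s1$matrix, floor = 2)
  expect_true(all(s1$truth$low_genes %in% attr(f, "removed")))
})

test_that("null simulation keeps the p<0.05 fraction near alpha", {
  coll <- make_universe(n_genes = 2000, n_pathways = 5,
                        size_range = c(5, 20), seed = 6)
  sim <- simulate_expression(coll, character(), effect_log2 = 0,
                             timepoints = 8, low_fraction = 0, seed = 6)
  res <- test_timepoint(sim$matrix, 8)
  half <- 2.576 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), half)
})

test_that("planted responsive genes are recovered with high power", {
  coll <- make_universe(n_genes = 2000, n_pathways = 20,
                        size_range = c(10, 80), seed = 7)
  planted <- names(coll$terms)[1:3]
  sim <- simulate_expression(coll, planted, seed = 7)
  degs <- suppressWarnings(call_degs(sim$matrix, c(8, 24, 72), floor = 2))
  recovered <- mean(sim$truth$responsive_genes %in% degs$up$members)
  expect_gte(recovered, 0.9)  # power at effect/sd = 4, n = 4/arm
})

test_that("simulate_rnai_screen respects rate edge cases and expectation", {
  coll <- make_universe(n_genes = 2000, n_pathways = 10,
                        size_range = c(10, 50), seed = 8)
  ess_terms <- names(coll$terms)[1:3]
  perfect <- simulate_rnai_screen(coll, ess_terms, sensitivity = 1,
                                  genome_fpr = 0, seed = 1)
  expect_setequal(perfect$hits$members, perfect$truth$essential_genes)
  none <- simulate_rnai_screen(coll, ess_terms, sensitivity = 0,
                               genome_fpr = 0, seed = 1)
  expect_equal(length(none$hits), 0L)
  # hit count within the 99% envelope of the closed-form expectation
  scr <- simulate_rnai_screen(coll, ess_terms, seed = 2)
  n_ess <- length(scr$truth$essential_genes)
  n_other <- 2000 - n_ess
  mu <- 0.5 * n_ess + 0.03 * n_other
  sd <- sqrt(0.5 * 0.5 * n_ess + 0.03 * 0.97 * n_other)
  expect_lt(abs(length(scr$hits) - mu), 2.576 * sd)
  expect_error(simulate_rnai_screen(coll, ess_terms, sensitivity = 2),
               "rates")
})

test_that("simulate_orthologs builds conserved maps deterministically", {
  coll <- make_universe(n_genes = 300, n_pathways = 6,
                        size_range = c(5, 20), seed = 9)
  full <- simulate_orthologs(coll, conservation = 1, seed = 1)
  expect_equal(nrow(full$map$pairs), 300L)
  expect_equal(unname(full$map$summary[["one_to_one"]]), 300L)
  expect_equal(length(full$collection$terms), length(coll$terms))
  o1 <- simulate_orthologs(coll, seed = 2)
  o2 <- simulate_orthologs(coll, seed = 2)
  expect_identical(o1$map$pairs, o2$map$pairs)
  expect_true(simulate_orthologs(coll, scramble_within_pathway = TRUE,
                                 seed = 3)$truth$scramble_within_pathway)
})

test_that("simulate_study separates signals completely at d = 1", {
  coll <- make_universe(n_genes = 1500, n_pathways = 25,
                        size_range = c(10, 60), seed = 10)
  planted <- names(coll$terms)[1:6]
  study <- simulate_study(coll, planted, disjointness = 1, seed = 10)
  R <- unique(unlist(study$truth$responsive_by_term))
  E <- unique(unlist(study$truth$essential_by_term))
  expect_equal(length(intersect(R, E)), 0L)
  # d = 0 draws roles independently: overlap at roughly rf * ef per term
  study0 <- simulate_study(coll, planted, disjointness = 0, seed = 10)
  R0 <- unique(unlist(study0$truth$responsive_by_term))
  E0 <- unique(unlist(study0$truth$essential_by_term))
  expect_gt(length(intersect(R0, E0)), 0L)
  # bit-reproducible
  again <- simulate_study(coll, planted, disjointness = 1, seed = 10)
  expect_identical(study$matrix$values, again$matrix$values)
  expect_identical(study$hits$members, again$hits$members)
})

test_that("scrambled orthologs keep pathway identity, not gene identity", {
  coll <- make_universe(n_genes = 1500, n_pathways = 20,
                        size_range = c(20, 60), seed = 11)
  planted <- names(coll$terms)[1:3]
  orth <- simulate_orthologs(coll, conservation = 0.95,
                             scramble_within_pathway = TRUE, seed = 11)
  # source species: one responsive draw; target species: independent draw
  src <- simulate_expression(coll, planted, seed = 100, timepoints = 8)
  tgt <- simulate_expression(orth$collection, planted, seed = 200,
                             timepoints = 8)
  src_degs <- suppressWarnings(call_degs(src$matrix, 8))
  tgt_degs <- suppressWarnings(call_degs(tgt$matrix, 8))
  mapped <- map_namespace(src_degs$up, orth$map)
  vc <- venn(mapped, tgt_degs$up)
  # pathway-level signal conserved...
  src_terms <- filter_terms(enrich(src_degs$up, coll))$term_id
  tgt_terms <- filter_terms(enrich(tgt_degs$up, orth$collection))$term_id
  expect_true(all(planted %in% intersect(src_terms, tgt_terms)))
  # ...while gene-level overlap stays near chance: responsive sets were
  # drawn independently (fraction 0.5), so expect ~50% of mapped DEGs,
  # far below the ~100% a conserved-gene model would give
  expect_lt(vc$size_intersection / vc$size_a, 0.75)
})
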
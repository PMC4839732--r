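# Differential-expression rule: Welch t + signed fold, low-abundance
# filter, per-timepoint union into up/down lists.

test_that("signed_fold arithmetic, symmetry and bounds", {
  expect_equal(signed_fold(10, 40, pseudo = 1e-12), 4, tolerance = 1e-9)
  expect_equal(signed_fold(40, 10, pseudo = 1e-12), -4, tolerance = 1e-9)
  expect_equal(signed_fold(7, 7), 1)
  expect_error(signed_fold(-1, 2), "non-negative")
  expect_error(signed_fold(1, 2, pseudo = 0), "pseudo")
  set.seed(1)
  f <- signed_fold(runif(200, 0, 50), runif(200, 0, 50))
  expect_true(all(abs(f) >= 1))
})

test_that("filter_low_expression implements the 'low in both' rule", {
  v <- rbind(low_both = rep(1.5, 8),
             low_ctrl = c(rep(1.5, 4), rep(3, 4)),
             high = rep(10, 8))
  s <- expand.grid(replicate = 1:4, timepoint = 8,
                   condition = c("control", "treated"),
                   stringsAsFactors = FALSE)
  mat <- expression_matrix(v, s)
  f <- filter_low_expression(mat, floor = 2)
  expect_setequal(rownames(f$values), c("low_ctrl", "high"))
  expect_equal(attr(f, "removed"), "low_both")
  f0 <- filter_low_expression(mat, floor = 0)
  expect_equal(rownames(f0$values), rownames(mat$values))
  mat$scale_tag <- "log2"
  expect_error(filter_low_expression(mat), "linear")
})

test_that("test_timepoint: null, planted, and conjunction cases", {
  # identical control/treated values -> no gene passes
  v <- matrix(rep(c(4, 5, 6, 7), each = 2), nrow = 1)
  v <- rbind(g1 = c(4, 5, 6, 7, 4, 5, 6, 7), g2 = rep(3, 8))
  s <- expand.grid(replicate = 1:4, timepoint = 8,
                   condition = c("control", "treated"),
                   stringsAsFactors = FALSE)
  res <- test_timepoint(expression_matrix(v, s), 8)
  expect_false(any(res$passes))
  expect_equal(res$p_value[res$gene == "g2"], 1)  # constant gene -> p = 1

  # planted log2 shift 2.0 at noise sd 0.1 (effect/sd = 20): passes
  mat <- toy_matrix(effects = list(g1 = 2), noise_sd = 0.1, seed = 7)
  res <- test_timepoint(mat, 8)
  r1 <- res[res$gene == "g1", ]
  expect_true(r1$passes && r1$p_value < 0.05 && r1$signed_fold > 2)

  # large fold but unstable replicates: conjunction fails on p
  v <- rbind(g1 = c(1, 1.2, 0.9, 1.1, 0.1, 200, 0.1, 200))
  res <- test_timepoint(expression_matrix(v, s), 8)
  expect_gt(res$signed_fold, 2)
  expect_gt(res$p_value, 0.05)
  expect_false(res$passes)

  expect_error(test_timepoint(mat, 24), "available")
})

test_that("call_degs unions timepoints and flags two-direction genes", {
  mat <- toy_matrix(effects = list(g1 = 3), noise_sd = 0.1, seed = 3)
  res <- suppressWarnings(call_degs(mat, 8))
  expect_equal(res$up$members, "g1")
  expect_equal(length(res$down), 0L)
  expect_equal(res$up$direction, "up")
  expect_equal(res$up$timepoints, 8)

  # up at 8 h, down at 72 h -> present in both lists, flagged
  set.seed(11)
  s <- expand.grid(replicate = 1:4, timepoint = c(8, 72),
                   condition = c("control", "treated"),
                   stringsAsFactors = FALSE)[, c("condition", "timepoint",
                                                 "replicate")]
  lv <- matrix(rnorm(2 * nrow(s), 4, 0.05), nrow = 2,
               dimnames = list(c("flip", "null"), NULL))
  sel_up <- s$condition == "treated" & s$timepoint == 8
  sel_dn <- s$condition == "treated" & s$timepoint == 72
  lv["flip", sel_up] <- lv["flip", sel_up] + 3
  lv["flip", sel_dn] <- lv["flip", sel_dn] - 3
  mat2 <- expression_matrix(2^lv, s)
  expect_warning(res2 <- call_degs(mat2, c(8, 72)), "both directions")
  expect_true("flip" %in% res2$up$members)
  expect_true("flip" %in% res2$down$members)
  expect_true(all(res2$records$both_directions[res2$records$gene == "flip"]))

  expect_error(call_degs(mat, numeric()), "empty timepoint")
  expect_error(call_degs(mat, c(8, 24)), "not present")
})

test_that("direction anti-symmetry: swapping condition labels swaps lists", {
  set.seed(5)
  coll <- make_universe(n_genes = 400, n_pathways = 10,
                        size_range = c(5, 30), seed = 5)
  sim <- simulate_expression(coll, names(coll$terms)[1:2], seed = 5,
                             timepoints = 8, low_fraction = 0)
  mat <- sim$matrix
  swapped <- mat
  swapped$samples$condition <- ifelse(mat$samples$condition == "control",
                                      "treated", "control")
  swapped <- expression_matrix(mat$values, swapped$samples,
                               namespace = mat$namespace)
  a <- suppressWarnings(call_degs(mat, 8))
  b <- suppressWarnings(call_degs(swapped, 8))
  expect_setequal(a$up$members, b$down$members)
  expect_setequal(a$down$members, b$up$members)
})

test_that("monotonicity: stricter thresholds never grow DEG lists", {
  coll <- make_universe(n_genes = 400, n_pathways = 10,
                        size_range = c(5, 30), seed = 6)
  mat <- simulate_expression(coll, names(coll$terms)[1:2], seed = 6,
                             timepoints = 8, noise_sd = 1)$matrix
  loose <- suppressWarnings(call_degs(mat, 8, p_threshold = 0.05,
                                      fold_threshold = 2))
  tight_fold <- suppressWarnings(call_degs(mat, 8, p_threshold = 0.05,
                                           fold_threshold = 3))
  tight_p <- suppressWarnings(call_degs(mat, 8, p_threshold = 0.01,
                                        fold_threshold = 2))
  expect_true(all(tight_fold$up$members %in% loose$up$members))
  expect_true(all(tight_fold$down$members %in% loose$down$members))
  expect_true(all(tight_p$up$members %in% loose$up$members))
  expect_true(all(tight_p$down$members %in% loose$down$members))
})

test_that("type-I control on null data", {
  # 10 independent null simulations; at most 2 may fall outside the 99%
  # binomial envelope of alpha (a sound multi-run version of the
  # within-Monte-Carlo-error check), and the full rule never rejects
  # more than the p-only criterion.
  coll <- make_universe(n_genes = 800, n_pathways = 5,
                        size_range = c(5, 20), seed = 8)
  outside <- 0L
  for (s in 1:10) {
    mat <- simulate_expression(coll, character(), effect_log2 = 0,
                               seed = 800 + s, timepoints = 8,
                               low_fraction = 0)$matrix
    res <- test_timepoint(mat, 8)
    frac_p <- mean(res$p_value < 0.05)
    expect_lte(mean(res$passes), frac_p)
    half <- 2.576 * sqrt(0.05 * 0.95 / nrow(res))
    if (abs(frac_p - 0.05) >= half) outside <- outside + 1L
  }
  expect_lte(outside, 2L)
})
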
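# Backward selection, permutation importance, permutation test, BH step-up.

test_that("backward selection discards noise and never hurts the score", {
  ds <- separable_dataset(n_per_class = 25, n_classes = 3, d = 2, gap = 4,
                          seed = 17, n_noise = 3)
  tr <- backward_select(ds)
  expect_gte(tr$f1, tr$f1_full)
  expect_true(length(tr$features) >= 1)
  # accepted removals are monotone in F1
  if (nrow(tr$steps) > 1) expect_true(all(diff(tr$steps$f1) > 0))
  # single-feature dataset returned unchanged
  one <- ds
  one$features <- ds$features[, 1, drop = FALSE]
  tr1 <- backward_select(one)
  expect_equal(tr1$features, colnames(one$features))
})

test_that("permutation importance: constant feature is exactly neutral", {
  ds <- separable_dataset(n_per_class = 20, n_classes = 2, d = 2, seed = 23)
  ds$features <- cbind(ds$features, flat = 0.5)
  e <- permutation_importance(ds, "flat")
  expect_equal(e$delta_f1, 0)
  expect_error(permutation_importance(ds, "nope"), "unknown feature")
})

test_that("permutation importance flags the informative feature", {
  # one informative feature, one pure-noise feature
  set.seed(29)
  x <- cbind(sig = c(rnorm(30, 0, 0.5), rnorm(30, 5, 0.5)),
             noi = rnorm(60))
  ds <- suppressWarnings(assemble_dataset(
    x, rep(1:2, each = 30), rep(sprintf("s%d", 1:6), 10)))
  e_sig <- permutation_importance(ds, "sig")
  e_noi <- permutation_importance(ds, "noi")
  expect_gt(e_sig$delta_f1, 0.3)
  expect_lt(abs(e_noi$delta_f1), 0.15)
  expect_gt(e_sig$delta_f1, e_noi$delta_f1)
})

test_that("importance subsampling cap bounds the evaluation count", {
  ds <- separable_dataset(n_per_class = 15, n_classes = 2, seed = 31)
  e <- permutation_importance(ds, "inf1", max_variants = 5, seed = 2)
  expect_true(is.finite(e$delta_f1))
})

test_that("permutation test: extremes and separable dataset", {
  ds <- separable_dataset(n_per_class = 12, n_classes = 2, seed = 37)
  pt <- permutation_test(ds, n_perm = 200, seed = 3)
  expect_lte(pt$p_value, 1 / 201 + 1e-12)
  expect_equal(length(pt$f1_permuted), 200)
  # observed below every permuted score -> p = 1
  fake_scorer_env <- new.env()
  fake_scorer_env$first <- TRUE
  fake_scorer <- function(d) {
    # first call (observed) scores 0, permutations score 1
    if (fake_scorer_env$first) {
      fake_scorer_env$first <- FALSE
      list(scores = list(f1 = 0))
    } else list(scores = list(f1 = 1))
  }
  p1 <- permutation_test(ds, scorer = fake_scorer, n_perm = 19, seed = 1)
  expect_equal(p1$p_value, 1)
})

test_that("permutation p is invariant to monotone score transforms", {
  ds <- separable_dataset(n_per_class = 10, n_classes = 2, seed = 41)
  sc1 <- function(d) suppressWarnings(leave_one_sample_out(d))
  sc2 <- function(d) {
    r <- suppressWarnings(leave_one_sample_out(d))
    r$scores$f1 <- exp(3 * r$scores$f1)   # strictly increasing map
    r
  }
  p1 <- permutation_test(ds, sc1, n_perm = 50, seed = 7)$p_value
  p2 <- permutation_test(ds, sc2, n_perm = 50, seed = 7)$p_value
  expect_equal(p1, p2)
})

test_that("Benjamini-Hochberg step-up matches the hand oracle", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_equal(fdr_adjust_suite(p, q = 0.05),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_adjust_suite(rep(1, 4)), rep(FALSE, 4))
  expect_equal(fdr_adjust_suite(rep(0, 4)), rep(TRUE, 4))
  # unsorted input handled in original order
  p2 <- c(0.2, 0.001, 0.04, 0.01, 0.02)
  expect_equal(fdr_adjust_suite(p2, 0.05), c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_error(fdr_adjust_suite(c(0.5, 1.2)), "0, 1")
  expect_error(fdr_adjust_suite(numeric(0)), "1 p-value")
})
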
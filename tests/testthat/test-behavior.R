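# Tracking errors, rating preprocessing, dataset assembly.

trace_from_offsets <- function(off) {
  data.frame(time_s = seq_len(nrow(off)) / 10,
             ball_x = 100 + off[, 1], ball_y = 200 + off[, 2],
             target_x = rep(100, nrow(off)), target_y = rep(200, nrow(off)))
}

test_that("tracking errors: hand sums and triangle inequalities", {
  z <- trace_from_offsets(cbind(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(tracking_errors(z), list(euclid_cum = 0, x_cum = 0, y_cum = 0))
  tri <- trace_from_offsets(cbind(c(0, 3, 0), c(0, 4, 0)))
  e <- tracking_errors(tri)
  expect_equal(e$euclid_cum, 5)
  expect_equal(e$x_cum, 3)
  expect_equal(e$y_cum, 4)
  ax <- trace_from_offsets(cbind(c(1, -2, 3), c(0, 0, 0)))
  ea <- tracking_errors(ax)
  expect_equal(ea$euclid_cum, ea$x_cum)
  expect_equal(ea$y_cum, 0)
  # property: euclid between max(x,y) and x + y on random traces
  set.seed(13)
  for (i in 1:20) {
    e <- tracking_errors(trace_from_offsets(matrix(rnorm(40), ncol = 2)))
    expect_gte(e$euclid_cum, max(e$x_cum, e$y_cum) - 1e-9)
    expect_lte(e$euclid_cum, e$x_cum + e$y_cum + 1e-9)
  }
  bad <- list(ball_x = 1:3, ball_y = 1:2, target_x = 1:3, target_y = 1:3)
  expect_error(tracking_errors(bad), "length")
})

test_that("error_for_rating maps kinds to axes and enforces protocol", {
  err <- list(euclid_cum = 10, x_cum = 6, y_cum = 7)
  expect_equal(error_for_rating("R1", "x", err), 6)
  expect_equal(error_for_rating("R1", "y", err), 7)
  expect_equal(error_for_rating("R2", "x", err), 7)
  expect_equal(error_for_rating("R3", "x", err), 10)
  expect_error(error_for_rating("R2", "x", err, condition = "individual"),
               "protocol")
  expect_error(error_for_rating("R3", "y", err, condition = "individual"),
               "protocol")
})

test_that("rating outlier correction follows the fence rule", {
  # six subjects with medians 6, 6, 7, 7, 6, 2: only the median-2 subject
  # is flagged; others' median is 6, so the shift is +4
  subj <- rep(letters[1:6], each = 5)
  ratings <- c(rep(6, 5), rep(6, 5), rep(7, 5), rep(7, 5), rep(6, 5),
               c(2, 2, 2, 1, 3))
  out <- correct_rating_outliers(ratings, subj)
  expect_equal(out$report$subject, "f")
  expect_equal(out$report$shift, 4)
  expect_equal(out$ratings[subj == "f"], c(6, 6, 6, 5, 7))
  # all other subjects untouched
  expect_equal(out$ratings[subj != "f"], ratings[subj != "f"])
  # identical medians: nothing flagged
  none <- correct_rating_outliers(rep(c(5, 6, 7), times = 3),
                                  rep(letters[1:3], each = 3))
  expect_equal(nrow(none$report), 0)
  expect_error(correct_rating_outliers(1:4, c("a", "a", "b", "b")),
               "3 subjects")
})

test_that("level selection keeps the L most frequent levels", {
  few <- select_rating_levels(c(4, 5, 5, 6), L = 6)
  expect_true(all(few$keep))
  expect_equal(few$n_discarded, 0L)
  # levels 3..9, level 3 rarest
  labels <- rep(3:9, times = c(1, 5, 6, 9, 9, 6, 4))
  sel <- select_rating_levels(labels, L = 6)
  expect_equal(sel$levels, 4:9)
  expect_equal(sel$n_discarded, 1L)
  expect_false(any(labels[sel$keep] == 3))
  expect_lte(length(sel$levels), 6)
  # deterministic tie-break: tie at the boundary resolved toward the level
  # closer to the grand median, then the lower level
  tied <- rep(1:7, times = c(3, 5, 5, 5, 5, 5, 3))
  s2 <- select_rating_levels(tied, L = 6)
  expect_equal(s2$levels, 1:6)  # grand median 4; level 1 beats level 7? no:
  # |1-4| = |7-4| -> lower level wins
})

test_that("dataset assembly normalises to [0, 1] and flags constants", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(10, 10, 10, 10), c = c(0, 5, 2, 1))
  expect_warning(
    ds <- assemble_dataset(x, c(1, 1, 2, 2), c("s1", "s1", "s2", "s2")),
    "constant")
  expect_equal(range(ds$features[, "a"]), c(0, 1))
  expect_equal(range(ds$features[, "c"]), c(0, 1))
  expect_true(all(ds$features[, "b"] == 0))
  expect_equal(ds$N, 4)
  # idempotent on already-normalised data
  ds2 <- suppressWarnings(
    assemble_dataset(ds$features, ds$labels, ds$subject_ids))
  expect_equal(ds2$features, ds$features)
  expect_error(assemble_dataset(x, 1:3, c("a", "b", "c")), "align")
  xna <- x; xna[2, 1] <- NA
  expect_error(suppressWarnings(
    assemble_dataset(xna, c(1, 1, 2, 2), rep("s", 4))), "missing")
})
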
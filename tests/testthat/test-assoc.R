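# Correlation analyses and the small-sample tests behind them.

test_that("pearson_r: extremes, direct-formula oracle, sentinels", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(2, 1, 4, 3, 6)
  got <- pearson_r(x, y)
  oracle <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  expect_close(got$r, oracle, 1e-12)
  # p matches the t-transform recomputed by hand
  tt <- oracle * sqrt(3 / (1 - oracle^2))
  expect_close(got$p, 2 * stats::pt(-abs(tt), 3), 1e-12)
  expect_true(is.na(pearson_r(rep(1, 5), y)$r))
  expect_error(pearson_r(1:2, 1:2), "3 observations")
  # affine invariance with positive slope
  z <- rnorm(10)
  w <- rnorm(10)
  expect_close(pearson_r(z, w)$r, pearson_r(2 * z + 5, w)$r, 1e-12)
})

test_that("Wilcoxon signed-rank equals exhaustive enumeration for n <= 12", {
  enum_p <- function(v) {
    v <- v[v != 0]
    n <- length(v)
    rk <- rank(abs(v))
    w_obs <- sum(rk[v > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% rk
    p_le <- mean(w_all <= w_obs)
    p_ge <- mean(w_all >= w_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  # 10 strictly positive values -> exact two-sided p = 2/1024
  v10 <- c(0.5, 1.2, 0.3, 2.2, 1.9, 0.8, 1.1, 0.2, 3.0, 0.6)
  expect_close(distribution_median_test(v10), 2 / 1024, 1e-12)
  expect_close(enum_p(v10), 2 / 1024, 1e-12)
  set.seed(19)
  for (i in 1:12) {
    n <- sample(5:12, 1)
    v <- round(rnorm(n), 3)
    v <- v[v != 0]
    if (length(v) < 5 || any(duplicated(abs(v)))) next
    expect_close(distribution_median_test(v), enum_p(v), 1e-10)
  }
  # symmetric +-a pairs: statistic at the null centre
  sym <- c(1, -1, 2, -2, 3, -3)
  expect_gt(distribution_median_test(sym), 0.9)
  expect_error(distribution_median_test(rep(0, 6)), "zero")
  expect_error(distribution_median_test(c(1, 2, 0, 0, 0, 0)), "5 nonzero")
})

test_that("paired t-test matches the hand formula and is antisymmetric", {
  a <- c(2, 3, 4)
  b <- c(1, 1, 1)
  got <- paired_t_test(a, b)
  expect_close(got$t, 2 / (1 / sqrt(3)), 1e-12)
  expect_close(got$p, 2 * stats::pt(-abs(got$t), 2), 1e-12)
  expect_true(is.na(paired_t_test(a, a)$t))
  sw <- paired_t_test(b, a)
  expect_close(sw$t, -got$t, 1e-12)
})

test_that("dyad rating correlations: structure and identical-sequence case", {
  co <- tiny_cohort(seed = 41)
  out <- dyad_rating_correlations(co)
  expect_true(all(c("dyad", "pair", "r", "p", "n", "significant") %in%
                    names(out)))
  expect_equal(sort(unique(out$pair)),
               sort(c(t(outer(c("R1", "R2", "R3"), c("R1", "R2", "R3"),
                              paste, sep = "-")))))
  # partners given identical rating sequences correlate perfectly
  co2 <- tiny_cohort(seed = 43)
  rc <- co2$ratings
  collab <- rc$condition == "collaborative"
  subs <- unique(rc$subject[rc$dyad == "D01"])
  seq_vals <- c(3, 7, 5)
  for (s in subs) {
    sel <- collab & rc$subject == s & rc$dyad == "D01"
    rc$R1[sel] <- seq_vals
    rc$R2[sel] <- seq_vals
    rc$R3[sel] <- seq_vals
  }
  out2 <- dyad_rating_correlations(rc)
  d1 <- out2[out2$dyad == "D01", ]
  expect_true(all(abs(d1$r - 1) < 1e-12))
})

test_that("subject rating-error correlations respond to error coupling", {
  co_err <- generate_cohort(cohort_config(
    n_dyads = 3L, days = 1L, trials_per_condition_per_day = 7L,
    coupling_autonomic = 0, coupling_error = 1, rating_noise_sd = 0.3,
    subject_heterogeneity = 0, seed = 51L))
  out <- subject_rating_error_correlations(co_err)
  r1 <- out[out$pair == "R1collab-err_own", ]
  expect_gte(mean(r1$r < 0, na.rm = TRUE), 0.9)
  # null couplings: median r near zero
  co_null <- generate_cohort(cohort_config(
    n_dyads = 3L, days = 1L, trials_per_condition_per_day = 7L,
    coupling_autonomic = 0, coupling_error = 0, subject_heterogeneity = 0,
    seed = 53L))
  out0 <- subject_rating_error_correlations(co_null)
  expect_lt(abs(stats::median(out0$r, na.rm = TRUE)), 0.3)
})
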
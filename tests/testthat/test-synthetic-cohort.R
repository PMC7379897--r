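# Synthetic cohort generator: structure, determinism, round-trip control of
# the stated signal properties.

test_that("cohort structure matches the configuration", {
  co <- tiny_cohort()
  cfg <- co$config
  n_expected <- 2 * cfg$n_dyads * cfg$days * 2 * cfg$trials_per_condition_per_day
  expect_length(co$trials, n_expected)
  expect_equal(nrow(co$ratings), n_expected)
  # per subject: days x 2 conditions x trials
  per_subject <- table(co$ratings$subject)
  expect_true(all(per_subject ==
                    cfg$days * 2 * cfg$trials_per_condition_per_day))
  # R2/R3 present iff collaborative
  collab <- co$ratings$condition == "collaborative"
  expect_true(all(!is.na(co$ratings$R2[collab])))
  expect_true(all(is.na(co$ratings$R2[!collab])))
  expect_true(all(is.na(co$ratings$R3[!collab])))
  # trial record invariants
  for (tr in co$trials[1:6]) {
    expect_true(all(diff(tr$rpeaks) > 0))
    expect_true(all(tr$rpeaks > 0 & tr$rpeaks <= cfg$trial_duration))
    expect_length(tr$resp, cfg$fs_resp_eda * cfg$trial_duration)
    expect_length(tr$eda, cfg$fs_resp_eda * cfg$trial_duration)
    expect_true(all(tr$ratings$R1 %in% cfg$rating_scale))
  }
})

test_that("same config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_dyads = 1L, days = 1L,
                       trials_per_condition_per_day = 2L, seed = 99L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$trials[[3]]$rpeaks, b$trials[[3]]$rpeaks)
  expect_identical(a$trials[[3]]$eda, b$trials[[3]]$eda)
  expect_identical(a$trials[[3]]$tracking, b$trials[[3]]$tracking)
})

test_that("invalid configuration names the offending field", {
  expect_error(cohort_config(n_dyads = 0), "n_dyads")
  expect_error(cohort_config(coupling_autonomic = 1.5), "coupling_autonomic")
  expect_error(cohort_config(trial_duration = -1), "trial_duration")
})

test_that("NN-series generator hits its stated mean, SD and band split", {
  # degenerate: no modulation, no noise
  rp <- generate_nn_series(800, 0, 0, 0, 0.25, duration = 30, seed = 1)
  expect_close(diff(rp) * 1000, 800, 1e-9)
  # realized mean within 2% across seeds
  rel_err <- vapply(1:50, function(s) {
    rp <- generate_nn_series(850, 50, 0.35, 0.35, 0.25, 120, seed = s)
    abs(mean(diff(rp)) * 1000 - 850) / 850
  }, numeric(1))
  expect_lt(max(rel_err), 0.02)
  # HF-dominant generation is recovered as HF-dominant (round trip)
  rp <- generate_nn_series(850, 50, lf_frac = 0.05, hf_frac = 0.85,
                           resp_rate = 0.25, duration = 120, seed = 2)
  h <- frequency_domain_hrv(nn_series(rp))
  expect_gt(h$ecg_HF / (h$ecg_LF + h$ecg_HF), 0.9)
  expect_error(generate_nn_series(mean_nn = -5), "mean_nn")
  expect_error(generate_nn_series(lf_frac = 0.7, hf_frac = 0.7), "lf_frac")
})

test_that("EDA generator: degenerate, deterministic, ground truth emitted", {
  g0 <- generate_eda_trace(tonic_level = 1.7, drift = 0, scr_rate = 0,
                           duration = 60, fs = 10, seed = 4, noise_sd = 0)
  expect_close(g0$trace, 1.7, 1e-12)
  g1 <- generate_eda_trace(duration = 60, seed = 8)
  g2 <- generate_eda_trace(duration = 60, seed = 8)
  expect_identical(g1$trace, g2$trace)
  expect_s3_class(g1$events, "data.frame")
  expect_equal(g1$kernel_area, 2 - 0.75)
})

test_that("tracking generator: skill limit, error-scale linearity, determinism", {
  tr <- generate_tracking_trace(skill = Inf, duration = 60, seed = 3)
  expect_close(tr$ball_x, tr$target_x, 1e-12)
  expect_close(tr$ball_y, tr$target_y, 1e-12)
  expect_identical(generate_tracking_trace(seed = 5, duration = 30),
                   generate_tracking_trace(seed = 5, duration = 30))
  # doubling the error scale doubles cumulative error (Monte Carlo slope)
  ratio <- vapply(1:50, function(s) {
    t1 <- generate_tracking_trace(skill = 0, duration = 60, seed = s,
                                  base_error = 30)
    t2 <- generate_tracking_trace(skill = 0, duration = 60, seed = s,
                                  base_error = 60)
    tracking_errors(t2)$euclid_cum / tracking_errors(t1)$euclid_cum
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 2), 0.1)
  expect_error(generate_tracking_trace(skill = -1), "skill")
})

test_that("rating generator obeys its couplings", {
  cfg0 <- cohort_config(coupling_autonomic = 0, coupling_error = 0,
                        rating_noise_sd = 0)
  r <- generate_ratings(rnorm(100), rep(0, 100), runif(100, 1e3, 1e4), cfg0,
                        seed = 2)
  expect_true(all(r == 6))              # base level only
  # pure error coupling: strongly negative correlation with error
  cfg_e <- cohort_config(coupling_autonomic = 0, coupling_error = 1,
                         rating_noise_sd = 0)
  set.seed(31)
  err <- exp(rnorm(300, 9, 0.7))
  re <- generate_ratings(rnorm(300), rep(0, 300), err, cfg_e, seed = 3)
  expect_lt(cor(re, err), -0.7)
  # clipping to the scale
  expect_true(all(re >= 1 & re <= 9))
})
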
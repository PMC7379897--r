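# Shared fixtures, built in code. Heavier objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small cohort reused by several files (4 subjects, 1 day, 3 trials/cond).
tiny_cohort <- function(seed = 11L, ...) {
  key <- paste0("cohort_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohort_config(n_dyads = 2L, days = 1L,
                         trials_per_condition_per_day = 3L, seed = seed, ...)
    .fixture_env[[key]] <- generate_cohort(cfg)
  }
  .fixture_env[[key]]
}

# Gaussian toy dataset with cleanly separable classes.
separable_dataset <- function(n_per_class = 30L, n_classes = 3L, d = 2L,
                              gap = 6, seed = 5L, n_noise = 0L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    matrix(stats::rnorm(n_per_class * d, mean = gap * k), n_per_class, d)
  }))
  if (n_noise > 0L) {
    x <- cbind(x, matrix(stats::rnorm(nrow(x) * n_noise), nrow(x)))
  }
  colnames(x) <- c(paste0("inf", seq_len(d)),
                   if (n_noise > 0L) paste0("noise", seq_len(n_noise)))
  y <- rep(seq_len(n_classes), each = n_per_class)
  subj <- rep(sprintf("s%02d", 1:6), length.out = nrow(x))
  suppressWarnings(assemble_dataset(x, y, subj))
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %g", max(abs(object - expected))))
}
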
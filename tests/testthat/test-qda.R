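# Quadratic discriminant classifier, macro scoring, cross-validation.

test_that("fit_qda recovers well-separated class moments", {
  set.seed(1)
  x <- matrix(c(rnorm(200, 0), rnorm(200, 10)), ncol = 1)
  y <- rep(c(1, 2), each = 200)
  m <- fit_qda(x, y)
  expect_lt(abs(m$fit[[1]]$mu - 0), 0.3)
  expect_lt(abs(m$fit[[2]]$mu - 10), 0.3)
  expect_equal(m$fit[[1]]$prior, 0.5)
  # duplicating every sample leaves the model invariant
  m2 <- fit_qda(rbind(x, x), c(y, y))
  expect_equal(m$fit[[1]]$mu, m2$fit[[1]]$mu)
  expect_close(m$fit[[1]]$chol, m2$fit[[1]]$chol, 1e-9)
  expect_error(fit_qda(x[c(1, 201, 202), , drop = FALSE], c(1, 2, 2)),
               "class 1")
})

test_that("predict_qda equals the brute-force Gaussian density oracle", {
  set.seed(2)
  x <- rbind(matrix(rnorm(90, 0, 1), ncol = 3),
             matrix(rnorm(90, 2, 2), ncol = 3),
             matrix(rnorm(90, -2, 0.5), ncol = 3))
  y <- rep(1:3, each = 30)
  m <- fit_qda(x, y)
  xq <- matrix(rnorm(300, 0, 3), ncol = 3)
  pred <- predict_qda(m, xq)
  oracle <- apply(xq, 1, function(v) {
    dens <- vapply(1:3, function(k) {
      xi <- x[y == k, ]
      mu <- colMeans(xi)
      S <- stats::cov(xi) * (nrow(xi) - 1) / nrow(xi)  # ML covariance
      S <- S + 1e-6 * (sum(diag(S)) / 3) * diag(3)     # same ridge as fit_qda
      (1 / 3) * exp(-0.5 * stats::mahalanobis(v, mu, S)) / sqrt(det(S))
    }, numeric(1))
    which.max(dens)
  })
  expect_equal(pred, oracle)
  # x at a class mean of a widely separated class predicts that class
  expect_equal(predict_qda(m, m$fit[[3]]$mu), 3)
  expect_error(predict_qda(m, c(1, 2)), "dimension")
})

test_that("symmetric 1-D midpoint tie breaks to the lower class index", {
  x <- matrix(c(-3, -1, 1, 3), ncol = 1)
  y <- c(1, 1, 2, 2)
  m <- fit_qda(x, y)  # symmetric about 0, equal priors and variances
  expect_equal(predict_qda(m, matrix(0)), 1)
})

test_that("QDA reduces to an LDA oracle when covariances are tied", {
  set.seed(3)
  x <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 1.5), ncol = 2))
  y <- rep(1:2, each = 50)
  # pooled covariance forced into both classes
  mu1 <- colMeans(x[y == 1, ]); mu2 <- colMeans(x[y == 2, ])
  xc <- rbind(sweep(x[y == 1, ], 2, mu1), sweep(x[y == 2, ], 2, mu2))
  S <- crossprod(xc) / (nrow(x) - 2)
  r <- chol(S)
  m <- structure(list(classes = 1:2, d = 2, feature_names = NULL,
                      fit = list(
                        list(prior = 0.5, mu = mu1, chol = r,
                             logdet = 2 * sum(log(diag(r)))),
                        list(prior = 0.5, mu = mu2, chol = r,
                             logdet = 2 * sum(log(diag(r)))))),
                 class = "qda_model")
  xq <- matrix(rnorm(200, 0.75), ncol = 2)
  pred <- predict_qda(m, xq)
  Sinv <- solve(S)
  lda_oracle <- apply(xq, 1, function(v) {
    s1 <- v %*% Sinv %*% mu1 - 0.5 * mu1 %*% Sinv %*% mu1
    s2 <- v %*% Sinv %*% mu2 - 0.5 * mu2 %*% Sinv %*% mu2
    if (s1 >= s2) 1 else 2
  })
  expect_equal(pred, as.integer(lda_oracle))
})

test_that("macro scores: perfect, hand example, zero-division convention", {
  perfect <- macro_scores(diag(c(5, 7, 9)))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  # rows = true: [[5, 5], [0, 10]]
  sc <- macro_scores(matrix(c(5, 0, 5, 10), 2))
  expect_close(sc$recall, 0.75, 1e-12)
  expect_close(sc$precision, 5 / 6, 1e-12)
  expect_close(sc$f1, 2 / (1 / 0.75 + 1 / (5 / 6)), 1e-12)
  # class never predicted: finite scores
  skew <- macro_scores(matrix(c(4, 2, 0, 0), 2))
  expect_true(is.finite(skew$f1))
  expect_true(skew$f1 >= 0 && skew$f1 <= 1)
  expect_error(macro_scores(matrix(0, 2, 2)), "empty")
})

test_that("leave-one-sample-out: separable ~1, shuffled ~chance, conserved", {
  ds <- separable_dataset()
  res <- leave_one_sample_out(ds)
  expect_gt(res$scores$f1, 0.95)
  expect_equal(sum(res$confusion), ds$N - res$n_skipped)
  # shuffled labels give chance-level performance (3 balanced classes)
  ds_null <- ds
  set.seed(8)
  ds_null$labels <- sample(ds$labels)
  null_res <- suppressWarnings(leave_one_sample_out(ds_null))
  expect_lt(null_res$scores$f1, 0.55)
  # generic path (explicit fitter/predictor) agrees with downdating path
  gen <- leave_one_sample_out(ds, fitter = fit_qda, predictor = predict_qda)
  expect_identical(res$confusion, gen$confusion)
})

test_that("leave-one-subject-out partitions samples once each", {
  ds <- separable_dataset()
  res <- leave_one_subject_out(ds)
  expect_equal(sum(res$confusion), ds$N)
  expect_gt(res$scores$f1, 0.9)
  two_subj <- ds
  two_subj$subject_ids <- rep(c("a", "b"), length.out = ds$N)
  expect_error(leave_one_subject_out(two_subj), "3 subjects")
})

test_that("folds losing a class are skipped with a warning", {
  set.seed(4)
  x <- matrix(rnorm(42), ncol = 2)
  y <- c(rep(1, 10), rep(2, 9), rep(3, 2))   # class 3 has exactly 2 samples
  ds <- suppressWarnings(
    assemble_dataset(x, y, rep(sprintf("s%d", 1:3), 7)))
  expect_warning(res <- leave_one_sample_out(ds), "skipped")
  expect_equal(res$n_skipped, 2L)            # both class-3 folds
  expect_equal(sum(res$confusion), 19)
})
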
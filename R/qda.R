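# Quadratic discriminant classification, macro precision/recall/F1 scoring,
# and the two cross-validation schemes. Everything is written from first
# principles (Gaussian class-conditional densities, empirical priors, ridge
# regularisation) so the classifier is auditable against a density oracle.

chol_or_null <- function(m) tryCatch(chol(m), error = function(e) NULL)

regularize_cov <- function(sigma, ridge = 1e-6) {
  d <- ncol(sigma)
  scale <- sum(diag(sigma)) / d
  if (scale <= 0) scale <- 1
  lam <- ridge
  repeat {
    r <- chol_or_null(sigma + lam * scale * diag(d))
    if (!is.null(r)) return(list(chol = r, lambda = lam))
    lam <- lam * 10
    if (lam > 1e6) stop("covariance could not be regularised", call. = FALSE)
  }
}

#' Fit a quadratic discriminant model
#'
#' Per class: empirical prior, sample mean and maximum-likelihood covariance
#' (divisor n, the convention under which duplicating every sample leaves
#' the model exactly invariant), ridge-regularised as
#' `Sigma + lambda (tr Sigma / d) I` with `lambda` escalated tenfold until
#' the Cholesky factorisation succeeds.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y class labels (integer levels).
#' @param ridge starting ridge coefficient.
#' @return object of class `qda_model`.
#' @export
fit_qda <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  n <- nrow(x)
  fit <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    if (nrow(xi) < 2L) {
      stop(sprintf("class %s has fewer than 2 samples", cl), call. = FALSE)
    }
    mu <- colMeans(xi)
    sigma <- stats::cov(xi) * (nrow(xi) - 1) / nrow(xi)
    reg <- regularize_cov(sigma, ridge)
    list(prior = nrow(xi) / n, mu = mu, chol = reg$chol,
         logdet = 2 * sum(log(diag(reg$chol))), lambda = reg$lambda)
  })
  structure(list(classes = classes, fit = fit, d = ncol(x),
                 feature_names = colnames(x)),
            class = "qda_model")
}

#' Predict class labels with a quadratic discriminant model
#'
#' Assigns each sample to `argmax_l [log pi_l - 1/2 log|Sigma_l|
#' - 1/2 (x - mu_l)' Sigma_l^{-1} (x - mu_l)]`, ties broken toward the
#' lowest class index.
#'
#' @param model a [fit_qda()] model.
#' @param x feature matrix (or single vector) with the model's
#'   dimensionality.
#' @return integer vector of predicted class labels.
#' @export
predict_qda <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$d) stop("feature dimension mismatch", call. = FALSE)
  scores <- vapply(model$fit, function(f) {
    dx <- t(x) - f$mu
    z <- backsolve(f$chol, dx, transpose = TRUE)
    log(f$prior) - 0.5 * f$logdet - 0.5 * colSums(z^2)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) scores <- matrix(scores, nrow = 1L)
  model$classes[max.col(scores, ties.method = "first")]
}

#' Confusion matrix over a fixed class set
#'
#' @param true,pred label vectors.
#' @param classes ordered class set defining rows/columns.
#' @return integer matrix `counts[true, predicted]`.
#' @export
confusion_matrix <- function(true, pred, classes = sort(unique(true))) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(true)) {
    cm[match(true[i], classes), match(pred[i], classes)] <-
      cm[match(true[i], classes), match(pred[i], classes)] + 1L
  }
  cm
}

#' Macro precision, recall and F1 from a confusion matrix
#'
#' Recall is the class-averaged TP/P, precision the class-averaged
#' TP/(TP + FP); classes with empty denominator contribute 0 to the
#' respective average. F1 is the harmonic mean of the two (0 when both are
#' 0).
#'
#' @param cm square confusion matrix, rows = true classes.
#' @return list of class `score_report`: `f1`, `precision`, `recall`,
#'   `n_test`.
#' @export
macro_scores <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  p <- rowSums(cm)
  predp <- colSums(cm)
  recall <- mean(ifelse(p > 0, tp / p, 0))
  precision <- mean(ifelse(predp > 0, tp / predp, 0))
  f1 <- if (recall + precision > 0) {
    2 / (1 / recall + 1 / precision)
  } else 0
  structure(list(f1 = f1, precision = precision, recall = recall,
                 n_test = sum(cm)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("F1 %.3f  precision %.3f  recall %.3f  (n = %d%s)\n",
              x$f1, x$precision, x$recall, x$n_test,
              if (!is.null(x$p_value)) sprintf(", p = %.4g", x$p_value)
              else ""))
  invisible(x)
}

# Sufficient statistics per class for O(d^2) leave-one-out downdating:
# holding out one sample only touches its own class's sum and crossproduct.
class_stats <- function(x, y, classes) {
  lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(n = nrow(xi), s = colSums(xi), q = crossprod(xi))
  })
}

model_from_stats <- function(stats_list, classes, n_total, ridge, d,
                             feature_names) {
  fit <- lapply(stats_list, function(st) {
    mu <- st$s / st$n
    sigma <- (st$q - st$n * tcrossprod(mu)) / st$n
    sigma <- (sigma + t(sigma)) / 2
    reg <- regularize_cov(sigma, ridge)
    list(prior = st$n / n_total, mu = mu, chol = reg$chol,
         logdet = 2 * sum(log(diag(reg$chol))), lambda = reg$lambda)
  })
  structure(list(classes = classes, fit = fit, d = d,
                 feature_names = feature_names),
            class = "qda_model")
}

# Internal engine shared by both CV schemes: `folds` is a list of integer
# index vectors to hold out. A fold is skipped (with one collected warning)
# when the training remainder leaves any class with fewer than 2 samples.
cv_engine <- function(dataset, folds, fitter = NULL, predictor = NULL,
                      ridge = 1e-6) {
  x <- dataset$features
  y <- dataset$labels
  classes <- sort(unique(y))
  n <- nrow(x)
  fast <- is.null(fitter) && is.null(predictor)
  if (is.null(fitter)) fitter <- fit_qda
  if (is.null(predictor)) predictor <- predict_qda
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  n_skipped <- 0L
  if (fast) stats_full <- class_stats(x, y, classes)
  for (fold in folds) {
    ytr <- y[-fold]
    cnt <- tabulate(match(ytr, classes), nbins = length(classes))
    if (any(cnt < 2L)) { n_skipped <- n_skipped + 1L; next }
    if (fast) {
      st <- stats_full
      for (i in fold) {
        ci <- match(y[i], classes)
        st[[ci]] <- list(n = st[[ci]]$n - 1L,
                         s = st[[ci]]$s - x[i, ],
                         q = st[[ci]]$q - tcrossprod(x[i, ]))
      }
      model <- model_from_stats(st, classes, n - length(fold), ridge,
                                ncol(x), colnames(x))
    } else {
      model <- fitter(x[-fold, , drop = FALSE], ytr)
    }
    pred <- predictor(model, x[fold, , drop = FALSE])
    for (j in seq_along(fold)) {
      cm[match(y[fold[j]], classes), match(pred[j], classes)] <-
        cm[match(y[fold[j]], classes), match(pred[j], classes)] + 1L
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d fold(s) skipped: a training class dropped below 2 samples",
                    n_skipped), call. = FALSE)
  }
  if (sum(cm) == 0) {
    stop("all cross-validation folds were skipped; the dataset is too small ",
         "for its class structure (reduce L or enlarge the cohort)",
         call. = FALSE)
  }
  scores <- macro_scores(cm)
  scores$n_skipped <- n_skipped
  list(scores = scores, confusion = cm, n_skipped = n_skipped)
}

#' Leave-one-sample-out cross-validation
#'
#' Trains on N - 1 samples and predicts the held-out one, for every sample;
#' the confusion matrix is aggregated over all scored folds and summarised
#' by [macro_scores()]. Folds whose training remainder loses a class (fewer
#' than 2 samples) are skipped with a warning. With the default fitter the
#' per-fold model is obtained by exact downdating of the class sufficient
#' statistics, which is algebraically identical to refitting.
#'
#' @param dataset a [assemble_dataset()] result (or any list with `features`
#'   and `labels`).
#' @param fitter,predictor optional replacements for [fit_qda()] /
#'   [predict_qda()]; supplying either disables the fast path.
#' @param ridge ridge coefficient passed to the default fitter.
#' @return list with `scores` (a `score_report`), `confusion`, `n_skipped`.
#' @export
leave_one_sample_out <- function(dataset, fitter = NULL, predictor = NULL,
                                 ridge = 1e-6) {
  n <- nrow(dataset$features)
  cls <- unique(dataset$labels)
  if (n < length(cls) + 1L) stop("too few samples for leave-one-sample-out",
                                 call. = FALSE)
  cv_engine(dataset, as.list(seq_len(n)), fitter, predictor, ridge)
}

#' Leave-one-subject-out cross-validation (the population model)
#'
#' One fold per subject: the classifier is trained on all other subjects and
#' tested on every sample of the held-out subject.
#'
#' @inheritParams leave_one_sample_out
#' @return as [leave_one_sample_out()].
#' @export
leave_one_subject_out <- function(dataset, fitter = NULL, predictor = NULL,
                                  ridge = 1e-6) {
  subjects <- unique(dataset$subject_ids)
  if (length(subjects) < 3L) stop("need >= 3 subjects", call. = FALSE)
  folds <- lapply(subjects, function(s) which(dataset$subject_ids == s))
  cv_engine(dataset, folds, fitter, predictor, ridge)
}
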
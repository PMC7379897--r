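# Backward feature selection, N(N-1) sample-substitution permutation
# importance, and the label-permutation significance test.

subset_dataset <- function(dataset, cols) {
  out <- dataset
  out$features <- dataset$features[, cols, drop = FALSE]
  out
}

#' Greedy backward feature selection
#'
#' Starting from the full feature set, each feature is temporarily omitted
#' and the dataset rescored; the omission that yields the strongest strict
#' F1 increase is made permanent. The loop stops when no removal strictly
#' improves the score or one feature remains.
#'
#' @param dataset a [assemble_dataset()] result with >= 2 features.
#' @param scorer function(dataset) -> list with `$scores$f1`; defaults to
#'   [leave_one_sample_out()].
#' @return list of class `selection_trace`: `steps` (data.frame of removed
#'   features and the F1 after each accepted removal), `features` (final
#'   set), `f1` (final F1), `f1_full` (full-set F1).
#' @export
backward_select <- function(dataset, scorer = leave_one_sample_out) {
  feats <- colnames(dataset$features)
  if (is.null(feats)) feats <- as.character(seq_len(ncol(dataset$features)))
  colnames(dataset$features) <- feats
  if (length(feats) < 2L) {
    sc <- scorer(dataset)$scores$f1
    return(structure(list(steps = data.frame(removed = character(),
                                             f1 = numeric()),
                          features = feats, f1 = sc, f1_full = sc),
                     class = "selection_trace"))
  }
  current <- feats
  f1_full <- suppressWarnings(scorer(dataset)$scores$f1)
  f1_cur <- f1_full
  steps <- list()
  while (length(current) > 1L) {
    cand_f1 <- vapply(current, function(f) {
      suppressWarnings(
        scorer(subset_dataset(dataset, setdiff(current, f)))$scores$f1)
    }, numeric(1))
    best <- which.max(cand_f1)
    if (cand_f1[best] <= f1_cur) break
    f1_cur <- cand_f1[best]
    steps[[length(steps) + 1L]] <- data.frame(removed = current[best],
                                              f1 = f1_cur)
    current <- setdiff(current, current[best])
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(removed = character(), f1 = numeric()),
    features = current, f1 = f1_cur, f1_full = f1_full),
    class = "selection_trace")
}

#' Sample-substitution permutation importance of one feature
#'
#' For each original sample i the classifier is trained on the other N - 1
#' samples (exactly as in leave-one-sample-out) and then evaluated on the
#' N - 1 variants of sample i in which the target feature's value is
#' replaced by its value in every other sample, giving N(N - 1) evaluations
#' in total. The importance is the baseline leave-one-sample-out F1 minus
#' the F1 of this substituted evaluation.
#'
#' @param dataset a [assemble_dataset()] result.
#' @param feature feature name (or column index).
#' @param baseline_f1 optional precomputed baseline; computed when `NULL`.
#' @param max_variants optional cap on the number of substituted variants
#'   per sample (drawn deterministically from `seed`) for large N.
#' @param seed seed for the variant subsample.
#' @param ridge ridge coefficient for the QDA fits.
#' @return list of class `importance_entry`: `feature`, `delta_f1`,
#'   `f1_permuted`, `f1_baseline`.
#' @export
permutation_importance <- function(dataset, feature, baseline_f1 = NULL,
                                   max_variants = NULL, seed = 1L,
                                   ridge = 1e-6) {
  x <- dataset$features
  y <- dataset$labels
  n <- nrow(x)
  if (is.character(feature)) {
    fidx <- match(feature, colnames(x))
    if (is.na(fidx)) stop(sprintf("unknown feature `%s`", feature),
                          call. = FALSE)
  } else fidx <- feature
  if (is.null(baseline_f1)) {
    baseline_f1 <- suppressWarnings(
      leave_one_sample_out(dataset, ridge = ridge)$scores$f1)
  }
  classes <- sort(unique(y))
  stats_full <- class_stats(x, y, classes)
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  donor_sets <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  if (!is.null(max_variants)) {
    donor_sets <- with_seed(seed, lapply(donor_sets, function(dn) {
      if (length(dn) > max_variants) sample(dn, max_variants) else dn
    }))
  }
  for (i in seq_len(n)) {
    ci <- match(y[i], classes)
    st <- stats_full
    st[[ci]] <- list(n = st[[ci]]$n - 1L, s = st[[ci]]$s - x[i, ],
                     q = st[[ci]]$q - tcrossprod(x[i, ]))
    cnt <- vapply(st, `[[`, numeric(1), "n")
    if (any(cnt < 2L)) next
    model <- model_from_stats(st, classes, n - 1L, ridge, ncol(x),
                              colnames(x))
    donors <- donor_sets[[i]]
    xv <- matrix(x[i, ], nrow = length(donors), ncol = ncol(x), byrow = TRUE)
    xv[, fidx] <- x[donors, fidx]
    pred <- predict_qda(model, xv)
    for (p in pred) {
      cm[ci, match(p, classes)] <- cm[ci, match(p, classes)] + 1L
    }
  }
  f1p <- macro_scores(cm)$f1
  structure(list(feature = if (is.character(feature)) feature else
    colnames(x)[fidx], delta_f1 = baseline_f1 - f1p,
    f1_permuted = f1p, f1_baseline = baseline_f1),
    class = "importance_entry")
}

#' Importance table for every feature of a dataset
#'
#' @inheritParams permutation_importance
#' @return data.frame with `feature`, `delta_f1`, `rank` (1 = most
#'   important).
#' @export
importance_table <- function(dataset, max_variants = NULL, seed = 1L,
                             ridge = 1e-6) {
  base <- suppressWarnings(
    leave_one_sample_out(dataset, ridge = ridge)$scores$f1)
  feats <- colnames(dataset$features)
  rows <- lapply(feats, function(f) {
    e <- permutation_importance(dataset, f, baseline_f1 = base,
                                max_variants = max_variants, seed = seed,
                                ridge = ridge)
    data.frame(feature = f, delta_f1 = e$delta_f1)
  })
  out <- do.call(rbind, rows)
  out$rank <- rank(-out$delta_f1, ties.method = "first")
  out[order(out$rank), ]
}

#' Label-permutation significance test for a classifier score
#'
#' The observed cross-validated F1 is compared with the distribution of F1
#' scores obtained after randomly permuting the class labels; the p-value
#' uses the add-one correction `p = (1 + #{F1_perm >= F1_obs}) /
#' (n_perm + 1)`, so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param dataset a [assemble_dataset()] result.
#' @param scorer function(dataset) -> list with `$scores$f1`.
#' @param n_perm number of label permutations (the emulated analysis used
#'   1000).
#' @param seed integer seed for the permutations.
#' @return list: `p_value`, `f1_observed`, `f1_permuted` (vector).
#' @export
permutation_test <- function(dataset, scorer = leave_one_sample_out,
                             n_perm = 1000L, seed = 1L) {
  check_count(n_perm, "n_perm")
  obs <- suppressWarnings(scorer(dataset)$scores$f1)
  perm_seeds <- derive_seeds(seed, n_perm, stream = 7L)
  f1p <- vapply(seq_len(n_perm), function(b) {
    ds <- dataset
    ds$labels <- with_seed(perm_seeds[b], sample(dataset$labels))
    suppressWarnings(scorer(ds)$scores$f1)
  }, numeric(1))
  list(p_value = (1 + sum(f1p >= obs)) / (n_perm + 1),
       f1_observed = obs, f1_permuted = f1p)
}

#' Benjamini-Hochberg step-up significance mask
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q false discovery rate level.
#' @return logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_adjust_suite <- function(p, q = 0.05) {
  if (length(p) < 1L) stop("need >= 1 p-value", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}
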
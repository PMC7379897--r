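# Pipeline orchestration: simulate -> features -> prep -> classify ->
# select -> importance -> correlate -> report.

#' Autonomic features and tracking errors for every subject-trial
#'
#' The workhorse table: one row per subject-trial with identifiers, the 23
#' autonomic parameters, the three cumulative tracking errors (own axis,
#' partner axis, Euclidean) and the raw ratings.
#'
#' @param cohort a `dyadphys_cohort`.
#' @param spec a [spectral_config()] for the HRV band powers.
#' @param include_autonomic compute the 23 signal-derived parameters; set
#'   `FALSE` for behavioural-only analyses (tracking errors and ratings),
#'   which skips all signal processing.
#' @return data.frame with `length(cohort$trials)` rows.
#' @export
cohort_features <- function(cohort, spec = spectral_config(),
                            include_autonomic = TRUE) {
  stopifnot(inherits(cohort, "dyadphys_cohort"))
  rows <- lapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]
    feats <- if (include_autonomic) {
      c(hrv_features(nn_series(tr$rpeaks), spec),
        resp_features(tr$resp, tr$fs),
        eda_features(tr$eda, tr$fs))
    } else {
      stats::setNames(as.list(rep(NA_real_,
                                  length(autonomic_parameter_names()))),
                      autonomic_parameter_names())
    }
    err <- tracking_errors(tr$tracking)
    own <- if (tr$own_axis == "x") err$x_cum else err$y_cum
    partner <- if (tr$own_axis == "x") err$y_cum else err$x_cum
    cbind(data.frame(dyad = tr$dyad_id, subject = tr$subject_id,
                     day = tr$day, condition = tr$condition,
                     trial = tr$trial_index),
          as.data.frame(feats[autonomic_parameter_names()]),
          data.frame(err_own = own, err_partner = partner,
                     err_euclid = err$euclid_cum,
                     R1 = tr$ratings$R1,
                     R2 = if (is.null(tr$ratings$R2)) NA_integer_ else
                       tr$ratings$R2,
                     R3 = if (is.null(tr$ratings$R3)) NA_integer_ else
                       tr$ratings$R3))
  })
  do.call(rbind, rows)
}

# The four analysis cells of the design: rating kind x condition.
analysis_cells <- function() {
  data.frame(rating = c("R1", "R2", "R3", "R1"),
             condition = c("collaborative", "collaborative",
                           "collaborative", "individual"),
             stringsAsFactors = FALSE)
}

error_column_for <- function(rating) {
  switch(rating, R1 = "err_own", R2 = "err_partner", R3 = "err_euclid")
}

#' Build the labelled dataset for one analysis cell
#'
#' Restricts the feature table to the cell's condition, applies per-cell
#' rating outlier correction and retains the `L` most frequent rating
#' levels, then assembles the normalised dataset for the requested
#' predictor set (all 23 autonomic parameters, the single matched tracking
#' error, or one named parameter).
#'
#' @param feats a [cohort_features()] table.
#' @param rating `"R1"`, `"R2"` or `"R3"`.
#' @param condition `"collaborative"` or `"individual"`.
#' @param predictor `"autonomic"`, `"objective"`, or one autonomic
#'   parameter name for single-parameter sweeps.
#' @param L number of rating levels retained.
#' @param correct_outliers apply [correct_rating_outliers()] first.
#' @param min_per_level drop rating levels with fewer samples than this
#'   (levels that thin cannot contribute a class covariance; small-cohort
#'   guard, inactive at realistic sizes).
#' @return a `labeled_dataset`.
#' @export
cell_dataset <- function(feats, rating = "R1", condition = "collaborative",
                         predictor = "autonomic", L = 6L,
                         correct_outliers = TRUE, min_per_level = 2L) {
  sub <- feats[feats$condition == condition & !is.na(feats[[rating]]), ]
  labels <- sub[[rating]]
  if (correct_outliers && length(unique(sub$subject)) >= 3L) {
    labels <- correct_rating_outliers(labels, sub$subject)$ratings
  }
  sel <- select_rating_levels(labels, L = L)
  sub <- sub[sel$keep, ]
  labels <- labels[sel$keep]
  counts <- table(labels)
  ok_levels <- as.numeric(names(counts))[counts >= min_per_level]
  sub <- sub[labels %in% ok_levels, ]
  labels <- labels[labels %in% ok_levels]
  cols <- if (identical(predictor, "autonomic")) {
    autonomic_parameter_names()
  } else if (identical(predictor, "objective")) {
    error_column_for(rating)
  } else {
    if (!predictor %in% autonomic_parameter_names()) {
      stop(sprintf("unknown predictor `%s`", predictor), call. = FALSE)
    }
    predictor
  }
  x <- as.matrix(sub[, cols, drop = FALSE])
  # r_RR and LF/HF can be undefined on degenerate series; impute at the
  # column mean before normalisation (rare in practice).
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- mean(x[!bad, j])
  }
  suppressWarnings(
    assemble_dataset(x, labels, sub$subject, rating_kind = rating,
                     condition = condition, predictor = predictor))
}

#' Run configuration for the full pipeline
#'
#' @param cohort a `cohort_config`, an existing `dyadphys_cohort`, or a path
#'   to a cohort directory written by [write_cohort()].
#' @param n_perm label permutations per classifier cell (0 disables the
#'   significance tests).
#' @param run_selection,run_importance toggle the backward-selection and
#'   permutation-importance stages (autonomic predictor only).
#' @param L retained rating levels.
#' @param seed master seed for permutations and subsampling.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), n_perm = 1000L,
                       run_selection = TRUE, run_importance = TRUE,
                       L = 6L, seed = 1L, out_dir = NULL) {
  structure(list(cohort = cohort, n_perm = n_perm,
                 run_selection = run_selection,
                 run_importance = run_importance, L = L, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, extracts the 23 autonomic parameters and
#' tracking errors per subject-trial, preprocesses ratings, and for each of
#' the 4 analysis cells (R1/R2/R3 collaborative, R1 individual) x 2
#' predictor sets (aggregated autonomic, matched tracking error) x 2
#' cross-validation schemes computes macro precision/recall/F1 and, when
#' `n_perm > 0`, a label-permutation p-value. Optionally runs backward
#' feature selection and permutation importance on the autonomic sets, and
#' the dyad- and subject-level correlation analyses.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with `features`, `scores`
#'   (data.frame of 16 rows under the defaults), `selection`, `importance`,
#'   `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config$cohort
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "dyadphys_cohort")) {
    stop("stage simulate: config$cohort is not a cohort, cohort_config or path",
         call. = FALSE)
  }
  feats <- cohort_features(cohort)
  cells <- analysis_cells()
  scores <- list()
  selection <- list()
  importance <- list()
  cell_seeds <- derive_seeds(config$seed, nrow(cells) * 2L, stream = 11L)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (pred in c("autonomic", "objective")) {
      k <- k + 1L
      ds <- cell_dataset(feats, cells$rating[ci], cells$condition[ci],
                         predictor = pred, L = config$L)
      cell_id <- sprintf("%s:%s:%s", cells$rating[ci], cells$condition[ci],
                         pred)
      use_feats <- colnames(ds$features)
      if (pred == "autonomic" && config$run_selection) {
        tr <- backward_select(ds)
        selection[[cell_id]] <- tr
        use_feats <- tr$features
      }
      ds_used <- subset_dataset(ds, use_feats)
      for (scheme in c("sample", "subject")) {
        scorer <- if (scheme == "sample") leave_one_sample_out else
          leave_one_subject_out
        res <- suppressWarnings(scorer(ds_used))
        p <- NA_real_
        if (config$n_perm > 0) {
          p <- permutation_test(ds_used, scorer, n_perm = config$n_perm,
                                seed = cell_seeds[k])$p_value
        }
        scores[[length(scores) + 1L]] <- data.frame(
          rating = cells$rating[ci], condition = cells$condition[ci],
          predictor = pred, cv = scheme,
          f1 = res$scores$f1, p = p,
          precision = res$scores$precision, recall = res$scores$recall,
          n = ds_used$N, n_features = length(use_feats))
      }
      if (pred == "autonomic" && config$run_importance) {
        importance[[cell_id]] <- importance_table(ds_used,
                                                  seed = cell_seeds[k])
      }
    }
  }
  scores <- do.call(rbind, scores)
  correlations <- list(
    dyad = dyad_rating_correlations(cohort),
    subject = subject_rating_error_correlations(cohort))
  manifest <- list(seed = config$seed, n_perm = config$n_perm,
                   L = config$L,
                   cohort_config = unclass(cohort$config),
                   n_subject_trials = length(cohort$trials),
                   package_version = as.character(
                     utils::packageVersion("dyadphys")))
  result <- structure(list(features = feats, scores = scores,
                           selection = selection, importance = importance,
                           correlations = correlations, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

#' Format pipeline scores as one table per cross-validation scheme
#'
#' Column layout mirrors the conventional reporting: per predictor set the
#' F1-score, permutation p, precision and recall, one row per analysis
#' cell, one table per CV scheme.
#'
#' @param results a `pipeline_result` (or its `scores` data.frame).
#' @return named list of data.frames (`sample`, `subject`).
#' @export
report_tables <- function(results) {
  sc <- if (inherits(results, "pipeline_result")) results$scores else results
  empty <- data.frame(rating = character(), condition = character(),
                      f1_autonomic = numeric(), p_autonomic = numeric(),
                      prec_autonomic = numeric(), recall_autonomic = numeric(),
                      f1_objective = numeric(), p_objective = numeric(),
                      prec_objective = numeric(), recall_objective = numeric())
  out <- list(sample = empty, subject = empty)
  if (is.null(sc) || nrow(sc) == 0L) return(out)
  for (scheme in c("sample", "subject")) {
    ss <- sc[sc$cv == scheme, ]
    if (nrow(ss) == 0L) next
    au <- ss[ss$predictor == "autonomic", ]
    ob <- ss[ss$predictor == "objective", ]
    key <- paste(au$rating, au$condition)
    ob <- ob[match(key, paste(ob$rating, ob$condition)), ]
    out[[scheme]] <- data.frame(
      rating = au$rating, condition = au$condition,
      f1_autonomic = au$f1, p_autonomic = au$p,
      prec_autonomic = au$precision, recall_autonomic = au$recall,
      f1_objective = ob$f1, p_objective = ob$p,
      prec_objective = ob$precision, recall_objective = ob$recall)
  }
  out
}

write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(result$correlations$dyad,
                   file.path(out_dir, "correlations_dyad.csv"),
                   row.names = FALSE)
  utils::write.csv(result$correlations$subject,
                   file.path(out_dir, "correlations_subject.csv"),
                   row.names = FALSE)
  for (cell in names(result$selection)) {
    fn <- gsub("[^A-Za-z0-9]+", "_", cell)
    utils::write.csv(result$selection[[cell]]$steps,
                     file.path(out_dir, sprintf("selection_%s.csv", fn)),
                     row.names = FALSE)
  }
  for (cell in names(result$importance)) {
    fn <- gsub("[^A-Za-z0-9]+", "_", cell)
    utils::write.csv(result$importance[[cell]],
                     file.path(out_dir, sprintf("importance_%s.csv", fn)),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
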
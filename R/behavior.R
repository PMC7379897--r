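# Objective tracking errors, rating preprocessing, and assembly of the
# pooled labelled dataset.

#' Cumulative tracking errors for one trial
#'
#' Sums, over logged samples (no time weighting), the Euclidean and per-axis
#' absolute distances between ball and target.
#'
#' @param trace data.frame with columns `ball_x`, `ball_y`, `target_x`,
#'   `target_y` (equal lengths).
#' @return list with `euclid_cum`, `x_cum`, `y_cum` in pixels.
#' @export
tracking_errors <- function(trace) {
  need <- c("ball_x", "ball_y", "target_x", "target_y")
  if (!all(need %in% names(trace))) {
    stop("tracking trace must contain ball/target x/y columns", call. = FALSE)
  }
  len <- lengths(trace[need])
  if (length(unique(len)) != 1L) stop("tracking columns differ in length",
                                      call. = FALSE)
  if (len[1] < 1L) stop("tracking trace is empty", call. = FALSE)
  dx <- trace$ball_x - trace$target_x
  dy <- trace$ball_y - trace$target_y
  list(euclid_cum = sum(sqrt(dx^2 + dy^2)),
       x_cum = sum(abs(dx)),
       y_cum = sum(abs(dy)))
}

#' Tracking error matched to a rating kind
#'
#' R1 (own performance) uses the cumulative error along the axis the subject
#' controlled, R2 (partner performance) the partner's axis, R3
#' (collaboration) the cumulative Euclidean distance.
#'
#' @param kind one of `"R1"`, `"R2"`, `"R3"`.
#' @param own_axis `"x"` or `"y"`, the axis the rating subject controlled.
#' @param err an error triple from [tracking_errors()].
#' @param condition `"collaborative"` or `"individual"`; R2/R3 are only
#'   defined after collaborative trials.
#' @return scalar error in pixels.
#' @export
error_for_rating <- function(kind = c("R1", "R2", "R3"),
                             own_axis = c("x", "y"), err,
                             condition = "collaborative") {
  kind <- match.arg(kind)
  own_axis <- match.arg(own_axis)
  if (condition == "individual" && kind != "R1") {
    stop(sprintf("protocol error: %s is not collected after individual trials",
                 kind), call. = FALSE)
  }
  switch(kind,
         R1 = if (own_axis == "x") err$x_cum else err$y_cum,
         R2 = if (own_axis == "x") err$y_cum else err$x_cum,
         R3 = err$euclid_cum)
}

#' Correct outlying raters by median alignment
#'
#' Computes each subject's median rating; a subject whose median lies more
#' than 1.5 interquartile ranges above the upper quartile or below the lower
#' quartile of the set of per-subject medians (quartiles by linear
#' interpolation) has all ratings shifted by minus the difference between
#' their own median and the median of all other subjects' medians, rounded
#' to the nearest integer and clipped to the rating scale.
#'
#' @param ratings numeric vector of ratings.
#' @param subjects subject id aligned with `ratings`.
#' @param scale integer rating scale for clipping.
#' @return list with `ratings` (corrected vector) and `report` (data.frame
#'   of corrected subjects with their median and applied shift).
#' @export
correct_rating_outliers <- function(ratings, subjects, scale = 1:9) {
  ok <- !is.na(ratings)
  subj_levels <- unique(subjects[ok])
  if (length(subj_levels) < 3L) stop("need >= 3 subjects", call. = FALSE)
  med <- vapply(subj_levels,
                function(s) stats::median(ratings[ok & subjects == s]),
                numeric(1))
  q <- stats::quantile(med, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  flagged <- med > q[2] + 1.5 * iqr | med < q[1] - 1.5 * iqr
  out <- ratings
  rep_rows <- list()
  for (i in which(flagged)) {
    s <- subj_levels[i]
    shift <- -(med[i] - stats::median(med[-i]))
    sel <- ok & subjects == s
    out[sel] <- pmin(max(scale), pmax(min(scale), round(ratings[sel] + shift)))
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(subject = s, median = med[i], shift = shift)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(subject = character(), median = numeric(), shift = numeric())
  list(ratings = out, report = report)
}

#' Keep only the most frequent rating levels
#'
#' Retains samples whose label is among the `L` most frequent levels.
#' Frequency ties at the boundary are broken toward the level closer to the
#' grand median of the labels, then toward the lower level, making the
#' retained set deterministic.
#'
#' @param labels integer rating labels.
#' @param L number of levels to retain.
#' @return list with `keep` (logical mask), `levels` (retained level set,
#'   sorted) and `n_discarded`.
#' @export
select_rating_levels <- function(labels, L = 6L) {
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  tab <- table(labels)
  lv <- as.numeric(names(tab))
  if (length(lv) <= L) {
    return(list(keep = rep(TRUE, length(labels)), levels = sort(lv),
                n_discarded = 0L))
  }
  gm <- stats::median(labels)
  ord <- order(-as.numeric(tab), abs(lv - gm), lv)
  retained <- sort(lv[ord[seq_len(L)]])
  keep <- labels %in% retained
  list(keep = keep, levels = retained, n_discarded = sum(!keep))
}

#' Assemble a pooled, normalised labelled dataset
#'
#' Applies per-feature min-max normalisation to the pooled feature matrix
#' (constant columns map to 0 with a warning) and bundles labels and subject
#' ids for the classifiers.
#'
#' @param features numeric matrix or data.frame (rows = subject-trials).
#' @param labels integer rating labels, one per row.
#' @param subject_ids subject id per row.
#' @param rating_kind,condition,predictor metadata strings carried along.
#' @return object of class `labeled_dataset`.
#' @export
assemble_dataset <- function(features, labels, subject_ids,
                             rating_kind = "R1", condition = "collaborative",
                             predictor = "autonomic") {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) != length(labels) || nrow(x) != length(subject_ids)) {
    stop("features, labels and subject_ids must align row-wise",
         call. = FALSE)
  }
  if (anyNA(x)) stop("missing feature value for a retained trial",
                     call. = FALSE)
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (rng[2] > rng[1]) {
      x[, j] <- (x[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      warning(sprintf("feature `%s` is constant; normalised to 0",
                      colnames(x)[j]), call. = FALSE)
      x[, j] <- 0
    }
  }
  structure(list(features = x, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 rating_kind = rating_kind, condition = condition,
                 predictor = predictor, N = nrow(x)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset: %d samples x %d features (%s, %s, %s), %d classes\n",
    x$N, ncol(x$features), x$rating_kind, x$condition, x$predictor,
    length(unique(x$labels))))
  invisible(x)
}
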
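# Correlation analyses of the behavioural data: rating-rating correlations
# within dyads, rating-error correlations within subjects, Wilcoxon
# signed-rank tests on correlation distributions, and the paired t-test on
# tracking errors.

#' Pearson correlation with a t-transform p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `r`, `p` (two-sided, t distribution with n - 2 df), `n`.
#'   Zero variance in either input yields `r = NA`, `p = NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Between-partner rating correlations per dyad
#'
#' For every dyad, pairs the collaborative trials of the two partners by day
#' and trial index and computes Pearson correlations between all 3 x 3
#' combinations of the ratings R1-R3 of partner x and partner y. Each pair
#' panel receives a Benjamini-Hochberg significance flag across dyads.
#'
#' @param cohort a `dyadphys_cohort` (or its `ratings` data.frame).
#' @param q FDR level for the per-panel significance flags.
#' @return data.frame: `dyad`, `pair`, `r`, `p`, `n`, `significant`.
#' @export
dyad_rating_correlations <- function(cohort, q = 0.05) {
  ratings <- if (inherits(cohort, "dyadphys_cohort")) cohort$ratings else cohort
  rc <- ratings[ratings$condition == "collaborative", ]
  rows <- list()
  for (d in unique(rc$dyad)) {
    rd <- rc[rc$dyad == d, ]
    subs <- sort(unique(rd$subject))
    if (length(subs) != 2L) next
    a <- rd[rd$subject == subs[1], ]
    b <- rd[rd$subject == subs[2], ]
    key_a <- paste(a$day, a$trial)
    key_b <- paste(b$day, b$trial)
    common <- intersect(key_a, key_b)
    if (length(common) < 3L) {
      message(sprintf("dyad %s skipped: fewer than 3 paired trials", d))
      next
    }
    a <- a[match(common, key_a), ]
    b <- b[match(common, key_b), ]
    for (ri in c("R1", "R2", "R3")) {
      for (rj in c("R1", "R2", "R3")) {
        pr <- pearson_r(a[[ri]], b[[rj]])
        rows[[length(rows) + 1L]] <- data.frame(
          dyad = d, pair = paste0(ri, "-", rj),
          r = pr$r, p = pr$p, n = pr$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- FALSE
  for (pp in unique(out$pair)) {
    sel <- out$pair == pp & !is.na(out$p)
    if (any(sel)) out$significant[sel] <- fdr_adjust_suite(out$p[sel], q)
  }
  out
}

#' Within-subject correlations between ratings and tracking errors
#'
#' Per subject (days pooled): R1 in the collaborative condition against the
#' cumulative error on the subject's own axis, R2 against the partner-axis
#' error, R3 against the cumulative Euclidean error, and R1 in the
#' individual condition against the own-axis error. Under error coupling
#' these correlations are expected to be negative (higher error, lower
#' rating). Subjects with constant ratings yield `r = NA` and are excluded
#' from downstream distribution tests.
#'
#' @param cohort a `dyadphys_cohort`.
#' @param q FDR level for per-panel significance flags.
#' @return data.frame: `subject`, `pair`, `r`, `p`, `n`, `significant`.
#' @export
subject_rating_error_correlations <- function(cohort, q = 0.05) {
  stopifnot(inherits(cohort, "dyadphys_cohort"))
  errs <- lapply(cohort$trials, function(tr) tracking_errors(tr$tracking))
  tab <- cohort$ratings
  tab$err_own <- vapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]
    if (tr$own_axis == "x") errs[[i]]$x_cum else errs[[i]]$y_cum
  }, numeric(1))
  tab$err_partner <- vapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]
    if (tr$own_axis == "x") errs[[i]]$y_cum else errs[[i]]$x_cum
  }, numeric(1))
  tab$err_euclid <- vapply(errs, `[[`, numeric(1), "euclid_cum")
  panels <- list(
    `R1collab-err_own` = list("R1", "err_own", "collaborative"),
    `R2-err_partner` = list("R2", "err_partner", "collaborative"),
    `R3-err_euclid` = list("R3", "err_euclid", "collaborative"),
    `R1indiv-err_own` = list("R1", "err_own", "individual"))
  rows <- list()
  for (pp in names(panels)) {
    spec <- panels[[pp]]
    sub <- tab[tab$condition == spec[[3]], ]
    for (s in unique(sub$subject)) {
      ss <- sub[sub$subject == s, ]
      if (nrow(ss) < 3L) {
        message(sprintf("subject %s skipped in %s: fewer than 3 trials",
                        s, pp))
        next
      }
      pr <- pearson_r(ss[[spec[[1]]]], ss[[spec[[2]]]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, pair = pp, r = pr$r, p = pr$p, n = pr$n)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- FALSE
  for (pp in unique(out$pair)) {
    sel <- out$pair == pp & !is.na(out$p)
    if (any(sel)) out$significant[sel] <- fdr_adjust_suite(out$p[sel], q)
  }
  out
}

#' Wilcoxon signed-rank test that a distribution's median is zero
#'
#' Zeros are dropped (standard signed-rank convention). For n <= 25 without
#' ties in the absolute values the exact signed-rank null distribution is
#' used; otherwise a normal approximation with continuity and tie
#' correction.
#'
#' @param values numeric vector; needs >= 5 nonzero values.
#' @return two-sided p-value.
#' @export
distribution_median_test <- function(values) {
  v <- values[!is.na(values)]
  v <- v[v != 0]
  if (length(v) == 0L) stop("all values are zero", call. = FALSE)
  if (length(v) < 5L) stop("need >= 5 nonzero values", call. = FALSE)
  n <- length(v)
  rk <- rank(abs(v))
  w_pos <- sum(rk[v > 0])
  ties <- any(duplicated(abs(v)))
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(w_pos, n),
                 1 - stats::psignrank(w_pos - 1, n))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired two-sided t-test
#'
#' @param a,b paired numeric vectors.
#' @return list: `t`, `p`, `n`. Zero variance of the differences yields the
#'   undefined sentinel `t = NA`, `p = NA`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("need >= 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) return(list(t = NA_real_, p = NA_real_, n = n))
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), n = n)
}
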
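# Respiration-rhythm and electrodermal parameters.

#' Instantaneous breathing rate from a respiration trace
#'
#' The trace is band-pass filtered to 0.05-0.5 Hz with a zero-phase
#' Butterworth filter; breath intervals are the spacings between successive
#' rising zero-crossings (crossing times linearly interpolated); intervals
#' at or below `min_interval` seconds are discarded as artifacts; rates are
#' the reciprocal intervals.
#'
#' @param trace respiration signal.
#' @param fs sampling rate in Hz (>= 2).
#' @param min_interval artifact threshold in seconds. The boundary is
#'   inclusive so an oscillation at exactly 1/(2 x band edge) = 2 Hz (0.5-s
#'   spacing) is treated as artifact.
#' @param band filter band edges in Hz.
#' @param crossing `"rising"` (default) or `"falling"`.
#' @return numeric vector of instantaneous rates in Hz.
#' @export
breathing_rate_series <- function(trace, fs, min_interval = 0.5,
                                  band = c(0.05, 0.5),
                                  crossing = c("rising", "falling")) {
  crossing <- match.arg(crossing)
  if (fs < 2) stop_config("fs", "must be >= 2 Hz")
  if (length(trace) < 20 * fs) {
    stop("insufficient data: need >= 20 s of respiration", call. = FALSE)
  }
  filt <- butter_bandpass(4, band[1], band[2], fs)
  x <- filtfilt(filt, trace)
  # A trace with no in-band energy (e.g. a pure tone far above the band)
  # leaves only numerical residue whose zero-crossings are meaningless.
  if (stats::sd(x) < 1e-4 * stats::sd(trace) || stats::sd(x) == 0) {
    stop("insufficient data: no respiration energy in the pass band",
         call. = FALSE)
  }
  if (crossing == "falling") x <- -x
  n <- length(x)
  idx <- which(x[-n] <= 0 & x[-1] > 0)
  if (length(idx) < 2L) {
    stop("insufficient data: fewer than 2 breath onsets detected",
         call. = FALSE)
  }
  # Linear interpolation of the crossing instant within the sample step.
  frac <- -x[idx] / (x[idx + 1] - x[idx])
  ctimes <- (idx - 1 + frac) / fs
  intervals <- diff(ctimes)
  # First and last breath cycles abut the filter's edge taper and are only
  # partially observed; drop them when enough cycles remain.
  if (length(intervals) >= 3L) {
    intervals <- intervals[-c(1L, length(intervals))]
  }
  intervals <- intervals[intervals > min_interval + 1e-9]
  if (length(intervals) < 1L) {
    stop("insufficient data: all breath intervals flagged as artifacts",
         call. = FALSE)
  }
  1 / intervals
}

#' Respiration parameters (breathing-rate statistics and band powers)
#'
#' `resp_mean`/`resp_std` summarise the instantaneous breathing-rate series.
#' `resp_MF`/`resp_HF` are the Fourier power of the band-pass filtered trace
#' integrated over 0.07-0.14 Hz and 0.15-0.5 Hz, each normalised by the
#' total power of the filtered trace.
#'
#' @inheritParams breathing_rate_series
#' @param mf_band,hf_band band edges in Hz for the normalised powers.
#' @return named list: `resp_mean`, `resp_std`, `resp_MF`, `resp_HF`.
#' @export
resp_features <- function(trace, fs, mf_band = c(0.07, 0.14),
                          hf_band = c(0.15, 0.5), band = c(0.05, 0.5)) {
  rates <- breathing_rate_series(trace, fs, band = band)
  filt <- butter_bandpass(4, band[1], band[2], fs)
  x <- filtfilt(filt, trace)
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  pos <- freq > 0 & freq <= fs / 2
  total <- sum(spec[pos])
  band_frac <- function(b) {
    if (total == 0) return(0)
    sum(spec[pos & freq >= b[1] & freq <= b[2]]) / total
  }
  list(resp_mean = mean(rates),
       resp_std = if (length(rates) > 1L) stats::sd(rates) else 0,
       resp_MF = band_frac(mf_band),
       resp_HF = band_frac(hf_band))
}

# Rolling quantile with edge-truncated centred windows, evaluated on a
# stride and linearly interpolated (the baseline it feeds is smoothed
# afterwards anyway).
roll_quantile <- function(x, width, prob, stride = 5L) {
  n <- length(x)
  h <- width %/% 2L
  at <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(at, function(i) {
    stats::quantile(x[max(1L, i - h):min(n, i + h)], prob, names = FALSE,
                    type = 7)
  }, numeric(1))
  if (length(at) == 1L) return(rep(vals, n))
  stats::approx(at, vals, xout = seq_len(n))$y
}

moving_average <- function(x, width) {
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(1L, i - h)
  b <- pmin(n, i + h)
  (cs[b + 1] - cs[a]) / (b - a + 1)
}

#' Decompose skin conductance into tonic (SCL) and phasic (SCR) components
#'
#' The tonic level is estimated first as a smoothed sliding-window lower
#' quantile of the trace; the nonnegative residual is deconvolved against a
#' bi-exponential Bateman kernel, the driver is clipped at zero and
#' re-convolved to give the SCR. The SCL is then defined as `trace - scr`,
#' so additivity is exact and `scr >= 0` everywhere.
#'
#' @param trace skin conductance in uS.
#' @param fs sampling rate in Hz (>= 2).
#' @param tau_rise,tau_decay Bateman kernel time constants in seconds.
#' @param baseline_win width (s) of the sliding window for the tonic
#'   estimate; should exceed the typical SCR duration.
#' @param baseline_prob quantile used for the tonic baseline.
#' @return list with numeric vectors `scl` and `scr` (same length as
#'   `trace`).
#' @export
decompose_eda <- function(trace, fs, tau_rise = 0.75, tau_decay = 2,
                          baseline_win = 15, baseline_prob = 0.1) {
  if (fs < 2) stop_config("fs", "must be >= 2 Hz")
  if (any(!is.finite(trace))) stop("EDA trace contains nonfinite samples",
                                   call. = FALSE)
  w <- max(3L, round(baseline_win * fs))
  tonic <- moving_average(roll_quantile(trace, w, baseline_prob), w)
  # The sliding lower quantile sits about qnorm(prob) noise SDs below the
  # true tonic level; estimate the noise scale robustly from first
  # differences and shift the baseline back up, then smooth below the
  # kernel rise time before clipping, so measurement noise is not rectified
  # into spurious phasic drive.
  sigma_hat <- stats::mad(diff(trace)) / sqrt(2)
  tonic <- tonic + abs(stats::qnorm(baseline_prob)) * sigma_hat
  resid <- moving_average(trace - tonic, max(3L, round(0.8 * fs)))
  resid <- pmax(resid, 0)
  n <- length(trace)
  tt <- (seq_len(n) - 1) / fs
  # Nonnegative deconvolution: sample-rate deconvolution against the kernel
  # is ill-conditioned, so the driver lives on a coarser grid (0.5 s) and is
  # fitted by nonnegative least squares; re-convolving the nonnegative
  # driver gives a phasic component that is >= 0 by construction.
  grid <- seq(0, tt[n], by = 0.5)
  kern_fun <- function(t, tau) {
    dtau <- t - tau
    out <- exp(-dtau / tau_decay) - exp(-dtau / tau_rise)
    out[dtau <= 0] <- 0
    out
  }
  a_mat <- outer(tt, grid, kern_fun)
  drv <- nnls_lh(a_mat, resid)
  scr <- as.numeric(a_mat %*% drv)
  list(scl = trace - scr, scr = scr)
}

# Lawson-Hanson active-set nonnegative least squares: min ||a x - b||, x >= 0.
# Works on the precomputed normal equations; the iteration cap trades the
# last, negligible driver components for bounded runtime on noisy input.
nnls_lh <- function(a, b, tol = NULL, max_iter = 100L) {
  m <- ncol(a)
  ata <- crossprod(a)
  atb <- crossprod(a, b)
  x <- numeric(m)
  passive <- logical(m)
  w <- atb
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * sum(abs(atb))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(m)
      sel <- which(passive)
      z[sel] <- tryCatch(
        solve(ata[sel, sel, drop = FALSE], atb[sel]),
        error = function(e) {
          qr.coef(qr(a[, sel, drop = FALSE]), b)
        })
      z[sel][is.na(z[sel])] <- 0
      if (all(z[sel] > 0)) { x <- z; break }
      neg <- sel[z[sel] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- atb - ata %*% x
  }
  x
}

#' Windowed electrodermal parameters (iSCL / iSCR)
#'
#' Integrates the tonic and phasic components over consecutive
#' non-overlapping windows (10 s by default; 12 windows for a 120-s trial)
#' by the trapezoidal rule, then reports means and standard deviations
#' across windows. The trace is extended by one sample (constant
#' continuation) so each window spans exactly `window` seconds; partial
#' trailing windows are dropped.
#'
#' @param trace skin conductance in uS.
#' @param fs sampling rate in Hz.
#' @param window window length in seconds.
#' @param ... passed to [decompose_eda()].
#' @return named list: `iscl_mean`, `iscl_std`, `iscr_mean`, `iscr_std`
#'   (uS s).
#' @export
eda_features <- function(trace, fs, window = 10, ...) {
  duration <- length(trace) / fs
  n_win <- floor(duration / window)
  if (n_win < 2L) stop("insufficient data: need >= 2 windows", call. = FALSE)
  dec <- decompose_eda(trace, fs, ...)
  wlen <- round(window * fs)
  integrate_windows <- function(x) {
    xe <- c(x, x[length(x)])
    te <- (seq_along(xe) - 1) / fs
    vapply(seq_len(n_win), function(w) {
      a <- (w - 1L) * wlen + 1L
      b <- w * wlen + 1L
      trapz(te[a:b], xe[a:b])
    }, numeric(1))
  }
  iscl <- integrate_windows(dec$scl)
  iscr <- integrate_windows(dec$scr)
  list(iscl_mean = mean(iscl), iscl_std = stats::sd(iscl),
       iscr_mean = mean(iscr), iscr_std = stats::sd(iscr),
       n_windows = n_win)
}
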
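# Heart rate variability parameters from a normal-to-normal interval series:
# time-domain statistics, Poincare-plot geometry, and Burg autoregressive
# band powers.

#' Construct a normal-to-normal (NN) interval series
#'
#' @param rpeaks R-peak event times in seconds (strictly increasing), or
#'   `NULL` if `intervals` is given directly.
#' @param intervals NN intervals in milliseconds (used when `rpeaks` is
#'   `NULL`); onset times are then their cumulative sums.
#' @return object of class `nn_series` with `intervals` (ms) and `times`
#'   (s, onset of each interval).
#' @export
nn_series <- function(rpeaks = NULL, intervals = NULL) {
  if (!is.null(rpeaks)) {
    if (length(rpeaks) < 3L) stop("need >= 3 R-peaks", call. = FALSE)
    if (any(diff(rpeaks) <= 0)) {
      stop("R-peak times must be strictly increasing", call. = FALSE)
    }
    intervals <- diff(rpeaks) * 1000
    times <- rpeaks[-length(rpeaks)]
  } else {
    if (is.null(intervals) || length(intervals) < 2L) {
      stop("need >= 2 NN intervals", call. = FALSE)
    }
    times <- c(0, cumsum(intervals[-length(intervals)]) / 1000)
  }
  if (any(intervals <= 0)) stop("NN intervals must be positive", call. = FALSE)
  structure(list(intervals = as.numeric(intervals),
                 times = as.numeric(times)),
            class = "nn_series")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Time-domain HRV parameters
#'
#' Mean NN, SDNN (population convention, matching the Poincare algebra used
#' in [poincare_hrv()]), RMSSD, NN50 (successive differences strictly larger
#' than 50 ms in magnitude) and pNN50 with the number of successive pairs
#' (n - 1) as denominator.
#'
#' @param nn an [nn_series()].
#' @param nn50_threshold threshold in ms for the NN50 count.
#' @return named list: `ecg_mean`, `ecg_SDNN`, `ecg_RMSSD`, `ecg_NN50`,
#'   `ecg_pNN50`.
#' @export
time_domain_hrv <- function(nn, nn50_threshold = 50) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$intervals
  if (length(x) < 3L) stop("insufficient data: need >= 3 NN intervals",
                           call. = FALSE)
  d <- diff(x)
  nn50 <- sum(abs(d) > nn50_threshold)
  list(ecg_mean = mean(x),
       ecg_SDNN = sqrt(pop_var(x)),
       ecg_RMSSD = sqrt(mean(d^2)),
       ecg_NN50 = nn50,
       ecg_pNN50 = nn50 / length(d))
}

#' Poincare-plot HRV parameters
#'
#' With x = NN(1..n-1) and y = NN(2..n): SD1 is the dispersion perpendicular
#' to the identity line, SD2 along it, and r_RR the Pearson correlation of
#' the plot. SD1 uses the uncentred second moment of the successive
#' differences, `SD1^2 = mean(diff^2) / 2`, so the identity
#' `SD1 = RMSSD / sqrt(2)` holds exactly; `SD2^2 = 2 Var(NN) - SD1^2`
#' (population variance), floored at 0. A zero-variance series yields
#' SD1 = SD2 = 0 with `r_RR = NA` (undefined, never silently 0).
#'
#' @param nn an [nn_series()].
#' @return named list: `ecg_SD1`, `ecg_SD2`, `ecg_r_RR`.
#' @export
poincare_hrv <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  v <- nn$intervals
  if (length(v) < 3L) stop("insufficient data: need >= 3 NN intervals",
                           call. = FALSE)
  x <- v[-length(v)]
  y <- v[-1]
  sd1 <- sqrt(mean((x - y)^2) / 2)
  sd2 <- sqrt(max(0, 2 * pop_var(v) - sd1^2))
  r <- if (pop_var(x) == 0 || pop_var(y) == 0) NA_real_ else stats::cor(x, y)
  list(ecg_SD1 = sd1, ecg_SD2 = sd2, ecg_r_RR = r)
}

#' Spectral configuration for frequency-domain HRV
#'
#' @param fs_interp tachogram resampling rate in Hz (4 Hz covers the 0.4-Hz
#'   upper band edge with margin).
#' @param ar_order order of the Burg autoregressive model.
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @param df integration grid spacing in Hz.
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(fs_interp = 4, ar_order = 16,
                            bands = list(VLF = c(0.009, 0.04),
                                         LF = c(0.04, 0.15),
                                         HF = c(0.15, 0.4)),
                            df = 5e-4) {
  structure(list(fs_interp = fs_interp, ar_order = ar_order, bands = bands,
                 df = df), class = "spectral_config")
}

# One-sided AR power spectral density (ms^2 / Hz) on a frequency grid.
ar_psd <- function(coefs, var_pred, fs, freq) {
  j <- seq_along(coefs)
  denom <- vapply(freq, function(f) {
    Mod(1 - sum(coefs * exp(-2i * pi * f * j / fs)))^2
  }, numeric(1))
  2 * var_pred / fs / denom
}

#' Frequency-domain HRV parameters via Burg autoregressive modelling
#'
#' The NN series is cubically interpolated onto an evenly sampled tachogram,
#' demeaned, fitted with a Burg AR model, and the one-sided AR spectrum is
#' integrated over the VLF (0.009-0.04), LF (0.04-0.15) and HF (0.15-0.4 Hz)
#' bands. Total power is their sum; normalised units are relative to total
#' power minus VLF. `LF/HF` is `NA` when HF is zero.
#'
#' A 120-s trial barely covers one VLF period, so the result carries an
#' attribute `vlf_low_confidence = TRUE` whenever the NN span is shorter
#' than two VLF periods.
#'
#' @param nn an [nn_series()] spanning at least 60 s.
#' @param spec a [spectral_config()].
#' @return named list: `ecg_VLF`, `ecg_LF`, `ecg_HF`, `ecg_tot_pwr`,
#'   `ecg_LF_HF`, `ecg_LFnu`, `ecg_HFnu` (powers in ms^2).
#' @export
frequency_domain_hrv <- function(nn, spec = spectral_config()) {
  stopifnot(inherits(nn, "nn_series"), inherits(spec, "spectral_config"))
  t_end <- nn$times + nn$intervals / 1000
  span <- t_end[length(t_end)] - nn$times[1]
  if (span < 60) stop("insufficient data: NN span must cover >= 60 s",
                      call. = FALSE)
  # Tachogram: NN value located at the closing R-peak of its interval.
  fs <- spec$fs_interp
  tg_t <- seq(t_end[1], t_end[length(t_end)], by = 1 / fs)
  tg <- stats::spline(t_end, nn$intervals, xout = tg_t, method = "fmm")$y
  tg <- tg - mean(tg)
  out <- list(ecg_VLF = 0, ecg_LF = 0, ecg_HF = 0, ecg_tot_pwr = 0,
              ecg_LF_HF = NA_real_, ecg_LFnu = NA_real_, ecg_HFnu = NA_real_)
  if (stats::var(tg) > 0) {
    ord <- min(spec$ar_order, length(tg) - 1L)
    fit <- stats::ar.burg(tg, aic = FALSE, order.max = ord, demean = TRUE)
    pw <- vapply(spec$bands, function(b) {
      fr <- seq(b[1], b[2], by = spec$df)
      trapz(fr, ar_psd(fit$ar, fit$var.pred, fs, fr))
    }, numeric(1))
    tot <- sum(pw)
    denom <- tot - pw[["VLF"]]
    out <- list(
      ecg_VLF = pw[["VLF"]], ecg_LF = pw[["LF"]], ecg_HF = pw[["HF"]],
      ecg_tot_pwr = tot,
      ecg_LF_HF = if (pw[["HF"]] > 0) pw[["LF"]] / pw[["HF"]] else NA_real_,
      ecg_LFnu = if (denom > 0) pw[["LF"]] / denom else NA_real_,
      ecg_HFnu = if (denom > 0) pw[["HF"]] / denom else NA_real_)
  }
  attr(out, "vlf_low_confidence") <- span < 2 / spec$bands$VLF[1]
  out
}

#' All 15 HRV parameters for one NN series
#'
#' @param nn an [nn_series()].
#' @param spec a [spectral_config()].
#' @return named list combining [time_domain_hrv()], [poincare_hrv()] and
#'   [frequency_domain_hrv()].
#' @export
hrv_features <- function(nn, spec = spectral_config()) {
  c(time_domain_hrv(nn), poincare_hrv(nn), frequency_domain_hrv(nn))
}

#' Names of the 23 autonomic parameters
#'
#' Column order used throughout the package: 15 HRV, 4 respiration and 4
#' electrodermal parameters.
#' @return character vector of length 23.
#' @export
autonomic_parameter_names <- function() {
  c("ecg_mean", "ecg_SDNN", "ecg_RMSSD", "ecg_NN50", "ecg_pNN50",
    "ecg_SD1", "ecg_SD2", "ecg_r_RR",
    "ecg_VLF", "ecg_LF", "ecg_HF", "ecg_tot_pwr", "ecg_LF_HF",
    "ecg_LFnu", "ecg_HFnu",
    "resp_mean", "resp_std", "resp_MF", "resp_HF",
    "iscl_mean", "iscl_std", "iscr_mean", "iscr_std")
}
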
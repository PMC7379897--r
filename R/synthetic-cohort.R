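# Synthetic dyadic-physiology cohort generator.
#
# Emulates the structure of a two-day dyadic target-tracking experiment:
# 14 dyads (28 subjects), 7 trials per condition (collaborative/individual)
# per day, 120-s trials, ECG R-peak surrogates, 10-Hz respiration and EDA
# traces, ball/target pixel trajectories, and 1-9 performance ratings
# (R1 own, R2 partner, R3 collaboration; R2/R3 only after collaborative
# trials). A latent per-subject-trial arousal state modulates the autonomic
# signals and, with configurable strength, the ratings; ratings can also be
# coupled to the objective tracking error. Ground-truth latents are carried
# in a separate attribute that no analysis function reads.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the cohort layout of the emulated study: 14 dyads, 2
#' recording days, 7 trials per condition per day, 120-s trials, 10-Hz
#' respiration/EDA sampling and integer ratings 1-9.
#'
#' @param n_dyads number of dyads (each contributes 2 subjects).
#' @param days number of recording days.
#' @param trials_per_condition_per_day trials in each condition per day.
#' @param trial_duration trial length in seconds.
#' @param fs_resp_eda sampling rate of the respiration/EDA traces (Hz).
#' @param rating_scale integer vector of admissible rating levels.
#' @param coupling_autonomic strength in `[0, 1]` with which ratings follow
#'   the latent arousal state (the interoceptive route).
#' @param coupling_error strength in `[0, 1]` with which ratings follow the
#'   (negated, standardised) tracking error (the objective route).
#' @param subject_heterogeneity scale (>= 0) of stable between-subject
#'   offsets in both physiology baselines and rating usage.
#' @param rating_noise_sd standard deviation of the additive rating noise, in
#'   rating units.
#' @param seed master seed; together with the configuration it fully
#'   determines the emitted cohort.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_dyads = 14L, days = 2L,
                          trials_per_condition_per_day = 7L,
                          trial_duration = 120, fs_resp_eda = 10,
                          rating_scale = 1:9,
                          coupling_autonomic = 0.6, coupling_error = 0.2,
                          subject_heterogeneity = 0.5,
                          rating_noise_sd = 0.8, seed = 1L) {
  cfg <- list(
    n_dyads = check_count(n_dyads, "n_dyads"),
    days = check_count(days, "days"),
    trials_per_condition_per_day =
      check_count(trials_per_condition_per_day, "trials_per_condition_per_day"),
    trial_duration = check_scalar_number(trial_duration, "trial_duration",
                                         lower = 1e-9),
    fs_resp_eda = check_scalar_number(fs_resp_eda, "fs_resp_eda",
                                      lower = 1e-9),
    rating_scale = rating_scale,
    coupling_autonomic = check_scalar_number(coupling_autonomic,
                                             "coupling_autonomic", 0, 1),
    coupling_error = check_scalar_number(coupling_error, "coupling_error",
                                         0, 1),
    subject_heterogeneity = check_scalar_number(subject_heterogeneity,
                                                "subject_heterogeneity",
                                                lower = 0),
    rating_noise_sd = check_scalar_number(rating_noise_sd, "rating_noise_sd",
                                          lower = 0),
    seed = check_count(seed, "seed", lower = 0L)
  )
  if (!is.numeric(rating_scale) || length(rating_scale) < 2L ||
      any(rating_scale != round(rating_scale))) {
    stop_config("rating_scale", "must be an integer vector of length >= 2")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Surrogate R-peak times with controlled spectral structure
#'
#' The inter-beat (NN) interval process is a constant mean plus a 0.1-Hz
#' low-frequency sinusoid, a high-frequency sinusoid at the respiration rate
#' (respiratory sinus arrhythmia) and white noise, with amplitudes chosen so
#' the realised SDNN approximates `sdnn_target` and the LF/HF variance split
#' matches `lf_frac`/`hf_frac`. R-peak times are the cumulative sums of the
#' intervals.
#'
#' @param mean_nn mean NN interval (ms), > 0.
#' @param sdnn_target target NN standard deviation (ms).
#' @param lf_frac,hf_frac fractions of NN variance placed at 0.1 Hz and at
#'   `resp_rate`; their sum must be <= 1 (the remainder is white noise).
#' @param resp_rate respiration frequency (Hz) carrying the HF modulation.
#' @param duration recording length (s), >= `mean_nn`.
#' @param seed integer seed.
#' @return numeric vector of strictly increasing R-peak times in (0, duration].
#' @export
generate_nn_series <- function(mean_nn = 850, sdnn_target = 50,
                               lf_frac = 0.35, hf_frac = 0.35,
                               resp_rate = 0.25, duration = 120,
                               seed = 1L) {
  check_scalar_number(mean_nn, "mean_nn", lower = .Machine$double.eps)
  check_scalar_number(sdnn_target, "sdnn_target", lower = 0)
  check_scalar_number(lf_frac, "lf_frac", 0, 1)
  check_scalar_number(hf_frac, "hf_frac", 0, 1)
  if (lf_frac + hf_frac > 1 + 1e-12) {
    stop_config("lf_frac + hf_frac", "must not exceed 1")
  }
  if (duration < mean_nn / 1000) {
    stop_config("duration", "must cover at least one mean NN interval")
  }
  a_lf <- sdnn_target * sqrt(2 * lf_frac)
  a_hf <- sdnn_target * sqrt(2 * hf_frac)
  sigma <- sdnn_target * sqrt(max(0, 1 - lf_frac - hf_frac))
  with_seed(seed, {
    phi_lf <- stats::runif(1, 0, 2 * pi)
    phi_hf <- stats::runif(1, 0, 2 * pi)
    t <- 0
    peaks <- numeric(0)
    nmax <- ceiling(duration / (mean_nn / 1000)) * 3 + 10
    eps <- stats::rnorm(nmax)
    i <- 0L
    while (t < duration && i < nmax) {
      i <- i + 1L
      nn <- mean_nn + a_lf * sin(2 * pi * 0.1 * t + phi_lf) +
        a_hf * sin(2 * pi * resp_rate * t + phi_hf) + sigma * eps[i]
      nn <- max(nn, 0.25 * mean_nn)  # floor guards against non-physiologic beats
      t <- t + nn / 1000
      if (t <= duration) peaks <- c(peaks, t)
    }
    peaks
  })
}

# Bateman kernel shared by the EDA generator and the decomposition.
bateman_kernel <- function(fs, tau_rise = 0.75, tau_decay = 2,
                           length_s = 8 * tau_decay) {
  tt <- seq_len(ceiling(length_s * fs)) / fs
  exp(-tt / tau_decay) - exp(-tt / tau_rise)
}

#' Synthetic electrodermal activity trace with ground-truth events
#'
#' The trace is a tonic component (level plus linear drift) plus
#' Poisson-timed phasic skin conductance responses, each a scaled
#' bi-exponential (Bateman) kernel, plus small measurement noise.
#'
#' @param tonic_level tonic conductance (uS).
#' @param drift tonic drift (uS per minute).
#' @param scr_rate expected SCR events per minute (>= 0).
#' @param scr_amp median event amplitude (uS).
#' @param duration trace length (s).
#' @param fs sampling rate (Hz), > 0.
#' @param seed integer seed.
#' @param events optional data.frame(time, amplitude) overriding the Poisson
#'   draw (used to inject known ground truth in tests).
#' @param noise_sd measurement noise (uS).
#' @param tau_rise,tau_decay Bateman kernel time constants (s).
#' @return list with `trace` (numeric vector), `fs`, `events` (ground-truth
#'   data.frame) and `kernel_area` (analytic integral of the unit kernel,
#'   `tau_decay - tau_rise`).
#' @export
generate_eda_trace <- function(tonic_level = 2, drift = 0.05, scr_rate = 4,
                               scr_amp = 0.3, duration = 120, fs = 10,
                               seed = 1L, events = NULL, noise_sd = 0.003,
                               tau_rise = 0.75, tau_decay = 2) {
  check_scalar_number(fs, "fs", lower = .Machine$double.eps)
  check_scalar_number(scr_rate, "scr_rate", lower = 0)
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    if (is.null(events)) {
      n_ev <- stats::rpois(1, scr_rate * duration / 60)
      events <- data.frame(
        time = sort(stats::runif(n_ev, 0, max(0, duration - 5 * tau_decay))),
        amplitude = scr_amp * exp(stats::rnorm(n_ev, 0, 0.3))
      )
    }
    tonic <- tonic_level + drift / 60 * tt
    phasic <- numeric(n)
    if (nrow(events) > 0L) {
      kern <- bateman_kernel(fs, tau_rise, tau_decay)
      for (j in seq_len(nrow(events))) {
        i0 <- floor(events$time[j] * fs) + 1L
        idx <- i0 + seq_along(kern)
        keep <- idx <= n
        phasic[idx[keep]] <- phasic[idx[keep]] +
          events$amplitude[j] * kern[keep]
      }
    }
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    list(trace = tonic + phasic + noise, fs = fs, events = events,
         kernel_area = tau_decay - tau_rise)
  })
}

#' Synthetic ball/target tracking trace
#'
#' The target moves at constant speed along a straight line, reversing
#' direction at random (exponential) intervals and reflecting at the border
#' of the play field. The ball follows the target plus an AR(1) pixel error
#' per axis whose stationary magnitude decreases with `skill`; `skill = Inf`
#' on an axis gives zero error there (used for the untracked axis in the
#' individual condition).
#'
#' @param skill non-negative skill, length 1 (both axes) or 2 (`x`, `y`).
#' @param duration trial length (s).
#' @param fs_track log rate of the trace (Hz).
#' @param seed integer seed.
#' @param base_error stationary error SD (px) at `skill = 0`.
#' @param ar_phi AR(1) coefficient of the pixel error.
#' @return data.frame with columns `time_s`, `ball_x`, `ball_y`, `target_x`,
#'   `target_y`.
#' @export
generate_tracking_trace <- function(skill = 1, duration = 120, fs_track = 10,
                                    seed = 1L, base_error = 60,
                                    ar_phi = 0.97) {
  if (any(skill < 0)) stop_config("skill", "must be >= 0")
  if (length(skill) == 1L) skill <- c(skill, skill)
  n <- round(fs_track * duration)
  tt <- (seq_len(n) - 1) / fs_track
  with_seed(seed, {
    # Arc-length position of the target along a diagonal line, constant speed
    # 80 px/s, direction reversals at Exp(mean 5 s) intervals, reflective
    # bounds at +-250 px.
    speed <- 80
    rev_times <- cumsum(stats::rexp(ceiling(duration / 2) + 5, rate = 1 / 5))
    dir_sign <- 1
    s <- numeric(n)
    pos <- 0
    next_rev <- 1L
    dt <- 1 / fs_track
    for (i in seq_len(n)) {
      if (next_rev <= length(rev_times) && tt[i] >= rev_times[next_rev]) {
        dir_sign <- -dir_sign
        next_rev <- next_rev + 1L
      }
      pos <- pos + dir_sign * speed * dt
      if (pos > 250) { pos <- 500 - pos; dir_sign <- -dir_sign }
      if (pos < -250) { pos <- -500 - pos; dir_sign <- -dir_sign }
      s[i] <- pos
    }
    target_x <- 512 + s / sqrt(2)
    target_y <- 384 + s / sqrt(2)
    err_sd <- base_error / (1 + skill)
    make_err <- function(sd) {
      if (sd == 0) return(numeric(n))
      e <- numeric(n)
      innov <- stats::rnorm(n, 0, sd * sqrt(1 - ar_phi^2))
      e[1] <- stats::rnorm(1, 0, sd)
      for (i in 2:n) e[i] <- ar_phi * e[i - 1] + innov[i]
      e
    }
    ex <- make_err(err_sd[1])
    ey <- make_err(err_sd[2])
    data.frame(time_s = tt,
               ball_x = target_x + ex, ball_y = target_y + ey,
               target_x = target_x, target_y = target_y)
  })
}

#' Generate integer ratings from latent arousal and tracking error
#'
#' Implements the two postulated routes into the subjective rating: an
#' interoceptive route (latent arousal, weight `coupling_autonomic`) and an
#' objective route (standardised tracking error, negative weight
#' `coupling_error`). Both inputs pass through standardising monotone maps so
#' the couplings are comparable; the result is rounded and clipped to the
#' rating scale.
#'
#' @param arousal numeric vector of latent arousal values (one per
#'   subject-trial), nominally standard normal.
#' @param subject_offset per-observation stable subject offset (rating units).
#' @param error tracking error (px) aligned with `arousal`; standardised
#'   internally (log scale) across the vector.
#' @param config a [cohort_config()] supplying couplings, noise SD and scale.
#' @param base_level centre of the rating scale usage (default 6; raters of
#'   this task mostly used the upper half of the 1-9 scale).
#' @param gain rating units per standard deviation of either route.
#' @param seed integer seed for the rating noise.
#' @return integer vector of ratings on `config$rating_scale`.
#' @export
generate_ratings <- function(arousal, subject_offset, error, config,
                             base_level = 6, gain = 2, seed = 1L) {
  stopifnot(length(arousal) == length(error),
            length(subject_offset) == length(arousal))
  z_err <- {
    le <- log(pmax(error, .Machine$double.eps))
    s <- stats::sd(le)
    if (!is.finite(s) || s == 0) rep(0, length(le)) else (le - mean(le)) / s
  }
  with_seed(seed, {
    noise <- if (config$rating_noise_sd > 0) {
      stats::rnorm(length(arousal), 0, config$rating_noise_sd)
    } else numeric(length(arousal))
    raw <- base_level + gain * config$coupling_autonomic * arousal -
      gain * config$coupling_error * z_err + subject_offset + noise
    lv <- round(raw)
    pmin(max(config$rating_scale), pmax(min(config$rating_scale), lv))
  })
}

#' Generate a complete synthetic cohort
#'
#' Emits one `TrialRecord` per subject and trial: identifiers, R-peak times,
#' respiration and EDA traces, the (dyad-shared, in the collaborative
#' condition) tracking trace, and ratings. Under the default configuration
#' this is 28 subjects x 14 trials/day x 2 days = 784 subject-trials.
#' Identical configuration and seed reproduce the cohort exactly.
#'
#' Ground truth (per-subject-trial arousal, per-subject offsets, SCR events)
#' is attached as `attr(cohort, "truth")`; analysis functions never read it.
#'
#' @param config a [cohort_config()].
#' @return object of class `dyadphys_cohort`: list with `config`, `trials`
#'   (list of trial records) and `ratings` (data.frame with one row per
#'   subject-trial).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_config("config", "must be created by cohort_config()")
  }
  n_sub <- 2L * config$n_dyads
  het <- config$subject_heterogeneity
  seeds <- derive_seeds(config$seed, 6L, stream = 1L)

  # Stable per-subject baselines; heterogeneity scales their spread.
  subj <- with_seed(seeds[1], {
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n_sub)),
      dyad_id = rep(sprintf("D%02d", seq_len(config$n_dyads)), each = 2L),
      own_axis = rep(c("x", "y"), config$n_dyads),
      mean_nn = 850 + het * 80 * stats::rnorm(n_sub),
      sdnn = pmax(20, 50 + het * 12 * stats::rnorm(n_sub)),
      resp_rate = pmin(0.38, pmax(0.17, 0.25 + het * 0.03 * stats::rnorm(n_sub))),
      eda_tonic = pmax(0.5, 2 + het * 0.8 * stats::rnorm(n_sub)),
      skill = exp(0.3 * stats::rnorm(n_sub)),
      rating_offset = het * stats::rnorm(n_sub)
    )
  })

  days <- seq_len(config$days)
  conds <- c("collaborative", "individual")
  tr_idx <- seq_len(config$trials_per_condition_per_day)
  grid <- expand.grid(trial_index = tr_idx, condition = conds, day = days,
                      dyad = seq_len(config$n_dyads),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_dt <- nrow(grid)                       # dyad-trials
  arousal <- with_seed(seeds[2], matrix(stats::rnorm(2L * n_dt), ncol = 2L))
  trial_seeds <- matrix(derive_seeds(config$seed, 9L * n_dt, stream = 2L),
                        ncol = 9L)

  trials <- vector("list", 2L * n_dt)
  truth_rows <- vector("list", 2L * n_dt)
  k <- 0L
  for (g in seq_len(n_dt)) {
    d <- grid$dyad[g]
    members <- which(subj$dyad_id == sprintf("D%02d", d))
    cond <- grid$condition[g]
    if (cond == "collaborative") {
      trace <- generate_tracking_trace(
        skill = c(subj$skill[members[1]], subj$skill[members[2]]),
        duration = config$trial_duration, fs_track = config$fs_resp_eda,
        seed = trial_seeds[g, 1])
    }
    for (m in 1:2) {
      k <- k + 1L
      srow <- subj[members[m], ]
      a <- arousal[g, m]
      if (cond == "individual") {
        sk <- if (srow$own_axis == "x") c(srow$skill, Inf) else c(Inf, srow$skill)
        trace_m <- generate_tracking_trace(
          skill = sk, duration = config$trial_duration,
          fs_track = config$fs_resp_eda, seed = trial_seeds[g, 1 + m])
      } else {
        trace_m <- trace
      }
      # Arousal modulates chronotropy, the LF/HF balance, respiration rate
      # and electrodermal phasic activity.
      rpeaks <- generate_nn_series(
        mean_nn = max(400, srow$mean_nn - 50 * a),
        sdnn_target = max(8, srow$sdnn * (1 - 0.15 * a)),
        lf_frac = min(0.6, max(0.05, 0.35 + 0.10 * a)),
        hf_frac = min(0.6, max(0.05, 0.35 - 0.10 * a)),
        resp_rate = srow$resp_rate,
        duration = config$trial_duration, seed = trial_seeds[g, 3 + m])
      resp_rate_t <- min(0.4, max(0.12, srow$resp_rate + 0.025 * a))
      nr <- round(config$fs_resp_eda * config$trial_duration)
      t_resp <- (seq_len(nr) - 1) / config$fs_resp_eda
      resp <- with_seed(trial_seeds[g, 5 + m], {
        ph <- stats::runif(1, 0, 2 * pi)
        sin(2 * pi * resp_rate_t * t_resp + ph) +
          0.1 * sin(4 * pi * resp_rate_t * t_resp + 2 * ph) +
          stats::rnorm(nr, 0, 0.05)
      })
      eda <- generate_eda_trace(
        tonic_level = max(0.2, srow$eda_tonic + 0.3 * a),
        drift = 0.05, scr_rate = max(0, 4 + 2 * a),
        scr_amp = 0.3 * exp(0.3 * a),
        duration = config$trial_duration, fs = config$fs_resp_eda,
        seed = trial_seeds[g, 7 + m])
      trials[[k]] <- list(
        dyad_id = srow$dyad_id, subject_id = srow$subject_id,
        day = grid$day[g], condition = cond,
        trial_index = grid$trial_index[g], own_axis = srow$own_axis,
        rpeaks = rpeaks, resp = resp, eda = eda$trace,
        fs = config$fs_resp_eda, tracking = trace_m,
        ratings = NULL)
      truth_rows[[k]] <- data.frame(
        subject_id = srow$subject_id, day = grid$day[g], condition = cond,
        trial_index = grid$trial_index[g], arousal = a,
        subject_offset = srow$rating_offset, n_scr = nrow(eda$events))
    }
  }

  # Ratings need the realised tracking errors, so they come last.
  errs <- lapply(trials, function(tr) tracking_errors(tr$tracking))
  own_err <- vapply(seq_along(trials), function(i) {
    if (trials[[i]]$own_axis == "x") errs[[i]]$x_cum else errs[[i]]$y_cum
  }, numeric(1))
  partner_err <- vapply(seq_along(trials), function(i) {
    if (trials[[i]]$own_axis == "x") errs[[i]]$y_cum else errs[[i]]$x_cum
  }, numeric(1))
  euclid_err <- vapply(errs, function(e) e$euclid_cum, numeric(1))
  truth <- do.call(rbind, truth_rows)
  rating_seeds <- derive_seeds(config$seed, 3L, stream = 3L)
  r1 <- generate_ratings(truth$arousal, truth$subject_offset, own_err,
                         config, seed = rating_seeds[1])
  r2 <- generate_ratings(truth$arousal, truth$subject_offset, partner_err,
                         config, seed = rating_seeds[2])
  r3 <- generate_ratings(truth$arousal, truth$subject_offset, euclid_err,
                         config, seed = rating_seeds[3])
  collab <- vapply(trials, function(tr) tr$condition == "collaborative",
                   logical(1))
  ratings <- data.frame(
    dyad = vapply(trials, `[[`, character(1), "dyad_id"),
    subject = vapply(trials, `[[`, character(1), "subject_id"),
    day = vapply(trials, `[[`, numeric(1), "day"),
    condition = vapply(trials, `[[`, character(1), "condition"),
    trial = vapply(trials, `[[`, numeric(1), "trial_index"),
    R1 = r1, R2 = ifelse(collab, r2, NA_integer_),
    R3 = ifelse(collab, r3, NA_integer_))
  for (i in seq_along(trials)) {
    trials[[i]]$ratings <- list(
      R1 = ratings$R1[i],
      R2 = if (collab[i]) ratings$R2[i] else NULL,
      R3 = if (collab[i]) ratings$R3[i] else NULL)
  }
  cohort <- list(config = config, trials = trials, ratings = ratings)
  class(cohort) <- "dyadphys_cohort"
  attr(cohort, "truth") <- truth
  cohort
}

#' @export
print.dyadphys_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic dyadic-physiology cohort: %d dyads, %d days, %d subject-trials\n",
    x$config$n_dyads, x$config$days, length(x$trials)))
  invisible(x)
}
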
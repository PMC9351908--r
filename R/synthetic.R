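#' Parameters of the simulated fibrillatory wave
#'
#' The f-wave is modelled as a harmonic ("sawtooth-like") sum at a
#' fundamental in the fibrillatory band, with slow amplitude and frequency
#' modulation emulating the waxing/waning of atrial activity seen on surface
#' leads during AF.
#'
#' @param f0 fundamental frequency (Hz), must lie in the fibrillatory band
#'   \[3, 12\] Hz.
#' @param n_harmonics number of harmonics (>= 1, fundamental included).
#' @param harmonic_decay per-harmonic amplitude ratio (harmonic k has
#'   relative amplitude `harmonic_decay^(k-1)`).
#' @param peak_to_peak target amplitude in uV: the median peak-to-trough of
#'   successive extrema of the generated wave (the same convention the FWA
#'   estimator uses, so recovery tests are self-consistent).
#' @param am_depth fractional amplitude-modulation depth in \[0, 1).
#' @param am_freq amplitude-modulation frequency (Hz).
#' @param fm_depth fractional frequency-modulation depth (instantaneous
#'   fundamental is `f0 * (1 + fm_depth * sin(2*pi*fm_freq*t))`).
#' @param fm_freq frequency-modulation frequency (Hz).
#' @param seed integer seed controlling the random component phases.
#' @return an object of class `fwave_params`.
#' @export
fwave_params <- function(f0 = 6, n_harmonics = 3, harmonic_decay = 0.5,
                         peak_to_peak = 60, am_depth = 0.15, am_freq = 0.45,
                         fm_depth = 0.03, fm_freq = 0.3, seed = 1L) {
  if (f0 < 3 || f0 > 12) stop_fw("fw_bad_param", "f0 must lie in [3, 12] Hz, got %g", f0)
  if (peak_to_peak <= 0) stop_fw("fw_bad_param", "peak_to_peak must be > 0")
  if (am_depth < 0 || am_depth >= 1) stop_fw("fw_bad_param", "am_depth must be in [0, 1)")
  if (n_harmonics < 1) stop_fw("fw_bad_param", "n_harmonics must be >= 1")
  structure(list(f0 = f0, n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay, peak_to_peak = peak_to_peak,
                 am_depth = am_depth, am_freq = am_freq,
                 fm_depth = fm_depth, fm_freq = fm_freq,
                 seed = as.integer(seed)),
            class = "fwave_params")
}

#' Parameters of the simulated ventricular (QRST) activity
#'
#' RR intervals are drawn i.i.d. from a log-normal law parameterized by its
#' mean and coefficient of variation (strictly positive and right-skewed,
#' like AF RR histograms), truncated so every interval exceeds the QRST
#' duration.
#'
#' @param mean_rr mean RR interval (s).
#' @param rr_cv coefficient of variation of the RR intervals (0 = periodic).
#' @param qrs_amp R-wave amplitude (uV).
#' @param t_amp T-wave amplitude (uV).
#' @param qrst_duration total QRST support per beat (s).
#' @param seed integer seed.
#' @return an object of class `ventricular_params`.
#' @export
ventricular_params <- function(mean_rr = 0.8, rr_cv = 0.15, qrs_amp = 1000,
                               t_amp = 200, qrst_duration = 0.45, seed = 2L) {
  if (mean_rr <= qrst_duration)
    stop_fw("fw_bad_param", "mean_rr (%g s) must exceed qrst_duration (%g s)",
            mean_rr, qrst_duration)
  if (rr_cv < 0) stop_fw("fw_bad_param", "rr_cv must be >= 0")
  if (qrs_amp <= 0) stop_fw("fw_bad_param", "qrs_amp must be > 0")
  structure(list(mean_rr = mean_rr, rr_cv = rr_cv, qrs_amp = qrs_amp,
                 t_amp = t_amp, qrst_duration = qrst_duration,
                 seed = as.integer(seed)),
            class = "ventricular_params")
}

#' Generate a synthetic fibrillatory wave
#'
#' Returns `sum_k a_k sin(2 pi k f0 t + k phi(t) + theta_k)` with
#' `a_k = harmonic_decay^(k-1)`, random initial phases `theta_k` drawn from
#' the seed, amplitude modulation `(1 + am_depth sin(2 pi am_freq t))` and
#' phase modulation such that the instantaneous fundamental equals
#' `f0 (1 + fm_depth sin(2 pi fm_freq t))`. The wave is rescaled so that the
#' median peak-to-trough amplitude of successive extrema equals
#' `peak_to_peak`. Deterministic given the seed.
#'
#' @param params an [fwave_params()] object.
#' @param fs sampling rate (Hz); must satisfy `fs >= 4 * f0 * n_harmonics`
#'   so no modelled harmonic aliases.
#' @param duration epoch duration (s).
#' @return numeric waveform in uV, `round(fs * duration)` samples.
#' @export
gen_fwave <- function(params = fwave_params(), fs, duration) {
  stopifnot(inherits(params, "fwave_params"))
  if (fs < 4 * params$f0 * params$n_harmonics)
    stop_fw("fw_aliasing",
            "fs = %g Hz is below 4 * f0 * n_harmonics = %g Hz: modelled harmonics would alias",
            fs, 4 * params$f0 * params$n_harmonics)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  theta <- with_seed(params$seed, runif(params$n_harmonics, 0, 2 * pi))
  # integrated instantaneous phase of the fundamental
  if (params$fm_depth > 0 && params$fm_freq > 0) {
    phi <- 2 * pi * params$f0 *
      (t + params$fm_depth / (2 * pi * params$fm_freq) *
         (1 - cos(2 * pi * params$fm_freq * t)))
  } else {
    phi <- 2 * pi * params$f0 * t
  }
  y <- numeric(n)
  for (k in seq_len(params$n_harmonics)) {
    y <- y + params$harmonic_decay^(k - 1) * sin(k * phi + theta[k])
  }
  if (params$am_depth > 0) {
    y <- y * (1 + params$am_depth * sin(2 * pi * params$am_freq * t))
  }
  amps <- peak_trough_amplitudes(y, fs)
  scale_ref <- if (length(amps) >= 2) median(amps) else diff(range(y))
  y * (params$peak_to_peak / scale_ref)
}

# fixed-shape QRST template built from raised-cosine segments; returns the
# waveform over [-pre_r, qrst_duration - pre_r] around the R peak.
qrst_template <- function(fs, qrs_amp, t_amp, qrst_duration, pre_r = 0.06) {
  t <- seq(-pre_r, qrst_duration - pre_r, by = 1 / fs)
  rc <- function(center, width, amp) {
    v <- numeric(length(t))
    in_w <- abs(t - center) <= width / 2
    v[in_w] <- amp / 2 * (1 + cos(2 * pi * (t[in_w] - center) / width))
    v
  }
  t_center <- min(0.27, qrst_duration - pre_r - 0.13)
  rc(-0.035, 0.030, -0.15 * qrs_amp) +  # Q dip
    rc(0.000, 0.050, qrs_amp) +         # R spike
    rc(0.035, 0.030, -0.25 * qrs_amp) + # S dip
    rc(t_center, 0.24, t_amp)           # T wave
}

#' Generate synthetic ventricular activity at irregular RR intervals
#'
#' Each beat places a fixed QRST template (Q dip, R spike, S dip, smooth
#' raised-cosine T wave) at its R time; RR intervals are log-normal with the
#' requested mean and CV, truncated to exceed the QRST duration. RR
#' intervals are quantized to whole samples, so with `rr_cv = 0` successive
#' R indices differ by exactly `round(mean_rr * fs)`.
#'
#' @param params a [ventricular_params()] object.
#' @param fs sampling rate (Hz).
#' @param duration epoch duration (s); must be at least `3 * mean_rr`.
#' @return list with `waveform` (uV, zero outside QRST supports) and
#'   `r_times` (1-based sample indices of the true R peaks).
#' @export
gen_ventricular <- function(params = ventricular_params(), fs, duration) {
  stopifnot(inherits(params, "ventricular_params"))
  if (duration < 3 * params$mean_rr)
    stop_fw("fw_bad_param", "duration must be >= 3 * mean_rr")
  n <- round(fs * duration)
  draw_rr <- function(k) {
    if (params$rr_cv == 0) return(rep(params$mean_rr, k))
    s2 <- log(1 + params$rr_cv^2)
    mu <- log(params$mean_rr) - s2 / 2
    rr <- rlnorm(k, mu, sqrt(s2))
    while (any(bad <- rr <= params$qrst_duration)) {
      rr[bad] <- rlnorm(sum(bad), mu, sqrt(s2))
    }
    rr
  }
  r_times <- with_seed(params$seed, {
    # generous upper bound on beat count, then trim to the epoch
    k <- ceiling(duration / params$qrst_duration) + 3L
    rr <- draw_rr(k)
    first <- max(1L, round(runif(1, 0.3, 0.7) * params$mean_rr * fs))
    idx <- first + c(0L, cumsum(round(rr * fs)))
    idx[idx <= n]
  })
  pre_r <- 0.06
  tpl <- qrst_template(fs, params$qrs_amp, params$t_amp, params$qrst_duration,
                       pre_r = pre_r)
  wav <- numeric(n)
  off <- -round(pre_r * fs)
  for (r in r_times) {
    lo <- r + off
    sel <- seq_along(tpl) + lo - 1L
    keep <- sel >= 1L & sel <= n
    wav[sel[keep]] <- wav[sel[keep]] + tpl[keep]
  }
  list(waveform = wav, r_times = r_times)
}

default_lead_gains <- function() {
  c(I = 0.5, II = 1.0, V1 = 0.7, V6 = 0.9)
}

#' Per-lead default f-wave amplitudes (uV peak-to-peak)
#'
#' Defaults follow the magnitude ordering seen across the four analyzed
#' surface leads in AF cohorts: V1 carries the largest f waves (closest to
#' the right atrium), lead I the smallest.
#' @export
default_fwave_amplitudes <- function() {
  c(I = 45, II = 65, V1 = 70, V6 = 57)
}

#' Noise specification for the synthetic ECG
#'
#' @param white_rms white (broadband) noise RMS in uV.
#' @param baseline_rms baseline-wander RMS in uV (sum of sub-0.5 Hz
#'   sinusoids with random phase).
#' @param powerline_rms powerline tone RMS in uV.
#' @param powerline_hz powerline frequency (Hz).
#' @param seed integer seed.
#' @export
noise_spec <- function(white_rms = 10, baseline_rms = 0, powerline_rms = 0,
                       powerline_hz = 60, seed = 3L) {
  structure(list(white_rms = white_rms, baseline_rms = baseline_rms,
                 powerline_rms = powerline_rms, powerline_hz = powerline_hz,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

gen_noise <- function(spec, fs, n) {
  t <- (seq_len(n) - 1) / fs
  with_seed(spec$seed, {
    out <- numeric(n)
    if (spec$white_rms > 0) out <- out + rnorm(n, 0, spec$white_rms)
    if (spec$baseline_rms > 0) {
      f <- c(0.12, 0.25, 0.4)
      ph <- runif(3, 0, 2 * pi)
      bl <- rowSums(sapply(1:3, function(i) sin(2 * pi * f[i] * t + ph[i])))
      out <- out + bl * (spec$baseline_rms / rms(bl))
    }
    if (spec$powerline_rms > 0) {
      out <- out + sqrt(2) * spec$powerline_rms *
        sin(2 * pi * spec$powerline_hz * t + runif(1, 0, 2 * pi))
    }
    out
  })
}

#' Generate a multi-lead synthetic AF ECG epoch with ground truth
#'
#' Per lead, the epoch is the sum of a lead-specific fibrillatory wave, the
#' shared ventricular QRST train scaled by a lead gain, and additive noise
#' (white, baseline wander, powerline). The returned ground truth carries
#' the pure atrial signal of every lead, the true R sample indices and the
#' generating parameters.
#'
#' @param fwave named list of [fwave_params()] per lead, or a single
#'   `fwave_params` applied to every lead (per-lead amplitudes from
#'   [default_fwave_amplitudes()] and distinct derived seeds).
#' @param ventricular a [ventricular_params()] object.
#' @param noise a [noise_spec()] object (a distinct derived seed is used per
#'   lead).
#' @param fs sampling rate (Hz), default 2000.
#' @param duration epoch duration (s), default 10.
#' @param leads lead labels; must include I, II, V1 and V6.
#' @param lead_gains named ventricular gain per lead.
#' @return list with `epoch` (an [ecg_epoch()]) and `truth`
#'   (`r_times`, `atrial_true` list per lead, `params`).
#' @export
gen_af_ecg <- function(fwave = NULL, ventricular = ventricular_params(),
                       noise = noise_spec(), fs = 2000, duration = 10,
                       leads = c("I", "II", "V1", "V6"),
                       lead_gains = default_lead_gains()) {
  leads <- canonical_lead(leads)
  required <- c("I", "II", "V1", "V6")
  if (!all(required %in% leads))
    stop_fw("fw_bad_lead", "leads must include %s",
            paste(setdiff(required, leads), collapse = ", "))
  known <- names(default_fwave_amplitudes())
  if (!all(leads %in% known))
    stop_fw("fw_bad_lead", "unknown lead label: %s",
            paste(setdiff(leads, known), collapse = ", "))

  use_default_amps <- is.null(fwave)
  if (use_default_amps) fwave <- fwave_params()
  if (inherits(fwave, "fwave_params")) {
    # replicate one parameter set across leads with derived per-lead seeds;
    # with fwave = NULL the lead-specific default amplitudes apply
    amps <- default_fwave_amplitudes()
    base <- fwave
    fwave <- setNames(lapply(seq_along(leads), function(i) {
      p <- base
      if (use_default_amps) p$peak_to_peak <- unname(amps[leads[i]])
      p$seed <- child_seed(base$seed, i)
      p
    }), leads)
  }
  if (!all(leads %in% names(fwave)))
    stop_fw("fw_bad_lead", "fwave params missing for lead(s): %s",
            paste(setdiff(leads, names(fwave)), collapse = ", "))

  vent <- gen_ventricular(ventricular, fs, duration)
  n <- round(fs * duration)
  atrial <- lapply(leads, function(ld) gen_fwave(fwave[[ld]], fs, duration))
  names(atrial) <- leads
  mat <- sapply(seq_along(leads), function(i) {
    ld <- leads[i]
    ns <- noise
    ns$seed <- child_seed(noise$seed, i)
    atrial[[ld]] + unname(lead_gains[ld]) * vent$waveform + gen_noise(ns, fs, n)
  })
  colnames(mat) <- leads
  epoch <- ecg_epoch(mat, fs = fs, leads = leads)
  list(epoch = epoch,
       truth = list(r_times = vent$r_times, atrial_true = atrial,
                    params = list(fwave = fwave, ventricular = ventricular,
                                  noise = noise)))
}
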
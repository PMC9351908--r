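# The five per-lead complexity parameters of the extracted atrial signal:
# FWA and SampEn in the time domain, DF, OI and SE in the frequency domain.

# pull (samples, fs) out of an atrial_signal or a plain numeric + fs
as_signal <- function(x, fs = NULL) {
  if (inherits(x, "atrial_signal")) list(x = x$samples, fs = x$fs)
  else {
    if (is.null(fs)) stop_fw("fw_bad_param", "fs required for a plain waveform")
    list(x = as.numeric(x), fs = fs)
  }
}

# Alternating local extrema of a lightly smoothed signal, each refined to
# the raw-signal extremum nearby. Shared by the FWA estimator and by the
# f-wave generator's amplitude rescaling so the two use one convention.
fwave_extrema <- function(x, fs, smooth_s = 0.02, min_sep_s = 0.04,
                          refine_s = 0.01) {
  s <- moving_average(x, round(smooth_s * fs))
  ds <- diff(s)
  sg <- sign(ds)
  sg[sg == 0] <- 1
  turn <- which(diff(sg) != 0) + 1L
  if (!length(turn)) return(list(idx = integer(), val = numeric(),
                                 is_max = logical()))
  typ <- sg[turn - 1L] > 0  # TRUE = local maximum
  # collapse runs of same-type extrema, keeping the most extreme
  out_i <- integer(0); out_t <- logical(0)
  for (k in seq_along(turn)) {
    last <- length(out_i)
    if (last && out_t[last] == typ[k]) {
      better <- if (typ[k]) s[turn[k]] > s[out_i[last]] else s[turn[k]] < s[out_i[last]]
      if (better) out_i[last] <- turn[k]
    } else {
      out_i <- c(out_i, turn[k]); out_t <- c(out_t, typ[k])
    }
  }
  # enforce the minimum separation, dropping the less prominent member and
  # restoring alternation
  min_gap <- round(min_sep_s * fs)
  repeat {
    v <- which(diff(out_i) < min_gap)
    if (!length(v) || length(out_i) < 2) break
    k <- v[1]
    dev <- abs(s[out_i[c(k, k + 1L)]] - median(s))
    drop <- if (dev[1] <= dev[2]) k else k + 1L
    out_i <- out_i[-drop]; out_t <- out_t[-drop]
    j <- 2L
    while (j <= length(out_i)) {
      if (out_t[j] == out_t[j - 1L]) {
        worse <- if (out_t[j]) which.min(s[out_i[c(j - 1L, j)]])
                 else which.max(s[out_i[c(j - 1L, j)]])
        out_i <- out_i[-(j - 2L + worse)]; out_t <- out_t[-(j - 2L + worse)]
      } else j <- j + 1L
    }
  }
  half <- as.integer(round(refine_s * fs))
  ref <- vapply(seq_along(out_i), function(k) {
    lo <- max(1L, out_i[k] - half); hi <- min(length(x), out_i[k] + half)
    as.integer(if (out_t[k]) lo - 1L + which.max(x[lo:hi])
               else lo - 1L + which.min(x[lo:hi]))
  }, integer(1))
  list(idx = ref, val = x[ref], is_max = out_t)
}

# successive peak-to-trough amplitudes (uV)
peak_trough_amplitudes <- function(x, fs, ...) {
  ext <- fwave_extrema(x, fs, ...)
  if (length(ext$val) < 2) return(numeric())
  abs(diff(ext$val))
}

#' Fibrillatory wave amplitude (FWA)
#'
#' Mean absolute difference between successive alternating extrema (mean
#' peak-to-trough) of the atrial signal, in uV. Extrema are located on a
#' 20-ms smoothed copy, required to be >= 40 ms apart, and refined to the
#' raw-signal extrema so smoothing does not bias the amplitude.
#'
#' @param atrial an `atrial_signal` or numeric waveform (uV).
#' @param fs sampling rate (Hz), required for a plain waveform.
#' @return FWA in uV; attribute `reliable` is FALSE when fewer than 4
#'   extrema were found.
#' @export
compute_fwa <- function(atrial, fs = NULL) {
  sg <- as_signal(atrial, fs)
  if (length(sg$x) < 2 * sg$fs)
    stop_fw("fw_too_short", "FWA needs at least 2 s of signal")
  ext <- fwave_extrema(sg$x, sg$fs)
  amps <- if (length(ext$val) >= 2) abs(diff(ext$val)) else numeric()
  out <- if (length(amps)) mean(amps) else 0
  attr(out, "reliable") <- length(ext$val) >= 4
  out
}

#' Welch power spectral density of the atrial signal
#'
#' Welch estimate with 2-s Hann segments at 50% overlap, zero-padded to a
#' 0.1-Hz display grid. The analysis band for DF and SE is \[3, 12\] Hz; a
#' wider \[3, 25\] Hz band is retained for the OI harmonics.
#'
#' @param atrial an `atrial_signal` or numeric waveform (uV).
#' @param fs sampling rate (Hz) for a plain waveform.
#' @param seg_s segment length (s).
#' @param grid_hz spectral grid spacing (Hz).
#' @param band_df,band_oi analysis bands (Hz).
#' @return object of class `spectral_summary` with `freqs`, `psd`
#'   (uV^2/Hz), `band_df`, `band_oi`, `resolution`, `fs`.
#' @export
estimate_spectrum <- function(atrial, fs = NULL, seg_s = 2, grid_hz = 0.1,
                              band_df = c(3, 12), band_oi = c(3, 25)) {
  sg <- as_signal(atrial, fs)
  x <- sg$x; fs <- sg$fs
  if (length(x) < 4 * fs)
    stop_fw("fw_too_short", "spectral analysis needs at least 4 s of signal")
  nseg <- round(seg_s * fs)
  step <- nseg %/% 2L
  nfft <- max(nseg, round(fs / grid_hz))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))  # Hann
  U <- sum(w^2)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- numeric(nfft)
  for (s0 in starts) {
    seg <- w * x[s0:(s0 + nseg - 1L)]
    X <- fft(c(seg, numeric(nfft - nseg)))
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * U)
  half <- nfft %/% 2L
  psd <- pxx[1:(half + 1L)]
  psd[2:half] <- 2 * psd[2:half]  # one-sided
  freqs <- (0:half) * fs / nfft
  # the zero-padded grid interpolates the spectrum for display and for
  # fine peak localization; the estimator's natural resolution is fs/nseg,
  # whose bins are the subsample below (energy accounting for OI happens
  # there, where a windowed tone's power is not smeared by interpolation)
  stride <- nfft %/% nseg
  nat <- seq(1L, half + 1L, by = stride)
  structure(list(freqs = freqs, psd = psd,
                 freqs_native = freqs[nat], psd_native = psd[nat],
                 band_df = band_df, band_oi = band_oi,
                 resolution = fs / nfft, native_resolution = fs / nseg,
                 fs = fs),
            class = "spectral_summary")
}

band_idx <- function(spec, band) {
  which(spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9)
}

#' Dominant frequency (DF)
#'
#' Frequency of the maximum PSD value within the fibrillatory band
#' (\[3, 12\] Hz by default); ties break toward the lower frequency. The
#' value is flagged invalid (NA) when the band carries no power, or when
#' the in-band maximum sits on a band edge without being a local peak of
#' the full spectrum (an out-of-band tone leaking in).
#'
#' @param spec a `spectral_summary`.
#' @return DF in Hz (NA when flagged); attribute `flag` explains why.
#' @export
compute_df <- function(spec) {
  stopifnot(inherits(spec, "spectral_summary"))
  bi <- band_idx(spec, spec$band_df)
  p <- spec$psd[bi]
  if (!any(p > 0)) {
    out <- NA_real_; attr(out, "flag") <- "no_band_power"; return(out)
  }
  k <- which.max(p)  # which.max returns the first (lowest-frequency) tie
  gi <- bi[k]
  # the in-band maximum is only a meaningful DF if no component outside the
  # band dominates the physiologic neighborhood (an out-of-band tone leaks
  # its skirt into the band); the factor-2 margin keeps noise fluctuation
  # from triggering the flag
  nbr <- spec$freqs >= 0.5 & spec$freqs <= spec$band_oi[2] &
    (spec$freqs < spec$band_df[1] - 1e-9 | spec$freqs > spec$band_df[2] + 1e-9)
  if (any(nbr) && max(spec$psd[nbr]) > 2 * p[k]) {
    out <- NA_real_; attr(out, "flag") <- "out_of_band_peak"; return(out)
  }
  out <- spec$freqs[gi]
  attr(out, "flag") <- "ok"
  out
}

#' Organization index (OI)
#'
#' Fraction of the \[3, 25\] Hz atrial spectral power concentrated in
#' +/-0.5 Hz windows around the DF and its harmonics (k = 1..4, restricted
#' to k*DF <= 25 Hz), clipped to \[0, 1\]. Higher values mean more
#' organized fibrillation. Power is accounted on the estimator's natural
#' frequency grid (segment-length resolution), not on the interpolated
#' display grid.
#'
#' @param spec a `spectral_summary`.
#' @param df dominant frequency (Hz), from [compute_df()].
#' @param half_width harmonic window half-width (Hz).
#' @param n_harmonics number of harmonics considered.
#' @return OI in \[0, 1\] (NA when the denominator is zero or `df` is NA).
#' @export
compute_oi <- function(spec, df, half_width = 0.5, n_harmonics = 4) {
  stopifnot(inherits(spec, "spectral_summary"))
  if (is.na(df)) { out <- NA_real_; attr(out, "flag") <- "no_df"; return(out) }
  bi <- which(spec$freqs_native >= spec$band_oi[1] - 1e-9 &
                spec$freqs_native <= spec$band_oi[2] + 1e-9)
  denom <- sum(spec$psd_native[bi])
  if (denom <= 0) { out <- NA_real_; attr(out, "flag") <- "no_band_power"; return(out) }
  f <- spec$freqs_native[bi]
  harm <- (1:n_harmonics) * df
  harm <- harm[harm <= spec$band_oi[2]]
  in_win <- Reduce(`|`, lapply(harm, function(h) abs(f - h) <= half_width + 1e-9))
  out <- min(1, max(0, sum(spec$psd_native[bi][in_win]) / denom))
  attr(out, "flag") <- "ok"
  out
}

#' Spectral entropy (SE)
#'
#' Shannon entropy (natural log, nats) of the PSD normalized to a
#' probability distribution over the \[3, 12\] Hz band on the 0.1-Hz grid
#' (91 bins, so the maximum is ln(91) ~ 4.51 for a flat band). The absolute
#' value depends on this binning; comparisons are only meaningful at a
#' fixed grid.
#'
#' @param spec a `spectral_summary`.
#' @return SE in nats (NA when the band carries no power); attribute
#'   `n_bins` gives the bin count.
#' @export
compute_se <- function(spec) {
  stopifnot(inherits(spec, "spectral_summary"))
  bi <- band_idx(spec, spec$band_df)
  p <- spec$psd[bi]
  tot <- sum(p)
  if (tot <= 0) { out <- NA_real_; attr(out, "flag") <- "no_band_power"; return(out) }
  p <- p / tot
  nz <- p > 0
  out <- -sum(p[nz] * log(p[nz]))
  attr(out, "n_bins") <- length(bi)
  attr(out, "flag") <- "ok"
  out
}

#' Sample entropy configuration
#'
#' Defaults m = 2, r = 0.2 SD on a 250-Hz resampled signal are the standard
#' SampEn parameters for short physiological series; a 10-s epoch gives
#' N = 2500 points, keeping the O(N^2) match count affordable.
#'
#' @param m embedding dimension (>= 1).
#' @param r_frac tolerance as a fraction of the SD of the resampled signal.
#' @param resample_fs analysis sampling rate (Hz).
#' @export
sampen_config <- function(m = 2L, r_frac = 0.2, resample_fs = 250) {
  if (m < 1) stop_fw("fw_bad_param", "m must be >= 1")
  if (r_frac <= 0 || r_frac >= 1) stop_fw("fw_bad_param", "r_frac must be in (0, 1)")
  structure(list(m = as.integer(m), r_frac = r_frac,
                 resample_fs = resample_fs), class = "sampen_config")
}

#' Sample entropy (SampEn)
#'
#' The signal is decimated (anti-aliased FIR) to `resample_fs`; the
#' tolerance is `r_frac` times the SD of the resampled signal. Template
#' matches of length m (count B) and m+1 (count A) under the Chebyshev
#' distance are counted over unordered template pairs, self-matches
#' excluded; SampEn = -ln(A/B).
#'
#' @param atrial an `atrial_signal` or numeric waveform.
#' @param cfg a [sampen_config()].
#' @param fs sampling rate (Hz) for a plain waveform.
#' @return SampEn (unitless). NA with flag `"undefined"` when B = 0; when
#'   A = 0 the finite upper bound ln(B) is returned with flag `"capped"`.
#' @export
compute_sampen <- function(atrial, cfg = sampen_config(), fs = NULL) {
  sg <- as_signal(atrial, fs)
  if (cfg$resample_fs > sg$fs)
    stop_fw("fw_bad_param", "resample_fs exceeds the signal sampling rate")
  q <- sg$fs / cfg$resample_fs
  if (abs(q - round(q)) > 1e-9)
    stop_fw("fw_bad_param", "fs must be an integer multiple of resample_fs")
  q <- as.integer(round(q))
  xr <- if (q > 1L) signal::decimate(sg$x, q, ftype = "fir") else sg$x
  if (length(xr) < 100)
    stop_fw("fw_too_short", "SampEn needs >= 100 resampled points, got %d",
            length(xr))
  r <- cfg$r_frac * sd(xr)
  if (!is.finite(r)) r <- 0
  cnt <- sampen_counts(as.numeric(xr), cfg$m, r)
  if (cnt$B == 0) { out <- NA_real_; attr(out, "flag") <- "undefined"; return(out) }
  if (cnt$A == 0) { out <- log(cnt$B); attr(out, "flag") <- "capped"; return(out) }
  out <- -log(cnt$A / cnt$B)
  attr(out, "flag") <- "ok"
  out
}

#' Analyze a multi-lead epoch end to end
#'
#' Runs band-limiting, R-peak detection (on lead II by default -- beat
#' times are lead-invariant and the shared impulse train is reused for all
#' leads), ESAF cancellation, and all five complexity metrics per lead.
#'
#' Metrics are computed on the residual with one kernel span trimmed from
#' each end of the epoch (`edge_guard`): near the record edges the band-pass
#' filter's reflection padding distorts the waveform and beats lack full
#' kernel support, so cancellation there is unreliable.
#'
#' @param epoch an [ecg_epoch()].
#' @param esaf_cfg an [esaf_config()].
#' @param sampen_cfg a [sampen_config()].
#' @param r_lead lead used for R detection (falls back to the first lead).
#' @param edge_guard seconds excluded from each end of the residual before
#'   metric computation; defaults to the ESAF kernel span.
#' @return data.frame, one row per lead: `lead`, `fwa_uV`, `df_Hz`, `oi`,
#'   `se_nats`, `sampen`, `n_beats`, `suppression_db`, `flags`.
#' @export
analyze_epoch <- function(epoch, esaf_cfg = esaf_config(),
                          sampen_cfg = sampen_config(), r_lead = "II",
                          edge_guard = esaf_cfg$kernel_pre + esaf_cfg$kernel_post) {
  stopifnot(inherits(epoch, "ecg_epoch"))
  fs <- epoch$fs
  filt <- apply(epoch$samples, 2, bandlimit_ecg, fs = fs)
  colnames(filt) <- epoch$leads
  r_lead <- canonical_lead(r_lead)
  if (!r_lead %in% epoch$leads) r_lead <- epoch$leads[1]
  peaks <- detect_r_peaks(filt[, r_lead], fs)
  train <- build_impulse_train(peaks, nrow(filt))
  rows <- lapply(epoch$leads, function(ld) {
    at <- tryCatch(esaf_cancel(filt[, ld], train, esaf_cfg, lead = ld),
                   error = function(e)
                     stop_fw("fw_lead_failed", "lead %s: %s", ld,
                             conditionMessage(e)))
    supp <- qrst_suppression_db(filt[, ld], at$samples, peaks)
    g <- round(edge_guard * fs)
    core <- at$samples[(g + 1):(length(at$samples) - g)]
    fwa <- compute_fwa(core, fs = fs)
    spec <- estimate_spectrum(core, fs = fs)
    df <- compute_df(spec)
    oi <- compute_oi(spec, df)
    se <- compute_se(spec)
    sampen <- compute_sampen(core, cfg = sampen_cfg, fs = fs)
    flags <- c(at$flags,
               if (!isTRUE(attr(fwa, "reliable"))) "fwa_unreliable",
               if (!identical(attr(df, "flag"), "ok")) paste0("df_", attr(df, "flag")),
               if (isTRUE(attr(supp, "capped"))) "suppression_capped")
    data.frame(lead = ld, fwa_uV = as.numeric(fwa), df_Hz = as.numeric(df),
               oi = as.numeric(oi), se_nats = as.numeric(se),
               sampen = as.numeric(sampen), n_beats = at$n_beats,
               suppression_db = as.numeric(supp),
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
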
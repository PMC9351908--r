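# Band-limiting, R-peak detection and the R-synchronized impulse train that
# drives the event-synchronous adaptive filter.

#' Zero-phase band-limiting of an ECG lead to ~1-32 Hz
#'
#' A linear-phase FIR band-pass (Hamming-window design, 2-s support, -6 dB
#' points at `low` and `high`) applied by symmetric-reflection padding and
#' centered convolution, which makes the overall response exactly zero
#' phase. The signal mean is removed first, so DC and slow drift are
#' rejected and powerline tones fall deep in the stop band.
#'
#' @param x waveform (uV).
#' @param fs sampling rate (Hz), must be >= 128.
#' @param low,high band edges (Hz).
#' @return filtered waveform, same length as `x`.
#' @export
bandlimit_ecg <- function(x, fs, low = 1, high = 32) {
  if (fs < 128) stop_fw("fw_bad_param", "fs must be >= 128 Hz")
  if (length(x) < 2 * fs)
    stop_fw("fw_too_short",
            "signal (%d samples) shorter than the 2-s filter support", length(x))
  h <- fir_bandpass_kernel(fs, low, high)
  conv_same_sym(x - mean(x), h)
}

# cache FIR kernels per (fs, low, high) within a session
.fir_cache <- new.env(parent = emptyenv())
fir_bandpass_kernel <- function(fs, low, high) {
  key <- sprintf("%g_%g_%g", fs, low, high)
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  ord <- 2L * round(fs)           # even order -> odd length, symmetric
  h <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  .fir_cache[[key]] <- h
  h
}

# zero-phase "same" convolution with a symmetric odd-length kernel, using
# symmetric reflection padding and FFT-based convolution
conv_same_sym <- function(x, h) {
  n <- length(x)
  pad <- (length(h) - 1L) %/% 2L
  if (pad >= n) stop_fw("fw_too_short", "signal shorter than filter support")
  xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  m <- length(xp) + length(h) - 1L
  nfft <- 2^ceiling(log2(m))
  X <- fft(c(xp, numeric(nfft - length(xp))))
  H <- fft(c(h, numeric(nfft - length(h))))
  full <- Re(fft(X * H, inverse = TRUE)) / nfft
  # full convolution index of x[i] aligned with kernel center: i + 2*pad
  full[(2L * pad + 1L):(2L * pad + n)]
}

#' R-peak series
#' @param indices strictly increasing 1-based sample positions.
#' @param fs sampling rate (Hz).
#' @param flags character vector of quality flags.
#' @export
r_peak_series <- function(indices, fs, flags = character()) {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    stop_fw("fw_bad_param", "R-peak indices must be strictly increasing")
  structure(list(indices = indices, fs = fs, flags = flags),
            class = "r_peak_series")
}

#' Detect R peaks in a band-limited ECG lead
#'
#' Energy-based detection: differentiate, square, 150-ms centered moving
#' integration, adaptive threshold at a running quantile of the integrated
#' energy, refinement of each detection to the local absolute-amplitude
#' maximum of the input within +/-50 ms, and a 200-ms refractory rule that
#' keeps the larger peak.
#'
#' Detections closer than `edge_margin` to either record end are dropped
#' (flag `"edge_beats_dropped"`): the band-pass filter's reflection padding
#' distorts the waveform there and the refinement window is clipped, so
#' peak positions are unreliable and would corrupt downstream template
#' adaptation.
#'
#' @param x band-limited waveform (uV).
#' @param fs sampling rate (Hz).
#' @param refractory minimum peak spacing (s).
#' @param edge_margin seconds at each record end where detections are
#'   discarded.
#' @return an [r_peak_series()]; empty (with a `"flat_signal"` flag and a
#'   warning) on a flat input.
#' @export
detect_r_peaks <- function(x, fs, refractory = 0.2, edge_margin = 0.15) {
  n <- length(x)
  if (n < 2 * fs) stop_fw("fw_too_short", "need at least 2 s of signal")
  if (all(abs(x - x[1]) < 1e-9)) {
    warning("flat signal: no R peaks detectable")
    return(r_peak_series(integer(), fs, flags = "flat_signal"))
  }
  energy <- moving_average(c(diff(x), 0)^2, round(0.15 * fs))
  # running quantile on a 1-s block grid, median-smoothed, interpolated
  block <- round(fs)
  starts <- seq(1L, n, by = block)
  q <- vapply(starts, function(s) {
    quantile(energy[s:min(s + block - 1L, n)], 0.98, names = FALSE)
  }, 0)
  if (length(q) >= 3) {
    q <- vapply(seq_along(q), function(i) {
      median(q[max(1, i - 2):min(length(q), i + 2)])
    }, 0)
  }
  thr <- approx(pmin(starts + block / 2, n), q, xout = seq_len(n),
                rule = 2)$y * 0.3
  above <- energy > thr
  if (!any(above)) return(r_peak_series(integer(), fs, flags = "no_peaks"))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  cand <- mapply(function(b, e) b - 1L + which.max(energy[b:e]),
                 begins[r$values], ends[r$values])
  # refine to the local absolute-amplitude maximum of the input
  half <- as.integer(round(0.05 * fs))
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    lo - 1L + which.max(abs(x[lo:hi]))
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory: iteratively drop the smaller of any pair closer than 200 ms
  min_gap <- round(refractory * fs)
  repeat {
    d <- diff(peaks)
    v <- which(d < min_gap)
    if (!length(v)) break
    i <- v[1]
    drop <- if (abs(x[peaks[i]]) >= abs(x[peaks[i + 1]])) i + 1L else i
    peaks <- peaks[-drop]
  }
  margin <- round(edge_margin * fs)
  inside <- peaks > margin & peaks <= n - margin
  flags <- if (all(inside)) character() else "edge_beats_dropped"
  r_peak_series(peaks[inside], fs, flags = flags)
}

#' Build the R-synchronized impulse train
#'
#' @param peaks an [r_peak_series()].
#' @param length train length in samples.
#' @return object of class `impulse_train` with unit impulses exactly at the
#'   peak indices.
#' @export
build_impulse_train <- function(peaks, length) {
  stopifnot(inherits(peaks, "r_peak_series"))
  length <- as.integer(length)
  if (base::length(peaks$indices) && max(peaks$indices) > length)
    stop_fw("fw_out_of_range", "peak index %d exceeds train length %d",
            max(peaks$indices), length)
  structure(list(impulse_positions = peaks$indices, length = length,
                 fs = peaks$fs),
            class = "impulse_train")
}

#' Dense 0/1 view of an impulse train
#' @param train an `impulse_train`.
#' @export
impulse_vector <- function(train) {
  v <- numeric(train$length)
  v[train$impulse_positions] <- 1
  v
}
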
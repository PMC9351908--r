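# Event-synchronous adaptive filtering: learn the R-locked ventricular
# (QRST) waveform from the impulse-train reference and subtract it, leaving
# the atrial (fibrillatory) signal.

#' ESAF configuration
#'
#' The kernel spans `[-kernel_pre, +kernel_post)` around each R peak
#' (default 0.25 s + 0.45 s, covering Q to T-end at AF rates). `step_size`
#' is the normalized-LMS adaptation rate; `n_passes` training sweeps are
#' made over the epoch, the last at a tenth of the step size while the
#' residual is generated.
#'
#' @param kernel_pre seconds of kernel support before the R peak.
#' @param kernel_post seconds after.
#' @param step_size normalized LMS rate, in (0, 2).
#' @param n_passes number of sweeps (>= 1).
#' @export
esaf_config <- function(kernel_pre = 0.25, kernel_post = 0.45,
                        step_size = 0.05, n_passes = 3L) {
  if (step_size <= 0 || step_size >= 2)
    stop_fw("fw_bad_param", "step_size must lie in (0, 2)")
  if (n_passes < 1) stop_fw("fw_bad_param", "n_passes must be >= 1")
  structure(list(kernel_pre = kernel_pre, kernel_post = kernel_post,
                 step_size = step_size, n_passes = as.integer(n_passes)),
            class = "esaf_config")
}

# R-locked mean beat over beats whose full kernel support lies inside the
# record; the standard average-beat estimate, used to initialize the kernel.
mean_beat <- function(x, r_times, pre_s, post_s) {
  L <- pre_s + post_s
  full <- r_times[r_times - pre_s >= 1 & r_times + post_s - 1 <= length(x)]
  if (!length(full)) return(numeric(L))
  seg <- vapply(full, function(r) x[(r - pre_s):(r + post_s - 1)], numeric(L))
  rowMeans(seg)
}

#' Cancel ventricular activity with the event-synchronous adaptive filter
#'
#' The impulse-train reference is advanced by `kernel_pre` so a causal FIR
#' kernel of length `round((kernel_pre + kernel_post) * fs)` spans the QRST
#' complex of every beat. The kernel starts from the R-locked mean beat and
#' is refined by normalized LMS over `n_passes` sweeps; the residual
#' (primary minus kernel convolved with the advanced train) is the atrial
#' signal. Outside kernel support the reference is zero, so the residual
#' equals the primary there exactly.
#'
#' @param filtered_lead band-limited lead waveform (uV).
#' @param train an `impulse_train` from [build_impulse_train()].
#' @param cfg an [esaf_config()].
#' @param lead lead label carried through to the result.
#' @return object of class `atrial_signal`: `samples`, `fs`, `lead`,
#'   `qrst_kernel` (the learned R-locked template), `kernel_t` (its time
#'   axis, s relative to R), `n_beats`, `flags`.
#' @export
esaf_cancel <- function(filtered_lead, train, cfg = esaf_config(), lead = NA) {
  stopifnot(inherits(train, "impulse_train"))
  r_times <- train$impulse_positions
  if (!length(r_times))
    stop_fw("fw_empty_train", "cannot cancel without beats: impulse train is empty")
  fs <- train$fs
  flags <- character()
  if (length(r_times) < 5) {
    warning("fewer than 5 beats in epoch; ESAF convergence may be poor")
    flags <- c(flags, "few_beats")
  }
  pre_s <- round(cfg$kernel_pre * fs)
  post_s <- round(cfg$kernel_post * fs)
  L <- pre_s + post_s
  if (length(r_times) >= 2 && L >= min(diff(r_times))) {
    warning("kernel span >= shortest RR interval: overlapping beats")
    flags <- c(flags, "overlapping_beats")
  }
  w0 <- mean_beat(filtered_lead, r_times, pre_s, post_s)
  fit <- esaf_nlms(as.numeric(filtered_lead),
                   as.integer(r_times - pre_s - 1L),  # 0-based advanced train
                   L, cfg$step_size, cfg$n_passes, w0)
  structure(list(samples = fit$residual, fs = fs, lead = lead,
                 qrst_kernel = fit$kernel,
                 kernel_t = (seq_len(L) - 1 - pre_s) / fs,
                 n_beats = length(r_times), flags = flags),
            class = "atrial_signal")
}

#' @export
print.atrial_signal <- function(x, ...) {
  cat(sprintf("<atrial_signal> lead %s, fs = %g Hz, %.3f s, %d beats cancelled%s\n",
              x$lead, x$fs, length(x$samples) / x$fs, x$n_beats,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Average-beat subtraction
#'
#' Plain R-locked mean-beat subtraction: the mean of the beat segments over
#' `[-window[1], +window[2])` around each R peak is subtracted at every
#' beat. Valid only when the beat windows do not overlap; serves as an
#' independent reference method for the adaptive filter.
#'
#' @param filtered_lead band-limited lead waveform (uV).
#' @param peaks an [r_peak_series()].
#' @param window `c(pre, post)` in seconds.
#' @return the beat-subtracted waveform.
#' @export
template_subtract <- function(filtered_lead, peaks, window = c(0.25, 0.45)) {
  stopifnot(inherits(peaks, "r_peak_series"))
  r_times <- peaks$indices
  if (length(r_times) < 2)
    stop_fw("fw_bad_param", "average-beat subtraction needs at least 2 beats")
  fs <- peaks$fs
  pre_s <- round(window[1] * fs)
  post_s <- round(window[2] * fs)
  L <- pre_s + post_s
  if (min(diff(r_times)) < L)
    stop_fw("fw_overlap", "beat windows overlap: average-beat subtraction invalid")
  tpl <- mean_beat(filtered_lead, r_times, pre_s, post_s)
  out <- as.numeric(filtered_lead)
  n <- length(out)
  for (r in r_times) {
    sel <- (r - pre_s):(r + post_s - 1)
    keep <- sel >= 1 & sel <= n
    out[sel[keep]] <- out[sel[keep]] - tpl[keep]
  }
  out
}

#' Ventricular suppression in decibels
#'
#' `10 log10` of the ratio of ventricular-only beat-window power of the
#' original signal to that of the residual. The ventricular-only power of
#' each signal is estimated by subtracting its out-of-window background
#' power (atrial activity and noise, which continue through the beat
#' windows) from its in-window power. Capped at +60 dB (with a `capped`
#' attribute) when the residual's ventricular power underflows.
#'
#' @param original,residual waveforms (uV).
#' @param peaks an [r_peak_series()].
#' @param window `c(pre, post)` in seconds.
#' @return numeric dB value; attribute `capped` is TRUE when the cap was hit.
#' @export
qrst_suppression_db <- function(original, residual, peaks,
                                window = c(0.25, 0.45)) {
  stopifnot(inherits(peaks, "r_peak_series"))
  if (!length(peaks$indices))
    stop_fw("fw_bad_param", "need at least one beat")
  fs <- peaks$fs
  pre_s <- round(window[1] * fs)
  post_s <- round(window[2] * fs)
  n <- length(original)
  inw <- logical(n)
  for (r in peaks$indices) {
    sel <- max(1, r - pre_s):min(n, r + post_s - 1)
    inw[sel] <- TRUE
  }
  bg_o <- if (any(!inw)) mean(original[!inw]^2) else 0
  bg_r <- if (any(!inw)) mean(residual[!inw]^2) else 0
  p_orig <- max(0, mean(original[inw]^2) - bg_o)
  p_res <- max(0, mean(residual[inw]^2) - bg_r)
  if (p_res <= p_orig * 1e-6 || p_res == 0) {
    out <- 60
    attr(out, "capped") <- TRUE
    return(out)
  }
  out <- 10 * log10(p_orig / p_res)
  attr(out, "capped") <- FALSE
  out
}
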
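#' Multi-lead ECG epoch container
#'
#' @param samples numeric matrix, one column per lead, amplitudes in uV.
#' @param fs sampling rate (Hz).
#' @param leads lead labels (defaults to column names of `samples`).
#' @param t0 epoch start offset within the source record (s).
#' @return object of class `ecg_epoch`.
#' @export
ecg_epoch <- function(samples, fs, leads = colnames(samples), t0 = 0) {
  samples <- as.matrix(samples)
  if (is.null(leads)) stop_fw("fw_missing_leads", "lead names are required")
  leads <- canonical_lead(leads)
  if (length(leads) != ncol(samples))
    stop_fw("fw_missing_leads", "one lead label per signal column required")
  if (fs <= 0) stop_fw("fw_bad_param", "fs must be > 0")
  if (!all(is.finite(samples)))
    stop_fw("fw_bad_units", "non-finite amplitudes in ECG epoch")
  colnames(samples) <- leads
  structure(list(samples = samples, fs = fs, leads = leads, t0 = t0),
            class = "ecg_epoch")
}

#' @export
print.ecg_epoch <- function(x, ...) {
  cat(sprintf("<ecg_epoch> %d leads (%s), fs = %g Hz, %.3f s, t0 = %g s\n",
              length(x$leads), paste(x$leads, collapse = ", "),
              x$fs, nrow(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Duration of an ECG epoch in seconds
#' @param epoch an `ecg_epoch`.
#' @export
epoch_duration <- function(epoch) nrow(epoch$samples) / epoch$fs

# ---------------------------------------------------------------- CSV ----

#' Write an ECG epoch as plain CSV (one column per lead, header row with
#' lead names, one row per sample, amplitudes in uV)
#'
#' @param epoch an `ecg_epoch`.
#' @param path output file.
#' @param fs_comment if TRUE (default) a `# fs=<Hz>` comment line precedes
#'   the header so the sampling rate round-trips.
#' @param header_lines optional extra `#` comment lines (provenance).
#' @export
write_ecg_csv <- function(epoch, path, fs_comment = TRUE, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  if (fs_comment) writeLines(sprintf("# fs=%.10g", epoch$fs), con)
  df <- as.data.frame(epoch$samples)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Amplitudes are assumed to be uV unless `scale` converts them (e.g.
#' `scale = 1000` for a file in mV). The sampling rate is taken from a
#' `# fs=` comment line if present, else from the `fs` argument.
#'
#' @param path CSV file with a header row of lead names.
#' @param fs sampling rate (Hz) if the file carries none.
#' @param scale multiplicative factor applied to the stored amplitudes to
#'   obtain uV.
#' @return an `ecg_epoch` with `t0 = 0`.
#' @export
read_ecg_csv <- function(path, fs = NULL, scale = 1) {
  lines <- readLines(path, n = 50)
  fs_line <- grep("^#\\s*fs=", lines, value = TRUE)
  if (length(fs_line)) fs <- as.numeric(sub("^#\\s*fs=", "", fs_line[1]))
  if (is.null(fs) || !is.finite(fs))
    stop_fw("fw_nonuniform_fs", "sampling rate unresolvable: no fs in file and none supplied")
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  numeric_names <- !is.na(suppressWarnings(as.numeric(names(df))))
  if (is.null(names(df)) || any(names(df) == "") || any(numeric_names))
    stop_fw("fw_missing_leads", "CSV lacks a lead-name header row: %s", path)
  ecg_epoch(as.matrix(df) * scale, fs = fs, leads = names(df))
}

# --------------------------------------------------------------- WFDB ----
# Minimal WFDB support: format-16 (int16 little-endian) single-segment
# records with a gain(baseline)/units field per signal.

#' Write an ECG epoch as a WFDB record (.hea + .dat, format 16)
#'
#' @param epoch an `ecg_epoch`.
#' @param record record path without extension.
#' @param gain ADC units per uV (quantization step is `1/gain` uV).
#' @export
write_wfdb <- function(epoch, record, gain = 8) {
  n <- nrow(epoch$samples)
  nsig <- ncol(epoch$samples)
  adc <- round(epoch$samples * gain)
  if (any(abs(adc) > 32767))
    stop_fw("fw_bad_units", "amplitudes overflow int16 at gain %g", gain)
  dat <- paste0(basename(record), ".dat")
  chks <- vapply(seq_len(nsig), function(j) {
    s <- sum(adc[, j]) %% 65536
    if (s >= 32768) s <- s - 65536
    as.integer(s)
  }, integer(1))
  hea <- c(sprintf("%s %d %.10g %d", basename(record), nsig, epoch$fs, n),
           sprintf("%s 16 %g(0)/uV 16 0 %d %d 0 %s",
                   dat, gain, as.integer(adc[1, ]), chks, epoch$leads))
  writeLines(hea, paste0(record, ".hea"))
  con <- file(paste0(record, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(record)
}

#' Read a WFDB record (format 16) as an ECG epoch
#'
#' Honors per-signal gain, baseline and units (uV, mV or V, converted to
#' uV). Only single-segment format-16 records, as written by
#' [write_wfdb()], are supported.
#'
#' @param record record path without extension.
#' @return an `ecg_epoch` with `t0 = 0`.
#' @export
read_wfdb <- function(record) {
  hea <- readLines(paste0(record, ".hea"))
  hea <- hea[!grepl("^#", hea)]
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  if (!is.finite(fs)) stop_fw("fw_nonuniform_fs", "no sampling rate in header")
  n <- as.integer(top[4])
  sig <- strsplit(trimws(hea[2:(1 + nsig)]), "\\s+")
  fmt <- vapply(sig, `[`, "", 2)
  if (!all(fmt == "16"))
    stop_fw("fw_bad_units", "only WFDB format 16 is supported")
  spec <- vapply(sig, `[`, "", 3)  # gain(baseline)/units
  m <- regmatches(spec, regexec("^([0-9.eE+-]+)(\\(([0-9-]+)\\))?(/(\\w+))?$", spec))
  gain <- vapply(m, function(g) as.numeric(g[2]), 0)
  base <- vapply(m, function(g) if (g[4] == "") 0 else as.numeric(g[4]), 0)
  units <- vapply(m, function(g) if (g[6] == "") "uV" else g[6], "")
  uscale <- c(uV = 1, uv = 1, mV = 1000, mv = 1000, V = 1e6)[units]
  if (any(is.na(uscale)))
    stop_fw("fw_bad_units", "unresolvable units in WFDB header: %s",
            paste(unique(units[is.na(uscale)]), collapse = ", "))
  desc <- vapply(sig, function(s) s[length(s)], "")
  con <- file(paste0(record, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = n * nsig, size = 2, endian = "little",
                 signed = TRUE)
  adc <- matrix(raw, ncol = nsig, byrow = TRUE)
  uv <- sweep(sweep(adc, 2, base, "-"), 2, gain, "/")
  uv <- sweep(uv, 2, unname(uscale), "*")
  ecg_epoch(uv, fs = fs, leads = desc)
}

#' Read an ECG record in a supported format
#'
#' @param path file path (CSV) or record path without extension (WFDB).
#' @param format `"csv"` or `"wfdb"`; guessed from the path when omitted.
#' @param ... passed to the format-specific reader.
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format, csv = read_ecg_csv(path, ...), wfdb = read_wfdb(path, ...))
}

# ---------------------------------------------------------- selection ----

#' Select a contiguous analysis epoch
#'
#' When `start` is omitted, the 10-s window minimizing a simple artifact
#' score (fraction of samples beyond +/-2 mV plus the clipped-sample count,
#' over 1-s candidate steps) is chosen, making epoch placement deterministic
#' and quality-driven.
#'
#' @param epoch an `ecg_epoch`.
#' @param start window start within the record (s), or `NULL` for the
#'   automatic choice.
#' @param duration window length (s), default 10.
#' @return the sliced `ecg_epoch`, with `t0` updated.
#' @export
select_epoch <- function(epoch, start = NULL, duration = 10) {
  n <- nrow(epoch$samples)
  len <- round(duration * epoch$fs)
  if (len > n)
    stop_fw("fw_out_of_range", "requested %g s from a %.3f s record",
            duration, n / epoch$fs)
  if (is.null(start)) {
    starts <- seq(0, floor((n - len) / epoch$fs), by = 1)
    score <- vapply(starts, function(s) {
      i0 <- round(s * epoch$fs) + 1L
      w <- epoch$samples[i0:(i0 + len - 1L), , drop = FALSE]
      mx <- max(abs(w))
      mean(abs(w) > 2000) + sum(abs(w) >= mx & mx >= 32767)
    }, 0)
    start <- starts[which.min(score)]
  }
  if (start < 0 || round(start * epoch$fs) + len > n)
    stop_fw("fw_out_of_range",
            "window [%g, %g] s exceeds the %.3f s record",
            start, start + duration, n / epoch$fs)
  i0 <- round(start * epoch$fs) + 1L
  ecg_epoch(epoch$samples[i0:(i0 + len - 1L), , drop = FALSE], fs = epoch$fs,
            leads = epoch$leads, t0 = epoch$t0 + start)
}

#' Restrict an epoch to a set of leads
#'
#' Matching is case- and whitespace-insensitive ("v1" matches "V1"); the
#' output preserves the requested order.
#'
#' @param epoch an `ecg_epoch`.
#' @param wanted lead labels to keep, default the four analysis leads.
#' @export
select_leads <- function(epoch, wanted = c("I", "II", "V1", "V6")) {
  wanted <- canonical_lead(wanted)
  missing <- setdiff(wanted, epoch$leads)
  if (length(missing))
    stop_fw("fw_missing_leads", "lead(s) not present in record: %s",
            paste(missing, collapse = ", "))
  ecg_epoch(epoch$samples[, wanted, drop = FALSE], fs = epoch$fs,
            leads = wanted, t0 = epoch$t0)
}
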
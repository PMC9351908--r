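# shared fixtures, all built in code

FS <- 2000

rms <- function(x) sqrt(mean(x^2))

# default synthetic epoch used by several end-to-end tests
make_default_sim <- function(seed = 101) {
  gen_af_ecg(fwave = fwave_params(peak_to_peak = 60, seed = seed),
             ventricular = ventricular_params(seed = seed + 1),
             noise = noise_spec(white_rms = 10, seed = seed + 2))
}

# band-limited lead + detected peaks + impulse train for one simulated lead
prep_lead <- function(sim, lead = "V1") {
  filt_ref <- bandlimit_ecg(sim$epoch$samples[, "II"], FS)
  peaks <- detect_r_peaks(filt_ref, FS)
  list(filt = bandlimit_ecg(sim$epoch$samples[, lead], FS),
       peaks = peaks,
       train = build_impulse_train(peaks, nrow(sim$epoch$samples)))
}

# independent brute-force SampEn counter (O(N^2)), used as the oracle
sampen_brute <- function(x, m, r) {
  N <- length(x)
  M <- N - m
  A <- 0; B <- 0
  for (i in 1:(M - 1)) {
    for (j in (i + 1):M) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, sampen = if (B > 0 && A > 0) -log(A / B) else NA_real_)
}

# tie-aware Mann-Whitney U based AUC oracle
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
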
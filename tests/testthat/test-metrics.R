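# the five complexity parameters

# hand-built spectral summary on the 0.1-Hz grid (for exact SE/DF cases)
fake_spec <- function(psd_band, band = c(3, 12)) {
  freqs <- seq(0, 40, by = 0.1)
  psd <- numeric(length(freqs))
  bi <- which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
  psd[bi] <- psd_band
  nat <- seq(1, length(freqs), by = 5)
  structure(list(freqs = freqs, psd = psd,
                 freqs_native = freqs[nat], psd_native = psd[nat],
                 band_df = band, band_oi = c(3, 25),
                 resolution = 0.1, native_resolution = 0.5, fs = 2000),
            class = "spectral_summary")
}

test_that("FWA of a sinusoid equals twice its amplitude", {
  t <- (0:(10 * FS - 1)) / FS
  fwa <- compute_fwa(30 * sin(2 * pi * 6 * t), fs = FS)
  expect_equal(as.numeric(fwa), 60, tolerance = 0.02)
  expect_true(attr(fwa, "reliable"))
})

test_that("FWA recovers the generator's amplitude convention", {
  y <- gen_fwave(fwave_params(peak_to_peak = 70, seed = 8), FS, 10)
  expect_equal(as.numeric(compute_fwa(y, fs = FS)), 70, tolerance = 0.05)
})

test_that("FWA of a flat signal is zero and flagged unreliable", {
  fwa <- compute_fwa(numeric(4 * FS), fs = FS)
  expect_equal(as.numeric(fwa), 0)
  expect_false(attr(fwa, "reliable"))
})

test_that("Welch tone concentration matches the Hann leakage oracle", {
  # oracle: energy fraction of a 2-s Hann-windowed on-bin tone within
  # +/-0.3 Hz, computed from the window transform directly
  n <- 2 * FS
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  W <- Mod(fft(c(w * sin(2 * pi * 6 * (0:(n - 1)) / FS),
                 numeric(20000 - n))))^2
  f <- (0:19999) * FS / 20000
  keep <- f <= FS / 2
  oracle <- sum(W[keep & abs(f - 6) <= 0.3]) / sum(W[keep])
  t <- (0:(10 * FS - 1)) / FS
  sp <- estimate_spectrum(sin(2 * pi * 6 * t), fs = FS)
  frac <- sum(sp$psd[abs(sp$freqs - 6) <= 0.3]) / sum(sp$psd)
  expect_equal(frac, oracle, tolerance = 0.02)
  expect_gt(frac, 0.75)
  # on the estimator's native grid the on-bin tone is fully concentrated
  fracn <- sum(sp$psd_native[abs(sp$freqs_native - 6) <= 0.5]) /
    sum(sp$psd_native)
  expect_gt(fracn, 0.999)
})

test_that("white-noise band power is stable across seeds within chi-square spread", {
  bp <- vapply(1:2, function(s) {
    x <- withr::with_seed(s, rnorm(20000))
    sp <- estimate_spectrum(x, fs = FS)
    bi <- sp$freqs >= 3 & sp$freqs <= 12
    sum(sp$psd[bi])
  }, 0)
  expect_lt(max(bp) / min(bp), 3)
})

test_that("integrated PSD satisfies Parseval within 5%", {
  y <- bandlimit_ecg(withr::with_seed(3, rnorm(20000, 0, 50)), FS)
  sp <- estimate_spectrum(y, fs = FS)
  expect_equal(sum(sp$psd) * sp$resolution, mean(y^2), tolerance = 0.05)
})

test_that("DF finds the fundamental of a harmonic f-wave", {
  y <- gen_fwave(fwave_params(f0 = 5, seed = 9), FS, 10)
  d <- compute_df(estimate_spectrum(y, fs = FS))
  expect_equal(as.numeric(d), 5, tolerance = 0.1)
})

test_that("DF ties break toward the lower frequency", {
  p <- numeric(91)
  p[c(21, 51)] <- 1  # equal peaks at 5 and 8 Hz
  expect_equal(as.numeric(compute_df(fake_spec(p))), 5)
})

test_that("an out-of-band tone flags DF instead of reporting its leakage", {
  t <- (0:(10 * FS - 1)) / FS
  d <- compute_df(estimate_spectrum(sin(2 * pi * 2 * t), fs = FS))
  expect_true(is.na(d))
  expect_equal(attr(d, "flag"), "out_of_band_peak")
})

test_that("OI is total for a pure on-bin tone and near 4/22 for white noise", {
  t <- (0:(10 * FS - 1)) / FS
  sp <- estimate_spectrum(sin(2 * pi * 6 * t), fs = FS)
  oi_tone <- compute_oi(sp, compute_df(sp))
  expect_gte(as.numeric(oi_tone), 0.95)
  ois <- vapply(1:15, function(s) {
    x <- withr::with_seed(s, rnorm(20000))
    spw <- estimate_spectrum(x, fs = FS)
    as.numeric(compute_oi(spw, compute_df(spw)))
  }, 0)
  expect_equal(mean(ois, na.rm = TRUE), 4 / 22, tolerance = 0.05 * 22 / 4)
  # adding broadband noise can only dilute the organization of a tone
  xn <- sin(2 * pi * 6 * t) + withr::with_seed(11, rnorm(10 * FS, 0, 0.5))
  spn <- estimate_spectrum(xn, fs = FS)
  expect_lt(as.numeric(compute_oi(spn, compute_df(spn))), as.numeric(oi_tone))
})

test_that("SE is exactly zero for one bin and ln(91) for a flat band", {
  one <- numeric(91); one[40] <- 7
  expect_equal(as.numeric(compute_se(fake_spec(one))), 0)
  flat <- rep(2.5, 91)
  expect_equal(as.numeric(compute_se(fake_spec(flat))), log(91))
  ran <- fake_spec(withr::with_seed(2, runif(91)))
  se <- as.numeric(compute_se(ran))
  expect_gte(se, 0); expect_lte(se, log(91))
})

test_that("SampEn matches the brute-force pairwise counter bit-exactly", {
  for (s in 1:3) {
    x <- withr::with_seed(s, rnorm(400))
    r <- 0.2 * sd(x)
    fast <- compute_sampen(x, sampen_config(resample_fs = 250), fs = 250)
    slow <- sampen_brute(x, m = 2, r = r)
    expect_identical(as.numeric(fast), slow$sampen)
  }
})

test_that("SampEn of a constant signal is zero by convention", {
  expect_equal(as.numeric(compute_sampen(rep(3, 500),
                                         sampen_config(resample_fs = 250),
                                         fs = 250)), 0)
})

test_that("white noise is less regular than a sinusoid under SampEn", {
  t <- (0:2499) / 250
  diffs <- vapply(1:10, function(s) {
    wn <- withr::with_seed(s, rnorm(2500))
    sn <- sin(2 * pi * 6 * t + s)
    as.numeric(compute_sampen(wn, fs = 250)) -
      as.numeric(compute_sampen(sn, fs = 250))
  }, 0)
  expect_gt(median(diffs), 0)
})

test_that("metrics are amplitude-equivariant", {
  y <- gen_fwave(fwave_params(seed = 14), FS, 10) +
    withr::with_seed(15, rnorm(20000, 0, 3))
  for (c0 in c(0.5, 4)) {
    y2 <- c0 * y
    expect_equal(as.numeric(compute_fwa(y2, fs = FS)),
                 c0 * as.numeric(compute_fwa(y, fs = FS)), tolerance = 0.01)
    s1 <- estimate_spectrum(y, fs = FS); s2 <- estimate_spectrum(y2, fs = FS)
    d1 <- compute_df(s1); d2 <- compute_df(s2)
    expect_equal(as.numeric(d2), as.numeric(d1))
    expect_equal(as.numeric(compute_oi(s2, d2)), as.numeric(compute_oi(s1, d1)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(compute_se(s2)), as.numeric(compute_se(s1)),
                 tolerance = 1e-9)
    expect_equal(as.numeric(compute_sampen(y2, fs = FS)),
                 as.numeric(compute_sampen(y, fs = FS)), tolerance = 1e-9)
  }
})

test_that("a circular shift leaves the metrics essentially unchanged", {
  y <- gen_fwave(fwave_params(seed = 16), FS, 10)
  shift <- round(0.8 * FS)
  y2 <- c(y[(shift + 1):length(y)], y[1:shift])
  expect_equal(as.numeric(compute_fwa(y2, fs = FS)),
               as.numeric(compute_fwa(y, fs = FS)), tolerance = 0.03)
  s1 <- estimate_spectrum(y, fs = FS); s2 <- estimate_spectrum(y2, fs = FS)
  expect_equal(as.numeric(compute_df(s2)), as.numeric(compute_df(s1)),
               tolerance = 0.1)
  expect_equal(as.numeric(compute_se(s2)), as.numeric(compute_se(s1)),
               tolerance = 0.15)
})

test_that("end-to-end analysis recovers planted truth and is deterministic", {
  pl <- list(I = fwave_params(peak_to_peak = 45, f0 = 6, seed = 1),
             II = fwave_params(peak_to_peak = 65, f0 = 6, seed = 2),
             V1 = fwave_params(peak_to_peak = 70, f0 = 6, seed = 3),
             V6 = fwave_params(peak_to_peak = 57, f0 = 6, seed = 4))
  sim <- gen_af_ecg(fwave = pl)
  m1 <- suppressWarnings(analyze_epoch(sim$epoch))
  v1 <- m1[m1$lead == "V1", ]
  expect_equal(v1$fwa_uV, 70, tolerance = 0.15)
  expect_equal(v1$df_Hz, 6, tolerance = 0.2)
  m2 <- suppressWarnings(analyze_epoch(sim$epoch))
  expect_identical(m1, m2)
})

test_that("a lead without atrial activity lands near the noise floor", {
  pl <- list(I = fwave_params(peak_to_peak = 45, seed = 1),
             II = fwave_params(peak_to_peak = 65, seed = 2),
             V1 = fwave_params(peak_to_peak = 1e-6, seed = 3),
             V6 = fwave_params(peak_to_peak = 57, seed = 4))
  sim <- gen_af_ecg(fwave = pl, noise = noise_spec(white_rms = 5))
  m <- suppressWarnings(analyze_epoch(sim$epoch))
  # the atrial-free lead reads only cancellation residue and noise: well
  # below the smallest planted f-wave amplitude (45 uV on lead I)
  expect_lt(m$fwa_uV[m$lead == "V1"], 0.7 * min(m$fwa_uV[m$lead != "V1"]))
  expect_lt(m$fwa_uV[m$lead == "V1"], 30)
})
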
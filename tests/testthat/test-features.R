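test_that("Welch PSD satisfies Parseval and resolves tones", {
  set.seed(14)
  fs <- 500
  x <- rnorm(5000)
  p <- estimate_psd(x, fs)
  integ <- sum(diff(p$freq) * (head(p$power, -1) + tail(p$power, -1)) / 2)
  expect_equal(integ, 1, tolerance = 0.1)
  # sinusoid of amplitude A: integrated power ~ A^2/2, peak at the tone bin
  A <- 3
  xs <- make_sine(10, fs, 4000, amp = A)
  ps <- estimate_psd(xs, fs)
  expect_equal(ps$freq[which.max(ps$power)], 10, tolerance = 0.6)
  integ_s <- sum(diff(ps$freq) * (head(ps$power, -1) + tail(ps$power, -1)) / 2)
  expect_equal(integ_s, A^2 / 2, tolerance = 0.1 * A^2 / 2)
  # zero in, zero out; short input falls back to a single segment
  expect_true(all(estimate_psd(rep(0, 1000), fs)$power == 0))
  expect_s3_class(estimate_psd(rnorm(100), fs), "psd_estimate")
})

test_that("relative band powers: tone containment, flat-noise proportionality, unit sum", {
  fs <- 500
  # pure 10 Hz tone: alpha_low captures ~1 at adequate resolution
  xs <- make_sine(10, fs, 4096)
  ps <- estimate_psd(xs, fs, nperseg = 512)
  expect_equal(relative_band_power(ps, "alpha_low"), 1, tolerance = 0.05)
  others <- setdiff(eeg_bands()$band, "alpha_low")
  for (b in others) expect_lt(relative_band_power(ps, b), 0.05)
  # white (flat) noise: band share proportional to bandwidth
  set.seed(15)
  pw <- estimate_psd(rnorm(60000), fs)
  bands <- eeg_bands()
  for (i in seq_len(nrow(bands))) {
    expect_lt(abs(relative_band_power(pw, bands$band[i]) -
                    (bands$f_hi[i] - bands$f_lo[i]) / 44.5), 0.05)
  }
  # partition identity: the six shares sum to 1 by shared denominator
  s <- sum(vapply(bands$band, function(b) relative_band_power(pw, b),
                  numeric(1)))
  expect_equal(s, 1, tolerance = 1e-6)
  # zero signal: zero share
  expect_equal(relative_band_power(estimate_psd(rep(0, 1000), fs), "beta"), 0)
})

test_that("harmonic parameters are spectral moments of the band", {
  fs <- 500
  xs <- make_sine(10, fs, 4096)
  hp <- harmonic_parameters(estimate_psd(xs, fs, nperseg = 512), "alpha_low")
  expect_equal(hp[["fc"]], 10, tolerance = 0.5)
  expect_lt(hp[["bw"]], 0.7)    # leakage-limited spread
  expect_gt(hp[["sfc"]], 0)
  # flat spectrum over [8,12]: fc = 10, spread = 4/sqrt(12)
  grid <- seq(0, 45, by = 0.05)
  flat <- structure(list(freq = grid,
                         power = as.numeric(grid >= 8 & grid <= 12),
                         fs_hz = fs, n_segments = 1),
                    class = "psd_estimate")
  hpf <- harmonic_parameters(flat, "alpha_low")
  expect_equal(hpf[["fc"]], 10, tolerance = 0.1)
  expect_equal(hpf[["bw"]], 4 / sqrt(12), tolerance = 0.1)
  # two equal tones at 9 and 11 Hz: centroid at 10 by symmetry
  x2 <- make_sine(9, fs, 8192) + make_sine(11, fs, 8192)
  hp2 <- harmonic_parameters(estimate_psd(x2, fs, nperseg = 1024), "alpha_low")
  expect_equal(hp2[["fc"]], 10, tolerance = 0.3)
  # zero in-band power: midpoint convention
  z <- harmonic_parameters(estimate_psd(rep(0, 1000), fs), "beta")
  expect_equal(unname(z), c(24, 0, 0))
})

test_that("bispectrum matches the brute-force triple product and detects QPC", {
  fs <- 250
  set.seed(16)
  x <- rnorm(512)
  b <- estimate_bispectrum(x, fs)
  o <- brute_bispectrum(x, fs)
  rel_err <- abs(b$B - o$B) / (abs(o$B) + 1e-300)
  expect_lt(max(rel_err, na.rm = TRUE), 1e-10)
  expect_equal(b$freq, o$freq)

  # quadratically phase-coupled triple (12, 7, 19 Hz): sharp diagonal peak,
  # biphase ~ 0
  n <- 8192
  tt <- (0:(n - 1)) / fs
  p1 <- 0.7; p2 <- 1.9
  xq <- cos(2 * pi * 12 * tt + p1) + cos(2 * pi * 7 * tt + p2) +
    cos(2 * pi * 19 * tt + p1 + p2) + rnorm(n, 0, 0.1)
  bq <- estimate_bispectrum(xq, fs)
  i1 <- which.min(abs(bq$freq - 12)); i2 <- which.min(abs(bq$freq - 7))
  peak <- Mod(bq$B[i1, i2])
  expect_gt(peak, 10 * median(Mod(bq$B), na.rm = TRUE))
  expect_lt(abs(Arg(bq$B[i1, i2])), 0.2)

  # independent random phases per realization: with segment averaging the
  # (12, 7) product cancels and the peak sinks into the noise floor
  set.seed(17)
  blocks <- lapply(seq_len(64), function(k) {
    tb <- (0:127) / fs
    rowSums(sapply(c(12, 7, 19), function(f)
      cos(2 * pi * f * tb + runif(1, 0, 2 * pi))))
  })
  xr <- unlist(blocks) + rnorm(64 * 128, 0, 10)
  br <- estimate_bispectrum(xr, fs, overlap = 0)
  expect_gte(br$n_segments, 64)
  expect_lt(Mod(br$B[i1, i2]), 3 * median(Mod(br$B), na.rm = TRUE))
  expect_error(estimate_bispectrum(rnorm(150), fs), "too few segments")
})

test_that("bispectral band features summarize the coupled region", {
  fs <- 250
  n <- 16384
  tt <- (0:(n - 1)) / fs
  p1 <- 2.1; p2 <- 0.4
  # coupling between alpha_low (10 Hz) and theta (6 Hz) components
  x <- cos(2 * pi * 10 * tt + p1) + cos(2 * pi * 6 * tt + p2) +
    cos(2 * pi * 16 * tt + p1 + p2) + rnorm(n, 0, 0.1)
  b <- estimate_bispectrum(x, fs)
  coupled <- bispectral_band_features(b, "theta", "alpha_low")
  control <- bispectral_band_features(b, "beta", "beta")
  expect_gt(coupled[["amp"]], 5 * control[["amp"]])
  expect_true(coupled[["phase"]] > -pi && coupled[["phase"]] <= pi)
  # zero signal: amp 0, phase defined as 0
  bz <- estimate_bispectrum(rep(0, 1024), fs)
  fz <- bispectral_band_features(bz, "theta", "alpha_low")
  expect_equal(unname(fz), c(0, 0))
})

test_that("feature vectors have the documented length, order and determinism", {
  set.seed(18)
  x27 <- matrix(rnorm(27 * 500), 27, 500,
                dimnames = list(default_montage(), NULL))
  v <- extract_features(eeg_epoch(x27, 500))
  expect_length(v, 1431)
  x1 <- x27[1, , drop = FALSE]
  v1 <- extract_features(eeg_epoch(x1, 500))
  expect_length(v1, 53)
  # identical epochs give identical vectors
  v2 <- extract_features(eeg_epoch(x27, 500))
  expect_identical(v, v2)
  # first channel block of the full vector equals the single-channel vector
  expect_equal(v[1:53], v1)
  expect_true(all(is.finite(v)))
})

test_that("feature scale behavior: invariants and homogeneity degrees", {
  set.seed(19)
  x <- matrix(rnorm(500) + 2 * make_sine(10, 500, 500), 1, 500,
              dimnames = list("C3", NULL))
  c0 <- 3.7
  v1 <- extract_features(eeg_epoch(x, 500))
  v2 <- extract_features(eeg_epoch(c0 * x, 500))
  bank <- build_feature_bank("C3")
  rel <- bank$family == "rel_power"
  fc <- bank$family == "harm_fc"; bw <- bank$family == "harm_bw"
  sfc <- bank$family == "harm_sfc"
  ba <- bank$family == "bisp_amp"; bp <- bank$family == "bisp_phase"
  ent <- bank$family == "spec_entropy"
  expect_equal(v2[rel], v1[rel], tolerance = 1e-12)
  expect_equal(v2[fc], v1[fc], tolerance = 1e-12)
  expect_equal(v2[bw], v1[bw], tolerance = 1e-12)
  expect_equal(v2[ent], v1[ent], tolerance = 1e-12)
  expect_equal(unname(v2[sfc]), unname(c0^2 * v1[sfc]), tolerance = 1e-10)
  expect_equal(unname(v2[ba]), unname(c0^3 * v1[ba]), tolerance = 1e-10)
  expect_equal(unname(v2[bp]), unname(v1[bp]), tolerance = 1e-10)
})

test_that("feature matrices carry linkage and exclude non-finite epochs", {
  coh <- generate_cohort(tiny_config(seed = 23))
  pp <- preprocess_cohort(coh)
  fm <- extract_feature_matrix(pp$epochs)
  expect_equal(nrow(fm$X), length(pp$epochs))
  expect_equal(ncol(fm$X), 53 * 3)
  expect_equal(length(fm$mv), nrow(fm$X))
  # augmented siblings share a trial id and an MV value
  tab <- table(fm$trial_ids)
  expect_true(all(tab == 2))
  for (id in names(tab)[1:3]) {
    rows <- fm$trial_ids == id
    expect_equal(diff(fm$mv[rows]), 0)
  }
})
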
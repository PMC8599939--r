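# 53-feature-per-channel bank: relative band powers, harmonic parameters,
# bispectral amplitude/phase over band pairs, spectral entropy.

hann_window <- function(m) 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m))

# Segment start indices for length n, segment length m, 50% overlap.
segment_starts <- function(n, m, overlap = 0.5) {
  hop <- max(1L, round(m * (1 - overlap)))
  s <- seq(1L, n - m + 1L, by = hop)
  s[s + m - 1L <= n]
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended segments (default 256 samples, 50 percent
#' overlap, FFT length twice the segment), one-sided density scaled so that
#' the integral of the PSD over frequency equals the time-domain variance
#' (Parseval). Inputs shorter than one segment fall back to a single
#' windowed periodogram.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate, Hz.
#' @param nperseg Segment length in samples.
#' @param nfft FFT length (zero-padded), default `2 * nperseg`.
#' @param overlap Fractional overlap between segments.
#' @return Object of class `psd_estimate`: list with `freq` (Hz), `power`
#'   (density, unit^2/Hz), `fs_hz`, `n_segments`.
#' @export
estimate_psd <- function(x, fs_hz, nperseg = 256, nfft = 2 * nperseg,
                         overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) {
    nperseg <- n
    nfft <- max(nfft, nperseg)
  }
  w <- hann_window(nperseg)
  u <- sum(w^2)
  starts <- segment_starts(n, nperseg, overlap)
  nf <- nfft %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  p <- acc / (length(starts) * fs_hz * u)
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided
  structure(list(freq = (seq_len(nf) - 1L) * fs_hz / nfft, power = p,
                 fs_hz = fs_hz, n_segments = length(starts)),
            class = "psd_estimate")
}

# Cumulative trapezoidal integral of y over x.
cumtrapz1 <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# Integral of the PSD over [lo, hi], linear interpolation at the edges.
psd_band_integral <- function(psd, lo, hi) {
  ci <- cumtrapz1(psd$freq, psd$power)
  at <- function(f) {
    f <- min(max(f, psd$freq[1]), psd$freq[length(psd$freq)])
    stats::approx(psd$freq, ci, xout = f)$y
  }
  at(hi) - at(lo)
}

#' Relative spectral power in a band
#'
#' Trapezoidal integral of the PSD over the band divided by the integral
#' over the full analysis range (0.5--45 Hz). The six standard bands tile
#' the analysis range, so their relative powers sum to one by construction.
#'
#' @param psd A [estimate_psd()] result.
#' @param band Band name (see [eeg_bands()]) or a c(lo, hi) pair in Hz.
#' @param total_range Analysis range, Hz.
#' @return Relative power in \[0, 1\]; 0 if the total power is zero.
#' @export
relative_band_power <- function(psd, band, total_range = c(0.5, 45)) {
  if (is.character(band)) {
    b <- eeg_bands()
    row <- b[b$band == band, ]
    if (nrow(row) == 0) stop("unknown band: ", band)
    band <- c(row$f_lo, row$f_hi)
  }
  tot <- psd_band_integral(psd, total_range[1], total_range[2])
  if (tot <= 0) return(0)
  psd_band_integral(psd, band[1], band[2]) / tot
}

# PSD bins belonging to a band: [lo, hi), upper-inclusive at 45 Hz.
band_bins <- function(freq, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (abs(hi - 45) < 1e-9) sel <- sel | abs(freq - hi) < 1e-9
  sel
}

#' Harmonic parameters of a band
#'
#' The per-band spectral summary triple: centroid frequency
#' `fc = sum(f * S) / sum(S)`, spectral spread
#' `f_sigma = sqrt(sum((f - fc)^2 * S) / sum(S))`, and the power density at
#' the grid frequency nearest the centroid. Bands with zero in-band power
#' return (band midpoint, 0, 0).
#'
#' @param psd A [estimate_psd()] result.
#' @param band Band name or c(lo, hi) in Hz.
#' @return Named numeric vector `c(fc, bw, sfc)`.
#' @export
harmonic_parameters <- function(psd, band) {
  if (is.character(band)) {
    b <- eeg_bands()
    row <- b[b$band == band, ]
    if (nrow(row) == 0) stop("unknown band: ", band)
    band <- c(row$f_lo, row$f_hi)
  }
  sel <- band_bins(psd$freq, band[1], band[2])
  f <- psd$freq[sel]; s <- psd$power[sel]
  if (length(f) == 0 || sum(s) <= 0)
    return(c(fc = mean(band), bw = 0, sfc = 0))
  fc <- sum(f * s) / sum(s)
  bw <- sqrt(sum((f - fc)^2 * s) / sum(s))
  sfc <- s[which.min(abs(f - fc))]
  c(fc = fc, bw = bw, sfc = sfc)
}

#' Spectral entropy of the band-power distribution
#'
#' Shannon entropy of the six relative band powers, normalized by log(6) so
#' a uniform distribution gives 1.
#'
#' @param rel_powers Numeric vector of the six relative band powers.
#' @return Entropy in \[0, 1\].
#' @export
spectral_entropy <- function(rel_powers) {
  p <- rel_powers[rel_powers > 0]
  if (length(p) == 0) return(0)
  p <- p / sum(p)
  -sum(p * log(p)) / log(length(rel_powers))
}

#' Direct bispectrum estimate
#'
#' Segment-averaged direct estimator: Hann-windowed, mean-detrended segments
#' (default 128 samples, 50 percent overlap); per segment
#' `B_k(f1, f2) = X_k(f1) X_k(f2) conj(X_k(f1 + f2))`, averaged over
#' segments, on the principal domain `0 <= f2 <= f1`, `f1 + f2 <= fs/2`.
#' Nonzero bispectral amplitude indicates quadratic phase coupling; the
#' argument is the biphase.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate, Hz.
#' @param nperseg Segment length in samples.
#' @param overlap Fractional overlap.
#' @param min_segments Minimum admissible number of segments.
#' @return Object of class `bispectrum_estimate`: `B` (complex matrix,
#'   `NA` outside the principal domain, indexed `[f1, f2]`), `freq` (Hz),
#'   `n_segments`.
#' @export
estimate_bispectrum <- function(x, fs_hz, nperseg = 128, overlap = 0.5,
                                min_segments = 4) {
  n <- length(x)
  starts <- if (n >= nperseg) segment_starts(n, nperseg, overlap) else integer()
  if (length(starts) < min_segments)
    stop("too few segments for bispectrum estimation: need at least ",
         min_segments, " segments of ", nperseg, " samples (>= ",
         nperseg + (min_segments - 1) * round(nperseg * (1 - overlap)),
         " samples), got ", n)
  w <- hann_window(nperseg)
  nf <- nperseg %/% 2 + 1L
  i1 <- matrix(seq_len(nf), nf, nf)
  i2 <- t(i1)
  i3 <- i1 + i2 - 1L                      # bin of f1 + f2
  valid <- (i2 <= i1) & (i3 <= nf)
  i3[!valid] <- 1L
  acc <- matrix(0 + 0i, nf, nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    X <- stats::fft((seg - mean(seg)) * w)[seq_len(nf)]
    acc <- acc + X[i1] * X[i2] * Conj(X[i3])
  }
  B <- acc / length(starts)
  B[!valid] <- NA
  structure(list(B = B, freq = (seq_len(nf) - 1L) * fs_hz / nperseg,
                 fs_hz = fs_hz, n_segments = length(starts)),
            class = "bispectrum_estimate")
}

#' Bispectral amplitude and phase over a band pair
#'
#' Mean bispectral magnitude over the rectangular bifrequency region
#' (band2 on the f1 axis, band1 on the f2 axis, band1 canonically the lower
#' band) intersected with the principal domain, and the argument of the
#' region-mean complex bispectrum (the mean is taken in the complex plane
#' first, then the argument).
#'
#' @param bisp A [estimate_bispectrum()] result.
#' @param band1,band2 Band names or c(lo, hi) pairs; `band1` is placed on
#'   the f2 axis.
#' @return Named vector `c(amp, phase)`; phase in (-pi, pi\], 0 for a zero
#'   region mean.
#' @export
bispectral_band_features <- function(bisp, band1, band2) {
  to_range <- function(b) {
    if (is.character(b)) {
      tab <- eeg_bands()
      row <- tab[tab$band == b, ]
      if (nrow(row) == 0) stop("unknown band: ", b)
      c(row$f_lo, row$f_hi)
    } else b
  }
  r1 <- to_range(band1); r2 <- to_range(band2)
  s1 <- band_bins(bisp$freq, r2[1], r2[2])   # f1 axis: higher band
  s2 <- band_bins(bisp$freq, r1[1], r1[2])   # f2 axis: lower band
  sub <- bisp$B[s1, s2, drop = FALSE]
  vals <- sub[!is.na(sub)]
  if (length(vals) == 0)
    stop("band pair (", paste(band1, collapse = "-"), ", ",
         paste(band2, collapse = "-"),
         ") does not intersect the bispectrum principal domain")
  m <- mean(vals)
  c(amp = mean(Mod(vals)),
    phase = if (Mod(m) == 0) 0 else Arg(m))
}

#' Extract the 53-feature-per-channel vector from an epoch
#'
#' Computes, per channel: 6 relative band powers, 18 harmonic parameters
#' (fc, spread, power-at-centroid for each band), 14 bispectral amplitudes
#' and 14 bispectral phases over the default band pairs, and 1 spectral
#' entropy -- 53 features per channel, concatenated in montage order.
#'
#' Estimation parameters are defined at the pipeline's 500 Hz augmented
#' rate (256-sample PSD segments, 128-sample bispectrum segments) and are
#' scaled with the sampling rate (to the nearest power of two) so the
#' spectral and bifrequency resolutions — and with them the band regions —
#' stay fixed for epochs at other rates.
#'
#' @param epoch An [eeg_epoch()] or a channels x samples matrix (then
#'   `fs_hz` must be given).
#' @param bank Feature-bank index restricted to the epoch's channels;
#'   default is built from the epoch's channel names.
#' @param fs_hz Sampling rate when `epoch` is a bare matrix.
#' @return Named numeric vector, `length = 53 * n_channels`, names equal to
#'   `bank$name`.
#' @export
extract_features <- function(epoch, bank = NULL, fs_hz = NULL) {
  if (is.matrix(epoch)) {
    stopifnot(!is.null(fs_hz))
    epoch <- eeg_epoch(epoch, fs_hz)
  }
  if (is.null(bank)) bank <- build_feature_bank(epoch$channel_names)
  stopifnot(all(bank$channel %in% epoch$channel_names))
  bands <- eeg_bands()
  pairs <- default_band_pairs()
  ranges <- lapply(seq_len(nrow(bands)),
                   function(i) c(bands$f_lo[i], bands$f_hi[i]))
  names(ranges) <- bands$band
  out <- numeric(nrow(bank))
  names(out) <- bank$name
  nper_psd <- 2^round(log2(epoch$fs_hz / (500 / 256)))
  nper_bisp <- 2^round(log2(epoch$fs_hz / (500 / 128)))
  for (ch in unique(bank$channel)) {
    x <- epoch$data[ch, ]
    psd <- estimate_psd(x, epoch$fs_hz, nperseg = nper_psd)
    bisp <- estimate_bispectrum(x, epoch$fs_hz, nperseg = nper_bisp)
    rel <- vapply(ranges, function(b) relative_band_power(psd, b),
                  numeric(1))
    harm <- lapply(ranges, function(b) harmonic_parameters(psd, b))
    bf <- mapply(function(b1, b2)
                   bispectral_band_features(bisp, ranges[[b1]], ranges[[b2]]),
                 pairs$band1, pairs$band2)
    sel <- bank$channel == ch
    vals <- c(rel,
              unlist(lapply(harm, unname)),
              bf["amp", ], bf["phase", ],
              spectral_entropy(rel))
    out[sel] <- vals
  }
  out
}

#' Feature matrix for a set of epochs
#'
#' Applies [extract_features()] to each epoch; epochs yielding any
#' non-finite feature are excluded and logged. Row order follows the input.
#'
#' @param epochs List of [eeg_epoch()] objects (all sharing a montage).
#' @param bank Feature-bank index (default from the first epoch).
#' @return List: `X` (epochs x features matrix), `mv` (per-row motor vigor
#'   from epoch meta), `trial_ids` (per-row trial identifier, shared by
#'   augmented siblings), `meta` (data frame of per-row linkage fields),
#'   `log` (character vector of exclusions), `bank`.
#' @export
extract_feature_matrix <- function(epochs, bank = NULL) {
  stopifnot(length(epochs) >= 1)
  if (is.null(bank)) bank <- build_feature_bank(epochs[[1]]$channel_names)
  rows <- vector("list", length(epochs))
  keep <- logical(length(epochs))
  log <- character()
  for (i in seq_along(epochs)) {
    v <- extract_features(epochs[[i]], bank)
    if (all(is.finite(v))) {
      rows[[i]] <- v
      keep[i] <- TRUE
    } else {
      log <- c(log, sprintf("epoch %d excluded: non-finite features", i))
    }
  }
  X <- do.call(rbind, rows[keep])
  colnames(X) <- bank$name
  meta_of <- function(e, f, default = NA)
    if (!is.null(e$meta[[f]])) e$meta[[f]] else default
  kept <- epochs[keep]
  meta <- data.frame(
    subject_id = vapply(kept, meta_of, "", f = "subject_id", default = ""),
    group = vapply(kept, meta_of, "", f = "group", default = ""),
    condition = vapply(kept, meta_of, "", f = "condition", default = ""),
    trial_uid = vapply(kept, function(e)
      as.character(meta_of(e, "trial_uid", "")), ""),
    phase = vapply(kept, function(e) e$phase, ""),
    stringsAsFactors = FALSE)
  mv <- vapply(kept, function(e) as.numeric(meta_of(e, "mv", NA_real_)),
               numeric(1))
  tid <- meta$trial_uid
  if (all(tid == "")) tid <- as.character(seq_len(nrow(meta)))
  list(X = X, mv = mv, trial_ids = tid, meta = meta, log = log, bank = bank)
}
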
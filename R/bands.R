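#' Standard EEG frequency bands
#'
#' The six analysis bands partitioning 0.5--45 Hz: delta \[0.5, 4), theta
#' \[4, 8), alpha-low \[8, 12), alpha-high \[12, 16), beta \[16, 32) and
#' gamma \[32, 45\]. The upper edge of gamma is inclusive so the bands
#' exactly tile the analysis range.
#'
#' @return A data frame with columns `band`, `f_lo`, `f_hi`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha_low", "alpha_high", "beta", "gamma"),
    f_lo = c(0.5, 4, 8, 12, 16, 32),
    f_hi = c(4, 8, 12, 16, 32, 45),
    stringsAsFactors = FALSE
  )
}

#' Default 27-channel montage
#'
#' 10-20 system labels. The montage is configurable everywhere it is used;
#' this default covers the frontal, central, temporal, parietal and occipital
#' sites typically reported for motor tasks, completed to 27 with F5, FC4,
#' CP4, P3 and P4.
#'
#' @return Character vector of 27 channel names.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "F5", "F6", "F7", "F8", "Fz",
    "FC4", "FC5", "FC6", "C3", "C4", "CP4", "CP5",
    "T7", "T8", "P3", "P4", "P7", "P8", "PO5", "PO6",
    "O1", "O2", "Oz")
}

#' Default bispectral band pairs
#'
#' The 14 band pairs (i <= j in canonical band order) used for the bispectral
#' amplitude/phase features: the first 14 ordered pairs whose rectangular
#' bifrequency region intersects the bispectrum principal domain.
#'
#' @return Data frame with columns `band1`, `band2` (band1 canonically first).
#' @export
default_band_pairs <- function() {
  b <- eeg_bands()$band
  pairs <- list(
    c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(1, 6),
    c(2, 2), c(2, 3), c(2, 4), c(2, 5), c(2, 6),
    c(3, 3), c(3, 4), c(3, 5)
  )
  data.frame(
    band1 = b[vapply(pairs, `[[`, numeric(1), 1L)],
    band2 = b[vapply(pairs, `[[`, numeric(1), 2L)],
    stringsAsFactors = FALSE
  )
}

#' Build the feature-bank index
#'
#' Constructs the ordered per-channel feature index of the default bank:
#' 6 relative band powers, 18 harmonic parameters (centroid frequency,
#' spectral spread and power-at-centroid for each band), 14 bispectral
#' amplitudes, 14 bispectral phases, and 1 spectral entropy -- 53 features
#' per channel. Channels are concatenated in montage order.
#'
#' @param channels Character vector of channel names.
#' @param bands Band definition data frame, see [eeg_bands()].
#' @param band_pairs Bispectral pair table, see [default_band_pairs()].
#' @return Data frame with one row per feature: `channel`, `family`
#'   (`rel_power`, `harm_fc`, `harm_bw`, `harm_sfc`, `bisp_amp`,
#'   `bisp_phase`, `spec_entropy`), `band` (single band name, `b1:b2` for
#'   pair features, `broadband` for entropy) and `name`
#'   (`<channel>__<family>__<band>`).
#' @export
build_feature_bank <- function(channels = default_montage(),
                               bands = eeg_bands(),
                               band_pairs = default_band_pairs()) {
  stopifnot(length(channels) >= 1, !anyDuplicated(channels))
  per_ch <- function(ch) {
    pair_lab <- paste(band_pairs$band1, band_pairs$band2, sep = ":")
    fam <- c(
      rep("rel_power", nrow(bands)),
      rep(c("harm_fc", "harm_bw", "harm_sfc"), nrow(bands)),
      rep("bisp_amp", nrow(band_pairs)),
      rep("bisp_phase", nrow(band_pairs)),
      "spec_entropy"
    )
    bnd <- c(
      bands$band,
      rep(bands$band, each = 3L),
      pair_lab, pair_lab,
      "broadband"
    )
    data.frame(channel = ch, family = fam, band = bnd,
               stringsAsFactors = FALSE)
  }
  idx <- do.call(rbind, lapply(channels, per_ch))
  idx$name <- paste(idx$channel, idx$family, idx$band, sep = "__")
  rownames(idx) <- NULL
  n_per <- nrow(idx) / length(channels)
  if (n_per != 53)
    stop("feature bank must contain 53 features per channel, got ", n_per)
  idx
}

#' Which bank features belong to a band-restricted model
#'
#' A single-band feature belongs to its band; a bispectral pair feature
#' belongs to both member bands; spectral entropy belongs only to the
#' broadband model. `"broadband"` selects every feature.
#'
#' @param bank Feature-bank index from [build_feature_bank()].
#' @param band Band name or `"broadband"`.
#' @return Logical vector over the bank rows.
#' @export
band_membership <- function(bank, band) {
  if (band == "broadband") return(rep(TRUE, nrow(bank)))
  if (!band %in% eeg_bands()$band)
    stop("unknown band: ", band)
  vapply(strsplit(bank$band, ":", fixed = TRUE),
         function(b) band %in% b, logical(1))
}
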
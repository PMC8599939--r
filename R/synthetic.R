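# Synthetic cohort generator: squeeze-bulb behavior + multichannel EEG with
# planted, recoverable feature-vigor coupling.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Cohort configuration
#'
#' Study-design parameters for the synthetic cohort: 20 healthy controls and
#' 18 PD participants, 10 trials per condition block, three stimulation
#' conditions (sham, GVS1, GVS2), 27 EEG channels sampled at 1 kHz. Each
#' trial starts with a 1500 ms fixation screen jittered by +/-500 ms,
#' followed by a 500 ms Go screen and a 1000 ms blank, so the Go cue falls
#' in \[1000, 2000\] ms from trial start.
#'
#' @param n_hc,n_pd Number of healthy-control / PD subjects.
#' @param trials_per_block Trials per condition block.
#' @param conditions Condition labels (first is the reference condition).
#' @param fs_hz EEG/pressure sampling rate, Hz.
#' @param channel_names EEG montage (10-20 labels).
#' @param seed Integer master seed; the full cohort is a pure function of
#'   (config, coupling, seed).
#' @param mv_mean_ms,mv_sd_ms Mean/SD (ms) of the lognormal time-to-peak
#'   distribution, truncated to `mv_range_ms`. Defaults give a mean motor
#'   vigor near 14e-4 1/ms in the reference condition.
#' @param mv_range_ms Truncation range for time-to-peak, ms.
#' @param condition_mv_mult Named multipliers applied to motor vigor per
#'   condition (time-to-peak is divided by these). Defaults reproduce the
#'   observed sham/GVS1/GVS2 mean MV ratios (1, 15.5/14, 15.4/14).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 20, n_pd = 18, trials_per_block = 10,
                          conditions = c("sham", "gvs1", "gvs2"),
                          fs_hz = 1000, channel_names = default_montage(),
                          seed = 1L,
                          mv_mean_ms = 700, mv_sd_ms = 120,
                          mv_range_ms = c(300, 1200),
                          condition_mv_mult = NULL) {
  if (is.null(condition_mv_mult)) {
    condition_mv_mult <- stats::setNames(rep(1, length(conditions)), conditions)
    if ("gvs1" %in% conditions) condition_mv_mult["gvs1"] <- 15.5 / 14
    if ("gvs2" %in% conditions) condition_mv_mult["gvs2"] <- 15.4 / 14
  }
  cfg <- list(n_hc = n_hc, n_pd = n_pd, trials_per_block = trials_per_block,
              conditions = conditions, fs_hz = fs_hz,
              n_channels = length(channel_names),
              channel_names = channel_names, seed = as.integer(seed),
              mv_mean_ms = mv_mean_ms, mv_sd_ms = mv_sd_ms,
              mv_range_ms = mv_range_ms,
              condition_mv_mult = condition_mv_mult)
  stopifnot(cfg$n_hc >= 1, cfg$n_pd >= 0, cfg$fs_hz > 90,
            cfg$trials_per_block >= 1,
            length(cfg$channel_names) == cfg$n_channels,
            all(conditions %in% names(condition_mv_mult)))
  class(cfg) <- "cohort_config"
  cfg
}

#' Feature--vigor coupling specification
#'
#' Declares which (channel, band, family) targets of the feature bank carry
#' a linear relation to motor vigor in the generated EEG, with what weight,
#' and how much independent noise dilutes the relation. For single-band
#' families (`rel_power`, `harm_*`) the band oscillation power varies
#' linearly with standardized MV; for bispectral families (`bisp_amp`,
#' `bisp_phase`) the `band` entry is a pair `"b1:b2"` and the strength of
#' quadratic phase coupling between the two band-centered components tracks
#' MV.
#'
#' With `weight = sqrt(r2)` and `noise_sd = sqrt(1 - r2)` the planted
#' feature--MV coupling has population R^2 approximately `r2`; the helper
#' [coupling_for_r2()] builds such a spec directly.
#'
#' @param targets Data frame with columns `channel`, `band`, `family`,
#'   `weight`.
#' @param noise_sd Standard deviation of the coupling noise (>= 0), on the
#'   same scale as `weight` (standardized MV has unit variance).
#' @param condition_modifiers Optional named list: condition -> scalar (or
#'   per-band named vector) multiplier applied to target weights in that
#'   condition.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(targets = NULL, noise_sd = 0,
                          condition_modifiers = NULL) {
  if (is.null(targets))
    targets <- data.frame(channel = character(), band = character(),
                          family = character(), weight = numeric(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("channel", "band", "family", "weight") %in% names(targets)),
            noise_sd >= 0)
  out <- list(targets = targets, noise_sd = noise_sd,
              condition_modifiers = condition_modifiers)
  class(out) <- "coupling_spec"
  out
}

#' Coupling spec with a requested planted R-squared
#'
#' The coupled oscillation's power is linear in the planted multiplier, so
#' power-type features (the default target, `harm_sfc` = power at the band
#' centroid) recover the requested R^2. Relative-power targets are diluted
#' by the epoch-to-epoch compositional variance of the background spectrum
#' in the normalizing denominator and recover a lower R^2.
#'
#' @param r2 Requested planted R^2 in \[0, 1).
#' @param channel,band,family Target feature (defaults: C3 beta power at
#'   centroid).
#' @return A `coupling_spec` with `weight = sqrt(r2)`,
#'   `noise_sd = sqrt(1 - r2)` and the requested R^2 recorded in
#'   `planted_r2`.
#' @export
coupling_for_r2 <- function(r2, channel = "C3", band = "beta",
                            family = "harm_sfc") {
  stopifnot(r2 >= 0, r2 < 1)
  cs <- coupling_spec(
    targets = data.frame(channel = channel, band = band, family = family,
                         weight = sqrt(r2), stringsAsFactors = FALSE),
    noise_sd = sqrt(1 - r2))
  cs$planted_r2 <- r2
  cs
}

validate_coupling <- function(coupling, config) {
  if (nrow(coupling$targets) == 0) return(invisible(TRUE))
  bands <- eeg_bands()$band
  for (i in seq_len(nrow(coupling$targets))) {
    tg <- coupling$targets[i, ]
    if (!tg$channel %in% config$channel_names)
      stop("coupling target references unknown channel: ", tg$channel)
    parts <- strsplit(tg$band, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% bands))
      stop("coupling target references unknown band: ", tg$band)
    if (!tg$family %in% c("rel_power", "harm_fc", "harm_bw", "harm_sfc",
                          "bisp_amp", "bisp_phase"))
      stop("coupling target references unknown feature family: ", tg$family)
    if (tg$family %in% c("bisp_amp", "bisp_phase") && length(parts) != 2)
      stop("bispectral coupling target needs a band pair 'b1:b2', got: ",
           tg$band)
  }
  invisible(TRUE)
}

#' Simulate a squeeze-bulb pressure trace
#'
#' The trace is flat at baseline until a reaction delay after the Go cue,
#' rises to a unique global maximum exactly `peak_latency_ms` after the cue,
#' then decays. The peak is locally pointed (two-sided exponential around the
#' designed sample) so that small additive noise does not displace the
#' argmax.
#'
#' @param peak_latency_ms Designed time from Go cue to peak, ms.
#' @param fs_hz Sampling rate, Hz.
#' @param go_onset_ms Go-cue time from trace start, ms.
#' @param duration_ms Total trace duration, ms (default `go_onset_ms + 1500`).
#' @param reaction_ms Squeeze-start delay t2 - t1, ms.
#' @param amplitude Peak pressure (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD, same units.
#' @param seed Integer seed.
#' @return Numeric pressure series of length `duration_ms * fs_hz / 1000`.
#' @export
simulate_pressure_trace <- function(peak_latency_ms, fs_hz = 1000,
                                    go_onset_ms = 1500, duration_ms = NULL,
                                    reaction_ms = 200, amplitude = 1,
                                    noise_sd = 0.002, seed = 1L) {
  if (is.null(duration_ms)) duration_ms <- go_onset_ms + 1500
  if (peak_latency_ms <= 0 || go_onset_ms + peak_latency_ms >= duration_ms)
    stop("peak_latency_ms outside the trial window")
  if (reaction_ms >= peak_latency_ms) reaction_ms <- peak_latency_ms / 2
  n <- round(duration_ms * fs_hz / 1000)
  t_ms <- (seq_len(n) - 1L) * 1000 / fs_hz
  tp <- go_onset_ms + peak_latency_ms
  t2 <- go_onset_ms + reaction_ms
  tau_r <- (tp - t2) / 5
  tau_d <- 300
  p <- numeric(n)
  rise <- t_ms >= t2 & t_ms <= tp
  p[rise] <- amplitude * exp(-(tp - t_ms[rise]) / tau_r)
  fall <- t_ms > tp
  p[fall] <- amplitude * exp(-(t_ms[fall] - tp) / tau_d)
  # snap the designed peak onto the sampling grid
  pk_idx <- which.min(abs(t_ms - tp))
  p[pk_idx] <- amplitude
  if (noise_sd > 0)
    p <- p + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  p
}

# Gaussian 1/f^alpha noise via spectral shaping, unit variance.
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  f <- seq(0, 1, length.out = n %/% 2 + 1)
  shape <- c(0, 1 / f[-1]^(alpha / 2))
  wf <- stats::fft(w)
  full <- c(shape, rev(shape[2:(n - length(shape) + 1)]))
  x <- Re(stats::fft(wf * full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Per-band baseline oscillation amplitudes (uV), chosen once; see vignette.
band_base_amp <- function() {
  c(delta = 4, theta = 3, alpha_low = 5, alpha_high = 3, beta = 2.5,
    gamma = 1.5)
}

#' Simulate one multichannel EEG segment
#'
#' Each channel is 1/f background noise plus one band-centered sinusoid per
#' EEG band. For each coupling target on the channel, the oscillation power
#' (or, for bispectral targets, the fraction of quadratic phase coupling in
#' a three-cosine triple at the band-pair centers) varies linearly with
#' standardized motor vigor, diluted by the coupling noise.
#'
#' @param mv Motor vigor of the trial (1/ms), > 0.
#' @param coupling A [coupling_spec()].
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param duration_ms Segment length, ms (>= 1500).
#' @param mv_ref Reference c(mean, sd) used to standardize `mv`; defaults to
#'   the sham-condition population values (14e-4, 2e-4 1/ms).
#' @param condition Condition label used to look up weight modifiers.
#' @param noise_uv SD of the 1/f background per channel (uV).
#' @param alpha 1/f spectral exponent.
#' @param coupled_amp_uv Baseline amplitude (uV) of oscillations carrying a
#'   coupling target; large enough that the planted linear relation
#'   dominates the in-band background, so the requested planted R^2 is
#'   recovered in the extracted feature.
#' @return A matrix (channels x samples) with `dimnames` set to channel
#'   names, attribute `fs_hz`.
#' @export
simulate_eeg_epoch <- function(mv, coupling, config, seed = 1L,
                               duration_ms = 1500,
                               mv_ref = c(mean = 14e-4, sd = 2e-4),
                               condition = NULL, noise_uv = 5, alpha = 1,
                               coupled_amp_uv = 12) {
  stopifnot(mv > 0, duration_ms >= 1500)
  validate_coupling(coupling, config)
  z <- (mv - mv_ref[["mean"]]) / mv_ref[["sd"]]
  fs <- config$fs_hz
  n <- round(duration_ms * fs / 1000)
  t <- (seq_len(n) - 1L) / fs
  bands <- eeg_bands()
  centers <- (bands$f_lo + bands$f_hi) / 2
  names(centers) <- bands$band
  amps <- band_base_amp()
  tg <- coupling$targets
  if (!is.null(condition) && !is.null(coupling$condition_modifiers) &&
      condition %in% names(coupling$condition_modifiers)) {
    mod <- coupling$condition_modifiers[[condition]]
    if (nrow(tg) > 0) {
      m <- if (length(mod) == 1 && is.null(names(mod)))
        rep(as.numeric(mod), nrow(tg))
      else {
        mm <- rep(1, nrow(tg))
        hit <- tg$band %in% names(mod)
        mm[hit] <- as.numeric(mod[tg$band[hit]])
        mm
      }
      tg$weight <- tg$weight * m
    }
  }
  with_seed(seed, {
    out <- matrix(0, config$n_channels, n,
                  dimnames = list(config$channel_names, NULL))
    for (ci in seq_len(config$n_channels)) {
      ch <- config$channel_names[ci]
      x <- noise_uv * pink_noise(n, alpha)
      for (bi in seq_len(nrow(bands))) {
        bname <- bands$band[bi]
        a <- amps[[bname]]
        hit <- which(tg$channel == ch & tg$band == bname &
                     tg$family %in% c("rel_power", "harm_fc", "harm_bw",
                                      "harm_sfc"))
        mult <- 1
        if (length(hit)) {
          a <- coupled_amp_uv
          w <- sum(tg$weight[hit])
          eps <- stats::rnorm(1)
          mult <- max(0.05, 1 + 0.35 * (w * z + coupling$noise_sd * eps))
        }
        phi <- stats::runif(1, 0, 2 * pi)
        x <- x + a * sqrt(mult) * sin(2 * pi * centers[[bname]] * t + phi)
      }
      # bispectral targets: three-cosine quadratic phase coupling
      hitb <- which(tg$channel == ch &
                    tg$family %in% c("bisp_amp", "bisp_phase"))
      for (k in hitb) {
        pr <- strsplit(tg$band[k], ":", fixed = TRUE)[[1]]
        f1 <- centers[[pr[2]]]; f2 <- centers[[pr[1]]]  # f1 >= f2
        w <- tg$weight[k]
        eps <- stats::rnorm(1)
        cf <- min(1, max(0, 0.5 + 0.25 * (w * z + coupling$noise_sd * eps)))
        p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
        pr_ <- stats::runif(1, 0, 2 * pi)
        aq <- 3
        x <- x + aq * (cos(2 * pi * f1 * t + p1) + cos(2 * pi * f2 * t + p2) +
               cf * cos(2 * pi * (f1 + f2) * t + p1 + p2) +
               (1 - cf) * cos(2 * pi * (f1 + f2) * t + pr_))
      }
      out[ci, ] <- x
    }
    attr(out, "fs_hz") <- fs
    out
  })
}

#' Trial schedule for a cohort configuration
#'
#' Lays out subjects, groups, condition blocks and per-trial timing (jittered
#' fixation, Go onset, designed time-to-peak drawn from the truncated
#' lognormal MV model) without generating any signals.
#'
#' @param config A [cohort_config()].
#' @return Data frame: `subject_id`, `group`, `condition`, `trial_idx`,
#'   `fs_hz`, `go_onset_ms`, `peak_time_true_ms`, `mv_true`,
#'   `duration_ms`.
#' @export
generate_trial_schedule <- function(config) {
  subj <- c(sprintf("hc%02d", seq_len(config$n_hc)),
            if (config$n_pd > 0) sprintf("pd%02d", seq_len(config$n_pd)))
  grp <- c(rep("HC", config$n_hc), rep("PD", config$n_pd))
  sdl <- sqrt(log(1 + (config$mv_sd_ms / config$mv_mean_ms)^2))
  mnl <- log(config$mv_mean_ms) - sdl^2 / 2
  with_seed(config$seed, {
    rows <- list()
    for (si in seq_along(subj)) {
      for (cond in config$conditions) {
        for (ti in seq_len(config$trials_per_block)) {
          go <- stats::runif(1, 1000, 2000)       # 1500 +/- 500 ms fixation
          repeat {
            tt <- stats::rlnorm(1, mnl, sdl)
            if (tt >= config$mv_range_ms[1] && tt <= config$mv_range_ms[2])
              break
          }
          tt <- tt / config$condition_mv_mult[[cond]]
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subj[si], group = grp[si], condition = cond,
            trial_idx = ti, fs_hz = config$fs_hz,
            go_onset_ms = round(go), peak_time_true_ms = round(tt),
            mv_true = 1 / round(tt),
            duration_ms = round(go) + 1500,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic cohort
#'
#' Produces, for every subject x condition x trial, a pressure trace with a
#' designed force peak and a continuous EEG segment covering the whole trial
#' (at least \[Go - 500 ms, Go + 1500 ms\]), with EEG feature--MV coupling
#' planted per `coupling`. The result is a pure function of
#' `(config, coupling, config$seed)`.
#'
#' @param config A [cohort_config()].
#' @param coupling A [coupling_spec()] (default: no coupling).
#' @return Object of class `synthetic_cohort`: list with `trials` (schedule
#'   data frame), `pressure` (list of numeric traces), `eeg` (list of
#'   channels x samples matrices), `config`, `coupling` and `truth`
#'   (coupling spec, per-trial true MV, planted R^2 if requested).
#' @export
generate_cohort <- function(config = cohort_config(),
                            coupling = coupling_spec()) {
  validate_coupling(coupling, config)
  trials <- generate_trial_schedule(config)
  n_tr <- nrow(trials)
  seeds <- with_seed(config$seed + 1L,
                     sample.int(.Machine$integer.max - 1L, 2L * n_tr))
  mv_ref <- c(mean = mean(trials$mv_true), sd = stats::sd(trials$mv_true))
  pressure <- vector("list", n_tr)
  eeg <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    pressure[[i]] <- simulate_pressure_trace(
      trials$peak_time_true_ms[i], fs_hz = config$fs_hz,
      go_onset_ms = trials$go_onset_ms[i],
      duration_ms = trials$duration_ms[i], seed = seeds[2 * i - 1L])
    eeg[[i]] <- simulate_eeg_epoch(
      trials$mv_true[i], coupling, config, seed = seeds[2 * i],
      duration_ms = trials$duration_ms[i], mv_ref = mv_ref,
      condition = trials$condition[i])
  }
  out <- list(trials = trials, pressure = pressure, eeg = eeg,
              config = config, coupling = coupling,
              truth = list(coupling = coupling, mv_true = trials$mv_true,
                           planted_r2 = coupling$planted_r2))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$trials), "trials;",
      length(unique(x$trials$subject_id)), "subjects;",
      x$config$n_channels, "channels @", x$config$fs_hz, "Hz\n")
  invisible(x)
}

#' Planted sparse design in feature space
#'
#' Generates a standardized feature matrix with column names taken from the
#' feature bank and a response carrying a sparse linear signal at a requested
#' population R^2 -- the calibration harness for the bootstrapped LASSO
#' (planted-signal recovery, selection fidelity, null calibration).
#'
#' @param n Number of rows (epochs).
#' @param bank Feature-bank index ([build_feature_bank()]); its rows define
#'   the columns.
#' @param planted Indices (or names) of planted columns.
#' @param betas Coefficients for the planted columns (recycled).
#' @param r2 Population R^2 of the signal (0 gives pure noise).
#' @param seed Integer seed.
#' @return List: `X` (n x p matrix, named columns), `y`, `beta_true` (length
#'   p), `trial_ids` (here one per row).
#' @export
make_planted_design <- function(n, bank = build_feature_bank(),
                                planted = integer(), betas = 1, r2 = 0.5,
                                seed = 1L) {
  p <- nrow(bank)
  if (is.character(planted)) planted <- match(planted, bank$name)
  stopifnot(!anyNA(planted), all(planted >= 1 & planted <= p))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, bank$name))
    beta_true <- numeric(p)
    if (length(planted)) beta_true[planted] <- rep_len(betas, length(planted))
    sig <- drop(X %*% beta_true)
    if (r2 > 0 && length(planted)) {
      noise_sd <- sqrt(stats::var(sig) * (1 - r2) / r2)
      y <- sig + stats::rnorm(n, 0, noise_sd)
    } else {
      y <- stats::rnorm(n)
    }
    list(X = X, y = y, beta_true = beta_true, trial_ids = seq_len(n))
  })
}
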
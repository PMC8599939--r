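# Shared fixtures and independent oracles used across the suite.

# A small montage/config for fast cohort-level tests.
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_hc = 2, n_pd = 2, trials_per_block = 3,
                channel_names = c("C3", "C4", "Fz"), seed = seed, ...)
}

make_sine <- function(f, fs, n, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# Brute-force direct bispectrum: explicit loops over segments and the
# (f1, f2) grid, mirroring the estimator's definition, independent of the
# vectorized implementation.
brute_bispectrum <- function(x, fs, nperseg = 128, overlap = 0.5) {
  hop <- round(nperseg * (1 - overlap))
  starts <- seq(1, length(x) - nperseg + 1, by = hop)
  starts <- starts[starts + nperseg - 1 <= length(x)]
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / nperseg))
  nf <- nperseg %/% 2 + 1
  B <- matrix(NA_complex_, nf, nf)
  Xs <- lapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1)]
    stats::fft((seg - mean(seg)) * w)
  })
  for (i1 in seq_len(nf)) {
    for (i2 in seq_len(i1)) {
      i3 <- i1 + i2 - 1
      if (i3 > nf) next
      acc <- 0 + 0i
      for (X in Xs) acc <- acc + X[i1] * X[i2] * Conj(X[i3])
      B[i1, i2] <- acc / length(Xs)
    }
  }
  list(B = B, freq = (seq_len(nf) - 1) * fs / nperseg)
}

# Brute-force sums-of-squares mixed ANOVA for a balanced design with one
# between factor and one within factor, computed from cell/marginal means
# with explicit sums (textbook decomposition).
brute_mixed_anova_2xw <- function(df, dv, between, within, unit) {
  y <- df[[dv]]
  b <- factor(df[[between]]); w <- factor(df[[within]]); u <- factor(df[[unit]])
  gm <- mean(y)
  n_u <- nlevels(u); n_w <- nlevels(w)
  # subject means
  mu_u <- tapply(y, u, mean)
  mu_b <- tapply(y, b, mean)
  mu_w <- tapply(y, w, mean)
  mu_bw <- tapply(y, list(b, w), mean)
  grp_of_u <- b[match(levels(u), u)]
  # SS between = n_w * sum over units of (group mean - grand mean)^2
  ss_b <- n_w * sum((mu_b[grp_of_u] - gm)^2)
  ss_subj <- n_w * sum((mu_u - gm)^2)
  ss_subj_within <- ss_subj - ss_b            # error for between effect
  ss_w <- n_u * sum((mu_w - gm)^2)
  ss_cells <- 0
  for (bi in levels(b)) for (wi in levels(w)) {
    nbw <- sum(b == bi & w == wi)
    ss_cells <- ss_cells + nbw * (mu_bw[bi, wi] - gm)^2
  }
  ss_bw <- ss_cells - ss_b - ss_w
  ss_tot <- sum((y - gm)^2)
  ss_err_w <- ss_tot - ss_subj - ss_w - ss_bw  # within error
  g <- nlevels(b)
  list(
    between = list(ss = ss_b, df1 = g - 1, ss_err = ss_subj_within,
                   df2 = n_u - g),
    within = list(ss = ss_w, df1 = n_w - 1, ss_err = ss_err_w,
                  df2 = (n_u - g) * (n_w - 1)),
    interaction = list(ss = ss_bw, df1 = (g - 1) * (n_w - 1),
                       ss_err = ss_err_w, df2 = (n_u - g) * (n_w - 1)),
    ss_total = ss_tot,
    ss_parts = c(ss_b, ss_subj_within, ss_w, ss_bw, ss_err_w))
}
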
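# Inferential layer: Fisher z, mixed ANOVA with Greenhouse-Geisser
# correction, paired and one-sample t-tests, Bonferroni correction,
# behavioral summary tables.

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, variance-stabilizing for averaging correlations;
#' averaging is performed in z-space and back-transformed with `tanh` for
#' display. Values with `|r| >= 1` are clamped to `+/-(1 - 1e-12)` with a
#' warning.
#'
#' @param r Correlation(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  bad <- abs(r) >= 1
  if (any(bad)) {
    warning("clamping ", sum(bad), " correlation(s) with |r| >= 1")
    r[bad] <- sign(r[bad]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Average correlations on the Fisher-z scale
#'
#' @param r Vector of correlations.
#' @return List: `mean_z`, `sd_z`, `mean_r` (tanh of `mean_z`).
#' @export
mean_fisher_z <- function(r) {
  z <- fisher_z(r)
  list(mean_z = mean(z), sd_z = stats::sd(z), mean_r = tanh(mean(z)))
}

#' Paired t-test
#'
#' Two-sided paired t-test with `df = n - 1`. Identical vectors give
#' `t = 0, p = 1`; a nonzero mean difference with zero variance is an
#' error.
#'
#' @param a,b Paired numeric vectors of equal length (n >= 2).
#' @return Named vector `c(t, df, p)`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(c(t = 0, df = n - 1, p = 1))
    stop("zero-variance differences with nonzero mean: t undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  c(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' One-sample t-test
#'
#' Two-sided test of the mean against `mu` (used for testing whether
#' aggregated LASSO coefficients differ from zero).
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param mu Null mean (default 0).
#' @return Named vector `c(t, df, p)`.
#' @export
one_sample_t <- function(values, mu = 0) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) stop("zero-variance sample: t undefined")
  n <- length(values)
  t <- (mean(values) - mu) / (s / sqrt(n))
  c(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Bonferroni correction
#'
#' @param p P-values in \[0, 1\].
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "bonferroni", n = m)
}

# Orthonormal contrast matrix (k x (k-1)) orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon and Mauchly test for one within effect.
# Y: units x cells matrix; M: cells x d orthonormal effect contrasts;
# grp: between-group factor over units.
sphericity_stats <- function(Y, M, grp) {
  S <- Y %*% M
  d <- ncol(M)
  if (d < 2)
    return(list(eps = 1, mauchly_w = NA_real_, mauchly_p = NA_real_))
  for (g in unique(grp)) {
    rows <- grp == g
    S[rows, ] <- sweep(S[rows, , drop = FALSE], 2,
                       colMeans(S[rows, , drop = FALSE]))
  }
  df <- nrow(Y) - length(unique(grp))
  E <- crossprod(S) / df
  tr <- sum(diag(E))
  eps <- tr^2 / (d * sum(E * E))
  W <- det(E) / (tr / d)^d
  if (!is.finite(W) || W <= 0) {
    mp <- NA_real_
  } else {
    f <- df - (2 * d^2 + d + 2) / (6 * d)
    chi2 <- -f * log(W)
    mp <- stats::pchisq(chi2, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  }
  list(eps = eps, mauchly_w = W, mauchly_p = mp)
}

#' Mixed-design ANOVA
#'
#' Classical univariate mixed ANOVA with one between-unit factor and one or
#' two within-unit factors, for balanced designs: sums of squares from the
#' standard error strata (`aov` with `Error(unit/(w1*w2))`), partial eta
#' squared `SS_effect / (SS_effect + SS_error)` per stratum, and, for
#' within effects with three or more levels, the Greenhouse-Geisser epsilon
#' and Mauchly's sphericity test computed from the pooled within-group
#' covariance of the effect contrasts. The GG-corrected p-value is reported
#' alongside the uncorrected one; the correction is recommended when
#' Mauchly's p < 0.05.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-unit factor column.
#' @param within Names of the within-unit factor columns (1 or 2).
#' @param unit Name of the unit (subject / bootstrap-run) column.
#' @return Object of class `anova_table`: data frame with `effect`, `df1`,
#'   `df2`, `ss`, `ss_error`, `F`, `p`, `pes`, `gg_eps`, `p_gg`,
#'   `mauchly_p`.
#' @export
mixed_anova <- function(data, dv, between, within, unit) {
  stopifnot(all(c(dv, between, within, unit) %in% names(data)),
            length(within) %in% 1:2)
  df <- data.frame(
    .y = as.numeric(data[[dv]]),
    .b = factor(data[[between]]),
    .u = factor(data[[unit]]),
    stringsAsFactors = FALSE)
  for (i in seq_along(within)) df[[paste0(".w", i)]] <- factor(data[[within[i]]])
  wnames <- paste0(".w", seq_along(within))

  # balance checks
  cell <- interaction(df[wnames], drop = FALSE)
  tab <- table(df$.u, cell)
  if (any(tab != 1)) {
    miss <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced design; offending (unit, cell) pairs: ",
         paste(sprintf("(%s, %s)", rownames(tab)[miss[, 1]],
                       colnames(tab)[miss[, 2]]), collapse = ", "))
  }
  ub <- unique(df[, c(".u", ".b")])
  if (any(table(ub$.u) > 1)) stop("a unit appears in more than one between level")
  if (any(table(ub$.b) < 2)) stop("need at least 2 units per between level")

  wprod <- paste(wnames, collapse = " * ")
  form <- stats::as.formula(sprintf(
    ".y ~ .b * %s + Error(.u / (%s))", wprod, wprod))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  rename_effect <- function(e) {
    e <- gsub("\\.b", between, e)
    for (i in seq_along(within)) e <- gsub(paste0("\\.w", i), within[i], e)
    gsub(" ", "", e)
  }

  rows <- list()
  for (stratum in sm) {
    tt <- as.data.frame(stratum[[1]])
    labs <- trimws(rownames(tt))
    resid <- labs == "Residuals"
    if (!any(resid)) next
    ss_err <- tt$`Sum Sq`[resid]
    df_err <- tt$Df[resid]
    for (j in which(!resid)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = rename_effect(labs[j]),
        df1 = tt$Df[j], df2 = df_err,
        ss = tt$`Sum Sq`[j], ss_error = ss_err,
        F = tt$`F value`[j], p = tt$`Pr(>F)`[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  # sphericity columns
  lev <- lapply(wnames, function(w) levels(df[[w]]))
  grid <- expand.grid(lev, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- wnames
  key_data <- interaction(df[wnames], drop = FALSE)
  key_grid <- interaction(grid, drop = FALSE)
  units <- levels(df$.u)
  Y <- matrix(NA_real_, length(units), nrow(grid),
              dimnames = list(units, as.character(key_grid)))
  for (i in seq_len(nrow(df)))
    Y[as.character(df$.u[i]), as.character(key_data[i])] <- df$.y[i]
  grp <- df$.b[match(units, df$.u)]

  contrast_for <- function(effect_within) {
    parts <- lapply(seq_along(wnames), function(i) {
      k <- length(lev[[i]])
      if (wnames[i] %in% effect_within) orthonormal_contrasts(k)
      else matrix(1 / sqrt(k), k, 1)
    })
    # expand.grid varies the first factor fastest -> kron in reverse order
    M <- parts[[length(parts)]]
    if (length(parts) > 1)
      for (i in rev(seq_len(length(parts) - 1))) M <- M %x% parts[[i]]
    M
  }

  out$gg_eps <- NA_real_; out$p_gg <- NA_real_; out$mauchly_p <- NA_real_
  within_named <- stats::setNames(wnames, vapply(wnames, rename_effect, ""))
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$effect[i], ":", fixed = TRUE)[[1]]
    wparts <- within_named[parts[parts %in% names(within_named)]]
    if (length(wparts) == 0) next
    sp <- sphericity_stats(Y, contrast_for(wparts), grp)
    out$gg_eps[i] <- sp$eps
    out$mauchly_p[i] <- sp$mauchly_p
    out$p_gg[i] <- stats::pf(out$F[i], out$df1[i] * sp$eps,
                             out$df2[i] * sp$eps, lower.tail = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 5); y$ss_error <- signif(y$ss_error, 5)
  y$F <- round(y$F, 3); y$p <- signif(y$p, 4)
  y$pes <- round(y$ss / (y$ss + y$ss_error), 3)
  print(y[, c("effect", "df1", "df2", "F", "p", "pes")], ...)
  invisible(x)
}

#' Partial eta squared from an ANOVA table
#'
#' @param tab An [mixed_anova()] result.
#' @return Named vector of `SS_effect / (SS_effect + SS_error)` per effect.
#' @export
partial_eta_squared <- function(tab) {
  stats::setNames(tab$ss / (tab$ss + tab$ss_error), tab$effect)
}

#' Behavioral summary: motor vigor by group and stimulus
#'
#' Aggregates motor vigor to subject-level means per condition, tabulates
#' cell means and SDs across subjects per (group, stimulus), and runs the
#' 2 x 3 mixed ANOVA (between: disease status, within: stimulus) on the
#' subject-level values.
#'
#' @param mv_records Data frame with columns `subject_id`, `group`,
#'   `condition`, `mv`.
#' @return List: `table` (group x condition mean/SD data frame), `anova`
#'   ([mixed_anova()] result), `subject_means`.
#' @export
behavior_summary <- function(mv_records) {
  stopifnot(all(c("subject_id", "group", "condition", "mv") %in%
                names(mv_records)))
  sm <- stats::aggregate(mv ~ subject_id + group + condition,
                         data = mv_records, FUN = mean)
  if (any(table(unique(sm[, c("subject_id", "group")])$group) < 2))
    stop("need at least 2 subjects per group")
  tab <- do.call(rbind, lapply(split(sm, sm[, c("group", "condition")]),
    function(d) data.frame(group = d$group[1], condition = d$condition[1],
                           mean_mv = mean(d$mv), sd_mv = stats::sd(d$mv),
                           n_subjects = nrow(d),
                           stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  an <- mixed_anova(sm, dv = "mv", between = "group", within = "condition",
                    unit = "subject_id")
  list(table = tab, anova = an, subject_means = sm)
}
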
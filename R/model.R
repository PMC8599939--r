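# Bootstrapped L1-penalized prediction of motor vigor from EEG features,
# band-restricted variants, and coefficient aggregation.

#' Pearson correlation between predicted and observed motor vigor
#'
#' @param pred,obs Equal-length numeric vectors (n >= 3) with nonzero
#'   variance.
#' @return Pearson product-moment correlation.
#' @export
performance <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("performance undefined: zero variance in predictions or observations")
  stats::cor(pred, obs)
}

#' LASSO coefficients at a fixed penalty
#'
#' L1-penalized least squares on the full data at a given `lambda` (glmnet
#' objective `(1/2n) RSS + lambda * ||beta||_1`). On a design with
#' `crossprod(X)/n` equal to the identity, each coefficient equals the
#' soft-thresholded univariate least-squares coefficient
#' `sign(b) * max(|b| - lambda, 0)`.
#'
#' @param X Feature matrix.
#' @param y Response.
#' @param lambda Penalty.
#' @param standardize Passed to glmnet (default `FALSE`).
#' @return List: `intercept`, `coefficients` (named numeric).
#' @export
lasso_coefficients <- function(X, y, lambda, standardize = FALSE) {
  fit <- glmnet::glmnet(X, y, lambda = lambda, standardize = standardize,
                        thresh = 1e-14)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  beta <- cf[-1]
  names(beta) <- colnames(X)
  list(intercept = cf[1], coefficients = beta)
}

#' One bootstrap iteration of the LASSO model
#'
#' Randomly splits the trials 80/20 (by trial, so the two augmented epochs
#' of one trial always land on the same side), selects the penalty by
#' 10-fold cross-validation on the training rows only (lambda minimizing CV
#' mean-squared error over glmnet's 100-point logarithmic path), fits the
#' L1-penalized least-squares model, and evaluates the Pearson correlation
#' between held-out predictions and observations.
#'
#' When the selected model is empty, held-out predictions are constant and
#' the correlation is undefined; the run records `performance_r = 0` with
#' `degenerate = TRUE` (an empty model carries no predictive association).
#' A split whose held-out observations have zero variance is resampled with
#' the next seed.
#'
#' @param X Feature matrix (rows standardized upstream).
#' @param y Motor-vigor response.
#' @param split_seed Integer seed for this run's split and CV folds.
#' @param trial_ids Trial identifier per row; augmented siblings share one.
#' @param train_frac Training fraction of trials (default 0.8).
#' @param lambda Optional fixed penalty; `NULL` selects by CV.
#' @param nfolds CV folds.
#' @param standardize Passed to glmnet; features are z-scored upstream, so
#'   the default is `FALSE`.
#' @return Object of class `lasso_run`: `split_seed`, `lambda`, `intercept`,
#'   `coefficients` (named, length ncol(X)), `heldout_pred`, `heldout_obs`,
#'   `performance_r`, `degenerate`, `resampled`.
#' @export
fit_lasso_run <- function(X, y, split_seed, trial_ids = NULL,
                          train_frac = 0.8, lambda = NULL, nfolds = 10,
                          standardize = FALSE) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 20)
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(nrow(X)))
  stopifnot(length(trial_ids) == nrow(X))
  resampled <- 0L
  seed <- split_seed
  repeat {
    split <- with_seed(seed, {
      ids <- unique(trial_ids)
      tr_ids <- sample(ids, floor(train_frac * length(ids)))
      list(train = trial_ids %in% tr_ids)
    })
    test <- !split$train
    if (sum(test) >= 3 && stats::sd(y[test]) > 0) break
    resampled <- resampled + 1L
    if (resampled > 25L) stop("could not find a non-degenerate test split")
    seed <- seed + 1000003L
  }
  train <- split$train
  fit <- with_seed(seed + 1L, {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(X[train, , drop = FALSE], y[train],
                              nfolds = nfolds, standardize = standardize)
      list(obj = cv$glmnet.fit, lambda = cv$lambda.min)
    } else {
      obj <- glmnet::glmnet(X[train, , drop = FALSE], y[train],
                            lambda = lambda, standardize = standardize,
                            thresh = 1e-12)
      list(obj = obj, lambda = lambda)
    }
  })
  cf <- as.numeric(stats::coef(fit$obj, s = fit$lambda))
  intercept <- cf[1]
  beta <- cf[-1]
  names(beta) <- colnames(X)
  pred <- drop(X[test, , drop = FALSE] %*% beta) + intercept
  obs <- y[test]
  degenerate <- stats::sd(pred) == 0
  r <- if (degenerate) 0 else performance(pred, obs)
  structure(list(split_seed = split_seed, lambda = fit$lambda,
                 intercept = intercept, coefficients = beta,
                 heldout_pred = pred, heldout_obs = obs,
                 performance_r = r, degenerate = degenerate,
                 resampled = resampled),
            class = "lasso_run")
}

#' Bootstrapped LASSO over repeated random splits
#'
#' Repeats [fit_lasso_run()] over `n_runs` independent 80/20 splits (seeds
#' `base_seed + 1 .. base_seed + n_runs`) and summarizes held-out
#' performance, both raw and on the Fisher-z scale.
#'
#' @inheritParams fit_lasso_run
#' @param n_runs Number of bootstrap iterations (default 40).
#' @param base_seed Base integer seed.
#' @param labels Optional named list of cell labels (group, stimulus, band)
#'   stored with the result.
#' @return Object of class `bootstrap_result`: `runs` (list of
#'   [fit_lasso_run()] results), `mean_r`, `sd_r`, `mean_z`, `sd_z`,
#'   `mean_r_backtransformed` (tanh of `mean_z`), `labels`.
#' @export
bootstrap_lasso <- function(X, y, trial_ids = NULL, n_runs = 40,
                            train_frac = 0.8, base_seed = 1L, lambda = NULL,
                            nfolds = 10, standardize = FALSE,
                            labels = list()) {
  runs <- lapply(seq_len(n_runs), function(i)
    fit_lasso_run(X, y, split_seed = base_seed + i, trial_ids = trial_ids,
                  train_frac = train_frac, lambda = lambda, nfolds = nfolds,
                  standardize = standardize))
  r <- vapply(runs, `[[`, numeric(1), "performance_r")
  z <- fisher_z(r)
  structure(list(runs = runs, n_runs = n_runs,
                 performance_r = r,
                 mean_r = mean(r),
                 sd_r = if (n_runs > 1) stats::sd(r) else 0,
                 mean_z = mean(z),
                 sd_z = if (n_runs > 1) stats::sd(z) else 0,
                 mean_r_backtransformed = tanh(mean(z)),
                 labels = labels),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  lab <- if (length(x$labels)) paste(unlist(x$labels), collapse = "/") else ""
  cat(sprintf("Bootstrap LASSO %s: %d runs, mean r = %.3f (sd %.3f)\n",
              lab, x$n_runs, x$mean_r, x$sd_r))
  invisible(x)
}

#' Band-restricted bootstrapped LASSO
#'
#' Restricts the feature matrix to the columns belonging to one band (pair
#' features belong to both member bands; spectral entropy only to
#' broadband) and runs [bootstrap_lasso()]. `"broadband"` keeps every
#' column and is identical to the unrestricted fit.
#'
#' @inheritParams bootstrap_lasso
#' @param bank Feature-bank index matching the columns of `X`.
#' @param band Band name or `"broadband"`.
#' @return A [bootstrap_lasso()] result with the band recorded in `labels`.
#' @export
band_restricted_fit <- function(X, y, bank, band, trial_ids = NULL,
                                n_runs = 40, train_frac = 0.8,
                                base_seed = 1L, lambda = NULL, nfolds = 10,
                                standardize = FALSE, labels = list()) {
  stopifnot(ncol(X) == nrow(bank))
  keep <- band_membership(bank, band)
  if (!any(keep)) stop("band restriction selects no features: ", band)
  labels$band <- band
  bootstrap_lasso(X[, keep, drop = FALSE], y, trial_ids = trial_ids,
                  n_runs = n_runs, train_frac = train_frac,
                  base_seed = base_seed, lambda = lambda, nfolds = nfolds,
                  standardize = standardize, labels = labels)
}

#' Aggregate LASSO coefficients across bootstrap runs
#'
#' Produces the coefficient map: per feature, the mean coefficient across
#' all runs and across its nonzero occurrences only, plus the selection
#' frequency (fraction of runs with a nonzero coefficient); then the
#' per-(channel, band) and per-band summaries obtained by averaging over
#' member features and channels.
#'
#' @param result A [bootstrap_lasso()] result.
#' @param bank Feature-bank index matching the fitted columns.
#' @return List of data frames: `features` (per feature), `channel_band`
#'   (per channel x band), `band` (per band, averaged across channels).
#' @export
aggregate_coefficients <- function(result, bank) {
  stopifnot(length(result$runs) >= 1)
  cf <- t(vapply(result$runs, `[[`, numeric(nrow(bank)), "coefficients"))
  nz <- cf != 0
  freq <- colMeans(nz)
  mean_all <- colMeans(cf)
  mean_nz <- vapply(seq_len(ncol(cf)), function(j) {
    v <- cf[nz[, j], j]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  feat <- cbind(bank,
                data.frame(mean_all_runs = mean_all,
                           mean_nonzero = mean_nz,
                           selection_freq = freq))
  bands <- eeg_bands()$band
  cb <- do.call(rbind, lapply(unique(bank$channel), function(ch) {
    do.call(rbind, lapply(bands, function(b) {
      sel <- bank$channel == ch & band_membership(bank, b)
      sub <- cf[, sel, drop = FALSE]
      subnz <- sub[sub != 0]
      data.frame(channel = ch, band = b,
                 mean_all_runs = mean(sub),
                 mean_nonzero = if (length(subnz)) mean(subnz) else 0,
                 selection_freq = mean(sub != 0),
                 stringsAsFactors = FALSE)
    }))
  }))
  bd <- do.call(rbind, lapply(bands, function(b) {
    sub <- cb[cb$band == b, ]
    data.frame(band = b,
               mean_all_runs = mean(sub$mean_all_runs),
               mean_nonzero = mean(sub$mean_nonzero),
               selection_freq = mean(sub$selection_freq),
               stringsAsFactors = FALSE)
  }))
  list(features = feat, channel_band = cb, band = bd)
}

#' Fit every (group x stimulus x band) cell
#'
#' Mirrors the 2 x 3 x 7 design: for each group and stimulus condition, fits
#' the broadband model and the six band-restricted models with
#' [band_restricted_fit()].
#'
#' @param fm A feature-matrix bundle from [extract_feature_matrix()] (with
#'   z-scored `X` and `mv`).
#' @param n_runs Bootstrap iterations per cell.
#' @param base_seed Integer seed; each cell uses a distinct derived seed.
#' @param bands Band models to fit (default broadband + 6 bands).
#' @param nfolds CV folds for the per-run penalty selection; small cells
#'   should use fewer folds than the default 10.
#' @return List: `runs` (data frame: group, condition, band, iteration,
#'   performance_r), `cells` (named list of [bootstrap_lasso()] results).
#' @export
fit_all_cells <- function(fm, n_runs = 40, base_seed = 1L,
                          bands = c("broadband", eeg_bands()$band),
                          nfolds = 10) {
  groups <- unique(fm$meta$group)
  conditions <- unique(fm$meta$condition)
  cells <- list()
  rows <- list()
  k <- 0L
  for (g in groups) for (cond in conditions) {
    sel <- fm$meta$group == g & fm$meta$condition == cond
    for (b in bands) {
      k <- k + 1L
      res <- band_restricted_fit(
        fm$X[sel, , drop = FALSE], fm$mv[sel], fm$bank, b,
        trial_ids = fm$trial_ids[sel], n_runs = n_runs,
        base_seed = base_seed + 10000L * k, nfolds = nfolds,
        labels = list(group = g, condition = cond, band = b))
      cells[[paste(g, cond, b, sep = ".")]] <- res
      rows[[k]] <- data.frame(group = g, condition = cond, band = b,
                              iteration = seq_len(n_runs),
                              performance_r = res$performance_r,
                              stringsAsFactors = FALSE)
    }
  }
  list(runs = do.call(rbind, rows), cells = cells)
}
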
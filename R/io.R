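# Cohort serialization (plain-text bundle) and the end-to-end pipeline.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a synthetic cohort to a plain-text bundle
#'
#' Directory layout: `trials.csv` (the schedule plus linkage columns),
#' `manifest.json` (sampling rate, montage, seed, counts),
#' `truth.yaml` (coupling targets, noise SD, planted R^2), and per-trial
#' `pressure_%04d.csv` / `eeg_%04d.csv` files (EEG as samples x channels
#' with a header row). Numbers are written with 17 significant digits so the
#' bundle round-trips bit-identically.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- cohort$trials
  tr$mv_true <- fmt_num(tr$mv_true)
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  manifest <- list(
    n_trials = nrow(cohort$trials),
    fs_hz = cohort$config$fs_hz,
    channel_names = cohort$config$channel_names,
    seed = cohort$config$seed,
    conditions = cohort$config$conditions)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- list(
    noise_sd = cohort$coupling$noise_sd,
    planted_r2 = cohort$truth$planted_r2,
    targets = if (nrow(cohort$coupling$targets))
      lapply(seq_len(nrow(cohort$coupling$targets)), function(i)
        as.list(cohort$coupling$targets[i, ]))
    else list())
  yaml::write_yaml(truth, file.path(path, "truth.yaml"))
  for (i in seq_along(cohort$pressure)) {
    writeLines(fmt_num(cohort$pressure[[i]]),
               file.path(path, sprintf("pressure_%04d.csv", i)))
    m <- t(cohort$eeg[[i]])
    out <- rbind(cohort$config$channel_names,
                 matrix(fmt_num(m), nrow(m), ncol(m)))
    utils::write.table(out, file.path(path, sprintf("eeg_%04d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' Validates the manifest against the trial files (every trial present,
#' channel sets matching) and restores the trials table, pressure traces
#' and EEG segments.
#'
#' @param path Bundle directory.
#' @return List with `trials`, `pressure`, `eeg`, `manifest`, `truth`;
#'   class `synthetic_cohort` (without the generator's config/coupling
#'   objects).
#' @export
read_cohort <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  n <- manifest$n_trials
  if (nrow(trials) != n)
    stop("manifest/trials mismatch: manifest lists ", n, " trials, ",
         "trials.csv has ", nrow(trials))
  pressure <- vector("list", n)
  eeg <- vector("list", n)
  for (i in seq_len(n)) {
    pf <- file.path(path, sprintf("pressure_%04d.csv", i))
    ef <- file.path(path, sprintf("eeg_%04d.csv", i))
    if (!file.exists(pf) || !file.exists(ef))
      stop("bundle is missing files for trial ", i)
    pressure[[i]] <- as.numeric(readLines(pf))
    m <- utils::read.csv(ef, check.names = FALSE)
    if (!identical(colnames(m), manifest$channel_names))
      stop("channel names in eeg_", sprintf("%04d", i),
           ".csv do not match the manifest montage")
    x <- t(as.matrix(m))
    attr(x, "fs_hz") <- as.numeric(manifest$fs_hz)
    eeg[[i]] <- x
  }
  truth <- yaml::read_yaml(file.path(path, "truth.yaml"))
  structure(list(trials = trials, pressure = pressure, eeg = eeg,
                 manifest = manifest, truth = truth,
                 config = list(fs_hz = manifest$fs_hz,
                               channel_names = manifest$channel_names,
                               n_channels = length(manifest$channel_names),
                               seed = manifest$seed)),
            class = "synthetic_cohort")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> preprocess -> extract features -> z-score within subject ->
#' fit every (group x stimulus x band) cell -> behavioral and performance
#' statistics. Every stage writes its outputs and a JSON manifest (stage
#' parameters, seed, dimensions) under `out_dir`; rerunning with the same
#' configuration reproduces all numeric outputs exactly.
#'
#' @param config A [cohort_config()].
#' @param coupling A [coupling_spec()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param n_runs Bootstrap iterations per cell.
#' @param bands Band models to fit.
#' @param filter_order FIR order for per-trial filtering.
#' @param wavelet_depth SWT depth (0 disables denoising).
#' @param nfolds CV folds for penalty selection (use fewer for small cells).
#' @return List: `trials`, `epochs_n`, `features` (z-scored bundle), `fits`
#'   (from [fit_all_cells()]), `behavior` (from [behavior_summary()]),
#'   `performance_anova` (2 x 3 x 7 mixed ANOVA on Fisher-z run
#'   performance, when >= 2 runs and 2 groups).
#' @export
run_pipeline <- function(config = cohort_config(),
                         coupling = coupling_spec(), out_dir = NULL,
                         n_runs = 40, bands = c("broadband",
                                                eeg_bands()$band),
                         filter_order = 750, wavelet_depth = 5,
                         nfolds = 10) {
  cohort <- generate_cohort(config, coupling)
  pp <- preprocess_cohort(cohort, filter_order = filter_order,
                          wavelet_depth = wavelet_depth)
  fm <- extract_feature_matrix(pp$epochs)
  # within-subject standardization of features and MV (population SD)
  zdf <- data.frame(subject_id = fm$meta$subject_id, mv = fm$mv,
                    stringsAsFactors = FALSE)
  zdf <- cbind(zdf, as.data.frame(fm$X, check.names = FALSE))
  zdf <- zscore_within_subject(zdf, cols = setdiff(names(zdf), "subject_id"))
  fm$X <- as.matrix(zdf[, -(1:2), drop = FALSE])
  fm$mv <- zdf$mv
  fits <- fit_all_cells(fm, n_runs = n_runs, base_seed = config$seed,
                        bands = bands, nfolds = nfolds)
  behav <- behavior_summary(pp$trials)
  perf_anova <- NULL
  runs <- fits$runs
  if (n_runs >= 2 && length(unique(runs$group)) == 2) {
    runs$z <- fisher_z(runs$performance_r)
    runs$unit <- paste(runs$group, runs$iteration, sep = "_")
    perf_anova <- mixed_anova(runs, dv = "z", between = "group",
                              within = c("condition", "band"), unit = "unit")
  }
  out <- list(trials = pp$trials, epochs_n = length(pp$epochs),
              features = fm, fits = fits, behavior = behav,
              performance_anova = perf_anova, log = pp$log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(pp$trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(fits$runs, file.path(out_dir, "runs.csv"),
                     row.names = FALSE)
    utils::write.csv(behav$table, file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
    if (!is.null(perf_anova))
      utils::write.csv(as.data.frame(perf_anova),
                       file.path(out_dir, "performance_anova.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_trials = nrow(pp$trials),
           n_epochs = length(pp$epochs), n_runs = n_runs, bands = bands,
           filter_order = filter_order, wavelet_depth = wavelet_depth,
           n_features = ncol(fm$X)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
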
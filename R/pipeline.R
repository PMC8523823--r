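#' Default pipeline configuration
#'
#' Central collection of the pipeline's processing constants with their
#' standard values: EMG filter edges 30/450 Hz and envelope cutoff 6 Hz,
#' the 101-node stance grid, the 40 ms electromechanical delay, the SPM
#' significance level 0.05, and the default study layout of 10 subjects
#' walking 4 trials on each of 4 surfaces. Overrides supplied through
#' `...` are echoed into the run log by the `run_*` functions.
#'
#' @param ... named overrides of any default entry.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    band = c(30, 450), lowpass = 6, grid_n = 101L, delay = 0.040,
    alpha = 0.05, n_perm = 999L, seed = 20211005L,
    n_subjects = 10L, trials_per_condition = 4L,
    noise_sd = 2, surface_effect = 0.08,
    calib_n_starts = 4L, calib_maxit = 600L,
    out_dir = "anklemsk-run", verbose = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration entries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg$overridden <- names(over)
  structure(cfg, class = "pipeline_config")
}

run_log <- function(cfg, lines) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hashable <- cfg[sort(setdiff(names(unclass(cfg)), "verbose"))]
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hashable, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  msg <- c(sprintf("config-hash: %s", hash),
           sprintf("seed: %d", cfg$seed),
           if (length(cfg$overridden))
             sprintf("override: %s", cfg$overridden),
           lines)
  cat(msg, file = file.path(cfg$out_dir, "run.log"), sep = "\n", append = TRUE)
  if (isTRUE(cfg$verbose)) message(paste(lines, collapse = "\n"))
  invisible(hash)
}

#' Write / read one gait trial as headered CSV
#'
#' Plain tabular text with `# key=value` header lines carrying the
#' sampling rate and metadata, then columns `time`, `emg_<muscle>...`,
#' `theta`, `tau_id`, `grf_v`, `grf_ap`.
#'
#' @param trial a [gait_trial()].
#' @param path output file path.
#' @return `write_trial`: the path, invisibly. `read_trial`: a
#'   [gait_trial()].
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  hdr <- sprintf("# %s=%s",
                 c("rate", "subject", "condition", "trial", "raw_emg",
                   "stance_start", "stance_end"),
                 c(trial$rate, trial$subject, trial$condition,
                   trial$trial_index, trial$emg_is_raw,
                   trial$stance_start, trial$stance_end))
  df <- data.frame(time = trial$time)
  for (m in colnames(trial$emg)) df[[paste0("emg_", m)]] <- trial$emg[, m]
  df$theta <- trial$theta
  df$tau_id <- trial$tau_id
  df$grf_v <- if (is.null(trial$grf_v)) NA_real_ else trial$grf_v
  df$grf_ap <- if (is.null(trial$grf_ap)) NA_real_ else trial$grf_ap
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  lines <- readLines(path)
  hdr_n <- sum(startsWith(lines, "#"))
  kv <- sub("^# ", "", lines[seq_len(hdr_n)])
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = lines[-seq_len(hdr_n)])
  emg_cols <- grep("^emg_", names(df), value = TRUE)
  emg <- as.matrix(df[emg_cols])
  colnames(emg) <- sub("^emg_", "", emg_cols)
  gait_trial(rate = as.numeric(meta["rate"]), time = df$time, emg = emg,
             theta = df$theta, tau_id = df$tau_id,
             grf_v = if (all(is.na(df$grf_v))) NULL else df$grf_v,
             grf_ap = if (all(is.na(df$grf_ap))) NULL else df$grf_ap,
             condition = meta[["condition"]],
             subject = as.integer(meta["subject"]),
             trial_index = as.integer(meta["trial"]),
             stance_start = as.integer(meta["stance_start"]),
             stance_end = as.integer(meta["stance_end"]),
             emg_is_raw = as.logical(meta["raw_emg"]))
}

#' Write / read a synthetic dataset directory
#'
#' One CSV per trial plus `manifest.csv` and a `truth.yaml` summarizing
#' the generating parameters (activation constants, strength coefficients,
#' bursts, noise, conditions, seed).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `write_dataset`: the directory, invisibly. `read_dataset`: a
#'   list with `trials` and `manifest` shaped like a `gait_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$file <- sprintf("subj%02d_%s_t%d.csv", man$subject, man$condition,
                      man$trial)
  for (i in seq_len(nrow(man)))
    write_trial(dataset$trials[[man$idx[i]]], file.path(dir, man$file[i]))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  tru <- dataset$truth
  yaml::write_yaml(list(
    activation = tru$activation[c("C1", "C2", "A", "d")],
    gamma_df = tru$gamma_df, gamma_pf = tru$gamma_pf,
    bursts = lapply(tru$bursts, as.list),
    noise_sd = tru$noise_sd, surface_effect = tru$surface_effect,
    conditions = as.list(tru$conditions), rate = tru$rate,
    stance_duration = tru$stance_duration, seed = tru$seed),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  trials <- lapply(man$file, function(f) read_trial(file.path(dir, f)))
  structure(list(trials = trials, manifest = man), class = "gait_dataset")
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Wraps [generate_dataset()] with configuration handling, writes the
#' dataset directory and logs the run.
#'
#' @param cfg a [pipeline_config()].
#' @param truth optional [synthetic_truth()]; by default built from the
#'   configuration's seed, noise and surface-effect entries.
#' @return The `gait_dataset`, invisibly.
#' @export
run_simulate <- function(cfg = pipeline_config(), truth = NULL) {
  if (is.null(truth))
    truth <- synthetic_truth(noise_sd = cfg$noise_sd,
                             surface_effect = cfg$surface_effect,
                             seed = cfg$seed)
  ds <- generate_dataset(truth, cfg$n_subjects, cfg$trials_per_condition)
  dir <- file.path(cfg$out_dir, "dataset")
  write_dataset(ds, dir)
  run_log(cfg, sprintf("simulate: %d trials written to %s",
                       nrow(ds$manifest), dir))
  invisible(ds)
}

#' Pipeline stage: per-subject calibration
#'
#' Calibrates the model for every subject in the dataset (all of the
#' subject's trials pooled) and writes a calibration report with
#' per-subject NRMSE and the cohort mean, the headline fit statistic.
#' Subjects whose calibration fails are recorded and skipped; the stage
#' fails only if every subject fails.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset a `gait_dataset`.
#' @param spec optional [calibration_spec()] (built from `cfg` otherwise).
#' @return A list with per-subject `results` ([calibrate()] outputs) and
#'   the `report` data frame, invisibly.
#' @export
run_calibrate <- function(cfg = pipeline_config(), dataset, spec = NULL) {
  if (is.null(spec))
    spec <- calibration_spec(delay = cfg$delay, n_starts = cfg$calib_n_starts,
                             maxit = cfg$calib_maxit, seed = cfg$seed)
  man <- dataset$manifest
  subjects <- sort(unique(man$subject))
  results <- list(); rows <- list()
  for (s in subjects) {
    idx <- man$idx[man$subject == s]
    res <- tryCatch(calibrate(dataset$trials[idx], spec),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[as.character(s)]] <- data.frame(subject = s, J = NA, nrmse = NA,
                                            error = conditionMessage(res))
      next
    }
    results[[as.character(s)]] <- res
    rows[[as.character(s)]] <- data.frame(subject = s, J = res$J,
                                          nrmse = res$nrmse_mean, error = "")
  }
  if (!length(results)) stop("calibration failed for every subject", call. = FALSE)
  report <- do.call(rbind, rows)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, file.path(cfg$out_dir, "calibration_report.csv"),
                   row.names = FALSE)
  pars <- lapply(results, function(r) as.list(r$par))
  yaml::write_yaml(pars, file.path(cfg$out_dir, "calibrated_params.yaml"))
  run_log(cfg, sprintf("calibrate: %d/%d subjects, cohort mean NRMSE %.3f",
                       length(results), length(subjects),
                       mean(report$nrmse, na.rm = TRUE)))
  invisible(list(results = results, report = report))
}

#' Pipeline stage: estimate joint curves for every trial
#'
#' Runs the forward chain for each trial with the subject's calibrated
#' model (or a common model) and writes the 101-node moment and stiffness
#' curves as one CSV.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset a `gait_dataset`.
#' @param calibration a [run_calibrate()] result, or `NULL` to use
#'   `model` for everyone.
#' @param model fallback [ankle_model()] when no calibration is given.
#' @return List of [estimate_trial()] results, invisibly.
#' @export
run_estimate <- function(cfg = pipeline_config(), dataset,
                         calibration = NULL, model = NULL) {
  man <- dataset$manifest
  spec <- calibration_spec(delay = cfg$delay)
  series <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- as.character(man$subject[i])
    mdl <- if (!is.null(calibration) && !is.null(calibration$results[[s]]))
      build_calibrated_model(calibration$results[[s]]$par, spec)
    else model
    if (is.null(mdl)) stop("no model available for subject ", s, call. = FALSE)
    series[[i]] <- estimate_trial(mdl, dataset$trials[[man$idx[i]]],
                                  n = cfg$grid_n)
  }
  long <- do.call(rbind, lapply(series, function(js) {
    data.frame(subject = js$subject, condition = js$condition,
               trial = js$trial_index, pct = js$pct, tau = js$tau,
               stiffness = js$stiffness)
  }))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(long, file.path(cfg$out_dir, "joint_curves.csv"),
                   row.names = FALSE)
  run_log(cfg, sprintf("estimate: %d trials -> joint_curves.csv", length(series)))
  invisible(series)
}

#' Pipeline stage: compare conditions with permutation SPM
#'
#' Builds subject-by-condition mean curves for the requested fields and
#' runs [permutation_inference()] on each, writing one cluster table.
#'
#' @param cfg a [pipeline_config()].
#' @param dataset a `gait_dataset`.
#' @param series optional [run_estimate()] output; enables the
#'   model-estimated `tau` and `stiffness` fields.
#' @param fields which curves to compare.
#' @return Named list of [permutation_inference()] results, invisibly.
#' @export
run_compare <- function(cfg = pipeline_config(), dataset, series = NULL,
                        fields = c("tau_id", "grf_v", "grf_ap")) {
  out <- list(); rows <- list()
  for (f in fields) {
    cd <- if (f %in% c("tau", "stiffness")) {
      if (is.null(series)) stop("field '", f, "' needs estimated series",
                                call. = FALSE)
      curves_from_series(series, f)
    } else if (startsWith(f, "exc_")) {
      curves_from_trials(dataset, "excitation", muscle = sub("^exc_", "", f),
                         n = cfg$grid_n)
    } else curves_from_trials(dataset, f, n = cfg$grid_n)
    res <- permutation_inference(cd, alpha = cfg$alpha, n_perm = cfg$n_perm,
                                 seed = cfg$seed)
    out[[f]] <- res
    rows[[f]] <- if (nrow(res$clusters))
      cbind(field = f, res$clusters)
    else data.frame(field = f, start = NA, end = NA, extent = NA, peak = NA,
                    p = NA, significant = FALSE)
  }
  tab <- do.call(rbind, rows)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(cfg$out_dir, "spm_clusters.csv"),
                   row.names = FALSE)
  run_log(cfg, sprintf("compare: %d fields -> spm_clusters.csv", length(out)))
  invisible(out)
}
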
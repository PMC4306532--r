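# Study orchestration: simulate N synthetic subjects, preprocess, build
# regressors, beamform with correlational source imaging per band/window/
# regressor variant, and run group statistics. Each stage is an exported
# function; run_study() composes them deterministically from a master seed.

#' Per-subject seeds from a master seed
#'
#' Documented counter scheme: subject `i` receives
#' `(master_seed mod 2e6) * 1000 + i`, keeping every seed a valid 32-bit
#' integer and making subjects independently reproducible (and
#' parallelizable) from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param n_subjects number of subjects.
#' @return integer vector of seeds.
#' @export
subject_seeds <- function(master_seed, n_subjects) {
  as.integer((as.numeric(master_seed) %% 2e6) * 1000 + seq_len(n_subjects))
}

#' Simulate one synthetic subject
#'
#' Trial schedule, sensor epochs with ground-truth source envelopes, RTs
#' coupled to the latent envelopes, and EOG traces.
#'
#' @param config a [sim_config()].
#' @param eog generate EOG traces too (default `TRUE`).
#' @return list: `table`, `epochs`, `true_amplitude`, `latents`, `eog`,
#'   `config`.
#' @export
simulate_subject <- function(config, eog = TRUE) {
  table <- generate_trial_schedule(config)
  sim <- simulate_sensor_epochs(table, config)
  # couple RT to the standardized realized envelope, so rt_coupling_r is the
  # population correlation of the measurable amplitude with RT
  latent <- if (ncol(sim$true_amplitude)) scale(sim$true_amplitude) else NULL
  table <- generate_rt(table, config, latent)
  traces <- if (eog) simulate_eog(table, config) else NULL
  list(table = table, epochs = sim$epochs,
       true_amplitude = sim$true_amplitude, latents = sim$latents,
       eog = traces, config = config)
}

#' Preprocess one subject: saccade detection and trial exclusion
#'
#' @param subject output of [simulate_subject()] (with EOG).
#' @param ... passed to [detect_saccades()].
#' @return list: `table` (included trials, RT = detected latency), `events`,
#'   `report`.
#' @export
preprocess_subject <- function(subject, ...) {
  if (is.null(subject$eog)) stop("subject has no EOG traces")
  events <- detect_saccades(subject$eog, ...)
  res <- apply_exclusions(events, subject$table)
  list(table = res$table, events = events, report = res$report)
}

#' Correlational source maps for one subject
#'
#' For every band x window combination: global covariance, scalar beamformer
#' weights, per-trial band amplitudes, and the correlational volume for each
#' requested regressor variant. Only single-target trials enter the RT
#' correlation, as in the underlying design.
#'
#' @param subject output of [simulate_subject()].
#' @param table trial table to use (e.g. after exclusions); defaults to the
#'   subject's.
#' @param grid a [source_grid()] (defaults to a 20 mm grid in the subject's
#'   head model).
#' @param bands list of `c(low, high)` Hz bands.
#' @param windows list of `c(t1, t2)` s windows.
#' @param regressors named list of per-trial regressor vectors aligned with
#'   `table` rows; defaults to the raw RT of single-target trials.
#' @param reg diagonal-loading fraction.
#' @return nested list `maps[[band]][[window]][[regressor]]` of
#'   `stat_volume`s, plus `grid`.
#' @export
subject_sam_maps <- function(subject, table = subject$table, grid = NULL,
                             bands = list(`5-15` = c(5, 15)),
                             windows = list(`[-1,0]` = c(-1, 0)),
                             regressors = NULL, reg = 0.05) {
  epochs <- subject$epochs
  if (is.null(grid)) grid <- source_grid(epochs$model, spacing = 20)
  sensors <- list(positions = epochs$channel_positions,
                  orientations = epochs$channel_orientations)
  single <- table$condition %in% c("left", "right")
  if (is.null(regressors)) regressors <- list(raw = table$rt)
  trial_rows <- match(table$trial_id, subject$table$trial_id)
  maps <- list()
  for (bn in names(bands)) {
    maps[[bn]] <- list()
    filt <- filter_epochs(epochs, bands[[bn]])
    for (wn in names(windows)) {
      cv <- global_covariance(epochs, bands[[bn]], windows[[wn]],
                              filtered = filt)
      ws <- sam_weights(cv, epochs$model, grid, sensors, reg = reg)
      amp <- trial_band_amplitude(ws, epochs, filtered = filt)
      amp_t <- amp[trial_rows, , drop = FALSE]
      attr(amp_t, "band") <- attr(amp, "band")
      attr(amp_t, "window") <- attr(amp, "window")
      maps[[bn]][[wn]] <- lapply(names(regressors), function(rn) {
        correlational_sam(amp_t[single, , drop = FALSE],
                          regressors[[rn]][single], grid = grid, tag = rn)
      })
      names(maps[[bn]][[wn]]) <- names(regressors)
    }
  }
  list(maps = maps, grid = grid)
}

#' Run a full synthetic study
#'
#' Simulates `n_subjects` subjects from per-subject seeds derived from
#' `master_seed` ([subject_seeds()]), preprocesses them, builds the regressor
#' cascade, computes correlational source maps per band/window/regressor, and
#' runs group statistics (one-sample tests on r-values and the sign-flip
#' omnibus). Identical inputs give identical outputs.
#'
#' @param config a [sim_config()] template (its `seed` is replaced per
#'   subject).
#' @param n_subjects number of synthetic subjects (default 12).
#' @param master_seed master RNG seed.
#' @param bands,windows band/window lists as in [subject_sam_maps()].
#' @param grid_spacing source grid spacing, mm.
#' @param preprocess run EOG detection/exclusion (default `TRUE`; when
#'   `FALSE` the generator's ground-truth RTs are used directly).
#' @param regressor_variants which RT variants to correlate
#'   (subset of `c("raw", "corrected", "detrended")`).
#' @return object of class `study_result`: `group` (per band/window/
#'   regressor: `one_sample` and `omnibus` results), `subject_maps`,
#'   `ledgers`, `reports`, `grid`, `manifest` (seeds, config echo, stage
#'   timings).
#' @export
run_study <- function(config, n_subjects = 12, master_seed = 1,
                      bands = list(`5-15` = c(5, 15)),
                      windows = list(`[-1,0]` = c(-1, 0)),
                      grid_spacing = 20, preprocess = TRUE,
                      regressor_variants = c("raw", "corrected", "detrended")) {
  t_start <- proc.time()[["elapsed"]]
  seeds <- subject_seeds(master_seed, n_subjects)
  model <- sphere_head_model(radius = config$head_radius)
  grid <- source_grid(model, spacing = grid_spacing)
  subject_maps <- list()
  ledgers <- list()
  reports <- list()
  for (i in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- seeds[i]
    sub <- simulate_subject(cfg, eog = preprocess)
    tab <- sub$table
    if (preprocess) {
      pp <- preprocess_subject(sub)
      tab <- pp$table
      reports[[i]] <- pp$report
    }
    regs <- build_regressors(tab)
    ledgers[[i]] <- regs$ledger
    reg_list <- list(raw = regs$raw_rt, corrected = regs$rt_corrected,
                     detrended = regs$rt_detrended)[regressor_variants]
    sm <- subject_sam_maps(sub, table = tab, grid = grid, bands = bands,
                           windows = windows, regressors = reg_list)
    subject_maps[[i]] <- sm$maps
  }
  group <- list()
  for (bn in names(bands)) {
    group[[bn]] <- list()
    for (wn in names(windows)) {
      group[[bn]][[wn]] <- list()
      for (rn in regressor_variants) {
        R <- t(vapply(subject_maps, function(m) m[[bn]][[wn]][[rn]]$values,
                      numeric(nrow(grid$positions))))
        group[[bn]][[wn]][[rn]] <- list(
          one_sample = one_sample_group_test(R),
          omnibus = permutation_omnibus(R),
          mean_map = colMeans(R))
      }
    }
  }
  manifest <- list(master_seed = master_seed, subject_seeds = seeds,
                   n_subjects = n_subjects,
                   bands = bands, windows = windows,
                   grid_spacing = grid_spacing,
                   n_voxels = nrow(grid$positions),
                   preprocess = preprocess,
                   elapsed_s = proc.time()[["elapsed"]] - t_start)
  structure(list(group = group, subject_maps = subject_maps,
                 ledgers = ledgers, reports = reports, grid = grid,
                 manifest = manifest),
            class = "study_result")
}

#' Peak-r summary per ROI and band
#'
#' Mirrors the two summary conventions of correlational source analyses: the
#' peak of the group-average map within each ROI (a lower-bound estimate of
#' the ROI's contribution) and the group average of per-subject peaks within
#' the ROI (an upper bound).
#'
#' @param study a [run_study()] result (grid must carry ROI `labels`).
#' @param band,window,regressor which map to summarize.
#' @return `data.frame`: `roi`, `peak_of_mean`, `mean_of_peaks`,
#'   `pct_var_lower`, `pct_var_upper`.
#' @export
study_roi_peaks <- function(study, band = 1, window = 1, regressor = "raw") {
  grid <- study$grid
  rois <- setdiff(unique(grid$labels), "")
  if (!length(rois)) stop("grid has no ROI labels")
  g <- study$group[[band]][[window]][[regressor]]
  subj <- lapply(study$subject_maps, function(m)
    m[[band]][[window]][[regressor]]$values)
  out <- lapply(rois, function(roi) {
    vx <- which(grid$labels == roi)
    pom <- max(g$mean_map[vx], na.rm = TRUE)
    mop <- mean(vapply(subj, function(v) max(v[vx], na.rm = TRUE),
                       numeric(1)))
    data.frame(roi = roi, peak_of_mean = pom, mean_of_peaks = mop,
               pct_var_lower = variance_explained(pom),
               pct_var_upper = variance_explained(mop))
  })
  do.call(rbind, out)
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", x$manifest$n_subjects, "subjects,",
      x$manifest$n_voxels, "voxels,",
      length(x$manifest$bands), "band(s) x",
      length(x$manifest$windows), "window(s); elapsed",
      round(x$manifest$elapsed_s, 1), "s\n")
  invisible(x)
}
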
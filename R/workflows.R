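# End-to-end drivers tying the generators, preprocessing, modelling and
# hydration analysis into reproducible workflows.  Each driver takes a
# flat config list (or YAML file via read_workflow_config), validates it
# against a schema of known keys, and returns a run_report whose every
# number is traceable to a stage log.

.spectra_quant_keys <- c(
  "workflow", "analyte", "concentrations_mM", "replicates_per_level",
  "grid", "noise_sd", "scatter_gain_sd", "baseline_offset_sd",
  "baseline_slope_sd", "outlier_fraction", "outlier_magnitude", "n_blanks",
  "input_csv", "background_csv", "include_ranges", "snv", "sg_window",
  "sg_polyorder", "sg_derivative", "mahalanobis_quantile",
  "variance_target", "osc_components", "max_lv", "cv_scheme", "k_out",
  "peak_window", "seed")

.mixture_quant_keys <- c(
  "workflow", "analytes", "mixture_table", "replicates_per_level", "grid",
  "noise_sd", "scatter_gain_sd", "baseline_offset_sd", "baseline_slope_sd",
  "n_blanks", "input_csv", "background_csv", "include_ranges", "max_pc",
  "k_out", "peak_window", "seed")

.hydration_keys <- c(
  "workflow", "solute", "n_waters", "n_frames", "box", "occupancy",
  "mean_residence", "xyz_path", "topology_path", "bin_width", "r_max",
  "last_frames", "min_persistence", "weight_exponent", "dist_OO",
  "dist_OS", "angle_dev", "seed")

check_config_keys <- function(config, allowed, workflow) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown ", workflow, " config key(s): ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

cfg <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

#' Read a workflow configuration from a flat YAML file
#'
#' The `workflow` key selects the schema (`spectra_quant`,
#' `mixture_quant` or `hydration`); unknown keys are errors.
#'
#' @param path YAML file.
#' @return named config list.
#' @export
read_workflow_config <- function(path) {
  config <- yaml::read_yaml(path)
  wf <- config$workflow
  if (is.null(wf)) stop("config must name a 'workflow'")
  allowed <- switch(wf,
                    spectra_quant = .spectra_quant_keys,
                    mixture_quant = .mixture_quant_keys,
                    hydration = .hydration_keys,
                    stop("unknown workflow kind: ", wf))
  check_config_keys(config, allowed, wf)
  config
}

stage <- function(report, name, params = list(), dims = NULL) {
  report$stages[[length(report$stages) + 1L]] <-
    list(stage = name, params = params, dims = dims)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> workflow: ", x$workflow, " (seed ", x$seed, ")\n",
      sep = "")
  cat("  stages: ",
      paste(vapply(x$stages, `[[`, "", "stage"), collapse = " -> "),
      "\n", sep = "")
  if (!is.null(x$metrics)) {
    print(x$metrics, row.names = FALSE)
  }
  if (!is.null(x$scores)) {
    print(x$scores, row.names = FALSE)
  }
  invisible(x)
}

#' Single-analyte quantification workflow
#'
#' The full chain: generate (or read) a concentration series and buffer
#' blanks; mask the usable wavelength regions; SNV; Savitzky-Golay
#' smoothing; PCA/Mahalanobis outlier screen; difference spectra against
#' the blank mean; cross-validated OSC + PLS with latent-variable
#' selection; final model fit and regression-vector peak localization.
#'
#' @param config named list (see `read_workflow_config()` for the schema);
#'   all keys optional, defaults reproduce the standard GSH series.
#' @return A `run_report` with metrics (calibration and cross-validated
#'   RMSE/R2), the removed outlier ids, the peak table and the fitted
#'   model (with its wavelength grid attached).
#' @export
run_spectra_quant <- function(config = list()) {
  check_config_keys(config, .spectra_quant_keys, "spectra_quant")
  seed <- cfg(config, "seed", 1L)
  analyte <- cfg(config, "analyte", "GSH")
  report <- structure(list(workflow = "spectra_quant", config = config,
                           seed = seed, stages = list()),
                      class = "run_report")

  if (!is.null(config$input_csv)) {
    set <- read_spectra(config$input_csv)
    blanks <- read_spectra(config$background_csv)
    truth <- NULL
    report <- stage(report, "read", list(path = config$input_csv),
                    dim(set$absorbance))
  } else {
    design <- experiment_design(
      analytes = list(analyte_signature(analyte)),
      concentrations_mM = cfg(config, "concentrations_mM", 1:10),
      replicates_per_level = cfg(config, "replicates_per_level", 25L),
      grid = cfg(config, "grid", c(1100, 2400, 2)),
      noise_sd = cfg(config, "noise_sd", 1e-3),
      scatter_gain_sd = cfg(config, "scatter_gain_sd", 0.01),
      baseline_offset_sd = cfg(config, "baseline_offset_sd", 5e-4),
      baseline_slope_sd = cfg(config, "baseline_slope_sd", 5e-7),
      n_blanks = cfg(config, "n_blanks", 25L),
      seed = seed)
    gen <- generate_spectra_set(design)
    full <- gen$set
    is_blank <- full$meta$analyte == "PBS"
    blanks <- spectra_set(full$grid,
                          full$absorbance[is_blank, , drop = FALSE],
                          full$meta[is_blank, , drop = FALSE],
                          full$provenance)
    set <- spectra_set(full$grid,
                       full$absorbance[!is_blank, , drop = FALSE],
                       full$meta[!is_blank, , drop = FALSE],
                       full$provenance)
    outlier_fraction <- cfg(config, "outlier_fraction", 0)
    injected_ids <- character(0)
    if (outlier_fraction > 0) {
      inj <- inject_outliers(set, outlier_fraction,
                             magnitude = cfg(config, "outlier_magnitude",
                                             0.1),
                             seed = seed + 7L)
      set <- inj$set
      injected_ids <- set$meta$id[inj$flags]
    }
    truth <- list(injected_ids = injected_ids)
    report <- stage(report, "generate",
                    list(analyte = analyte, seed = seed),
                    dim(set$absorbance))
  }

  ranges <- cfg(config, "include_ranges",
                list(c(1100, 1850), c(2050, 2400)))
  set <- mask_regions(set, ranges)
  blanks <- mask_regions(blanks, ranges)
  report <- stage(report, "mask", list(ranges = ranges),
                  dim(set$absorbance))
  if (cfg(config, "snv", TRUE)) {
    set <- snv(set); blanks <- snv(blanks)
    report <- stage(report, "snv", list(), dim(set$absorbance))
  }
  sg_w <- cfg(config, "sg_window", 15L)
  set <- savitzky_golay(set, sg_w, cfg(config, "sg_polyorder", 2L),
                        cfg(config, "sg_derivative", 0L))
  blanks <- savitzky_golay(blanks, sg_w, cfg(config, "sg_polyorder", 2L),
                           cfg(config, "sg_derivative", 0L))
  report <- stage(report, "savitzky_golay", list(window = sg_w),
                  dim(set$absorbance))

  # outlier screen on the preprocessed sample spectra
  pca_all <- fit_pca(set$absorbance,
                     k = min(10L, n_spectra(set) - 1L, n_channels(set)))
  k_screen <- choose_k_explained(pca_all,
                                 cfg(config, "variance_target", 0.95))
  screen <- mahalanobis_screen(
    fit_pca(set$absorbance, k = k_screen),
    cfg(config, "mahalanobis_quantile", 0.975))
  removed_ids <- set$meta$id[screen$removed]
  keep <- screen$kept
  set <- spectra_set(set$grid, set$absorbance[keep, , drop = FALSE],
                     set$meta[keep, , drop = FALSE], set$provenance)
  report <- stage(report, "outlier_screen",
                  list(k = k_screen, removed = removed_ids),
                  dim(set$absorbance))

  set <- difference_spectra(set, blanks)
  report <- stage(report, "difference", list(), dim(set$absorbance))

  y <- set$meta$concentration_mM
  osc_k <- cfg(config, "osc_components", 1L)
  cvres <- cv_plsr(set$absorbance, y,
                   max_lv = cfg(config, "max_lv", 10L),
                   osc_components = osc_k,
                   scheme = cfg(config, "cv_scheme", "loo"),
                   k_out = cfg(config, "k_out", 5L), seed = seed)
  report <- stage(report, "cross_validate",
                  list(scheme = cfg(config, "cv_scheme", "loo"),
                       osc_components = osc_k, n_lv = cvres$n_lv))

  # final model on all retained spectra at the selected size
  X <- set$absorbance
  osc <- NULL
  if (osc_k > 0L) {
    osc <- fit_osc(X, y, n_components = osc_k)
    X <- apply_osc(osc, X)
  }
  model <- fit_plsr(X, y, n_lv = cvres$n_lv)
  model$grid <- set$grid
  cal <- regression_metrics(y, model$fitted.values)
  peaks <- regression_vector_peaks(
    model, window = cfg(config, "peak_window", c(1300, 1600)),
    min_prominence = 0.1 * max(abs(model$b)))
  report <- stage(report, "fit", list(n_lv = cvres$n_lv))

  report$metrics <- data.frame(
    analyte = analyte, n_lv = cvres$n_lv,
    rmse_cal = cal$rmse, r2_cal = cal$r2,
    rmse_cv = cvres$cv$rmse, r2_cv = cvres$cv$r2)
  report$outliers_removed <- removed_ids
  report$injected_outliers <- if (!is.null(truth)) truth$injected_ids
  report$peaks <- peaks
  report$model <- model
  report$osc <- osc
  report$cv <- cvres
  report$predictions <- cvres$cv$predictions
  report$y <- y
  report
}

#' Mixture quantification workflow
#'
#' Reproduces the mixed-solution analysis: a paired concentration design
#' (by default GSH k mM with GSSG (10 - k)/2 mM, k = 1..9), masking to
#' the 1300-1600 nm water first overtone, difference spectra against the
#' buffer blanks -- no other preprocessing -- then two-response principal
#' component regression validated by leave-five-spectra-out.
#'
#' @param config named list; all keys optional.
#' @return A `run_report` with per-analyte held-out metrics, dual
#'   regression vectors and their peak tables.
#' @export
run_mixture_quant <- function(config = list()) {
  check_config_keys(config, .mixture_quant_keys, "mixture_quant")
  seed <- cfg(config, "seed", 1L)
  analyte_names <- cfg(config, "analytes", c("GSH", "GSSG"))
  mix <- cfg(config, "mixture_table", {
    k <- 1:9
    tb <- data.frame(k, (10 - k) / 2)
    names(tb) <- analyte_names[1:2]
    tb
  })
  report <- structure(list(workflow = "mixture_quant", config = config,
                           seed = seed, stages = list()),
                      class = "run_report")
  design <- experiment_design(
    analytes = lapply(analyte_names, analyte_signature),
    mixture_table = mix,
    replicates_per_level = cfg(config, "replicates_per_level", 25L),
    grid = cfg(config, "grid", c(1100, 2400, 2)),
    noise_sd = cfg(config, "noise_sd", 1e-3),
    scatter_gain_sd = cfg(config, "scatter_gain_sd", 0.01),
    baseline_offset_sd = cfg(config, "baseline_offset_sd", 5e-4),
    baseline_slope_sd = cfg(config, "baseline_slope_sd", 5e-7),
    n_blanks = cfg(config, "n_blanks", 25L),
    seed = seed)
  gen <- generate_spectra_set(design)
  full <- gen$set
  is_blank <- full$meta$analyte == "PBS"
  blanks <- spectra_set(full$grid,
                        full$absorbance[is_blank, , drop = FALSE],
                        full$meta[is_blank, , drop = FALSE])
  set <- spectra_set(full$grid,
                     full$absorbance[!is_blank, , drop = FALSE],
                     full$meta[!is_blank, , drop = FALSE])
  report <- stage(report, "generate", list(seed = seed),
                  dim(set$absorbance))

  ranges <- cfg(config, "include_ranges", list(c(1300, 1600)))
  set <- mask_regions(set, ranges)
  blanks <- mask_regions(blanks, ranges)
  set <- difference_spectra(set, blanks)
  report <- stage(report, "mask+difference", list(ranges = ranges),
                  dim(set$absorbance))

  Y <- as.matrix(set$meta[paste0("conc_", analyte_names)])
  colnames(Y) <- analyte_names
  cvres <- cv_pcr(set$absorbance, Y, max_pc = cfg(config, "max_pc", 10L),
                  scheme = "lko", k_out = cfg(config, "k_out", 5L),
                  seed = seed)
  model <- fit_pcr(set$absorbance, Y, k = cvres$k)
  model$grid <- set$grid
  report <- stage(report, "pcr", list(k = cvres$k))

  peak_window <- cfg(config, "peak_window", c(1300, 1600))
  peaks <- lapply(seq_along(analyte_names), function(j) {
    regression_vector_peaks(model, window = peak_window, response = j,
                            min_prominence = 0.1 * max(abs(model$b[, j])))
  })
  names(peaks) <- analyte_names
  report$metrics <- do.call(rbind, lapply(analyte_names, function(a) {
    m <- cvres$per_response[[a]]
    cal <- regression_metrics(Y[, a], model$fitted.values[, a])
    data.frame(analyte = a, k = cvres$k, rmse_cal = cal$rmse,
               r2_cal = cal$r2, rmse_cv = m$rmse, r2_cv = m$r2)
  }))
  report$peaks <- peaks
  report$model <- model
  report$cv <- cvres
  report$Y <- Y
  report
}

#' Hydration-shell analysis workflow
#'
#' Generates (or reads) a solvation trajectory, computes the sulfur-water
#' RDF with first-peak location, the coordination number at the first
#' minimum, and the directional residence-weighted interaction scores
#' (total and per sulfur).
#'
#' @param config named list; all keys optional, defaults analyze a
#'   thiol-like solute.
#' @return A `run_report` with the RDF profile, peak/coordination summary
#'   and score table.
#' @export
run_hydration <- function(config = list()) {
  check_config_keys(config, .hydration_keys, "hydration")
  seed <- cfg(config, "seed", 1L)
  report <- structure(list(workflow = "hydration", config = config,
                           seed = seed, stages = list()),
                      class = "run_report")
  if (!is.null(config$xyz_path)) {
    traj <- read_trajectory(config$xyz_path, config$topology_path)
    schedule <- NULL
    report <- stage(report, "read", list(path = config$xyz_path),
                    dim(traj$coords))
  } else {
    gen <- generate_solvation_trajectory(
      solute = cfg(config, "solute", "thiol"),
      n_waters = cfg(config, "n_waters", 200L),
      n_frames = cfg(config, "n_frames", 2000L),
      box = cfg(config, "box", c(30, 30, 30)),
      occupancy = cfg(config, "occupancy", 0.6),
      mean_residence = cfg(config, "mean_residence", 20),
      seed = seed)
    traj <- gen$trajectory
    schedule <- gen$schedule
    report <- stage(report, "generate",
                    list(solute = cfg(config, "solute", "thiol"),
                         seed = seed), dim(traj$coords))
  }
  criteria <- hbond_criteria(dist_OO = cfg(config, "dist_OO", 3.5),
                             dist_OS = cfg(config, "dist_OS", 4.0),
                             angle_dev = cfg(config, "angle_dev", 30))
  nf <- n_frames(traj)
  window <- if (!is.null(config$last_frames)) {
    c(max(1L, nf - as.integer(config$last_frames) + 1L), nf)
  } else c(1L, nf)

  rdf <- compute_rdf(traj, bin_width = cfg(config, "bin_width", 0.1),
                     r_max = cfg(config, "r_max", NULL))
  pk <- tryCatch(first_peak(rdf), error = function(e) NULL)
  no_structure <- is.null(pk)
  coord <- NA_real_
  r_min <- NA_real_
  if (!no_structure) {
    # first minimum of g after the first peak (bounded search)
    after <- which(rdf$r > pk$r_peak & rdf$r <= pk$r_peak + 3)
    r_min <- rdf$r[after[which.min(rdf$g[after])]]
    coord <- coordination_number(rdf, r_min)
  }
  report <- stage(report, "rdf",
                  list(bin_width = rdf$bin_width,
                       no_structure = no_structure))

  intervals <- bond_intervals(traj, criteria, window = window)
  n_sulfur <- length(role_ids(traj$topology, "sulfur"))
  mp <- cfg(config, "min_persistence", 1L)
  we <- cfg(config, "weight_exponent", 0)
  s_ohs <- interaction_score(intervals, "OH-S", mp, we)
  s_sho <- interaction_score(intervals, "SH-O", mp, we)
  scores <- per_sulfur_summary(list(s_ohs, s_sho), n_sulfur)
  report <- stage(report, "hbond_score",
                  list(window = window, min_persistence = mp,
                       weight_exponent = we))

  report$rdf <- rdf
  report$no_structure <- no_structure
  report$first_peak <- pk
  report$first_minimum <- r_min
  report$coordination_number <- coord
  report$scores <- scores
  report$intervals <- intervals
  report$interval_stats <- data.frame(
    direction = c("OH-S", "SH-O"),
    n_intervals = c(sum(intervals$direction == "OH-S"),
                    sum(intervals$direction == "SH-O")),
    mean_length = c(mean(intervals$length[intervals$direction == "OH-S"]),
                    mean(intervals$length[intervals$direction == "SH-O"])))
  report$schedule <- schedule
  report$n_sulfur <- n_sulfur
  report
}
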
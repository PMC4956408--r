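default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "widefieldpool-run",
    verbosity = 1L,
    signal = "spiking",
    suites = c("orientation", "contrast", "position"),
    grid = list(pixel_size = 0.1, ny = 48, nx = 48),
    map = list(period = 0.7, bandwidth = 0.15),
    retinotopy = list(magnification = 1.5, center_deg = c(2.5, -2.5)),
    neuron = list(Wx = 2.0, Wtheta = 40, ftheta = 0.9, ns = 3.0),
    pooling = list(p50 = 0.5, sigma_x0 = 0.5, kappa_theta = 2),
    generator = list(noise_sd = 0.15, optical_blur_sd = 0.2, n_trials = 10),
    analysis = list(window_start_ms = 35, window_dur_ms = 200,
                    bp_low = 0.8, bp_high = 3.0, roi_side_mm = 1.6,
                    roi_side_pos_mm = 0.75, dprime_threshold = 3.0),
    fit = list(refine = TRUE)
  )
}

merge_strict <- function(defaults, user, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop(sprintf("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        stop(sprintf("config key `%s%s` must be a section", path, k), call. = FALSE)
      }
      defaults[[k]] <- merge_strict(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Loads (or builds from a list) the single configuration that drives a
#' seeded end-to-end run. Unknown keys are rejected by name; omitted keys
#' take the documented defaults. Required top-level keys: `seed`, `outdir`.
#'
#' @param x Path to a YAML config file, a named list of overrides, or
#'   `NULL` for pure defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = NULL) {
  user <- if (is.null(x)) {
    list()
  } else if (is.character(x)) {
    yaml::read_yaml(x)
  } else if (is.list(x)) {
    x
  } else {
    stop("`x` must be a path, a list, or NULL", call. = FALSE)
  }
  for (k in c("seed", "outdir")) {
    if (!is.null(x) && is.character(x) && is.null(user[[k]])) {
      stop(sprintf("config is missing required key `%s`", k), call. = FALSE)
    }
  }
  cfg <- merge_strict(default_pipeline_config(), user)
  bad <- setdiff(cfg$suites, c("orientation", "contrast", "position"))
  if (length(bad)) stop("unknown suite kind: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(cfg, ...) {
  if ((cfg$verbosity %||% 1) > 0) message(sprintf(...))
}

manifest_entry <- function(stage, inputs, outputs, params = list()) {
  list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       inputs = as.list(tools::md5sum(inputs)),
       outputs = as.list(tools::md5sum(outputs)),
       params = params)
}

write_manifest <- function(entries, outdir) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(
    list(package = "widefieldpool",
         version = as.character(utils::packageVersion("widefieldpool")),
         r_version = R.version.string, stages = entries),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

cfg_objects <- function(cfg) {
  grid <- cortical_grid(cfg$grid$pixel_size, cfg$grid$ny, cfg$grid$nx)
  list(
    grid = grid,
    map = make_orientation_map(grid, cfg$map$period, seed = cfg$seed,
                               bandwidth = cfg$map$bandwidth),
    retino = make_retinotopy(grid, cfg$retinotopy$magnification,
                             unlist(cfg$retinotopy$center_deg)),
    neuron = do.call(single_neuron_params, cfg$neuron),
    pooling = do.call(pooling_params, cfg$pooling),
    gen = generator_config(cfg$signal, noise_sd = cfg$generator$noise_sd,
                           optical_blur_sd = cfg$generator$optical_blur_sd,
                           seed = cfg$seed)
  )
}

#' Run the simulation stage
#'
#' Builds the synthetic cortex and one recording per configured suite,
#' writes them (plus the orientation map and the resolved config) to
#' `outdir`, and records a manifest with file digests.
#'
#' @param cfg A [pipeline_config()] (or anything it accepts).
#' @return Invisibly, the vector of recording paths.
#' @export
run_simulate <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  ob <- cfg_objects(cfg)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  save_recording(ob$map, file.path(cfg$outdir, "orientation_map.rds"))
  paths <- character()
  for (kind in cfg$suites) {
    log_msg(cfg, "simulate: %s suite (%s, seed %d)", kind, cfg$signal, cfg$seed)
    rec <- generate_experiment_suite(kind, cfg$signal, ob$map, ob$retino,
                                     ob$neuron, ob$pooling, ob$gen,
                                     n_trials = cfg$generator$n_trials,
                                     seeds = cfg$seed)[[1]]
    p <- file.path(cfg$outdir, sprintf("recording_%s.rds", kind))
    save_recording(rec, p)
    paths[kind] <- p
  }
  entries <- list(manifest_entry(
    "simulate", character(),
    c(file.path(cfg$outdir, c("config.yaml", "orientation_map.rds")), paths),
    params = list(seed = cfg$seed, signal = cfg$signal, suites = cfg$suites)))
  write_manifest(entries, cfg$outdir)
  invisible(paths)
}

#' Run the analysis stage
#'
#' Applies the standard pipeline to each simulated suite found in
#' `cfg$outdir`: blank subtraction, windowed or harmonic amplitudes,
#' d-prime ROI selection, maps, and tuning curves; writes curves as CSV and
#' maps as serialized objects.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of [tuning_curve()]s.
#' @export
run_analyze <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  an <- cfg$analysis
  curves <- list()
  outputs <- character()
  sig <- cfg$signal
  for (kind in cfg$suites) {
    p <- file.path(cfg$outdir, sprintf("recording_%s.rds", kind))
    if (!file.exists(p)) {
      stop(sprintf("missing recording `%s`; run run_simulate() first", p),
           call. = FALSE)
    }
    rec <- load_recording(p)
    log_msg(cfg, "analyze: %s suite (window %g+%g ms, bandpass %g-%g cyc/mm)",
            kind, an$window_start_ms, an$window_dur_ms, an$bp_low, an$bp_high)
    if (kind == "orientation") {
      scm <- single_condition_maps(rec, an$bp_low, an$bp_high)
      cmap <- composite_orientation_map(scm)
      roi <- if (sig == "potential") {
        resolve_roi(dprime_map(rec, "harmonic"), "dprime_threshold",
                    threshold = an$dprime_threshold)
      } else {
        resolve_roi(dprime_map(rec, "harmonic"), "max_dprime_square",
                    side_mm = an$roi_side_mm)
      }
      curves[[paste0("orientation.", sig)]] <-
        orientation_tuning_curve(scm, cmap, roi)
      save_recording(cmap, file.path(cfg$outdir, "composite_map.rds"))
      utils::write.csv(pairwise_map_correlation(scm),
                       file.path(cfg$outdir, "map_correlations.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, file.path(cfg$outdir, c("composite_map.rds",
                                                    "map_correlations.csv")))
    } else {
      wa <- window_amplitude(blank_subtract(rec), an$window_start_ms,
                             an$window_dur_ms)
      if (kind == "contrast") {
        roi <- resolve_roi(dprime_map(rec, "window", an$window_start_ms,
                                      an$window_dur_ms),
                           "max_dprime_square", side_mm = an$roi_side_mm)
        curves[[paste0("contrast.", sig)]] <- contrast_tuning_curve(wa, roi)
      } else {
        retino <- make_retinotopy(rec$grid, cfg$retinotopy$magnification,
                                  unlist(cfg$retinotopy$center_deg))
        roi <- resolve_roi(rec$grid, "retinotopic_square",
                           side_mm = an$roi_side_pos_mm,
                           center_mm = rev(grid_center_mm(rec$grid)))
        curves[[paste0("position.", sig)]] <-
          position_tuning_curve(wa, roi, retino)
      }
    }
  }
  curve_path <- file.path(cfg$outdir, "tuning_curves.csv")
  write_tuning_csv(curves, curve_path)
  entries <- list(manifest_entry("analyze",
                                 file.path(cfg$outdir,
                                           sprintf("recording_%s.rds", cfg$suites)),
                                 c(curve_path, outputs), params = an))
  write_manifest(entries, cfg$outdir)
  invisible(curves)
}

#' Run the full pipeline
#'
#' Simulate, analyze, fit the scatter parameters to the extracted curves,
#' and write a JSON summary. One seed determines every output.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `curves`, `fit`, and the summary path.
#' @export
run_full <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  run_simulate(cfg)
  curves <- run_analyze(cfg)
  ob <- cfg_objects(cfg)
  fit <- NULL
  if (any(vapply(curves, `[[`, "", "dimension") == "position") &&
      any(vapply(curves, `[[`, "", "dimension") == "orientation")) {
    log_msg(cfg, "fit: grid search over (sigma_x0, kappa_theta)")
    fit <- fit_scatter(curves, ob$neuron, ob$pooling,
                       fit_config(refine = cfg$fit$refine))
  }
  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(list(
    seed = cfg$seed, signal = cfg$signal,
    sigma_x0_true = cfg$pooling$sigma_x0,
    kappa_theta_true = cfg$pooling$kappa_theta,
    sigma_x0_hat = if (!is.null(fit)) fit$sigma_x0_hat,
    kappa_theta_hat = if (!is.null(fit)) fit$kappa_theta_hat,
    sse = if (!is.null(fit)) fit$sse
  ), summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(curves = curves, fit = fit, summary = summary_path))
}
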
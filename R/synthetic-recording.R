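#' Stimulus protocol for one condition
#'
#' Describes a flashed-stimulus condition: a full-field grating or a small
#' Gabor patch, flashed `n_cycles` times at `flash_rate` Hz with the given
#' on/off durations, imaged at `frame_rate` Hz for `trial_s` seconds.
#'
#' @param stimulus_type `"fullfield_grating"` or `"gabor"`.
#' @param contrast Stimulus contrast, %.
#' @param orientation Grating orientation, deg.
#' @param position_deg Visual-field position `c(x, y)` in deg (Gabor only).
#' @param flash_rate Flash rate, Hz.
#' @param on_ms,off_ms Flash on/off durations; must sum to `1000/flash_rate`.
#' @param n_cycles Number of flashes per trial.
#' @param frame_rate Imaging frame rate, Hz (20 for calcium, 100 for VSD by
#'   convention).
#' @param trial_s Trial duration, s.
#' @param n_trials Repeats of this condition.
#' @param include_blanks Whether matching blank trials are generated.
#' @param label Condition label; auto-generated if `NULL`.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(stimulus_type = c("fullfield_grating", "gabor"),
                              contrast = 99, orientation = 0,
                              position_deg = NULL,
                              flash_rate = 4, on_ms = 100, off_ms = 150,
                              n_cycles = 6, frame_rate = 20, trial_s = 1.5,
                              n_trials = 10, include_blanks = TRUE,
                              label = NULL) {
  stimulus_type <- match.arg(stimulus_type)
  if (abs(on_ms + off_ms - 1000 / flash_rate) > 1e-9) {
    stop("`on_ms + off_ms` must equal 1000/flash_rate", call. = FALSE)
  }
  if (contrast < 0 || contrast > 100) stop("`contrast` must be in [0, 100]", call. = FALSE)
  if (stimulus_type == "gabor" && is.null(position_deg)) {
    stop("a gabor protocol requires `position_deg`", call. = FALSE)
  }
  if (n_cycles / flash_rate > trial_s + 1e-9) {
    stop("flash train does not fit in the trial", call. = FALSE)
  }
  if (is.null(label)) {
    label <- switch(stimulus_type,
      fullfield_grating = sprintf("ori%03.0f_c%05.1f", orientation %% 180, contrast),
      gabor = sprintf("pos_%+05.2f_%+05.2f", position_deg[1], position_deg[2]))
  }
  structure(list(stimulus_type = stimulus_type, contrast = contrast,
                 orientation = orientation %% 180,
                 position_deg = position_deg, flash_rate = flash_rate,
                 on_ms = on_ms, off_ms = off_ms, n_cycles = n_cycles,
                 frame_rate = frame_rate, trial_s = trial_s,
                 n_trials = n_trials, include_blanks = include_blanks,
                 label = label),
            class = "stimulus_protocol")
}

# Timing defaults used in the experiments being emulated: orientation runs
# use fast flash trains (4 Hz calcium / 5 Hz VSD); contrast and position
# runs use 2 Hz (200 on / 300 off).
protocol_timing <- function(kind, signal) {
  if (kind == "orientation") {
    if (signal == "spiking") {
      list(flash_rate = 4, on_ms = 100, off_ms = 150, n_cycles = 6,
           frame_rate = 20, trial_s = 1.5)
    } else {
      list(flash_rate = 5, on_ms = 60, off_ms = 140, n_cycles = 5,
           frame_rate = 100, trial_s = 1)
    }
  } else {
    list(flash_rate = 2, on_ms = 200, off_ms = 300, n_cycles = 3,
         frame_rate = if (signal == "spiking") 20 else 100, trial_s = 1.5)
  }
}

#' Generator configuration
#'
#' Parameters of the synthetic-recording generator: which signal kind is
#' emulated (spiking-like, as for a calcium indicator, or potential-like, as
#' for a voltage-sensitive dye), the temporal kernel, the peak
#' fractional-fluorescence amplitude, the additive pixel noise, the optical
#' blur, and the seed.
#'
#' Defaults: the spiking-like kernel rises in ~50 ms and decays with a
#' 400 ms constant (slow indicator, builds up across 4 Hz flashes); the
#' potential-like kernel uses 15/60 ms (fast dye, returns near baseline
#' between 5 Hz flashes). Peak amplitudes are calibrated so the
#' spiking-like (GCaMP) signal is 5 times the potential-like (VSD) signal
#' (0.05 vs 0.01 dF/F).
#'
#' @param signal `"spiking"` or `"potential"`.
#' @param kernel_rise_ms,kernel_decay_ms Temporal-kernel time constants, ms.
#' @param peak_dff Peak dF/F at full contrast for a preferred stimulus.
#' @param noise_sd Additive per-pixel per-frame Gaussian noise SD, as a
#'   fraction of `peak_dff`. The default 0.15 is calibrated so that the
#'   best pixel's single-trial response d-prime is ~3.5 (trial-averaged
#'   d-prime ~10 over 10 repeats), the signal quality reported for
#'   high-contrast gratings in widefield recordings.
#' @param optical_blur_sd Gaussian optical point-spread SD, mm (default
#'   0.2 mm, the widefield pooling scale).
#' @param seed Integer seed recorded in every output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(signal = c("spiking", "potential"),
                             kernel_rise_ms = NULL, kernel_decay_ms = NULL,
                             peak_dff = NULL, noise_sd = 0.15,
                             optical_blur_sd = 0.2, seed = 1) {
  signal <- match.arg(signal)
  kernel_rise_ms <- kernel_rise_ms %||% if (signal == "spiking") 50 else 15
  kernel_decay_ms <- kernel_decay_ms %||% if (signal == "spiking") 400 else 60
  peak_dff <- peak_dff %||% if (signal == "spiking") 0.05 else 0.01
  if (kernel_rise_ms <= 0 || kernel_decay_ms <= 0) {
    stop("kernel time constants must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (optical_blur_sd < 0) stop("`optical_blur_sd` must be >= 0", call. = FALSE)
  structure(list(signal = signal, kernel_rise_ms = kernel_rise_ms,
                 kernel_decay_ms = kernel_decay_ms, peak_dff = peak_dff,
                 noise_sd = noise_sd, optical_blur_sd = optical_blur_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Indicator temporal kernel
#'
#' Difference-of-exponentials impulse response,
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, sampled at the frame rate and
#' normalized to peak 1. Requires `decay > rise` (otherwise the kernel is
#' non-physical).
#'
#' @param rise_ms,decay_ms Time constants, ms.
#' @param frame_rate Sampling rate, Hz.
#' @param duration_s Kernel support; defaults to 8 decay constants.
#' @return Numeric vector (unit peak) with attribute `frame_rate`.
#' @export
#' @examples
#' k <- temporal_kernel(50, 400, 20)
temporal_kernel <- function(rise_ms, decay_ms, frame_rate, duration_s = NULL) {
  if (decay_ms <= rise_ms) {
    stop("`decay_ms` must exceed `rise_ms` (non-physical kernel)", call. = FALSE)
  }
  duration_s <- duration_s %||% (8 * decay_ms / 1000)
  t <- seq(0, duration_s, by = 1 / frame_rate)
  k <- exp(-t * 1000 / decay_ms) - exp(-t * 1000 / rise_ms)
  k <- k / max(k)
  attr(k, "frame_rate") <- frame_rate
  k
}

#' Per-frame flash-train drive
#'
#' Indicator vector (one entry per frame) that is 1 while the stimulus is
#' on: flash `j` (0-based) is on during
#' `[j/flash_rate, j/flash_rate + on_ms/1000)`. A frame counts as "on" if
#' its midpoint falls in an on-window.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Numeric 0/1 vector of length `round(trial_s * frame_rate)`.
#' @export
flash_drive <- function(protocol) {
  nf <- round(protocol$trial_s * protocol$frame_rate)
  mid <- (seq_len(nf) - 0.5) / protocol$frame_rate
  on <- rep(0, nf)
  for (j in seq_len(protocol$n_cycles) - 1) {
    t0 <- j / protocol$flash_rate
    on[mid >= t0 & mid < t0 + protocol$on_ms / 1000] <- 1
  }
  on
}

# Unit-peak temporal response profile of one trial: flash train convolved
# with the indicator kernel, truncated to the trial and normalized so the
# calibration peak_dff is the trial's peak dF/F.
temporal_profile <- function(protocol, config) {
  nf <- round(protocol$trial_s * protocol$frame_rate)
  drive <- flash_drive(protocol)
  k <- temporal_kernel(config$kernel_rise_ms, config$kernel_decay_ms,
                       protocol$frame_rate)
  full <- stats::convolve(c(drive, numeric(length(k))), rev(k), type = "open")
  prof <- full[seq_len(nf)]
  prof / max(prof)
}

# Pooled model curves sampled finely for per-pixel interpolation.
pooled_lookup <- function(dimension, signal, neuron, pooling, axis) {
  crv <- pooled_tuning_curve(dimension, signal, neuron, pooling, axis)
  function(x) {
    x <- pmin(pmax(x, min(axis)), max(axis))
    stats::approx(crv$stimulus, crv$response, xout = x)$y
  }
}

#' Per-pixel peak response amplitude for one stimulus condition
#'
#' Evaluates the pooling model at every pixel: the pooled contrast response
#' at the stimulus contrast, times the pooled position response at the
#' cortical distance between the pixel and the stimulus' retinotopic center
#' (full-field gratings bypass this factor), times the pooled orientation
#' response at the angular distance between the stimulus orientation and
#' the pixel's preferred orientation, times the pixel's selectivity (a
#' per-pixel gain so weakly selective pixels near pinwheels contribute
#' weakly).
#'
#' @param protocol A [stimulus_protocol()].
#' @param ori_map An [make_orientation_map()] result.
#' @param retinotopy A [make_retinotopy()] result (required for Gabor
#'   protocols).
#' @param neuron,pooling Model parameter sets.
#' @param signal `"spiking"` or `"potential"`.
#' @return ny x nx matrix of dimensionless amplitudes.
#' @export
pixel_amplitude_field <- function(protocol, ori_map, retinotopy = NULL,
                                  neuron = single_neuron_params(),
                                  pooling = pooling_params(),
                                  signal = c("spiking", "potential")) {
  signal <- match.arg(signal)
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(ori_map, "orientation_map"))
  grid <- ori_map$grid
  if (protocol$contrast == 0) {
    return(matrix(0, grid$ny, grid$nx))
  }
  pc <- pooled_lookup("contrast", signal, neuron, pooling, seq(0, 100, 0.5))
  po <- pooled_lookup("orientation", signal, neuron, pooling, seq(0, 90, 0.5))
  dtheta <- circ_dist_180(protocol$orientation, ori_map$preferred)
  amp <- ori_map$selectivity * pc(protocol$contrast) * po(dtheta)
  if (protocol$stimulus_type == "gabor") {
    if (is.null(retinotopy)) {
      stop("a gabor protocol requires a retinotopy map", call. = FALSE)
    }
    ctr <- visual_to_cortical(retinotopy, protocol$position_deg)  # (x, y) mm
    coords <- pixel_coords(grid)
    dist <- sqrt(outer((coords$y - ctr[2])^2, (coords$x - ctr[1])^2, `+`))
    dmax <- max(8, ceiling(max(dist)))
    px <- pooled_lookup("position", signal, neuron, pooling, seq(0, dmax, 0.05))
    amp <- amp * px(dist)
  }
  amp
}

gaussian_blur <- function(m, sd_px) {
  if (sd_px <= 0) return(m)
  EBImage::gblur(m, sigma = sd_px)
}

#' Generate a synthetic widefield recording for one condition
#'
#' Builds trial movies as
#' `blur(amplitude field) * (flash train (*) kernel) * peak_dff + noise`,
#' with the temporal profile normalized to unit peak so `peak_dff` is the
#' calibration amplitude. Blank trials contain noise only. Fully
#' deterministic given `config$seed`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param ori_map,retinotopy Synthetic cortex (see
#'   [make_orientation_map()], [make_retinotopy()]).
#' @param neuron,pooling Model parameters.
#' @param config A [generator_config()].
#' @return A `widefield_recording`: list with `data`
#'   (trial x frame x y x x array of dF/F), `frame_rate`, `condition`,
#'   `blank`, `grid`, `protocols`, `signal`, and `provenance`.
#' @export
generate_recording <- function(protocol, ori_map, retinotopy = NULL,
                               neuron = single_neuron_params(),
                               pooling = pooling_params(),
                               config = generator_config()) {
  assemble_recording(list(protocol), ori_map, retinotopy, neuron, pooling,
                     config, seed = config$seed)
}

# Shared assembly for single conditions and interleaved suites.
assemble_recording <- function(protocols, ori_map, retinotopy, neuron,
                               pooling, config, seed, kind = NULL) {
  grid <- ori_map$grid
  fr <- protocols[[1]]$frame_rate
  nf <- round(protocols[[1]]$trial_s * fr)
  for (p in protocols) {
    if (p$frame_rate != fr || round(p$trial_s * p$frame_rate) != nf) {
      stop("all protocols in a recording must share frame count and rate",
           call. = FALSE)
    }
  }
  names(protocols) <- vapply(protocols, `[[`, "", "label")
  movies <- lapply(protocols, function(p) {
    amp <- pixel_amplitude_field(p, ori_map, retinotopy, neuron, pooling,
                                 config$signal)
    amp <- gaussian_blur(amp, config$optical_blur_sd / grid$pixel_size)
    prof <- temporal_profile(p, config)
    array(outer(prof, amp * config$peak_dff), dim = c(nf, grid$ny, grid$nx))
  })
  n_rep <- vapply(protocols, `[[`, 0, "n_trials")
  cond <- rep(names(protocols), n_rep)
  if (any(vapply(protocols, `[[`, TRUE, "include_blanks"))) {
    cond <- c(cond, rep("blank", max(n_rep)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cond <- sample(cond)  # randomly interleaved trial order
  nt <- length(cond)
  data <- array(0, dim = c(nt, nf, grid$ny, grid$nx))
  for (t in seq_len(nt)) {
    if (cond[t] != "blank") data[t, , , ] <- movies[[cond[t]]]
  }
  if (config$noise_sd > 0) {
    data <- data + stats::rnorm(length(data),
                                sd = config$noise_sd * config$peak_dff)
  }
  structure(list(
    data = data, frame_rate = fr, condition = cond,
    blank = cond == "blank", grid = grid, protocols = protocols,
    signal = config$signal,
    provenance = list(config = unclass(config), seed = seed, kind = kind,
                      map_seed = ori_map$seed, map_period = ori_map$period,
                      neuron = unclass(neuron), pooling = unclass(pooling),
                      ground_truth = ori_map)
  ), class = "widefield_recording")
}

#' @export
print.widefield_recording <- function(x, ...) {
  cat(sprintf("Widefield recording (%s-like): %d trials x %d frames x %d x %d px @ %g Hz\n",
              x$signal, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              dim(x$data)[4], x$frame_rate))
  cat(sprintf("  conditions: %s\n",
              paste(utils::head(unique(x$condition), 8), collapse = ", ")))
  invisible(x)
}

#' Generate a full tuning experiment
#'
#' Builds the interleaved multi-condition recording for one tuning
#' dimension: a contrast ladder of full-field gratings, 12 grating
#' orientations in 15-degree steps, or a line of Gabor positions, each with
#' `n_trials` repeats plus blank trials, in a random interleaved order.
#' Orientation runs use 4 Hz (spiking/calcium) or 5 Hz (potential/VSD)
#' flash trains; contrast and position runs use 2 Hz.
#'
#' @param kind `"contrast"`, `"orientation"`, or `"position"`.
#' @param signal `"spiking"` or `"potential"`.
#' @param ori_map Synthetic orientation map; generated from `seeds[1]` if
#'   `NULL`.
#' @param retinotopy Retinotopy; default [make_retinotopy()] on the map's
#'   grid.
#' @param neuron,pooling Model parameters.
#' @param config A [generator_config()]; its `signal` must match.
#' @param n_trials Repeats per condition (>= 10 in the emulated
#'   experiments; smaller values are useful for quick noise-free runs).
#' @param contrasts Contrast ladder, %.
#' @param orientations Grating orientations, deg.
#' @param position_offsets_deg Gabor offsets (deg) along the radial
#'   (fovea-to-periphery) axis through the retinotopic center.
#' @param stim_orientation Grating/Gabor orientation used in contrast and
#'   position runs.
#' @param seeds Integer vector; one recording is generated per seed.
#' @return A list of `widefield_recording` objects, one per seed.
#' @export
generate_experiment_suite <- function(kind = c("contrast", "orientation", "position"),
                                      signal = c("spiking", "potential"),
                                      ori_map = NULL, retinotopy = NULL,
                                      neuron = single_neuron_params(),
                                      pooling = pooling_params(),
                                      config = NULL, n_trials = 10,
                                      contrasts = c(2.5, 5, 12.5, 25, 50, 99),
                                      orientations = seq(0, 165, by = 15),
                                      position_offsets_deg = seq(-2, 2, by = 0.5),
                                      stim_orientation = 0, seeds = 1) {
  kind <- match.arg(kind)
  signal <- match.arg(signal)
  config <- config %||% generator_config(signal)
  if (config$signal != signal) {
    stop("`config$signal` must match `signal`", call. = FALSE)
  }
  if (is.null(ori_map)) {
    ori_map <- make_orientation_map(cortical_grid(pixel_size = 0.1, ny = 48, nx = 48),
                                    seed = seeds[1])
  }
  retinotopy <- retinotopy %||% make_retinotopy(ori_map$grid)
  tm <- protocol_timing(kind, signal)
  mk <- function(...) do.call(stimulus_protocol, c(list(...), tm,
                                                   list(n_trials = n_trials)))
  protocols <- switch(kind,
    contrast = lapply(contrasts, function(cc) {
      mk(stimulus_type = "fullfield_grating", contrast = cc,
         orientation = stim_orientation, label = sprintf("c%05.1f", cc))
    }),
    orientation = lapply(orientations, function(oo) {
      mk(stimulus_type = "fullfield_grating", contrast = 99, orientation = oo,
         label = sprintf("ori%03d", as.integer(oo)))
    }),
    position = {
      u <- retinotopy$center_deg / sqrt(sum(retinotopy$center_deg^2))
      lapply(position_offsets_deg, function(d) {
        mk(stimulus_type = "gabor", contrast = 99,
           orientation = stim_orientation,
           position_deg = retinotopy$center_deg + d * u,
           label = sprintf("pos%+05.2f", d))
      })
    })
  if (length(protocols) < 2) stop("a suite needs at least 2 conditions", call. = FALSE)
  lapply(seeds, function(s) {
    rec <- assemble_recording(protocols, ori_map, retinotopy, neuron, pooling,
                              config, seed = s, kind = kind)
    rec$provenance$retinotopy <- list(magnification = retinotopy$magnification,
                                      center_deg = retinotopy$center_deg)
    if (kind == "position") {
      rec$provenance$position_offsets_deg <- stats::setNames(
        position_offsets_deg, vapply(protocols, `[[`, "", "label"))
    }
    rec
  })
}

#' Persist recordings and maps
#'
#' Recordings, maps, and other generator outputs are stored with R's native
#' serialization, which preserves the full object including provenance.
#'
#' @param object Any package object (recording, map, fit result, ...).
#' @param path File path (conventionally `.rds`).
#' @return `save_recording()` returns `path` invisibly; `load_recording()`
#'   the restored object.
#' @export
save_recording <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  readRDS(path)
}
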
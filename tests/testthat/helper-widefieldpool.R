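# Shared fixtures, all generated in code.

test_cortex <- function(seed = 2, ny = 48, nx = 48, pixel_size = 0.1) {
  grid <- cortical_grid(pixel_size = pixel_size, ny = ny, nx = nx)
  list(grid = grid,
       map = make_orientation_map(grid, seed = seed),
       retino = make_retinotopy(grid))
}

noisefree_config <- function(signal, seed = 1) {
  generator_config(signal, noise_sd = 0, optical_blur_sd = 0, seed = seed)
}

grid_center <- function(grid) {
  c(grid$nx, grid$ny) * grid$pixel_size / 2
}

center_square_roi <- function(grid, side_mm = 1.6) {
  resolve_roi(grid, "retinotopic_square", side_mm = side_mm,
              center_mm = grid_center(grid))
}

# Bare recording fixture with hand-set data, for analysis unit tests.
shell_recording <- function(data, frame_rate, condition, protocol,
                            pixel_size = 0.1) {
  protocols <- stats::setNames(
    rep(list(protocol), length(unique(condition[condition != "blank"]))),
    unique(condition[condition != "blank"]))
  structure(list(
    data = data, frame_rate = frame_rate, condition = condition,
    blank = condition == "blank",
    grid = cortical_grid(pixel_size = pixel_size, ny = dim(data)[3],
                         nx = dim(data)[4]),
    protocols = protocols, signal = "spiking", provenance = list()
  ), class = "widefield_recording")
}

one_flash_protocol <- function(frame_rate = 20, trial_s = 1.5, label = "stim") {
  stimulus_protocol("fullfield_grating", flash_rate = 4, on_ms = 100,
                    off_ms = 150, n_cycles = 1, frame_rate = frame_rate,
                    trial_s = trial_s, n_trials = 1, label = label)
}

# Independent Monte-Carlo pooling oracle: samples neurons from the scatter
# distribution and averages closed-form single-neuron responses. Formulas
# are written out here on purpose, independent of the package's pooling
# path.
mc_pool_oracle <- function(dimension, signal, neuron, pooling, axis,
                           n = 1e5, seed = 1) {
  set.seed(seed)
  ns_exp <- if (signal == "spiking") neuron$ns else 1
  Wxh <- neuron$Wx * sqrt(neuron$ns)
  Wth <- neuron$Wtheta * sqrt(neuron$ns)
  fth <- 1 - (1 - neuron$ftheta)^(1 / neuron$ns)
  resp_fun <- switch(dimension,
    contrast = {
      w <- pooling$c50_grid^(-pooling$p50)
      smp <- sample(pooling$c50_grid, n, replace = TRUE, prob = w)
      function(v) (v / sqrt(v^2 + smp^2))^ns_exp
    },
    position = {
      w <- exp(-0.5 * (pooling$x0_grid / pooling$sigma_x0)^2)
      smp <- sample(pooling$x0_grid, n, replace = TRUE, prob = w)
      function(v) exp(-2 * log(4) * ((v - smp) / Wxh)^2)^ns_exp
    },
    orientation = {
      w <- exp(pooling$kappa_theta * cos(2 * pooling$theta0_grid * pi / 180))
      smp <- sample(pooling$theta0_grid, n, replace = TRUE, prob = w)
      function(v) {
        d <- abs(v - smp) %% 180
        d <- pmin(d, 180 - d)
        (fth * exp(-2 * log(4) * (d / Wth)^2) + (1 - fth))^ns_exp
      }
    })
  m <- vapply(axis, function(v) mean(resp_fun(v)), 0)
  se <- vapply(axis, function(v) stats::sd(resp_fun(v)) / sqrt(n), 0)
  list(mean = m, se = se)
}

rms <- function(a, b) sqrt(mean((a - b)^2))
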
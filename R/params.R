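#' Single-neuron tuning parameters (spiking-referenced)
#'
#' Container for the mean tuning properties of single V1 neurons, referenced
#' to spiking activity as they are usually reported in the single-unit
#' literature. Defaults are the literature means used throughout the package:
#' receptive-field width 2 mm (of cortex), orientation bandwidth 40 deg,
#' tuned fraction 0.9, spiking-nonlinearity exponent 3.
#'
#' @param Wx Receptive-field full width at half maximum of the spiking
#'   response, in mm of cortex. Must be positive.
#' @param Wtheta Orientation-tuning full width at half maximum of the spiking
#'   response, in degrees; in (0, 180).
#' @param ftheta Fraction of the spiking response that is orientation tuned,
#'   in \[0, 1\].
#' @param ns Spiking-nonlinearity exponent (membrane potential to firing
#'   rate), >= 1.
#' @return An object of class `single_neuron_params`.
#' @seealso [derive_potential_params()] for the membrane-potential
#'   (subthreshold) equivalents.
#' @export
#' @examples
#' single_neuron_params()
single_neuron_params <- function(Wx = 2.0, Wtheta = 40, ftheta = 0.9, ns = 3.0) {
  stopifnot_scalar(Wx, "Wx")
  stopifnot_scalar(Wtheta, "Wtheta")
  stopifnot_scalar(ftheta, "ftheta")
  stopifnot_scalar(ns, "ns")
  if (Wx <= 0) stop("`Wx` must be > 0", call. = FALSE)
  if (Wtheta <= 0 || Wtheta >= 180) stop("`Wtheta` must be in (0, 180)", call. = FALSE)
  if (ftheta < 0 || ftheta > 1) stop("`ftheta` must be in [0, 1]", call. = FALSE)
  if (ns < 1) stop("`ns` must be >= 1", call. = FALSE)
  structure(list(Wx = Wx, Wtheta = Wtheta, ftheta = ftheta, ns = ns),
            class = "single_neuron_params")
}

#' @export
print.single_neuron_params <- function(x, ...) {
  cat("Single-neuron parameters (spiking-referenced)\n")
  cat(sprintf("  Wx     = %.4g mm (RF FWHM)\n", x$Wx))
  cat(sprintf("  Wtheta = %.4g deg (orientation FWHM)\n", x$Wtheta))
  cat(sprintf("  ftheta = %.4g (tuned fraction)\n", x$ftheta))
  cat(sprintf("  ns     = %.4g (spiking exponent)\n", x$ns))
  invisible(x)
}

#' Convert spiking-referenced parameters to membrane-potential equivalents
#'
#' Tuning parameters are usually reported for spikes. The membrane-potential
#' ("hatted") equivalents are obtained by undoing the power-law spiking
#' nonlinearity: a Gaussian tuning curve narrows by `sqrt(ns)` when raised to
#' the power `ns`, and the untuned floor `1 - ftheta` is the `ns`-th power of
#' the potential floor. Hence
#' `Wx_hat = Wx * sqrt(ns)`, `Wtheta_hat = Wtheta * sqrt(ns)`,
#' `ftheta_hat = 1 - (1 - ftheta)^(1/ns)`.
#'
#' @param p A [single_neuron_params()] object.
#' @return An object of class `potential_params` with fields `Wx_hat` (mm),
#'   `Wtheta_hat` (deg), `ftheta_hat`, and the originating `ns`.
#' @export
#' @examples
#' derive_potential_params(single_neuron_params())
derive_potential_params <- function(p) {
  stopifnot(inherits(p, "single_neuron_params"))
  structure(list(
    Wx_hat = p$Wx * sqrt(p$ns),
    Wtheta_hat = p$Wtheta * sqrt(p$ns),
    ftheta_hat = 1 - (1 - p$ftheta)^(1 / p$ns),
    ns = p$ns
  ), class = "potential_params")
}

#' @export
print.potential_params <- function(x, ...) {
  cat("Membrane-potential (subthreshold) parameters\n")
  cat(sprintf("  Wx_hat     = %.4f mm\n", x$Wx_hat))
  cat(sprintf("  Wtheta_hat = %.4f deg\n", x$Wtheta_hat))
  cat(sprintf("  ftheta_hat = %.4f\n", x$ftheta_hat))
  invisible(x)
}

#' Population pooling parameters
#'
#' Parameters of the three scatter distributions that describe which neurons
#' contribute to the signal at one imaged location: a power-law distribution
#' of contrast semi-saturation values `C50`, a Gaussian scatter of
#' receptive-field centers, and a (180-degree periodic) von Mises scatter of
#' preferred orientations. Each distribution comes with a discretization grid
#' over which pooled responses are summed.
#'
#' The default `c50_grid` (1-82% contrast, 1% steps) is calibrated so that
#' the `p50 = 0.5` power-law weights have mean C50 of 30% contrast, the value
#' reported for V1.
#'
#' @param p50 Power-law decay exponent of the C50 weight distribution.
#' @param sigma_x0 SD of receptive-field-center scatter, mm; >= 0.
#' @param kappa_theta Concentration of preferred-orientation scatter
#'   (dimensionless, >= 0; 0 = uniform).
#' @param c50_grid Strictly increasing, strictly positive support for C50
#'   (% contrast).
#' @param x0_grid Strictly increasing support for RF-center offsets (mm).
#' @param theta0_grid Strictly increasing support for preferred-orientation
#'   offsets (deg), covering one 180-degree cycle.
#' @return An object of class `pooling_params`.
#' @export
#' @examples
#' pooling_params(sigma_x0 = 0.5, kappa_theta = 2)
pooling_params <- function(p50 = 0.5, sigma_x0 = 0.5, kappa_theta = 2,
                           c50_grid = 1:82,
                           x0_grid = seq(-6, 6, by = 0.05),
                           theta0_grid = seq(-90, 89, by = 1)) {
  stopifnot_scalar(p50, "p50")
  stopifnot_scalar(sigma_x0, "sigma_x0")
  stopifnot_scalar(kappa_theta, "kappa_theta")
  if (sigma_x0 < 0) stop("`sigma_x0` must be >= 0", call. = FALSE)
  if (kappa_theta < 0) stop("`kappa_theta` must be >= 0", call. = FALSE)
  check_grid <- function(g, name, positive = FALSE) {
    if (length(g) < 1L || !all(is.finite(g))) {
      stop(sprintf("`%s` must be nonempty and finite", name), call. = FALSE)
    }
    if (length(g) > 1L && any(diff(g) <= 0)) {
      stop(sprintf("`%s` must be strictly increasing", name), call. = FALSE)
    }
    if (positive && any(g <= 0)) {
      stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
    }
  }
  check_grid(c50_grid, "c50_grid", positive = TRUE)
  check_grid(x0_grid, "x0_grid")
  check_grid(theta0_grid, "theta0_grid")
  structure(list(p50 = p50, sigma_x0 = sigma_x0, kappa_theta = kappa_theta,
                 c50_grid = as.numeric(c50_grid),
                 x0_grid = as.numeric(x0_grid),
                 theta0_grid = as.numeric(theta0_grid)),
            class = "pooling_params")
}

#' @export
print.pooling_params <- function(x, ...) {
  cat("Population pooling parameters\n")
  cat(sprintf("  p50         = %.4g (C50 power-law exponent)\n", x$p50))
  cat(sprintf("  sigma_x0    = %.4g mm (RF-center scatter SD)\n", x$sigma_x0))
  cat(sprintf("  kappa_theta = %.4g (orientation-scatter concentration)\n",
              x$kappa_theta))
  cat(sprintf("  grids: C50 %d pts [%g, %g]%%, x0 %d pts, theta0 %d pts\n",
              length(x$c50_grid), min(x$c50_grid), max(x$c50_grid),
              length(x$x0_grid), length(x$theta0_grid)))
  invisible(x)
}

#' Write or read model parameters as a flat key-value config file
#'
#' Round-trips a [single_neuron_params()] / [pooling_params()] pair through a
#' human-readable YAML file with flat keys named after the model symbols
#' (`Wx`, `Wtheta`, `ftheta`, `ns`, `p50`, `sigma_x0`, `kappa_theta`, plus
#' the three grids).
#'
#' @param neuron A [single_neuron_params()] object.
#' @param pooling A [pooling_params()] object.
#' @param path File path to write to / read from.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns `list(neuron =, pooling =)`.
#' @export
write_model_config <- function(neuron, pooling, path) {
  stopifnot(inherits(neuron, "single_neuron_params"),
            inherits(pooling, "pooling_params"))
  yaml::write_yaml(c(unclass(neuron), unclass(pooling)), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  v <- yaml::read_yaml(path)
  needed <- c("Wx", "Wtheta", "ftheta", "ns", "p50", "sigma_x0",
              "kappa_theta", "c50_grid", "x0_grid", "theta0_grid")
  missing <- setdiff(needed, names(v))
  if (length(missing)) {
    stop("model config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(
    neuron = single_neuron_params(v$Wx, v$Wtheta, v$ftheta, v$ns),
    pooling = pooling_params(v$p50, v$sigma_x0, v$kappa_theta,
                             v$c50_grid, v$x0_grid, v$theta0_grid)
  )
}
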
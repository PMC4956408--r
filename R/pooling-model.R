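#' Single-neuron membrane-potential response to contrast
#'
#' Contrast-response function with gain control:
#' `L = c / sqrt(c^2 + C50^2)`. Monotone increasing in contrast, saturating
#' at 1; equals `1/sqrt(2)` at `c = C50` (the semi-saturation contrast).
#'
#' @param c Stimulus contrast, % (>= 0). Vectorized.
#' @param C50 Contrast semi-saturation constant, % (> 0).
#' @return Response in \[0, 1).
#' @export
#' @examples
#' potential_contrast_response(30, 30) # 1/sqrt(2)
potential_contrast_response <- function(c, C50) {
  if (any(!is.finite(c)) || any(c < 0)) stop("`c` must be >= 0", call. = FALSE)
  if (any(!is.finite(C50)) || any(C50 <= 0)) stop("`C50` must be > 0", call. = FALSE)
  c / sqrt(c^2 + C50^2)
}

#' Single-neuron membrane-potential response to stimulus position
#'
#' Gaussian spatial receptive field expressed in cortical coordinates,
#' parameterized by its full width at half maximum:
#' `L = exp(-2 log(4) ((x - x0) / Wx_hat)^2)`.
#'
#' @param x Stimulus position on the cortex, mm. Vectorized.
#' @param x0 Receptive-field center, mm.
#' @param Wx_hat Membrane-potential RF full width at half maximum, mm (> 0).
#' @return Response in (0, 1\].
#' @export
potential_position_response <- function(x, x0, Wx_hat) {
  if (any(!is.finite(Wx_hat)) || any(Wx_hat <= 0)) {
    stop("`Wx_hat` must be > 0", call. = FALSE)
  }
  gauss_fwhm(x - x0, Wx_hat)
}

#' Single-neuron membrane-potential response to orientation
#'
#' Circular-Gaussian orientation tuning riding on an untuned pedestal:
#' `L = ftheta_hat * exp(-2 log(4) (dtheta / Wtheta_hat)^2) + (1 - ftheta_hat)`
#' where `dtheta` is the minimal circular distance between `theta` and
#' `theta0` on the 180-degree orientation circle.
#'
#' @param theta Stimulus orientation, deg. Vectorized.
#' @param theta0 Preferred orientation, deg.
#' @param Wtheta_hat Membrane-potential orientation FWHM, deg (> 0).
#' @param ftheta_hat Membrane-potential tuned fraction, in \[0, 1\].
#' @return Response in (0, 1\].
#' @export
potential_orientation_response <- function(theta, theta0, Wtheta_hat, ftheta_hat) {
  if (any(!is.finite(Wtheta_hat)) || any(Wtheta_hat <= 0)) {
    stop("`Wtheta_hat` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(ftheta_hat)) || any(ftheta_hat < 0) || any(ftheta_hat > 1)) {
    stop("`ftheta_hat` must be in [0, 1]", call. = FALSE)
  }
  d <- circ_dist_180(theta, theta0)
  ftheta_hat * gauss_fwhm(d, Wtheta_hat) + (1 - ftheta_hat)
}

#' Spiking response from a normalized membrane-potential response
#'
#' Power-law spiking nonlinearity: `R = L^ns`.
#'
#' @param L Normalized membrane-potential response in \[0, 1\]. Vectorized.
#' @param ns Spiking exponent, >= 1.
#' @return Response in \[0, 1\].
#' @export
spiking_from_potential <- function(L, ns) {
  if (any(!is.finite(L)) || any(L < 0)) stop("`L` must be >= 0", call. = FALSE)
  if (any(!is.finite(ns)) || any(ns < 1)) stop("`ns` must be >= 1", call. = FALSE)
  L^ns
}

new_weight_vector <- function(support, weights) {
  s <- sum(weights)
  if (!is.finite(s) || s <= 0) stop("weights must have positive sum", call. = FALSE)
  structure(list(support = support, weights = weights / s),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Weight vector over %d support points [%g, %g]\n",
              length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' Pooling weights over contrast semi-saturation values
#'
#' Power-function decay `w(C50) ~ C50^(-p50)`, normalized to sum to 1 over
#' the grid. With the default grid and `p50 = 0.5`, the weighted mean C50 is
#' 30% contrast.
#'
#' @param p50 Decay exponent (0 gives uniform weights).
#' @param c50_grid Strictly positive support, % contrast.
#' @return A `weight_vector`.
#' @export
contrast_weights <- function(p50 = 0.5, c50_grid = 1:82) {
  if (length(c50_grid) < 1L || any(c50_grid <= 0)) {
    stop("`c50_grid` must be strictly positive", call. = FALSE)
  }
  new_weight_vector(as.numeric(c50_grid), as.numeric(c50_grid)^(-p50))
}

#' Pooling weights over receptive-field-center scatter
#'
#' Gaussian scatter of RF centers around the imaged location (offset 0):
#' `w(x0) ~ exp(-x0^2 / (2 sigma_x0^2))`. `sigma_x0 = 0` degenerates to a
#' point mass at the grid value nearest 0.
#'
#' @param sigma_x0 Scatter SD, mm (>= 0).
#' @param x0_grid Support of RF-center offsets, mm.
#' @return A `weight_vector`.
#' @export
position_weights <- function(sigma_x0 = 0.5, x0_grid = seq(-6, 6, by = 0.05)) {
  if (length(x0_grid) < 1L) stop("`x0_grid` must be nonempty", call. = FALSE)
  if (sigma_x0 < 0) stop("`sigma_x0` must be >= 0", call. = FALSE)
  if (sigma_x0 == 0) {
    w <- numeric(length(x0_grid))
    w[which.min(abs(x0_grid))] <- 1
  } else {
    w <- exp(-0.5 * (x0_grid / sigma_x0)^2)
  }
  new_weight_vector(as.numeric(x0_grid), w)
}

#' Pooling weights over preferred-orientation scatter
#'
#' Von Mises scatter of preferred orientations around the imaged location's
#' preference (offset 0), made 180-degree periodic by doubling the angle:
#' `w(theta0) ~ exp(kappa_theta * cos(2 * theta0 * pi / 180))`.
#' `kappa_theta = 0` gives uniform weights.
#'
#' @param kappa_theta Concentration (>= 0).
#' @param theta0_grid Support of preferred-orientation offsets, deg.
#' @return A `weight_vector`.
#' @export
orientation_weights <- function(kappa_theta = 2, theta0_grid = seq(-90, 89, by = 1)) {
  if (length(theta0_grid) < 1L) stop("`theta0_grid` must be nonempty", call. = FALSE)
  if (kappa_theta < 0) stop("`kappa_theta` must be >= 0", call. = FALSE)
  w <- exp(kappa_theta * cos(2 * theta0_grid * pi / 180))
  new_weight_vector(as.numeric(theta0_grid), w)
}

#' Construct a tuning curve
#'
#' Light container for a response as a function of one stimulus dimension
#' (contrast in %, cortical position in mm, or orientation difference in
#' deg).
#'
#' @param dimension One of `"contrast"`, `"position"`, `"orientation"`.
#' @param stimulus Strictly increasing stimulus axis.
#' @param response Responses, same length as `stimulus`.
#' @param dispersion Optional per-point SEM.
#' @param n Optional per-point sample counts.
#' @param signal Optional signal kind label (`"potential"` or `"spiking"`).
#' @param normalized Logical; if `TRUE`, `max(response)` must be 1.
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(dimension, stimulus, response, dispersion = NULL,
                         n = NULL, signal = NULL, normalized = FALSE) {
  dimension <- match.arg(dimension, c("contrast", "position", "orientation"))
  stimulus <- as.numeric(stimulus)
  response <- as.numeric(response)
  if (length(stimulus) != length(response)) {
    stop("`stimulus` and `response` must have the same length", call. = FALSE)
  }
  if (length(stimulus) > 1L && any(diff(stimulus) <= 0)) {
    stop("`stimulus` must be strictly increasing", call. = FALSE)
  }
  if (normalized && abs(max(response) - 1) > 1e-12) {
    stop("normalized curve must have max(response) == 1", call. = FALSE)
  }
  structure(list(dimension = dimension, stimulus = stimulus,
                 response = response, dispersion = dispersion, n = n,
                 signal = signal, normalized = normalized),
            class = "tuning_curve")
}

#' Peak-normalize a tuning curve
#'
#' @param curve A [tuning_curve()].
#' @return The curve scaled so its maximum response is exactly 1.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  pk <- max(curve$response)
  if (pk <= 0) stop("cannot normalize a curve with nonpositive peak", call. = FALSE)
  curve$response <- curve$response / pk
  curve$response[which.max(curve$response)] <- 1  # guard rounding
  if (!is.null(curve$dispersion)) curve$dispersion <- curve$dispersion / pk
  curve$normalized <- TRUE
  curve
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve: %s%s, %d points%s\n", x$dimension,
              if (!is.null(x$signal)) paste0(" (", x$signal, ")") else "",
              length(x$stimulus),
              if (isTRUE(x$normalized)) ", peak-normalized" else ""))
  print(utils::head(as.data.frame(x), 8), ...)
  if (length(x$stimulus) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.tuning_curve <- function(x, ...) {
  d <- data.frame(dimension = x$dimension, stimulus = x$stimulus,
                  response = x$response)
  d$dispersion <- if (is.null(x$dispersion)) NA_real_ else x$dispersion
  d$n <- if (is.null(x$n)) NA_integer_ else x$n
  d
}

#' @export
plot.tuning_curve <- function(x, ..., add = FALSE, col = "steelblue4") {
  xlab <- switch(x$dimension,
                 contrast = "Contrast (%)",
                 position = "Cortical distance (mm)",
                 orientation = "Orientation difference (deg)")
  if (add) {
    graphics::lines(x$stimulus, x$response, col = col, ...)
  } else {
    graphics::plot(x$stimulus, x$response, type = "o", pch = 16, col = col,
                   xlab = xlab, ylab = "Response (norm.)", ...)
  }
  invisible(x)
}

# Matrix of single-neuron responses: rows = stimulus axis, cols = pooling
# grid; `signal` applies the spiking exponent per neuron before pooling.
neuron_response_matrix <- function(dimension, signal, neuron, pooling, axis) {
  hat <- derive_potential_params(neuron)
  L <- switch(dimension,
    contrast = outer(axis, pooling$c50_grid, potential_contrast_response),
    position = outer(axis, pooling$x0_grid,
                     function(x, x0) potential_position_response(x, x0, hat$Wx_hat)),
    orientation = outer(axis, pooling$theta0_grid,
                        function(th, th0) potential_orientation_response(
                          th, th0, hat$Wtheta_hat, hat$ftheta_hat))
  )
  if (signal == "spiking") L <- spiking_from_potential(L, neuron$ns)
  L
}

default_axis <- function(dimension) {
  switch(dimension,
         contrast = seq(0, 100, by = 1),
         position = seq(-6, 6, by = 0.1),
         orientation = seq(-90, 90, by = 1))
}

#' Pooled population tuning curve
#'
#' The model's prediction for the signal at one imaged location: a weighted
#' sum of single-neuron responses over the scatter distribution matched to
#' the probed stimulus dimension (C50 weights for contrast, RF-center
#' weights for position, preferred-orientation weights for orientation; one
#' scatter per dimension). For `signal = "potential"` the membrane-potential
#' response is pooled directly (VSD-like); for `signal = "spiking"` each
#' neuron's response is first raised to the exponent `ns` (GCaMP-like). The
#' result is peak-normalized.
#'
#' @param dimension `"contrast"`, `"position"`, or `"orientation"`.
#' @param signal `"potential"` or `"spiking"`.
#' @param neuron A [single_neuron_params()].
#' @param pooling A [pooling_params()].
#' @param stimulus_axis Optional axis (contrast %, mm, or deg); sensible
#'   defaults per dimension.
#' @param normalize Peak-normalize the result (default `TRUE`).
#' @return A [tuning_curve()].
#' @export
#' @examples
#' pooled_tuning_curve("orientation", "spiking")
pooled_tuning_curve <- function(dimension = c("contrast", "position", "orientation"),
                                signal = c("potential", "spiking"),
                                neuron = single_neuron_params(),
                                pooling = pooling_params(),
                                stimulus_axis = NULL, normalize = TRUE) {
  dimension <- match.arg(dimension)
  signal <- match.arg(signal)
  axis <- stimulus_axis %||% default_axis(dimension)
  if (dimension == "contrast" && any(axis < 0)) {
    stop("contrast axis must be >= 0", call. = FALSE)
  }
  w <- switch(dimension,
              contrast = contrast_weights(pooling$p50, pooling$c50_grid),
              position = position_weights(pooling$sigma_x0, pooling$x0_grid),
              orientation = orientation_weights(pooling$kappa_theta,
                                                pooling$theta0_grid))
  L <- neuron_response_matrix(dimension, signal, neuron, pooling, axis)
  resp <- drop(L %*% w$weights)
  curve <- tuning_curve(dimension, axis, resp, signal = signal)
  if (normalize) curve <- normalize_curve(curve)
  curve
}

#' Summarize a single-peaked tuning curve
#'
#' Computes the full width at half maximum (measured at half height between
#' the curve's floor and its peak, by linear interpolation between samples;
#' for a curve peaking at an axis endpoint the one-sided half width is
#' doubled), the floor (minimum response), and -- for contrast-like curves --
#' the semi-response point (axis value where the normalized response first
#' reaches 0.5). A curve that is not single-peaked (not monotone on both
#' sides of its maximum) is flagged and the summary fields are `NA`.
#'
#' @param curve A normalized [tuning_curve()].
#' @return A list with `fwhm`, `floor`, `semi_response`, `peak_at`,
#'   `single_peaked`.
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  x <- curve$stimulus
  y <- curve$response
  i_pk <- which.max(y)
  tol <- 1e-9 * max(abs(y))
  single <- (max(y) > min(y)) &&
    all(diff(y[seq_len(i_pk)]) >= -tol) &&
    all(diff(y[i_pk:length(y)]) <= tol)
  if (!single) {
    return(list(fwhm = NA_real_, floor = NA_real_, semi_response = NA_real_,
                peak_at = NA_real_, single_peaked = FALSE))
  }
  floor_v <- min(y)
  half <- floor_v + (max(y) - floor_v) / 2
  right <- cross_level(x, y, half, i_pk, +1L)
  left <- cross_level(x, y, half, i_pk, -1L)
  fwhm <- if (!is.na(left) && !is.na(right)) {
    right - left
  } else if (!is.na(right)) {
    2 * (right - x[i_pk])
  } else if (!is.na(left)) {
    2 * (x[i_pk] - left)
  } else {
    NA_real_
  }
  semi <- cross_level(x, y / max(y), 0.5, 1L, +1L)
  list(fwhm = fwhm, floor = floor_v, semi_response = semi,
       peak_at = x[i_pk], single_peaked = TRUE)
}

#' Write or read tuning curves as CSV
#'
#' Columns: `dimension, stimulus, response, dispersion, n`.
#'
#' @param curves A [tuning_curve()] or list of them.
#' @param path CSV path.
#' @return `write_tuning_csv()` returns `path` invisibly; `read_tuning_csv()`
#'   returns a list of `tuning_curve` objects (one per dimension block).
#' @export
write_tuning_csv <- function(curves, path) {
  if (inherits(curves, "tuning_curve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tuning_csv
#' @export
read_tuning_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$dimension), function(b) {
    o <- order(b$stimulus)
    b <- b[o, ]
    tuning_curve(b$dimension[1], b$stimulus, b$response,
                 dispersion = if (all(is.na(b$dispersion))) NULL else b$dispersion,
                 n = if (all(is.na(b$n))) NULL else b$n)
  })
}
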
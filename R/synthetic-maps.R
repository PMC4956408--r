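#' Cortical pixel grid
#'
#' Geometry of the imaged cortical patch: pixel size (mm), pixel counts, and
#' the mm offset of pixel (1, 1). Pixel centers are at
#' `origin + (index - 0.5) * pixel_size`.
#'
#' @param pixel_size Pixel size, mm (> 0).
#' @param ny,nx Pixel counts.
#' @param origin Length-2 mm offset (y, x) of the patch corner; default c(0, 0).
#' @return An object of class `cortical_grid`.
#' @export
#' @examples
#' cortical_grid() # 6.4 mm patch at 0.05 mm/pixel
cortical_grid <- function(pixel_size = 0.05, ny = 128, nx = 128,
                          origin = c(0, 0)) {
  stopifnot_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (ny < 2 || nx < 2) stop("grid must be at least 2 x 2 pixels", call. = FALSE)
  structure(list(pixel_size = pixel_size, ny = as.integer(ny),
                 nx = as.integer(nx), origin = as.numeric(origin)),
            class = "cortical_grid")
}

#' @export
print.cortical_grid <- function(x, ...) {
  cat(sprintf("Cortical grid: %d x %d pixels, %.3g mm/pixel (%.2g x %.2g mm)\n",
              x$ny, x$nx, x$pixel_size, x$ny * x$pixel_size, x$nx * x$pixel_size))
  invisible(x)
}

# Pixel-center coordinates (mm): list(y = ny-vector, x = nx-vector).
pixel_coords <- function(grid) {
  list(y = grid$origin[1] + (seq_len(grid$ny) - 0.5) * grid$pixel_size,
       x = grid$origin[2] + (seq_len(grid$nx) - 0.5) * grid$pixel_size)
}

grid_center_mm <- function(grid) {
  c(grid$origin[1] + grid$ny * grid$pixel_size / 2,
    grid$origin[2] + grid$nx * grid$pixel_size / 2)
}

#' Synthesize an orientation-preference map
#'
#' Generates a semi-periodic V1-like orientation map (columns of ~`period`
#' mm spacing, pinwheel singularities) by band-pass filtering complex
#' Gaussian noise with a Gaussian annulus centered at spatial frequency
#' `1/period`. Preferred orientation is half the argument of the filtered
#' complex field; selectivity is its magnitude normalized to \[0, 1\].
#'
#' @param grid A [cortical_grid()]; extent should be at least 3 periods.
#' @param period Target column spacing, mm (default 0.7, the V1 value).
#' @param seed Integer seed; the map is a deterministic function of it.
#' @param bandwidth Relative width (SD / center frequency) of the spectral
#'   annulus.
#' @param saturation Quantile of the field magnitude at which selectivity
#'   saturates at 1. Real orientation maps are strongly selective almost
#'   everywhere, with weak selectivity confined to pinwheel cores; the raw
#'   Rayleigh-distributed magnitude is therefore compressed so that pixels
#'   above this quantile have selectivity 1.
#' @return An object of class `orientation_map` with per-pixel `preferred`
#'   (deg in \[0, 180)) and `selectivity` matrices.
#' @export
#' @examples
#' m <- make_orientation_map(cortical_grid(ny = 64, nx = 64), seed = 1)
make_orientation_map <- function(grid, period = 0.7, seed = 1,
                                 bandwidth = 0.15, saturation = 0.2) {
  stopifnot(inherits(grid, "cortical_grid"))
  if (period <= 2 * grid$pixel_size) {
    stop("`period` must exceed twice the pixel size (map not resolvable)",
         call. = FALSE)
  }
  f0 <- 1 / period
  fr <- radial_freq(grid$ny, grid$nx, grid$pixel_size)
  mask <- exp(-(fr - f0)^2 / (2 * (bandwidth * f0)^2))
  mask[1, 1] <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise <- matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx) +
    1i * matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
  z <- ifft2(fft2(noise) * mask)
  preferred <- (Arg(z) / 2 * 180 / pi) %% 180
  selectivity <- pmin(Mod(z) / stats::quantile(Mod(z), saturation)[[1]], 1)
  structure(list(grid = grid, preferred = preferred,
                 selectivity = selectivity, period = period, seed = seed,
                 bandwidth = bandwidth, saturation = saturation),
            class = "orientation_map")
}

# Save/restore the global RNG state so generators are seed-local.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("Orientation-preference map: %d x %d px, period %.2f mm, seed %d\n",
              x$grid$ny, x$grid$nx, x$period, x$seed))
  cat(sprintf("  pinwheels detected: %d\n", nrow(find_pinwheels(x))))
  invisible(x)
}

#' @export
plot.orientation_map <- function(x, ...) {
  graphics::image(t(x$preferred), col = grDevices::hsv(seq(0, 1, length.out = 64)),
                  axes = FALSE, asp = x$grid$ny / x$grid$nx,
                  main = "Preferred orientation", ...)
  invisible(x)
}

#' Locate pinwheel singularities in an orientation map
#'
#' A pinwheel is a point where all orientations meet: the doubled-angle
#' phase winds by +/- 360 degrees around it. Detected by summing wrapped
#' doubled-angle differences around every 2x2 pixel plaquette.
#'
#' @param map An [make_orientation_map()] result.
#' @return A data frame with columns `y`, `x` (pixel indices of the
#'   plaquette corner) and `charge` (+1 or -1).
#' @export
find_pinwheels <- function(map) {
  stopifnot(inherits(map, "orientation_map"))
  ph <- 2 * map$preferred * pi / 180   # doubled angle, radians
  wrap <- function(a) atan2(sin(a), cos(a))
  ny <- nrow(ph); nx <- ncol(ph)
  a <- ph[-ny, -nx]; b <- ph[-ny, -1]; c <- ph[-1, -1]; d <- ph[-1, -nx]
  wind <- wrap(b - a) + wrap(c - b) + wrap(d - c) + wrap(a - d)
  charge <- round(wind / (2 * pi))
  idx <- which(charge != 0, arr.ind = TRUE)
  data.frame(y = idx[, 1], x = idx[, 2], charge = charge[idx])
}

#' Radially averaged power spectrum of the doubled-angle map
#'
#' Forms the unit-modulus complex map `exp(2i * preferred)`, computes its 2-D
#' power spectrum, and averages power in annular bins one DFT frequency step
#' wide. Used to measure the dominant spatial period of the columnar
#' pattern.
#'
#' @param map An [make_orientation_map()] result.
#' @return A data frame with `freq` (cyc/mm, bin centers) and `power`.
#' @export
map_radial_spectrum <- function(map) {
  stopifnot(inherits(map, "orientation_map"))
  z <- exp(2i * map$preferred * pi / 180)
  P <- Mod(fft2(z))^2
  fr <- radial_freq(map$grid$ny, map$grid$nx, map$grid$pixel_size)
  db <- 1 / (min(map$grid$ny, map$grid$nx) * map$grid$pixel_size)
  bin <- round(fr / db)
  pw <- tapply(as.vector(P), as.vector(bin), mean)
  f <- as.numeric(names(pw)) * db
  keep <- f > 0
  data.frame(freq = f[keep], power = as.numeric(pw[keep]))
}

#' Dominant spatial period of an orientation map
#'
#' Inverse of the peak frequency of [map_radial_spectrum()].
#'
#' @param map An [make_orientation_map()] result.
#' @return Period in mm.
#' @export
estimate_map_period <- function(map) {
  sp <- map_radial_spectrum(map)
  1 / sp$freq[which.max(sp$power)]
}

#' Affine retinotopic map
#'
#' Simplified retinotopy: visual-field position (deg) maps affinely to
#' cortical position (mm), `cortical = A %*% visual + b`, with isotropic
#' magnification by default. The visual position `center_deg` maps to the
#' center of the cortical patch.
#'
#' @param grid A [cortical_grid()].
#' @param magnification Cortical magnification, mm/deg (> 0).
#' @param center_deg Visual-field position (deg, length 2 `c(x, y)`)
#'   represented at the patch center. Default `c(2.5, -2.5)` (parafoveal
#'   lower field, as for dorsal V1 recordings).
#' @return An object of class `retinotopy_map`.
#' @export
make_retinotopy <- function(grid, magnification = 1.5,
                            center_deg = c(2.5, -2.5)) {
  stopifnot(inherits(grid, "cortical_grid"))
  stopifnot_scalar(magnification, "magnification")
  if (magnification <= 0) stop("`magnification` must be > 0", call. = FALSE)
  A <- diag(2) * magnification
  center_mm <- rev(grid_center_mm(grid))  # (x, y) order
  b <- center_mm - A %*% center_deg
  structure(list(grid = grid, A = A, b = as.numeric(b),
                 magnification = magnification,
                 center_deg = as.numeric(center_deg)),
            class = "retinotopy_map")
}

#' @export
print.retinotopy_map <- function(x, ...) {
  cat(sprintf("Affine retinotopy: %.3g mm/deg, patch center at (%g, %g) deg\n",
              x$magnification, x$center_deg[1], x$center_deg[2]))
  invisible(x)
}

#' Convert between visual-field and cortical coordinates
#'
#' @param retino A [make_retinotopy()] result.
#' @param pos_deg,pos_mm Positions as length-2 vectors `c(x, y)` or n x 2
#'   matrices.
#' @return An n x 2 matrix (or length-2 vector for vector input) of mapped
#'   coordinates.
#' @export
visual_to_cortical <- function(retino, pos_deg) {
  stopifnot(inherits(retino, "retinotopy_map"))
  p <- if (is.matrix(pos_deg)) pos_deg else matrix(pos_deg, nrow = 1)
  out <- t(retino$A %*% t(p) + retino$b)
  if (!is.matrix(pos_deg)) drop(out) else out
}

#' @rdname visual_to_cortical
#' @export
cortical_to_visual <- function(retino, pos_mm) {
  stopifnot(inherits(retino, "retinotopy_map"))
  p <- if (is.matrix(pos_mm)) pos_mm else matrix(pos_mm, nrow = 1)
  out <- t(solve(retino$A) %*% (t(p) - retino$b))
  if (!is.matrix(pos_mm)) drop(out) else out
}
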
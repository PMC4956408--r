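# Internal helpers shared across modules.

# Gaussian bump parameterized by full width at half maximum:
# value 1 at d = 0, exactly 0.5 at |d| = w/2.
gauss_fwhm <- function(d, w) exp(-2 * log(4) * (d / w)^2)

# Minimal circular distance between orientations on the 180-degree circle.
circ_dist_180 <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# DFT frequencies (cycles per unit) for n samples at spacing d, in FFT order.
fft_freq <- function(n, d = 1) {
  i <- 0L:(n - 1L)
  ifelse(i <= n / 2, i, i - n) / (n * d)
}

# Matrix of radial spatial frequencies for an ny x nx image.
radial_freq <- function(ny, nx, pixel_size) {
  fy <- fft_freq(ny, pixel_size)
  fx <- fft_freq(nx, pixel_size)
  sqrt(outer(fy^2, fx^2, `+`))
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Linear interpolation of the x value where y crosses `level`, searching
# from index `from` in direction `dir` (+1/-1). NA if no crossing.
cross_level <- function(x, y, level, from, dir) {
  n <- length(x)
  i <- from
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if ((y[i] - level) * (y[j] - level) <= 0 && y[i] != y[j]) {
      return(x[i] + (level - y[i]) * (x[j] - x[i]) / (y[j] - y[i]))
    }
    i <- j
  }
  NA_real_
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
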
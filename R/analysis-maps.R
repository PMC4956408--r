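#' Spatial bandpass filter for cortical maps
#'
#' Frequency-domain annular filter that isolates the columnar scale
#' (default passband 0.8-3 cyc/mm): unit gain in the passband,
#' raised-cosine transition bands of total width 20% of each cutoff, zero
#' outside, and DC exactly removed, so the output is zero-mean.
#'
#' @param plane ny x nx matrix.
#' @param pixel_size Pixel size, mm.
#' @param low,high Passband cutoffs, cyc/mm (`high > low`).
#' @return Filtered matrix (zero mean).
#' @export
bandpass_map <- function(plane, pixel_size, low = 0.8, high = 3.0) {
  if (high <= low) stop("`high` must exceed `low`", call. = FALSE)
  fr <- radial_freq(nrow(plane), ncol(plane), pixel_size)
  H <- matrix(0, nrow(plane), ncol(plane))
  lo1 <- 0.9 * low; lo2 <- 1.1 * low
  hi1 <- 0.9 * high; hi2 <- 1.1 * high
  H[fr >= lo2 & fr <= hi1] <- 1
  i <- fr > lo1 & fr < lo2
  H[i] <- 0.5 * (1 - cos(pi * (fr[i] - lo1) / (lo2 - lo1)))
  i <- fr > hi1 & fr < hi2
  H[i] <- 0.5 * (1 + cos(pi * (fr[i] - hi1) / (hi2 - hi1)))
  H[1, 1] <- 0
  Re(ifft2(fft2(plane) * H))
}

#' Band-passed single-condition orientation maps
#'
#' The map-making pipeline: blank subtraction, first-harmonic amplitude per
#' orientation condition, then the columnar-scale spatial bandpass. The raw
#' (un-bandpassed) amplitudes are kept alongside, since tuning-curve
#' magnitudes are read from them (the bandpass removes the untuned DC
#' component that the tuning floor lives in).
#'
#' @param rec A `widefield_recording` from an orientation suite (equally
#'   spaced orientations).
#' @param low,high Bandpass cutoffs, cyc/mm.
#' @return A `single_condition_maps` object: `planes` (bandpassed,
#'   condition x y x x), `raw` (a harmonic `response_map`), `orientations`
#'   (deg), `grid`.
#' @export
single_condition_maps <- function(rec, low = 0.8, high = 3.0) {
  cm <- blank_subtract(rec)
  raw <- harmonic_amplitude(cm)
  ori <- vapply(cm$protocols, `[[`, 0, "orientation")
  if (length(unique(ori)) != length(ori)) {
    stop("duplicate orientation conditions", call. = FALSE)
  }
  sp <- sort(ori)
  if (length(ori) < 2 || length(unique(round(diff(sp), 6))) != 1) {
    stop("orientation conditions must be equally spaced", call. = FALSE)
  }
  planes <- raw$amplitude
  for (i in seq_along(cm$conditions)) {
    planes[i, , ] <- bandpass_map(raw$amplitude[i, , ], cm$grid$pixel_size,
                                  low, high)
  }
  structure(list(planes = planes, raw = raw, orientations = unname(ori),
                 conditions = cm$conditions, grid = cm$grid,
                 signal = cm$signal),
            class = "single_condition_maps")
}

#' Mean pairwise map correlation by orientation difference
#'
#' Pearson correlation between every pair of band-passed single-condition
#' maps, averaged over pairs sharing the same (circular) stimulus
#' orientation difference. For V1-like columnar maps this decreases from
#' positive at small differences to negative at 90 degrees.
#'
#' @param maps A `single_condition_maps` object, or a condition x y x x
#'   array (then `orientations` is required).
#' @param orientations Stimulus orientations, deg (if `maps` is an array).
#' @param mask Optional logical pixel mask (default: all pixels).
#' @return A data frame with `delta` (deg), `mean_r`, `n_pairs`.
#' @export
pairwise_map_correlation <- function(maps, orientations = NULL, mask = NULL) {
  if (inherits(maps, "single_condition_maps")) {
    orientations <- maps$orientations
    maps <- maps$planes
  }
  nc <- dim(maps)[1]
  stopifnot(length(orientations) == nc)
  sel <- if (is.null(mask)) TRUE else as.vector(mask)
  vecs <- lapply(seq_len(nc), function(i) as.vector(maps[i, , ])[sel])
  const <- vapply(vecs, function(v) stats::sd(v) == 0, TRUE)
  if (any(const)) {
    warning(sum(const), " constant plane(s) excluded from correlations")
  }
  rows <- list()
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      if (const[i] || const[j]) next
      rows[[length(rows) + 1]] <- data.frame(
        delta = circ_dist_180(orientations[i], orientations[j]),
        r = stats::cor(vecs[[i]], vecs[[j]]))
    }
  }
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(r ~ delta, d, mean)
  n <- stats::aggregate(r ~ delta, d, length)
  data.frame(delta = agg$delta, mean_r = agg$r, n_pairs = n$r)
}

#' Composite orientation-preference map
#'
#' Per pixel, the vector sum `V = sum_k A_k exp(2i theta_k)` over the
#' single-condition amplitudes: the preferred orientation is `arg(V)/2`
#' mapped to \[0, 180), and the selectivity is `|V| / sum_k |A_k|` (0 when
#' all condition responses are equal; preferred is `NA` where every
#' amplitude is zero).
#'
#' @param maps A `single_condition_maps` object, or a condition x y x x
#'   array plus `orientations`.
#' @param orientations Stimulus orientations, deg (if `maps` is an array).
#' @param grid Optional [cortical_grid()] (if `maps` is an array).
#' @return A `composite_orientation_map`: `preferred` (deg), `selectivity`,
#'   `grid`.
#' @export
composite_orientation_map <- function(maps, orientations = NULL, grid = NULL) {
  if (inherits(maps, "single_condition_maps")) {
    orientations <- maps$orientations
    grid <- maps$grid
    maps <- maps$planes
  }
  nc <- dim(maps)[1]
  stopifnot(length(orientations) == nc)
  ph <- exp(2i * orientations * pi / 180)
  V <- matrix(0i, dim(maps)[2], dim(maps)[3])
  denom <- matrix(0, dim(maps)[2], dim(maps)[3])
  for (k in seq_len(nc)) {
    V <- V + maps[k, , ] * ph[k]
    denom <- denom + abs(maps[k, , ])
  }
  preferred <- (Arg(V) / 2 * 180 / pi) %% 180
  selectivity <- ifelse(denom > 0, Mod(V) / denom, 0)
  preferred[denom == 0] <- NA_real_
  structure(list(preferred = preferred, selectivity = selectivity,
                 grid = grid, orientations = orientations),
            class = "composite_orientation_map")
}

#' @export
print.composite_orientation_map <- function(x, ...) {
  cat(sprintf("Composite orientation map from %d conditions; mean selectivity %.3f\n",
              length(x$orientations), mean(x$selectivity, na.rm = TRUE)))
  invisible(x)
}

#' Grayscale conversion of an orientation map
#'
#' Maps preferred orientation to \[-1, 1\] by `sin(2 * preferred)`, the
#' standard grayscale used to compare orientation maps across sessions and
#' indicators.
#'
#' @param cmap A `composite_orientation_map` (or a matrix of preferred
#'   orientations in degrees).
#' @return ny x nx matrix in \[-1, 1\].
#' @export
grayscale_orientation_map <- function(cmap) {
  pref <- if (inherits(cmap, "composite_orientation_map")) cmap$preferred else cmap
  sin(2 * pref * pi / 180)
}

#' Pearson correlation between two grayscale orientation maps
#'
#' @param g1,g2 Matrices on the same grid (pre-aligned).
#' @param mask Optional logical pixel mask.
#' @return Pearson r.
#' @export
map_session_correlation <- function(g1, g2, mask = NULL) {
  stopifnot(all(dim(g1) == dim(g2)))
  sel <- if (is.null(mask)) rep(TRUE, length(g1)) else as.vector(mask)
  a <- as.vector(g1)[sel]
  b <- as.vector(g2)[sel]
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cannot correlate a constant map", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Circular correlation between two preferred-orientation maps
#'
#' Correlation of the doubled-angle unit phasors, used to score recovery of
#' a ground-truth orientation map: 1 for identical maps, 0 for unrelated
#' ones.
#'
#' @param pref1,pref2 Matrices of preferred orientation, deg.
#' @return Circular correlation in \[-1, 1\].
#' @export
orientation_map_agreement <- function(pref1, pref2) {
  keep <- is.finite(pref1) & is.finite(pref2)
  d <- 2 * (pref1[keep] - pref2[keep]) * pi / 180
  mean(cos(d))
}
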
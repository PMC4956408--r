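#' Orientation tuning curve from single-condition maps
#'
#' For every ROI pixel, the 12 condition amplitudes are re-indexed by the
#' circular distance between the stimulus orientation and the pixel's
#' preferred orientation (from the composite map), folded to \[0, 90\],
#' binned at the stimulus spacing, averaged across pixels, and
#' peak-normalized. Response magnitudes come from the raw (un-bandpassed)
#' harmonic amplitudes so the untuned floor survives; the band-passed maps
#' only define each pixel's preferred orientation.
#'
#' @param maps A `single_condition_maps` object.
#' @param cmap A `composite_orientation_map` (defaults to one computed from
#'   `maps`).
#' @param roi An `roi` from [resolve_roi()].
#' @param bin_deg Bin width, deg (default 15, the stimulus spacing).
#' @return A [tuning_curve()] (dimension `"orientation"`, axis 0..90 deg)
#'   with per-bin SEM and counts.
#' @export
orientation_tuning_curve <- function(maps, cmap = NULL, roi, bin_deg = 15) {
  stopifnot(inherits(maps, "single_condition_maps"), inherits(roi, "roi"))
  cmap <- cmap %||% composite_orientation_map(maps)
  sel <- which(roi$mask & is.finite(cmap$preferred))
  if (!length(sel)) stop("ROI is empty", call. = FALSE)
  bins <- seq(0, 90, by = bin_deg)
  acc_sum <- acc_sq <- acc_n <- numeric(length(bins))
  pref <- cmap$preferred[sel]
  for (k in seq_along(maps$orientations)) {
    a <- maps$raw$amplitude[k, , ][sel]
    d <- circ_dist_180(maps$orientations[k], pref)
    b <- pmin(round(d / bin_deg), length(bins) - 1) + 1
    acc_sum <- acc_sum + tapply_sum(a, b, length(bins))
    acc_sq <- acc_sq + tapply_sum(a^2, b, length(bins))
    acc_n <- acc_n + tabulate(b, length(bins))
  }
  keep <- acc_n > 0
  m <- acc_sum[keep] / acc_n[keep]
  v <- pmax(0, acc_sq[keep] / acc_n[keep] - m^2)
  sem <- sqrt(v / acc_n[keep])
  normalize_curve(tuning_curve("orientation", bins[keep], m, dispersion = sem,
                               n = acc_n[keep], signal = maps$signal))
}

tapply_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Contrast tuning curve from windowed response maps
#'
#' ROI-mean window amplitude per contrast condition, peak-normalized.
#'
#' @param rmap A `response_map` from [window_amplitude()] over a contrast
#'   suite (>= 3 contrasts).
#' @param roi An `roi`.
#' @return A [tuning_curve()] (dimension `"contrast"`).
#' @export
contrast_tuning_curve <- function(rmap, roi) {
  stopifnot(inherits(rmap, "response_map"), inherits(roi, "roi"))
  sel <- which(roi$mask)
  if (!length(sel)) stop("ROI is empty", call. = FALSE)
  contrasts <- vapply(rmap$protocols, `[[`, 0, "contrast")
  if (length(contrasts) < 3) stop("need at least 3 contrasts", call. = FALSE)
  resp <- vapply(seq_along(rmap$conditions), function(i) {
    mean(rmap$amplitude[i, , ][sel])
  }, 0)
  sem <- vapply(seq_along(rmap$conditions), function(i) {
    stats::sd(rmap$amplitude[i, , ][sel]) / sqrt(length(sel))
  }, 0)
  o <- order(contrasts)
  normalize_curve(tuning_curve("contrast", contrasts[o], resp[o],
                               dispersion = sem[o], signal = rmap$signal))
}

#' Position tuning curve from windowed response maps
#'
#' ROI-mean window amplitude per Gabor position, plotted against the signed
#' cortical distance between the stimulus' retinotopic center and the ROI
#' center (negative toward the foveal representation), peak-normalized.
#' Stimuli mapping outside the imaged patch are flagged but kept.
#'
#' @param rmap A `response_map` from [window_amplitude()] over a position
#'   suite.
#' @param roi An `roi` (conventionally the 0.75 mm square at the retinotopic
#'   center of the middle stimulus).
#' @param retinotopy A [make_retinotopy()] result.
#' @param fovea_deg Visual-field position of the fovea (default origin);
#'   defines the sign convention.
#' @return A [tuning_curve()] (dimension `"position"`, axis in mm) with an
#'   attribute `outside_patch` flagging extrapolated positions.
#' @export
position_tuning_curve <- function(rmap, roi, retinotopy, fovea_deg = c(0, 0)) {
  stopifnot(inherits(rmap, "response_map"), inherits(roi, "roi"),
            inherits(retinotopy, "retinotopy_map"))
  sel <- which(roi$mask)
  if (!length(sel)) stop("ROI is empty", call. = FALSE)
  ctr_roi <- roi_center_mm(roi)
  fovea_mm <- visual_to_cortical(retinotopy, fovea_deg)
  u <- ctr_roi - fovea_mm
  u <- u / sqrt(sum(u^2))  # unit vector pointing away from the fovea
  grid <- rmap$grid
  extent <- c(grid$nx, grid$ny) * grid$pixel_size
  pos <- t(vapply(rmap$protocols, function(p) {
    visual_to_cortical(retinotopy, p$position_deg)
  }, numeric(2)))
  dist_mm <- as.vector((pos - matrix(ctr_roi, nrow(pos), 2, byrow = TRUE)) %*% u)
  outside <- pos[, 1] < grid$origin[2] | pos[, 1] > grid$origin[2] + extent[1] |
    pos[, 2] < grid$origin[1] | pos[, 2] > grid$origin[1] + extent[2]
  resp <- vapply(seq_along(rmap$conditions), function(i) {
    mean(rmap$amplitude[i, , ][sel])
  }, 0)
  o <- order(dist_mm)
  crv <- normalize_curve(tuning_curve("position", dist_mm[o], resp[o],
                                      signal = rmap$signal))
  attr(crv, "outside_patch") <- outside[o]
  crv
}
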
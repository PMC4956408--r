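#' Blank subtraction and trial averaging
#'
#' Averages stimulus trials within each condition, then subtracts the mean
#' blank-trial time course frame-wise (the standard correction for
#' stimulus-independent fluctuations shared with blank trials). Blank trials
#' are consumed and removed from the output.
#'
#' @param rec A `widefield_recording`.
#' @param allow_no_blanks If `TRUE`, a recording without blank trials is
#'   processed with a zero baseline instead of raising an error.
#' @return A `condition_movies` object: `data` (condition x frame x y x x),
#'   `conditions`, `frame_rate`, `protocols`, `grid`, `signal`.
#' @export
blank_subtract <- function(rec, allow_no_blanks = FALSE) {
  stopifnot(inherits(rec, "widefield_recording"))
  nb <- sum(rec$blank)
  if (nb == 0 && !allow_no_blanks) {
    stop("recording has no blank trials; rerun with `allow_no_blanks = TRUE` ",
         "to use a zero baseline", call. = FALSE)
  }
  d <- dim(rec$data)
  baseline <- if (nb > 0) {
    colMeans(rec$data[rec$blank, , , , drop = FALSE], dims = 1)
  } else {
    array(0, d[-1])
  }
  conds <- unique(rec$condition[!rec$blank])
  out <- array(0, dim = c(length(conds), d[2], d[3], d[4]),
               dimnames = list(conds, NULL, NULL, NULL))
  for (i in seq_along(conds)) {
    sel <- rec$condition == conds[i]
    out[i, , , ] <- colMeans(rec$data[sel, , , , drop = FALSE], dims = 1) - baseline
  }
  structure(list(data = out, conditions = conds, frame_rate = rec$frame_rate,
                 protocols = rec$protocols[conds], grid = rec$grid,
                 signal = rec$signal),
            class = "condition_movies")
}

# Frames (indices) whose midpoints fall in [onset + start, onset + start + dur).
window_frames <- function(frame_rate, n_frames, onset_s, start_ms, dur_ms) {
  mid <- (seq_len(n_frames) - 0.5) / frame_rate
  t0 <- onset_s + start_ms / 1000
  t1 <- t0 + dur_ms / 1000
  if (t1 > n_frames / frame_rate + 1e-9) {
    stop("analysis window extends beyond the trial", call. = FALSE)
  }
  which(mid >= t0 & mid < t1)
}

#' Response amplitude from a fixed post-onset window
#'
#' Per-pixel mean of the blank-subtracted response over a window starting
#' `start_ms` after each flash onset and lasting `dur_ms` (defaults 35 and
#' 200 ms), averaged over the flashes of the trial. A frame belongs to the
#' window if its midpoint lies inside it.
#'
#' @param cm A `condition_movies` object from [blank_subtract()].
#' @param start_ms,dur_ms Window start (after flash onset) and duration, ms.
#' @return A `response_map`: `amplitude` (condition x y x x), `grid`,
#'   `conditions`, `protocols`, `method = "window"`.
#' @export
window_amplitude <- function(cm, start_ms = 35, dur_ms = 200) {
  stopifnot(inherits(cm, "condition_movies"))
  d <- dim(cm$data)
  amp <- array(0, dim = c(d[1], d[3], d[4]),
               dimnames = list(cm$conditions, NULL, NULL))
  for (i in seq_along(cm$conditions)) {
    p <- cm$protocols[[cm$conditions[i]]]
    onsets <- (seq_len(p$n_cycles) - 1) / p$flash_rate
    fr <- unlist(lapply(onsets, function(o) {
      window_frames(cm$frame_rate, d[2], o, start_ms, dur_ms)
    }))
    amp[i, , ] <- colMeans(cm$data[i, fr, , , drop = FALSE], dims = 2)
  }
  structure(list(amplitude = amp, grid = cm$grid, conditions = cm$conditions,
                 protocols = cm$protocols, method = "window",
                 signal = cm$signal),
            class = "response_map")
}

#' Response amplitude at the stimulus flash frequency
#'
#' Per-pixel first-harmonic Fourier amplitude of the blank-subtracted mean
#' time course: `2 |X(f_stim)| / N`, so a pure sinusoid of amplitude A
#' returns A. Requires the trial to contain an integer number of stimulus
#' cycles (the flash frequency must be an exact DFT bin).
#'
#' @param cm A `condition_movies` object.
#' @param f_stim Stimulus frequency, Hz; defaults to each condition's flash
#'   rate.
#' @return A `response_map` with `method = "harmonic"`.
#' @export
harmonic_amplitude <- function(cm, f_stim = NULL) {
  stopifnot(inherits(cm, "condition_movies"))
  d <- dim(cm$data)
  n <- d[2]
  amp <- array(0, dim = c(d[1], d[3], d[4]),
               dimnames = list(cm$conditions, NULL, NULL))
  for (i in seq_along(cm$conditions)) {
    f <- f_stim %||% cm$protocols[[cm$conditions[i]]]$flash_rate
    k <- f * n / cm$frame_rate
    if (abs(k - round(k)) > 1e-9) {
      stop("`f_stim` is not an exact DFT bin; use an integer number of cycles",
           call. = FALSE)
    }
    k <- round(k)
    e <- exp(-2i * pi * k * (seq_len(n) - 1) / n)
    x <- matrix(cm$data[i, , , ], nrow = n)
    amp[i, , ] <- 2 * Mod(drop(e %*% x)) / n
  }
  structure(list(amplitude = amp, grid = cm$grid, conditions = cm$conditions,
                 protocols = cm$protocols, method = "harmonic",
                 signal = cm$signal),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("Response map (%s): %d conditions, %d x %d px\n",
              x$method, dim(x$amplitude)[1], dim(x$amplitude)[2],
              dim(x$amplitude)[3]))
  invisible(x)
}

# Single-trial amplitudes per condition: each stimulus trial minus the mean
# blank time course, summarized by the requested amplitude method.
single_trial_amplitudes <- function(rec, method = c("window", "harmonic"),
                                    start_ms = 35, dur_ms = 200,
                                    f_stim = NULL) {
  method <- match.arg(method)
  if (!any(rec$blank)) stop("d-prime requires blank trials", call. = FALSE)
  d <- dim(rec$data)
  baseline <- colMeans(rec$data[rec$blank, , , , drop = FALSE], dims = 1)
  conds <- unique(rec$condition[!rec$blank])
  lapply(stats::setNames(conds, conds), function(cc) {
    sel <- which(rec$condition == cc)
    if (length(sel) < 2) {
      stop("d-prime requires at least 2 trials per condition", call. = FALSE)
    }
    p <- rec$protocols[[cc]]
    out <- array(0, dim = c(length(sel), d[3], d[4]))
    for (j in seq_along(sel)) {
      trial <- rec$data[sel[j], , , ] - baseline
      if (method == "window") {
        onsets <- (seq_len(p$n_cycles) - 1) / p$flash_rate
        fr <- unlist(lapply(onsets, function(o) {
          window_frames(rec$frame_rate, d[2], o, start_ms, dur_ms)
        }))
        out[j, , ] <- colMeans(trial[fr, , , drop = FALSE], dims = 1)
      } else {
        f <- f_stim %||% p$flash_rate
        k <- round(f * d[2] / rec$frame_rate)
        e <- exp(-2i * pi * k * (seq_len(d[2]) - 1) / d[2])
        out[j, , ] <- 2 * Mod(drop(e %*% matrix(trial, nrow = d[2]))) / d[2]
      }
    }
    out
  })
}

#' Per-pixel d-prime map
#'
#' Sensitivity index per pixel: the mean single-trial response amplitude
#' divided by the across-trial standard deviation (sample SD), maximized
#' over stimulus conditions. Pixels with zero SD get `NA`.
#'
#' @param rec A `widefield_recording` with blank trials and >= 2 trials per
#'   condition.
#' @param method Amplitude method, `"window"` or `"harmonic"`.
#' @param start_ms,dur_ms Window parameters (window method).
#' @return A `dprime_map`: `dprime` (y x x matrix), `grid`, `method`.
#' @export
dprime_map <- function(rec, method = c("window", "harmonic"),
                       start_ms = 35, dur_ms = 200) {
  method <- match.arg(method)
  amps <- single_trial_amplitudes(rec, method, start_ms, dur_ms)
  dp_all <- lapply(amps, function(a) {
    m <- colMeans(a, dims = 1)
    s <- apply(a, c(2, 3), stats::sd)
    dp <- m / s
    dp[s == 0] <- NA_real_
    dp
  })
  dp <- Reduce(function(a, b) pmax(a, b, na.rm = FALSE), dp_all)
  structure(list(dprime = dp, grid = rec$grid, method = method),
            class = "dprime_map")
}

#' @export
print.dprime_map <- function(x, ...) {
  cat(sprintf("d-prime map (%s): max %.2f, median %.2f\n", x$method,
              max(x$dprime, na.rm = TRUE),
              stats::median(x$dprime, na.rm = TRUE)))
  invisible(x)
}

square_mask <- function(grid, center_px, side_mm) {
  n <- round(side_mm / grid$pixel_size)
  if (n < 1) stop("ROI side smaller than one pixel", call. = FALSE)
  half_lo <- floor((n - 1) / 2)
  half_hi <- ceiling((n - 1) / 2)
  ys <- max(1, center_px[1] - half_lo):min(grid$ny, center_px[1] + half_hi)
  xs <- max(1, center_px[2] - half_lo):min(grid$nx, center_px[2] + half_hi)
  mask <- matrix(FALSE, grid$ny, grid$nx)
  mask[ys, xs] <- TRUE
  mask
}

#' Resolve a region of interest
#'
#' Three ROI rules used for tuning curves: a square of side `side_mm`
#' centered on the pixel with maximal d-prime (default 1.6 mm, used for
#' contrast and orientation tuning of calcium signals); all pixels with
#' d-prime above a threshold (default 3, used for VSD); or a square centered
#' at a retinotopic location (default 0.75 mm, used for position tuning).
#' Squares are clipped at the patch edge.
#'
#' @param x A `dprime_map` (first two rules) or a `cortical_grid`
#'   (retinotopic rule).
#' @param rule `"max_dprime_square"`, `"dprime_threshold"`, or
#'   `"retinotopic_square"`.
#' @param side_mm Square side, mm.
#' @param threshold d-prime threshold.
#' @param center_mm Cortical center `c(x, y)` in mm (retinotopic rule).
#' @return An `roi` object: logical `mask`, `grid`, `rule`, `center_px`.
#' @export
resolve_roi <- function(x, rule = c("max_dprime_square", "dprime_threshold",
                                    "retinotopic_square"),
                        side_mm = 1.6, threshold = 3, center_mm = NULL) {
  rule <- match.arg(rule)
  if (rule == "retinotopic_square") {
    grid <- if (inherits(x, "cortical_grid")) x else x$grid
    if (is.null(center_mm)) stop("`center_mm` required for retinotopic ROI", call. = FALSE)
    center_px <- c(round((center_mm[2] - grid$origin[1]) / grid$pixel_size + 0.5),
                   round((center_mm[1] - grid$origin[2]) / grid$pixel_size + 0.5))
    mask <- square_mask(grid, center_px, side_mm)
  } else {
    stopifnot(inherits(x, "dprime_map"))
    grid <- x$grid
    if (rule == "max_dprime_square") {
      center_px <- which(x$dprime == max(x$dprime, na.rm = TRUE), arr.ind = TRUE)[1, ]
      mask <- square_mask(grid, center_px, side_mm)
    } else {
      mask <- !is.na(x$dprime) & x$dprime > threshold
      center_px <- NULL
      if (!any(mask)) stop("no pixels exceed the d-prime threshold", call. = FALSE)
    }
  }
  if (!any(mask)) stop("resolved ROI is empty", call. = FALSE)
  structure(list(mask = mask, grid = grid, rule = rule,
                 center_px = center_px, side_mm = side_mm),
            class = "roi")
}

# Cortical (x, y) mm coordinates of an ROI's center of mass.
roi_center_mm <- function(roi) {
  idx <- which(roi$mask, arr.ind = TRUE)
  coords <- pixel_coords(roi$grid)
  c(mean(coords$x[idx[, 2]]), mean(coords$y[idx[, 1]]))
}

#' Collapse a periodic response across stimulus cycles
#'
#' Splits a time course into flash cycles, anchors each cycle by subtracting
#' its mean over an initial window after cycle onset (50 ms / 1 frame for
#' 20 Hz calcium, 36 ms / 4 frames for 100 Hz VSD in the emulated
#' experiments), and averages the anchored cycles.
#'
#' @param timecourse Numeric vector of frames.
#' @param frame_rate Sampling rate, Hz.
#' @param flash_rate Stimulus cycle rate, Hz; frames per cycle must be an
#'   integer.
#' @param anchor_ms Anchoring-window duration, ms (at least one frame).
#' @return Numeric vector of one cycle-averaged, anchored cycle.
#' @export
collapse_cycles <- function(timecourse, frame_rate, flash_rate, anchor_ms) {
  fpc <- frame_rate / flash_rate
  if (abs(fpc - round(fpc)) > 1e-9) {
    stop("frames per cycle must be an integer", call. = FALSE)
  }
  fpc <- round(fpc)
  ncyc <- length(timecourse) %/% fpc
  if (ncyc < 1) stop("time course shorter than one cycle", call. = FALSE)
  n_anchor <- max(1L, round(anchor_ms * frame_rate / 1000))
  n_anchor <- min(n_anchor, fpc)
  seg <- matrix(timecourse[seq_len(ncyc * fpc)], nrow = fpc)
  seg <- sweep(seg, 2, colMeans(seg[seq_len(n_anchor), , drop = FALSE]))
  rowMeans(seg)
}
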
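test_that("blank subtraction removes shared drift and is offset invariant", {
  pro <- one_flash_protocol()
  nf <- 30
  base <- array(0, dim = c(4, nf, 4, 4))
  drift <- sin(seq(0, pi, length.out = nf))   # common to all trials
  sig <- outer(rep(1, nf), matrix(runif(16), 4, 4))
  data <- base
  for (t in 1:2) data[t, , , ] <- sig + drift          # stimulus trials
  for (t in 3:4) data[t, , , ] <- drift                # blanks
  rec <- shell_recording(data, 20, c("stim", "stim", "blank", "blank"), pro)
  cm <- blank_subtract(rec)
  expect_equal(cm$data[1, , , ], sig, tolerance = 1e-12)

  # a condition identical to blank subtracts to zero
  rec0data <- array(0, dim = c(2, nf, 4, 4))
  rec0data[1, , , ] <- drift
  rec0data[2, , , ] <- drift
  rec0 <- shell_recording(rec0data, 20, c("stim", "blank"), pro)
  expect_true(all(abs(blank_subtract(rec0)$data) < 1e-12))

  # constant offset on every trial leaves the output unchanged
  rec2 <- rec
  rec2$data <- rec$data + 0.37
  expect_equal(blank_subtract(rec2)$data, cm$data, tolerance = 1e-12)

  expect_error(blank_subtract(shell_recording(base[1:2, , , , drop = FALSE], 20,
                                              c("stim", "stim"), pro)),
               "allow_no_blanks")
})

test_that("window amplitude selects frames by midpoint within 35-235 ms", {
  pro <- one_flash_protocol()   # one flash at t = 0, 20 Hz, 30 frames
  data <- array(99, dim = c(2, 30, 4, 4))
  data[1, 2:5, , ] <- 5   # frames with midpoints 75..225 ms
  data[2, , , ] <- 0      # blank
  rec <- shell_recording(data, 20, c("stim", "blank"), pro)
  wa <- window_amplitude(blank_subtract(rec), start_ms = 35, dur_ms = 200)
  expect_equal(as.vector(wa$amplitude[1, , ]), rep(5, 16))

  # signal entirely outside the window contributes nothing
  data2 <- array(0, dim = c(2, 30, 4, 4))
  data2[1, 10:30, , ] <- 3
  rec2 <- shell_recording(data2, 20, c("stim", "blank"), pro)
  expect_equal(max(abs(window_amplitude(blank_subtract(rec2),
                                        35, 200)$amplitude)), 0)
  expect_error(window_amplitude(blank_subtract(rec), 35, 2000), "beyond the trial")
})

test_that("harmonic amplitude recovers sinusoid amplitudes and ignores other harmonics", {
  pro <- one_flash_protocol()
  tvec <- (0:29) / 20
  A <- 0.8; B <- 0.3
  mk_rec <- function(x) {
    data <- array(0, dim = c(2, 30, 3, 3))
    data[1, , , ] <- x
    shell_recording(data, 20, c("stim", "blank"), pro)
  }
  h <- function(x, f = NULL) {
    unname(harmonic_amplitude(blank_subtract(mk_rec(x)),
                              f_stim = f)$amplitude[1, 1, 1])
  }
  expect_equal(h(A * sin(2 * pi * 4 * tvec)), A, tolerance = 1e-9)
  expect_equal(h(rep(2.5, 30)), 0, tolerance = 1e-12)
  expect_equal(h(A * sin(2 * pi * 4 * tvec) + B * sin(2 * pi * 8 * tvec)), A,
               tolerance = 1e-9)
  # amplitude is phase invariant
  expect_equal(h(A * cos(2 * pi * 4 * tvec)), A, tolerance = 1e-9)
  expect_error(h(tvec, f = 3.3), "DFT bin")
})

test_that("window and harmonic amplitudes are linear in the movie", {
  pro <- one_flash_protocol()
  set.seed(21)
  d1 <- array(rnorm(2 * 30 * 16), c(2, 30, 4, 4)); d1[2, , , ] <- 0
  d2 <- array(rnorm(2 * 30 * 16), c(2, 30, 4, 4)); d2[2, , , ] <- 0
  cm1 <- blank_subtract(shell_recording(d1, 20, c("stim", "blank"), pro))
  cm2 <- blank_subtract(shell_recording(d2, 20, c("stim", "blank"), pro))
  cm3 <- cm1
  cm3$data <- 2 * cm1$data + 3 * cm2$data
  expect_equal(window_amplitude(cm3)$amplitude,
               2 * window_amplitude(cm1)$amplitude +
                 3 * window_amplitude(cm2)$amplitude, tolerance = 1e-12)
  # harmonic amplitude is linear for co-phased inputs (same complex phase)
  cm4 <- cm1
  cm4$data <- 5 * cm1$data
  expect_equal(harmonic_amplitude(cm4)$amplitude,
               5 * harmonic_amplitude(cm1)$amplitude, tolerance = 1e-12)
})

test_that("d-prime is mean over SD of single-trial amplitudes, NA when degenerate", {
  pro <- one_flash_protocol()
  data <- array(0, dim = c(5, 30, 4, 4))
  for (t in 1:3) data[t, , , ] <- t   # trial amplitudes 1, 2, 3
  rec <- shell_recording(data, 20, c("stim", "stim", "stim", "blank", "blank"), pro)
  dm <- dprime_map(rec, "window")
  expect_equal(as.vector(dm$dprime), rep(2, 16))   # mean 2, SD 1

  data2 <- data
  for (t in 1:3) data2[t, , , ] <- 2   # identical trials: SD 0
  rec2 <- shell_recording(data2, 20, c("stim", "stim", "stim", "blank", "blank"), pro)
  expect_true(all(is.na(dprime_map(rec2, "window")$dprime)))

  rec1 <- shell_recording(data[c(1, 4, 5), , , , drop = FALSE], 20,
                          c("stim", "blank", "blank"), pro)
  expect_error(dprime_map(rec1, "window"), "at least 2 trials")
})

test_that("ROI rules resolve to the stated pixel sets", {
  grid <- cortical_grid(pixel_size = 0.05, ny = 64, nx = 64)
  dp <- matrix(0, 64, 64)
  dp[20, 30] <- 10
  dmap <- structure(list(dprime = dp, grid = grid, method = "window"),
                    class = "dprime_map")
  roi <- resolve_roi(dmap, "max_dprime_square", side_mm = 1.6)
  expect_equal(sum(roi$mask), 32 * 32)   # 1.6 mm at 0.05 mm/pixel
  expect_true(roi$mask[20, 30])
  idx <- which(roi$mask, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(20 - 15, 20 + 16))

  dmap2 <- dmap
  dmap2$dprime <- matrix(5, 64, 64)
  expect_equal(sum(resolve_roi(dmap2, "dprime_threshold", threshold = 3)$mask),
               64 * 64)
  expect_error(resolve_roi(dmap2, "dprime_threshold", threshold = 10),
               "no pixels")

  roi3 <- resolve_roi(grid, "retinotopic_square", side_mm = 0.75,
                      center_mm = c(1.6, 1.6))
  expect_equal(sum(roi3$mask), 15 * 15)   # 0.75 mm -> 15 px
})

test_that("bandpass filter passes the columnar band, removes DC, and kills high frequencies", {
  n <- 64; px <- 0.05
  xk <- (0:(n - 1)) * px
  expect_lt(max(abs(bandpass_map(matrix(3, n, n), px))), 1e-10)
  probe <- function(f) {
    pl <- outer(rep(1, n), sin(2 * pi * f * xk))
    stats::sd(bandpass_map(pl, px)) / stats::sd(pl)
  }
  expect_gt(probe(1.5625), 0.99)   # in-band DFT frequency
  expect_lt(probe(1.5625), 1.01)
  expect_lt(probe(5.0), 0.01)      # stop band
  out <- bandpass_map(matrix(rnorm(n * n), n, n), px)
  expect_lt(abs(mean(out)), 1e-10)
  expect_error(bandpass_map(matrix(0, n, n), px, low = 3, high = 1), "exceed")
})

test_that("composite orientation maps perform the doubled-angle vector sum", {
  oris <- seq(0, 165, by = 15)
  mk_planes <- function(amps) {
    planes <- array(0, dim = c(12, 3, 3))
    for (k in 1:12) planes[k, , ] <- amps[k]
    planes
  }
  grid <- cortical_grid(pixel_size = 0.1, ny = 3, nx = 3)
  # single active condition
  a <- rep(0, 12); a[oris == 30] <- 1
  cm <- composite_orientation_map(mk_planes(a), oris, grid)
  expect_equal(as.vector(cm$preferred), rep(30, 9), tolerance = 1e-9)
  expect_equal(as.vector(cm$selectivity), rep(1, 9), tolerance = 1e-12)
  # equal amplitudes cancel
  cm2 <- composite_orientation_map(mk_planes(rep(1, 12)), oris, grid)
  expect_equal(max(cm2$selectivity), 0, tolerance = 1e-12)
  # half-rectified cosine pattern peaks at its generating orientation
  cm3 <- composite_orientation_map(
    mk_planes(pmax(0, cos(2 * (oris - 50) * pi / 180))), oris, grid)
  expect_equal(as.vector(cm3$preferred), rep(50, 9), tolerance = 0.5)
  # all-zero pixel: undefined preference, zero selectivity
  cm4 <- composite_orientation_map(mk_planes(rep(0, 12)), oris, grid)
  expect_true(all(is.na(cm4$preferred)))
  expect_equal(max(cm4$selectivity), 0)
})

test_that("grayscale conversion is sin(2 theta) with its fixed points", {
  expect_equal(grayscale_orientation_map(matrix(45)), matrix(1))
  expect_equal(grayscale_orientation_map(matrix(0)), matrix(0))
  expect_equal(grayscale_orientation_map(matrix(135)), matrix(-1))
  set.seed(5)
  p <- matrix(runif(100, 0, 180), 10)
  g <- grayscale_orientation_map(p)
  expect_true(all(g >= -1 & g <= 1))
  expect_equal(grayscale_orientation_map(p + 180), g, tolerance = 1e-12)
})

test_that("map correlations behave for identical, negated, and constant planes", {
  set.seed(6)
  g <- matrix(rnorm(64), 8)
  expect_equal(map_session_correlation(g, g), 1)
  expect_equal(map_session_correlation(g, -g), -1)
  expect_error(map_session_correlation(g, matrix(1, 8, 8)), "constant")
})

test_that("cycle collapsing anchors and averages flash cycles", {
  pat <- c(0, 2, 5, 3, 1)
  tc <- rep(pat, 4)
  out <- collapse_cycles(tc, 20, 4, anchor_ms = 50)   # 1 anchor frame
  expect_equal(out, pat - pat[1])
  # linear ramp: anchoring removes the cross-cycle offsets exactly
  ramp <- seq_len(40)
  out2 <- collapse_cycles(ramp, 20, 4, anchor_ms = 50)
  expect_equal(out2, 0:4)
  # anchor window covering the whole cycle gives a zero-mean cycle
  out3 <- collapse_cycles(tc, 20, 4, anchor_ms = 250)
  expect_equal(mean(out3), 0, tolerance = 1e-12)
  expect_error(collapse_cycles(tc, 20, 3, 50), "integer")
})
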
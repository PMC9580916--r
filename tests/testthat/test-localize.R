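test_that("DoG of a constant frame is zero and the operator is linear", {
  f <- matrix(5, 20, 20)
  expect_lt(max(abs(dog_filter(f, 1, 2))), 1e-9)
  set.seed(1)
  g <- matrix(runif(400), 20, 20)
  expect_equal(dog_filter(3 * g, 1, 2), 3 * dog_filter(g, 1, 2),
               tolerance = 1e-12)
  expect_error(dog_filter(array(0, c(2, 2, 2)), 1, 2), "2D")
  expect_error(dog_filter(f, 2, 1))
})

test_that("DoG impulse response equals the sampled kernel difference", {
  f <- matrix(0, 33, 33); f[17, 17] <- 1
  out <- dog_filter(f, 1, 2)
  kern <- function(s) {
    rad <- max(1, ceiling(4 * s))
    k <- exp(-0.5 * (-rad:rad)^2 / s^2); k / sum(k)
  }
  k1 <- kern(1); k2 <- kern(2)
  expected <- outer(c(rep(0, 16 - 4), k1, rep(0, 16 - 4)),
                    c(rep(0, 16 - 4), k1, rep(0, 16 - 4))) -
    outer(c(rep(0, 16 - 8), k2, rep(0, 16 - 8)),
          c(rep(0, 16 - 8), k2, rep(0, 16 - 8)))
  expect_equal(out, expected, tolerance = 1e-12)
  expect_equal(which(out == max(out), arr.ind = TRUE)[1, ], c(row = 17, col = 17))
})

test_that("candidate finding isolates bright Gaussian peaks", {
  blank <- matrix(0, 40, 40)
  expect_equal(nrow(find_candidates(blank, blank)), 0)
  # single Gaussian at (row 10, col 20), 0-based -> one candidate there
  f1 <- matrix(0, 40, 40)
  g <- psf_roi(0, 0, sigma = 1.3, h = 3, photons = 5000)
  f1[8:14, 18:24] <- g   # centre pixel at 1-based (11, 21) = 0-based (10, 20)
  got <- find_candidates(dog_filter(f1, 1, 2), f1)
  expect_equal(nrow(got), 1)
  expect_equal(unname(got[1, ]), c(10, 20))
  # two Gaussians 20 px apart -> two candidates
  f2 <- f1
  f2[28:34, 18:24] <- g
  got2 <- find_candidates(dog_filter(f2, 1, 2), f2)
  expect_equal(nrow(got2), 2)
})

test_that("close candidate pairs are both dropped (single-emitter ROI rule)", {
  f <- matrix(0, 40, 40)
  g <- psf_roi(0, 0, sigma = 1.0, h = 2, photons = 5000)
  f[10:14, 10:14] <- g
  f[10:14, 14:18] <- f[10:14, 14:18] + g   # peaks 4 px apart < 2*roi_halfsize
  got <- find_candidates(dog_filter(f, 1, 2), f)
  expect_equal(nrow(got), 0)
  got_keep <- find_candidates(dog_filter(f, 1, 2), f,
                              detection_params(min_separation_px = 0))
  expect_gte(nrow(got_keep), 1)
})

test_that("phasor anchor cases are exact", {
  # centred symmetric Gaussian -> (0, 0)
  p0 <- phasor_localize(psf_roi(0, 0))
  expect_equal(p0$dx, 0, tolerance = 1e-9)
  expect_equal(p0$dy, 0, tolerance = 1e-9)
  # delta at (col 5, row 3) of a 7x7 -> dx = +2, dy = 0 exactly
  roi <- matrix(0, 7, 7); roi[3 + 1, 5 + 1] <- 4
  p <- phasor_localize(roi)
  expect_identical(c(p$dx, p$dy), c(2, 0))
  # all delta positions agree with direct DFT phase evaluation
  for (u0 in 0:6) for (v0 in 0:6) {
    roi <- matrix(0, 7, 7); roi[v0 + 1, u0 + 1] <- 1
    p <- phasor_localize(roi)
    o <- oracle_phasor_delta(7, u0, v0)
    expect_equal(c(p$dx, p$dy), unname(o), tolerance = 1e-12)
  }
  # constant ROI is degenerate
  expect_true(phasor_localize(matrix(1, 7, 7))$degenerate)
})

test_that("phasor tracks sub-pixel offsets within 0.05 px of a Gaussian fit", {
  for (off in seq(-0.5, 0.5, 0.1)) {
    roi <- psf_roi(off, -off / 2)
    p <- phasor_localize(roi)
    o <- oracle_gaussfit_roi(roi)
    expect_lt(abs(p$dx - o[["dx"]]), 0.05)
    expect_lt(abs(p$dy - o[["dy"]]), 0.05)
    expect_lt(abs(p$dx - off), 0.05)       # and of the true offset
  }
})

test_that("well-separated static emitters are all recovered accurately", {
  pos <- cbind(c(10, 25, 10, 25, 17), c(10, 10, 25, 25, 17))
  sim <- simulate_movie(
    emitter_model(pos, k_on = 1, k_off = 0, photons_per_frame = 5000),
    noise_model(background_offset = 10, read_noise_sigma = 1),
    n_frames = 5, shape = c(36, 36), seed = 2)
  locs <- localize_movie(sim$movie)
  expect_equal(nrow(locs), 5 * 5)
  # match each localization to nearest truth, RMS error < 0.1 px
  err <- sapply(seq_len(nrow(locs)), function(i) {
    min(sqrt((pos[, 1] - locs$x[i])^2 + (pos[, 2] - locs$y[i])^2))
  })
  expect_lt(sqrt(mean(err^2)), 0.1)
})

test_that("blank movies localize to an empty table", {
  m <- smlm_movie(array(3, c(20, 20, 3)))
  expect_equal(nrow(localize_movie(m)), 0)
})

test_that("integer frame shifts shift localizations exactly", {
  sim <- simulate_movie(
    emitter_model(cbind(15.3, 14.6), k_on = 1, k_off = 0,
                  photons_per_frame = 8000),
    noise_model(background_offset = 5, poisson = FALSE),
    n_frames = 1, shape = c(32, 32), seed = 3)
  f <- get_frame(sim$movie, 0)
  shifted <- matrix(0, 32, 32)
  shifted[4:32, 3:32] <- f[1:29, 1:30]   # shift by (+3 rows, +2 cols)
  l1 <- localize_movie(smlm_movie(f))
  l2 <- localize_movie(smlm_movie(shifted))
  expect_equal(l2$x, l1$x + 2, tolerance = 1e-9)
  expect_equal(l2$y, l1$y + 3, tolerance = 1e-9)
})

test_that("localizations never leave their source ROI", {
  set.seed(9)
  pos <- cbind(runif(8, 8, 40), runif(8, 8, 40))
  sim <- simulate_movie(
    emitter_model(pos, k_on = 0.5, k_off = 0.5, photons_per_frame = 2000),
    noise_model(background_offset = 15, read_noise_sigma = 2),
    n_frames = 20, shape = c(48, 48), seed = 10)
  filt <- temporal_median_filter(sim$movie, 11)
  locs <- localize_movie(sim$movie, filt)
  # x = col + 0.5 + dx with |dx| <= h (phasor range), so fractional offsets
  # stay within the ROI half-width of the peak pixel
  expect_true(all(abs(locs$x - (floor(locs$x) + 0.5)) <= 0.5 + 1e-9))
  expect_gt(nrow(locs), 0)
})
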
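test_that("jump extraction gives exact distances and honours gaps", {
  tab <- loc_table(frame = c(0, 1, 2), x = c(0, 3, 3), y = c(0, 4, 4),
                   intensity = 1, track_id = 0L)
  j <- extract_jumps(tab)
  expect_equal(sort(j$r), c(0, 5))
  gap <- loc_table(frame = c(0, 2), x = c(0, 1), y = c(0, 0), intensity = 1,
                   track_id = 0L)
  expect_equal(length(extract_jumps(gap)$r), 0)
  unassigned <- loc_table(frame = 0:1, x = c(0, 1), y = c(0, 0), intensity = 1)
  expect_equal(length(extract_jumps(unassigned)$r), 0)
})

test_that("simulator jump counts match the truth bookkeeping", {
  sim <- simulate_tracks(40, 0.3, n_frames = 15, p_blink = 0.2, seed = 2)
  df <- as.data.frame(sim$table)
  expected <- sum(vapply(split(df$frame, df$track_id),
                         function(f) sum(diff(sort(f)) == 1), numeric(1)))
  expect_equal(length(extract_jumps(sim$table)$r), expected)
})

test_that("the fitted mixture density integrates to 1", {
  for (k in 1:3) {
    D <- c(0.05, 0.4, 2)[1:k]; f <- rep(1 / k, k)
    igr <- integrate(jd_density, 0, Inf, D = D, fractions = f)
    expect_equal(igr$value, 1, tolerance = 1e-6)
  }
})

test_that("single-population JD fit recovers D within 5%", {
  D <- 0.5
  sim <- simulate_tracks(500, D, n_frames = 21, seed = 9)
  jumps <- extract_jumps(sim$table)
  expect_gte(length(jumps$r), 1e4)
  fit <- fit_jd(jumps, 1)
  expect_lt(abs(fit$D - D) / D, 0.05)
  expect_false(fit$bin_sensitive)
})

test_that("two-population JD fit recovers both D and the fractions", {
  D <- c(0.05, 1.0); f <- c(0.5, 0.5)
  sim <- simulate_tracks(1100, D, f, n_frames = 21, seed = 10)
  jumps <- extract_jumps(sim$table)
  expect_gte(length(jumps$r), 2e4)
  fit <- fit_jd(jumps, 2)
  expect_lt(abs(fit$D[1] - D[1]) / D[1], 0.10)
  expect_lt(abs(fit$D[2] - D[2]) / D[2], 0.10)
  expect_lt(abs(fit$fractions[1] - 0.5), 0.05)
})

test_that("a single-population fit on mixed data is clearly worse", {
  sim <- simulate_tracks(1100, c(0.05, 1.0), c(0.5, 0.5), n_frames = 21,
                         seed = 10)
  jumps <- extract_jumps(sim$table)
  f1 <- fit_jd(jumps, 1)
  f2 <- fit_jd(jumps, 2)
  expect_gt(f1$resid_ss, 5 * f2$resid_ss)
})

test_that("MLE cross-check agrees with the histogram fit", {
  sim <- simulate_tracks(500, 0.5, n_frames = 21, seed = 12)
  jumps <- extract_jumps(sim$table)
  hfit <- fit_jd(jumps, 1)
  mfit <- fit_jd(jumps, 1, method = "mle")
  expect_lt(abs(hfit$D - mfit$D) / mfit$D, 0.05)
})

test_that("frozen particles give all-zero mean jump distances", {
  sim <- simulate_tracks(30, 1e-30, n_frames = 10, seed = 1)
  fit <- fit_mjd(sim$table, 1)
  expect_equal(fit$D, 0)
})

test_that("mJD Gaussian mean matches sqrt(pi D tau) for long tracks", {
  D <- 0.4
  sim <- simulate_tracks(500, D, n_frames = 51, seed = 13)
  fit <- fit_mjd(sim$table, 1, min_jumps_per_track = 40)
  expected <- sqrt(pi * D)
  se <- sd(fit$mjd) / sqrt(length(fit$mjd))
  expect_lt(abs(fit$mjd_means - expected), 3 * se + 0.01 * expected)
  expect_lt(abs(fit$D - D) / D, 0.10)
})

test_that("mJD separates close populations better than pooled JD", {
  # D1/D2 = 2: heavily overlapping Rayleighs, but per-track means separate
  D <- c(0.3, 0.6)
  sim <- simulate_tracks(600, D, c(0.5, 0.5), n_frames = 51, seed = 14)
  jumps <- extract_jumps(sim$table)
  mfit <- fit_mjd(sim$table, 2, min_jumps_per_track = 40)
  # separation statistic: gap between component means over mean width
  sep_mjd <- abs(diff(mfit$mjd_means)) / mean(mfit$mjd_sds)
  # pooled JD: same statistic on the Rayleigh modes sqrt(2 D tau) over the
  # Rayleigh sd sqrt((4 - pi) D tau)
  jfit <- fit_jd(jumps, 2)
  modes <- sqrt(2 * jfit$D)
  widths <- sqrt((4 - pi) * jfit$D)
  sep_jd <- abs(diff(modes)) / mean(widths)
  expect_gt(sep_mjd, sep_jd)
})

test_that("MSD of a 2-point track is exact and slopes recover D", {
  two <- loc_table(frame = 0:1, x = c(0, 1), y = c(0, 0), intensity = 1,
                   track_id = 0L)
  m <- compute_msd(two)
  expect_equal(m$msd[1], 1)
  expect_equal(m$n_pairs[1], 1L)
  # Brownian ensemble: slope/4 within 5% of D, intercept near 0
  D <- 0.35
  sim <- simulate_tracks(800, D, n_frames = 21, seed = 15)
  mc <- compute_msd(sim$table)
  expect_lt(abs(mc$D - D) / D, 0.05)
  # intercept consistent with zero: within sampling error of the fit,
  # and in any case small against the per-lag MSD scale 4*D
  expect_lt(abs(mc$intercept), max(3 * mc$intercept_se, 0.02 * 4 * D))
  expect_true(all(diff(mc$n_pairs) <= 0))
})

test_that("static emitters yield slope ~0 and intercept ~4 sigma^2", {
  sigma <- 0.1
  tab <- simulate_static_locs(cbind(runif(300, 0, 50), runif(300, 0, 50)),
                              21, sigma_loc_px = sigma, seed = 16)
  m <- compute_msd(tab)
  expect_lt(abs(m$D), 0.001)
  expect_lt(abs(m$intercept - 4 * sigma^2) / (4 * sigma^2), 0.10)
  expect_lt(abs(m$sigma_loc - sigma) / sigma, 0.10)
})

test_that("D estimates from JD, mJD and MSD agree on one population", {
  D <- 0.5
  sim <- simulate_tracks(600, D, n_frames = 41, seed = 17)
  jd <- fit_jd(extract_jumps(sim$table), 1)$D
  mjd <- fit_mjd(sim$table, 1, min_jumps_per_track = 30)$D
  msd <- compute_msd(sim$table)$D
  expect_lt(max(abs(c(jd, mjd, msd) - D)) / D, 0.10)
})
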
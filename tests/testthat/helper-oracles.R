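# Independent reference implementations used as oracles. These deliberately
# use the naive formulation (per-pixel loops, exhaustive search) so they stay
# independent of the production code paths they check.

# naive per-pixel, per-frame sliding temporal median with shifted edge windows
oracle_temporal_median <- function(arr, i, clamp = TRUE) {
  d <- dim(arr)
  nf <- d[3]
  half <- (i - 1) %/% 2
  out <- array(0, d)
  for (t in seq_len(nf)) {
    s <- min(max(t - 1 - half, 0), nf - i)
    win <- (s + 1):(s + i)
    for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
      out[r, cc, t] <- arr[r, cc, t] - median(arr[r, cc, win])
    }
  }
  if (clamp) out[out < 0] <- 0
  out
}

# brute-force DBSCAN: exhaustive neighbour matrix + BFS over core points,
# edge points to the lowest adjacent label
oracle_dbscan <- function(xy, eps, min_points, count_self = TRUE) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  nb <- d <= eps
  if (!count_self) diag(nb) <- FALSE
  core <- rowSums(nb) >= min_points
  lab <- rep(-1L, n)
  nl <- 0L
  for (s in seq_len(n)) {
    if (!core[s] || lab[s] >= 0) next
    lab[s] <- nl
    queue <- s
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      nxt <- which(nb[p, ] & core & lab < 0)
      lab[nxt] <- nl
      queue <- c(queue, nxt)
    }
    nl <- nl + 1L
  }
  for (p in which(!core)) {
    adj <- lab[nb[p, ] & core]
    if (length(adj)) lab[p] <- min(adj)
  }
  lab
}

# direct DFT first-order phase evaluation for a delta ROI (col u0, row v0,
# both 0-based)
oracle_phasor_delta <- function(N, u0, v0) {
  h <- (N - 1) %/% 2
  ang_x <- -2 * pi * u0 / N
  ang_y <- -2 * pi * v0 / N
  pos <- function(ang) ((-ang * N / (2 * pi)) %% N) - h
  c(dx = pos(ang_x), dy = pos(ang_y))
}

# noiseless pixel-integrated Gaussian PSF ROI (pixel-centre convention:
# ROI centre pixel centre at offset (0,0))
psf_roi <- function(dx, dy, sigma = 1.3, h = 3, photons = 1000) {
  N <- 2 * h + 1
  fx <- diff(pnorm(seq(0, N), mean = h + 0.5 + dx, sd = sigma))
  fy <- diff(pnorm(seq(0, N), mean = h + 0.5 + dy, sd = sigma))
  photons * (fy %o% fx)
}

# least-squares 2D Gaussian fit on an ROI (the slow reference localizer)
oracle_gaussfit_roi <- function(roi, sigma0 = 1.3) {
  N <- nrow(roi)
  h <- (N - 1) / 2
  # moment-based initial centre
  w <- sum(roi)
  cx0 <- sum(roi %*% cbind((1:N) - 0.5)) / w
  cy0 <- sum(cbind((1:N) - 0.5) * rowSums(roi)) / w
  obj <- function(th) {
    fx <- diff(pnorm(seq(0, N), th[1], th[3]))
    fy <- diff(pnorm(seq(0, N), th[2], th[3]))
    sum((roi - th[4] * (fy %o% fx))^2)
  }
  fit <- suppressWarnings(
    optim(c(cx0, cy0, sigma0, w), obj,
          control = list(maxit = 5000, reltol = 1e-14)))
  c(dx = fit$par[1] - (h + 0.5), dy = fit$par[2] - (h + 0.5))
}

# analytic CDF of a Rayleigh mixture of single-frame jump distances
jd_mixture_cdf <- function(r, D, fractions, tau = 1) {
  out <- numeric(length(r))
  for (i in seq_along(D))
    out <- out + fractions[i] * (1 - exp(-r^2 / (4 * D[i] * tau)))
  out
}

# random loc_table helper (sorted by frame, as produced by localization)
rand_table <- function(n, box = 20, seed = 1, frames = 10) {
  set.seed(seed)
  f <- sort(sample(0:(frames - 1), n, TRUE))
  loc_table(frame = f, x = runif(n, 0, box), y = runif(n, 0, box),
            intensity = runif(n, 100, 1000))
}
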
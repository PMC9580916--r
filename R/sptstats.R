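#' Extract single-frame jump distances from tracked localizations
#'
#' For every track, the Euclidean distance between localizations exactly one
#' frame apart is collected; pairs spanning a blinking gap are excluded.
#' Unassigned rows (`track_id == -1`) are ignored.
#'
#' @param table a `loc_table` with `track_id` assigned.
#' @return a `jump_set`: list with `r` (distances, px), `tau_frames` (1),
#'   `track_id` (source track per jump) and `frame_interval_s`.
#' @export
extract_jumps <- function(table) {
  df <- as.data.frame(table)
  df <- df[df$track_id >= 0, , drop = FALSE]
  r <- numeric(0); src <- integer(0)
  if (nrow(df)) {
    df <- df[order(df$track_id, df$frame), , drop = FALSE]
    same <- df$track_id[-1] == df$track_id[-nrow(df)]
    consec <- df$frame[-1] - df$frame[-nrow(df)] == 1
    i <- which(same & consec)
    r <- sqrt((df$x[i + 1] - df$x[i])^2 + (df$y[i + 1] - df$y[i])^2)
    src <- df$track_id[i]
  }
  structure(list(r = r, tau_frames = 1, track_id = src,
                 frame_interval_s = attr(table, "frame_interval_s")),
            class = "jump_set")
}

#' Rayleigh-mixture jump-distance density
#'
#' Single-frame jump distances of 2D Brownian motion follow a noncentral
#' chi (Rayleigh) law; a mixture of `k` diffusive states has density
#' `p(r) = sum_i f_i * r/(2 D_i tau) * exp(-r^2 / (4 D_i tau))`.
#'
#' @param r distances.
#' @param D diffusion coefficients (px^2/frame).
#' @param fractions mixture fractions summing to 1.
#' @param tau frame interval in frames (default 1).
#' @return density values.
#' @export
jd_density <- function(r, D, fractions, tau = 1) {
  out <- numeric(length(r))
  for (i in seq_along(D))
    out <- out + fractions[i] * r / (2 * D[i] * tau) * exp(-r^2 / (4 * D[i] * tau))
  out
}

softmax_fracs <- function(g) {
  w <- exp(c(g, 0))
  w / sum(w)
}

#' Fit a Rayleigh mixture to a jump-distance histogram
#'
#' Least-squares fit of [jd_density] to the normalized jump-distance
#' histogram, initialised from quantiles of `r^2 / (4 tau)`. Because the bin
#' count can influence histogram fits, the fit is repeated at half and twice
#' `n_bins`; the result is flagged when any diffusion coefficient moves by
#' more than 10 percent. A maximum-likelihood fit on the raw distances is
#' available as a bin-free cross-check via `method = "mle"`.
#'
#' @param jumps a `jump_set` from [extract_jumps].
#' @param n_populations number of diffusive states (1-3).
#' @param n_bins histogram bin count.
#' @param tau frame interval in frames.
#' @param method `"histogram"` (default) or `"mle"`.
#' @return a `diffusion_fit`: list with `D` (ascending), `fractions`,
#'   `n_populations`, `resid_ss`, `bin_sensitive` flag, `hist` (mids,
#'   density) and `n_jumps`.
#' @export
fit_jd <- function(jumps, n_populations = 1, n_bins = 50, tau = 1,
                   method = c("histogram", "mle")) {
  method <- match.arg(method)
  stopifnot(n_populations %in% 1:3)
  r <- jumps$r[jumps$r >= 0]
  if (length(r) < 10 * n_populations) stop("too few jumps to fit")
  k <- n_populations
  D0 <- quantile(r^2 / (4 * tau), probs = (2 * seq_len(k) - 1) / (2 * k),
                 names = FALSE)
  D0 <- pmax(D0, 1e-8)
  fit_once <- function(nb) {
    h <- graphics::hist(r, breaks = nb, plot = FALSE)
    dens <- h$density; mids <- h$mids
    resid_fun <- function(th) {
      D <- exp(th[1:k])
      f <- if (k > 1) softmax_fracs(th[(k + 1):(2 * k - 1)]) else 1
      dens - jd_density(mids, D, f, tau)
    }
    th0 <- c(log(D0), rep(0, k - 1))
    fit <- minpack.lm::nls.lm(th0, fn = resid_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    if (fit$info == 0) stop("jump-distance fit did not converge")
    D <- exp(fit$par[1:k])
    f <- if (k > 1) softmax_fracs(fit$par[(k + 1):(2 * k - 1)]) else 1
    ord <- order(D)
    list(D = D[ord], fractions = f[ord], resid_ss = sum(resid_fun(fit$par)^2),
         hist = list(mids = mids, density = dens))
  }
  if (method == "mle") {
    nll <- function(th) {
      D <- exp(th[1:k])
      f <- if (k > 1) softmax_fracs(th[(k + 1):(2 * k - 1)]) else 1
      -sum(log(pmax(jd_density(r, D, f, tau), 1e-300)))
    }
    opt <- stats::optim(c(log(D0), rep(0, k - 1)), nll, method = "BFGS")
    D <- exp(opt$par[1:k])
    f <- if (k > 1) softmax_fracs(opt$par[(k + 1):(2 * k - 1)]) else 1
    ord <- order(D)
    return(structure(list(D = D[ord], fractions = f[ord], n_populations = k,
                          resid_ss = opt$value, bin_sensitive = FALSE,
                          hist = NULL, n_jumps = length(r), tau = tau,
                          method = "mle"),
                     class = "diffusion_fit"))
  }
  main <- fit_once(n_bins)
  sens <- FALSE
  for (nb in c(max(5, round(n_bins / 2)), 2 * n_bins)) {
    alt <- tryCatch(fit_once(nb), error = function(e) NULL)
    if (!is.null(alt) && any(abs(alt$D - main$D) / main$D > 0.10)) sens <- TRUE
  }
  if (k > 1 && any(main$fractions < 1e-4))
    warning("a mixture fraction is pinned near 0; consider fewer populations")
  structure(list(D = main$D, fractions = main$fractions, n_populations = k,
                 resid_ss = main$resid_ss, bin_sensitive = sens,
                 hist = main$hist, n_jumps = length(r), tau = tau,
                 method = "histogram"),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion_fit (%s, %d jumps): ", x$method, x$n_jumps))
  cat(paste(sprintf("D=%.4g (f=%.2f)", x$D, x$fractions), collapse = ", "), "\n")
  if (isTRUE(x$bin_sensitive))
    cat("  note: fit is sensitive to the histogram bin count\n")
  invisible(x)
}

#' Fit a Gaussian mixture to per-track mean jump distances
#'
#' The mean jump distance (mJD) of a trajectory averages out the Rayleigh
#' spread, so per-track means of sufficiently long tracks are approximately
#' Gaussian (central limit theorem) and populations with similar D separate
#' more cleanly than in the pooled jump-distance histogram. Gaussian means
#' are converted to diffusion coefficients through the Rayleigh mean
#' `E[r] = sqrt(pi * D * tau)` (pure 2D Brownian motion assumed).
#'
#' @param table a tracked `loc_table`.
#' @param n_populations number of Gaussian components (1-3).
#' @param min_jumps_per_track minimum jumps for a track to qualify
#'   (default 4).
#' @param n_bins histogram bin count.
#' @param tau frame interval in frames.
#' @return a `diffusion_fit` with extra fields `mjd_means`, `mjd_sds` and
#'   `mjd` (the per-track values).
#' @export
fit_mjd <- function(table, n_populations = 1, min_jumps_per_track = 4,
                    n_bins = 30, tau = 1) {
  stopifnot(n_populations %in% 1:3)
  jumps <- extract_jumps(table)
  if (!length(jumps$r)) stop("no jumps available")
  cnt <- tapply(jumps$r, jumps$track_id, length)
  keep <- as.integer(names(cnt)[cnt >= min_jumps_per_track])
  if (length(keep) < 5) stop("too few tracks with enough jumps")
  mjd <- tapply(jumps$r[jumps$track_id %in% keep],
                jumps$track_id[jumps$track_id %in% keep], mean)
  mjd <- as.numeric(mjd)
  k <- n_populations
  if (max(mjd) <= 0) {
    # frozen particles: all mean jumps zero, D = 0 exactly
    return(structure(list(D = rep(0, k), fractions = rep(1 / k, k),
                          n_populations = k, resid_ss = 0,
                          bin_sensitive = FALSE, hist = NULL,
                          n_jumps = length(jumps$r), tau = tau,
                          method = "mjd", mjd_means = rep(0, k),
                          mjd_sds = rep(0, k), mjd = mjd),
                     class = "diffusion_fit"))
  }
  h <- graphics::hist(mjd, breaks = n_bins, plot = FALSE)
  mids <- h$mids; dens <- h$density
  mu0 <- quantile(mjd, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  s0 <- rep(max(sd(mjd) / k, 1e-6), k)
  resid_fun <- function(th) {
    mu <- th[1:k]; s <- exp(th[(k + 1):(2 * k)])
    f <- if (k > 1) softmax_fracs(th[(2 * k + 1):(3 * k - 1)]) else 1
    model <- numeric(length(mids))
    for (i in seq_len(k))
      model <- model + f[i] * stats::dnorm(mids, mu[i], s[i])
    dens - model
  }
  th0 <- c(mu0, log(s0), rep(0, k - 1))
  fit <- minpack.lm::nls.lm(th0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  mu <- fit$par[1:k]; s <- exp(fit$par[(k + 1):(2 * k)])
  f <- if (k > 1) softmax_fracs(fit$par[(2 * k + 1):(3 * k - 1)]) else 1
  ord <- order(mu)
  mu <- mu[ord]; s <- s[ord]; f <- if (k > 1) f[ord] else f
  structure(list(D = pmax(mu, 0)^2 / (pi * tau), fractions = f,
                 n_populations = k, resid_ss = sum(resid_fun(fit$par)^2),
                 bin_sensitive = FALSE,
                 hist = list(mids = mids, density = dens),
                 n_jumps = length(jumps$r), tau = tau, method = "mjd",
                 mjd_means = mu, mjd_sds = s, mjd = mjd),
            class = "diffusion_fit")
}

#' Ensemble mean squared displacement with linear fit
#'
#' Pools squared displacements over all tracks and all starting positions
#' for each lag, then fits `msd = 4 D dt + 4 sigma_loc^2` by weighted least
#' squares over the first `fit_lags` lags (short-lag restriction guards
#' against the noise accumulated by long-lag points of short tracks).
#'
#' @param table a tracked `loc_table`.
#' @param fit_lags number of initial lags used in the fit (default 4).
#' @param tau frame interval in frames.
#' @return an `msd_curve`: list with `lag`, `msd`, `n_pairs`, `D`,
#'   `sigma_loc` (clipped at 0 when the intercept is negative) and
#'   `intercept`.
#' @export
compute_msd <- function(table, fit_lags = 4, tau = 1) {
  df <- as.data.frame(table)
  df <- df[df$track_id >= 0, , drop = FALSE]
  if (nrow(df) == 0) stop("no tracked localizations")
  tracks <- split(df[, c("frame", "x", "y")], df$track_id)
  maxlen <- max(vapply(tracks, function(t) diff(range(t$frame)) + 1, numeric(1)))
  if (maxlen < 2) stop("no track is longer than one frame")
  nlag <- as.integer(maxlen - 1)
  ssum <- numeric(nlag); npair <- integer(nlag)
  for (tr in tracks) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lag <- tr$frame[j] - tr$frame[i]
      if (lag > nlag) next
      ssum[lag] <- ssum[lag] + (tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2
      npair[lag] <- npair[lag] + 1L
    }
  }
  ok <- npair > 0
  lag <- which(ok)
  msd <- ssum[ok] / npair[ok]
  np <- npair[ok]
  usel <- lag <= fit_lags
  if (sum(usel) < 2) usel <- seq_len(min(2, length(lag)))
  fit <- stats::lm(msd[usel] ~ lag[usel], weights = np[usel])
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(list(lag = lag, msd = msd, n_pairs = np,
                 D = slope / (4 * tau),
                 sigma_loc = sqrt(max(icpt, 0) / 4),
                 intercept = icpt, intercept_se = unname(ses[1]),
                 slope_se = unname(ses[2])),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("msd_curve: %d lags, D = %.4g px^2/frame, sigma_loc = %.4g px\n",
              length(x$lag), x$D, x$sigma_loc))
  invisible(x)
}
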
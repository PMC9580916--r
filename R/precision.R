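#' Image resolution by Fourier ring correlation
#'
#' The localization table is split uniformly at random (seeded) into two
#' halves; both are rendered as 2D histograms on a common zero-padded
#' square; the ring-wise correlation of their Fourier transforms
#' `FRC(q) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)` is computed
#' at integer radial frequency indices, smoothed by a centred moving
#' average, and the resolution read off as `1/q` at the first downward
#' crossing of the threshold (1/7 by default), linearly interpolated
#' between rings. A random split is used rather than odd/even frames, which
#' would overestimate resolution by correlating re-detections of the same
#' emitters.
#'
#' Only meaningful for structurally static data.
#'
#' @param table a `loc_table` with `pixel_size_nm` metadata.
#' @param render_pixel_nm render pixel size of the half-images in nm
#'   (default 10; should be comfortably below the expected resolution).
#' @param seed seed for the random split.
#' @param threshold FRC threshold (default 1/7).
#' @param smooth_span moving-average span in rings (default 7).
#' @return an `frc_curve`: list with `q` (1/nm per ring), `frc` (raw),
#'   `frc_smooth`, `threshold`, `resolution_nm` (NA when the curve never
#'   crosses the threshold before Nyquist), `render_pixel_nm`, `n_side`.
#' @export
frc_resolution <- function(table, render_pixel_nm = 10, seed = 1,
                           threshold = 1 / 7, smooth_span = 7) {
  df <- as.data.frame(table)
  if (nrow(df) < 2) stop("need at least 2 localizations for FRC")
  px_nm <- attr(table, "pixel_size_nm") %||% 100
  x_nm <- df$x * px_nm; y_nm <- df$y * px_nm
  set.seed(seed)
  half <- runif(nrow(df)) < 0.5
  if (!any(half) || all(half)) stop("random split produced an empty half")
  span_nm <- max(max(x_nm) - min(x_nm), max(y_nm) - min(y_nm))
  bins_needed <- ceiling(span_nm / render_pixel_nm) + 1
  N <- stats::nextn(bins_needed + 16, 2)     # zero-padded square side
  x0 <- min(x_nm) - (N - bins_needed) / 2 * render_pixel_nm
  y0 <- min(y_nm) - (N - bins_needed) / 2 * render_pixel_nm
  rasterize <- function(sel) {
    cx <- floor((x_nm[sel] - x0) / render_pixel_nm) + 1L
    cy <- floor((y_nm[sel] - y0) / render_pixel_nm) + 1L
    ok <- cx >= 1 & cx <= N & cy >= 1 & cy <= N
    matrix(tabulate((cx[ok] - 1L) * N + cy[ok], nbins = N * N), N, N)
  }
  F1 <- fft(rasterize(half))
  F2 <- fft(rasterize(!half))
  k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  kr <- sqrt(outer(k^2, k^2, "+"))
  ring <- round(kr)
  nring <- N %/% 2
  idx <- ring + 1L
  sel <- ring < nring
  ringsum <- function(v) {
    out <- numeric(nring)
    agg <- tapply(v[sel], idx[sel], sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  }
  num <- ringsum(Re(F1 * Conj(F2)))
  den1 <- ringsum(Mod(F1)^2)
  den2 <- ringsum(Mod(F2)^2)
  frc <- num / sqrt(den1 * den2)
  frc[!is.finite(frc)] <- 0
  sm <- moving_average(frc, smooth_span)
  q <- (seq_along(frc) - 1) / (N * render_pixel_nm)
  resolution <- NA_real_
  for (i in seq_len(length(sm) - 1)) {
    if (sm[i] >= threshold && sm[i + 1] < threshold) {
      frac <- (sm[i] - threshold) / (sm[i] - sm[i + 1])
      ring_star <- (i - 1) + frac
      q_star <- ring_star / (N * render_pixel_nm)
      resolution <- 1 / q_star
      break
    }
  }
  structure(list(q = q, frc = frc, frc_smooth = sm, threshold = threshold,
                 resolution_nm = resolution, render_pixel_nm = render_pixel_nm,
                 n_side = N, seed = seed),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  if (is.finite(x$resolution_nm))
    cat(sprintf("frc_curve: resolution %.1f nm at threshold %.3f (render px %g nm)\n",
                x$resolution_nm, x$threshold, x$render_pixel_nm))
  else
    cat("frc_curve: threshold not crossed before Nyquist (resolution not reached)\n")
  invisible(x)
}

#' Localization precision by nearest-neighbour analysis (NeNA)
#'
#' In non-merged data, most nearest-neighbour pairs in adjacent frames are
#' re-detections of the same (static) emitter, so their true distance is
#' zero and the observed distance distribution reflects the localization
#' error alone: with per-axis precision sigma, the adjacent-frame distance
#' follows `p(d) = d/(2 sigma^2) * exp(-d^2 / (4 sigma^2))` (a noncentral
#' chi law; each coordinate difference has variance `2 sigma^2`). The fit
#' of this density to the distance histogram yields sigma.
#'
#' @param table a non-merged `loc_table`.
#' @param capture_radius_px nearest-neighbour search radius (default 2 px);
#'   pairs farther apart are treated as unrelated emitters and dropped.
#' @param intensity_split optional intensity threshold: the table is
#'   partitioned into dim (`< threshold`, e.g. PALM) and bright
#'   (`>= threshold`, e.g. fiducial) subsets fitted separately.
#' @param n_bins histogram bin count for the fit.
#' @return a `nena_fit`: list with `sigma_px`, `sigma_nm`, `n_distances`,
#'   `distances`, `hist`; with `intensity_split`, a list of two `nena_fit`s
#'   (`dim`, `bright`).
#' @export
nena_precision <- function(table, capture_radius_px = 2,
                           intensity_split = NULL, n_bins = 50) {
  if (!is.null(intensity_split)) {
    df <- as.data.frame(table)
    lo <- keep_loc_attrs(df[df$intensity < intensity_split, , drop = FALSE], table)
    hi <- keep_loc_attrs(df[df$intensity >= intensity_split, , drop = FALSE], table)
    return(list(dim = nena_precision(lo, capture_radius_px, NULL, n_bins),
                bright = nena_precision(hi, capture_radius_px, NULL, n_bins)))
  }
  df <- as.data.frame(table)
  px_nm <- attr(table, "pixel_size_nm") %||% 100
  d_all <- numeric(0)
  by_frame <- split(seq_len(nrow(df)), df$frame)
  frames <- as.integer(names(by_frame))
  for (f in frames) {
    nxt <- by_frame[[as.character(f + 1L)]]
    cur <- by_frame[[as.character(f)]]
    if (is.null(nxt) || !length(cur)) next
    dx <- outer(df$x[cur], df$x[nxt], "-")
    dy <- outer(df$y[cur], df$y[nxt], "-")
    dmin <- apply(sqrt(dx^2 + dy^2), 1, min)
    d_all <- c(d_all, dmin[dmin <= capture_radius_px])
  }
  if (length(d_all) < 10) stop("too few adjacent-frame neighbour distances for NeNA")
  if (length(d_all) < 100)
    warning("fewer than 100 distances; NeNA fit may be unreliable")
  if (max(d_all) <= 0)
    stop("degenerate NeNA input: all adjacent-frame distances are zero")
  h <- graphics::hist(d_all, breaks = n_bins, plot = FALSE)
  resid_fun <- function(th) {
    s <- exp(th)
    h$density - h$mids / (2 * s^2) * exp(-h$mids^2 / (4 * s^2))
  }
  fit <- minpack.lm::nls.lm(log(sd(d_all) / sqrt(2)), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0) stop("NeNA fit did not converge")
  sigma <- exp(fit$par)
  structure(list(sigma_px = sigma, sigma_nm = sigma * px_nm,
                 n_distances = length(d_all), distances = d_all,
                 hist = list(mids = h$mids, density = h$density),
                 capture_radius_px = capture_radius_px),
            class = "nena_fit")
}

#' @export
print.nena_fit <- function(x, ...) {
  cat(sprintf("nena_fit: sigma = %.4g px (%.2f nm) from %d distances\n",
              x$sigma_px, x$sigma_nm, x$n_distances))
  invisible(x)
}
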
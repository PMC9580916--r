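#' Fiducial-based drift estimation
#'
#' Fiducial markers are bright, continuously emitting beads present through
#' (almost) the whole acquisition. They are identified here by their
#' constant signal: after nearest-neighbour linking, any track spanning at
#' least `min_presence_fraction` of the movie qualifies. Each marker's
#' per-frame displacement is taken relative to its own first observation
#' (avoiding bias when markers appear on different frames), traces are
#' averaged across markers, missing frames filled by linear interpolation,
#' optionally smoothed by a centred moving average, and the result re-zeroed
#' at frame 0.
#'
#' @param table a `loc_table` (linked or not; when `track_id` is unassigned
#'   the table is linked with `link_radius_px` and gap tolerance 2).
#' @param n_frames total number of movie frames.
#' @param min_presence_fraction minimal track span (fraction of `n_frames`)
#'   for a track to qualify as a fiducial.
#' @param link_radius_px linking radius used when the table is unlinked.
#' @param smoothing_window_frames odd moving-average window (1 = none).
#' @return list with `trace` (a [drift_trace], reference frame 0) and
#'   `fiducial_ids` (track ids classified as fiducials).
#' @export
estimate_drift_fiducial <- function(table, n_frames,
                                    min_presence_fraction = 0.9,
                                    link_radius_px = 1.0,
                                    smoothing_window_frames = 1) {
  stopifnot(min_presence_fraction > 0, min_presence_fraction <= 1)
  df <- as.data.frame(table)
  if (nrow(df) == 0 || all(df$track_id < 0)) {
    table <- link_localizations(table, link_params(link_radius_px, 2L),
                                auto_sort = TRUE)
    df <- as.data.frame(table)
  }
  spans <- tapply(df$frame, df$track_id, function(f) diff(range(f)) + 1)
  fid_ids <- as.integer(names(spans)[spans >= min_presence_fraction * n_frames])
  if (length(fid_ids) == 0)
    stop(sprintf(paste0("no fiducial track found: longest track spans %d of %d ",
                        "frames (need >= %.0f%%)"),
                 as.integer(max(spans)), n_frames, 100 * min_presence_fraction))
  acc_x <- matrix(NA_real_, n_frames, length(fid_ids))
  acc_y <- matrix(NA_real_, n_frames, length(fid_ids))
  for (k in seq_along(fid_ids)) {
    tr <- df[df$track_id == fid_ids[k], , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    acc_x[tr$frame + 1L, k] <- tr$x - tr$x[1]
    acc_y[tr$frame + 1L, k] <- tr$y - tr$y[1]
  }
  dx <- rowMeans(acc_x, na.rm = TRUE)
  dy <- rowMeans(acc_y, na.rm = TRUE)
  fill <- function(v) {
    if (!anyNA(v)) return(v)
    ok <- which(is.finite(v))
    approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  dx <- fill(dx); dy <- fill(dy)
  if (smoothing_window_frames > 1) {
    w <- as.integer(smoothing_window_frames)
    if (w %% 2 == 0) stop("smoothing_window_frames must be odd")
    dx <- moving_average(dx, w); dy <- moving_average(dy, w)
  }
  dx <- dx - dx[1]; dy <- dy - dy[1]
  list(trace = drift_trace(dx, dy, 0L), fiducial_ids = fid_ids)
}

# centred moving average with shrinking windows at the ends
moving_average <- function(v, w) {
  h <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(v[lo:hi])
  }, numeric(1))
}

#' Cross-correlation drift estimation
#'
#' For structurally static data, frames are partitioned into temporal bins,
#' each bin rendered as a 2D histogram at sub-pixel zoom, and the lateral
#' shift of every bin relative to bin 0 measured as the peak of their
#' spectral cross-correlation, refined to sub-render-pixel precision by a
#' three-point parabola fit per axis. Bin shifts are attributed to the bin's
#' temporal centre and interpolated to a per-frame trace with a natural
#' cubic spline, held flat beyond the outer bin centres, then re-zeroed at
#' frame 0.
#'
#' @param table a `loc_table` (drifting, uncorrected).
#' @param n_frames total frame count.
#' @param bin_frames frames per temporal bin (default `n_frames / 10`,
#'   at least 1).
#' @param zoom rendering sub-pixels per camera pixel (default 5).
#' @return a [drift_trace] with reference frame 0.
#' @export
estimate_drift_cc <- function(table, n_frames, bin_frames = NULL, zoom = 5) {
  df <- as.data.frame(table)
  if (is.null(bin_frames)) bin_frames <- max(1L, floor(n_frames / 10))
  n_bins <- ceiling(n_frames / bin_frames)
  if (n_bins < 2) stop("need at least 2 temporal bins for cross-correlation")
  # common rendering extent over the whole dataset, padded by 1 camera px
  xmin <- floor(min(df$x)) - 1; xmax <- ceiling(max(df$x)) + 1
  ymin <- floor(min(df$y)) - 1; ymax <- ceiling(max(df$y)) + 1
  ncol_r <- as.integer((xmax - xmin) * zoom)
  nrow_r <- as.integer((ymax - ymin) * zoom)
  render_bin <- function(rows) {
    cx <- floor((df$x[rows] - xmin) * zoom) + 1L
    cy <- floor((df$y[rows] - ymin) * zoom) + 1L
    ok <- cx >= 1 & cx <= ncol_r & cy >= 1 & cy <= nrow_r
    matrix(tabulate((cx[ok] - 1L) * nrow_r + cy[ok],
                    nbins = nrow_r * ncol_r), nrow_r, ncol_r)
  }
  bin_of <- pmin(df$frame %/% bin_frames, n_bins - 1L)
  ref <- render_bin(which(bin_of == 0L))
  Fr <- fft(ref)
  centres <- numeric(n_bins); sx <- numeric(n_bins); sy <- numeric(n_bins)
  for (b in seq_len(n_bins) - 1L) {
    f0 <- b * bin_frames
    f1 <- min(n_frames, f0 + bin_frames) - 1L
    centres[b + 1] <- (f0 + f1) / 2
    if (b == 0L) next
    img <- render_bin(which(bin_of == b))
    cc <- Re(fft(Conj(Fr) * fft(img), inverse = TRUE))
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    refine <- function(vals, ipk, n) {
      im <- ((ipk - 2) %% n) + 1; ip <- (ipk %% n) + 1
      y1 <- vals[im]; y2 <- vals[ipk]; y3 <- vals[ip]
      den <- y1 - 2 * y2 + y3
      d <- if (abs(den) < 1e-12) 0 else 0.5 * (y1 - y3) / den
      s <- (ipk - 1) + d
      if (s > n / 2) s <- s - n
      s
    }
    sy[b + 1] <- refine(cc[, pk[2]], pk[1], nrow_r) / zoom
    sx[b + 1] <- refine(cc[pk[1], ], pk[2], ncol_r) / zoom
    if (abs(sx[b + 1]) > (xmax - xmin) / 4 || abs(sy[b + 1]) > (ymax - ymin) / 4)
      warning("correlation shift is a large fraction of the field; unreliable")
  }
  frames <- seq_len(n_frames) - 1
  interp <- function(s) {
    if (n_bins > 2) {
      fn <- splinefun(centres, s, method = "natural")
      v <- fn(pmin(pmax(frames, centres[1]), centres[n_bins]))
    } else {
      v <- approx(centres, s, xout = frames, rule = 2)$y
    }
    v - v[1]
  }
  drift_trace(interp(sx), interp(sy), 0L)
}

#' Subtract a drift trace from a localization table
#'
#' @param table a `loc_table`.
#' @param trace a [drift_trace] covering every frame present in `table`.
#' @return corrected `loc_table` (`x - dx[frame]`, `y - dy[frame]`; other
#'   columns unchanged).
#' @export
apply_drift <- function(table, trace) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(table)
  if (max(df$frame) >= length(trace$dx))
    stop("drift trace does not cover all frames in the table")
  df$x <- df$x - trace$dx[df$frame + 1L]
  df$y <- df$y - trace$dy[df$frame + 1L]
  keep_loc_attrs(df, table)
}

#' Negate a drift trace
#' @param trace a [drift_trace].
#' @return the sign-flipped trace.
#' @export
negate_drift <- function(trace) drift_trace(-trace$dx, -trace$dy,
                                            trace$reference_frame)
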
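#' Temporal median background subtraction
#'
#' For every pixel and frame `t`, subtracts the median of that pixel's trace
#' over a window of `window_frames` frames centred on `t`. Because blinking
#' equilibria in SMLM favour the off-state, this median tracks the slowly
#' varying background while leaving sparse emitter signal intact. Near the
#' movie start/end the window is shifted (never shrunk) so that exactly
#' `window_frames` frames anchored at the movie boundary are always used,
#' keeping the breakdown point of the statistic constant.
#'
#' The window must be substantially longer than the longest emitter
#' on-period (at least twice); the default of 51 frames suits typical
#' blinking data. The filter should not be used when emitters are on more
#' than half the time, since the median then tracks signal, not background —
#' this is the caller's responsibility and is not auto-detected.
#'
#' @param movie an [smlm_movie].
#' @param window_frames odd temporal window length `i`, `3 <= i <= n_frames`.
#' @param clamp if `TRUE` (default) negative differences are clamped to 0;
#'   set `FALSE` to keep signed output (downstream detection tolerates
#'   negatives, TIFF export does not).
#' @return an [smlm_movie] of the same shape with background removed.
#' @export
temporal_median_filter <- function(movie, window_frames = 51, clamp = TRUE) {
  stopifnot(inherits(movie, "smlm_movie"))
  i <- as.integer(window_frames)
  nf <- n_frames(movie)
  if (i %% 2 == 0) stop("window_frames must be odd")
  if (i < 3) stop("window_frames must be >= 3")
  if (i > nf) stop("window_frames exceeds movie length")
  d <- dim(movie$data)
  npix <- d[1] * d[2]
  flat <- matrix(movie$data, nrow = npix, ncol = nf)  # pixel x frame
  half <- (i - 1L) %/% 2L
  # distinct window start per output frame (0-based), shifted at the edges
  starts <- pmin(pmax(seq_len(nf) - 1L - half, 0L), nf - i)
  out <- matrix(0, npix, nf)
  last_s <- -1L; med <- NULL  # starts repeat only at the movie edges
  for (t in seq_len(nf)) {
    s <- starts[t]
    if (s != last_s) {
      med <- cpp_col_medians(t(flat[, (s + 1L):(s + i), drop = FALSE]))
      last_s <- s
    }
    out[, t] <- flat[, t] - med
  }
  if (clamp) out[out < 0] <- 0
  res <- movie
  res$data <- array(out, dim = d)
  res
}
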
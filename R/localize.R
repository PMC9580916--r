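#' Detection and localization parameters
#'
#' @param dog_sigma_small,dog_sigma_large Gaussian sigmas (px) of the
#'   difference-of-Gaussian bandpass; the defaults (1.0, 2.0) bracket a
#'   diffraction-limited PSF of sigma ~1.3 px at 100 nm pixels.
#' @param threshold_k detection threshold in robust-sd units
#'   (`median + k * 1.4826 * MAD`) above the DoG-image median.
#' @param roi_halfsize half-size `h` of the square fitting ROI (side
#'   `2h + 1`; default 3, i.e. 7x7).
#' @param min_border_px candidates closer than this to the frame edge are
#'   discarded (default `roi_halfsize` so every ROI fits in the frame).
#' @param min_separation_px candidate pairs closer than this are both
#'   dropped, since each ROI is assumed to hold a single fluorophore
#'   (default `2 * roi_halfsize`; set 0 to disable).
#' @return a `detection_params` list.
#' @export
detection_params <- function(dog_sigma_small = 1.0, dog_sigma_large = 2.0,
                             threshold_k = 3, roi_halfsize = 3,
                             min_border_px = NULL, min_separation_px = NULL) {
  stopifnot(dog_sigma_small < dog_sigma_large, roi_halfsize >= 2,
            threshold_k > 0)
  if (is.null(min_border_px)) min_border_px <- roi_halfsize
  if (is.null(min_separation_px)) min_separation_px <- 2 * roi_halfsize
  structure(list(dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 threshold_k = threshold_k,
                 roi_halfsize = as.integer(roi_halfsize),
                 min_border_px = as.integer(min_border_px),
                 min_separation_px = min_separation_px),
            class = "detection_params")
}

#' Difference-of-Gaussian bandpass filter
#'
#' `gaussian_blur(frame, sigma_small) - gaussian_blur(frame, sigma_large)`
#' with symmetric (reflective) boundary handling; highlights PSF-sized blobs.
#'
#' @param frame 2D numeric matrix.
#' @param sigma_small,sigma_large blur sigmas in px, small < large.
#' @return filtered matrix of the same shape.
#' @export
dog_filter <- function(frame, sigma_small = 1.0, sigma_large = 2.0) {
  if (!is.matrix(frame)) stop("dog_filter expects a 2D matrix")
  stopifnot(sigma_small < sigma_large)
  cpp_gauss_blur_reflect(frame, sigma_small) -
    cpp_gauss_blur_reflect(frame, sigma_large)
}

#' Find candidate emitter pixels
#'
#' Thresholds the filtered frame at `median + k * 1.4826 * MAD` (robust to
#' the bright emitter tail), then keeps pixels that are local maxima of the
#' raw frame in their 3x3 neighbourhood. Plateau ties are resolved to the
#' lexicographically smallest (row, col). Candidates within
#' `min_border_px` of the edge, and pairs closer than `min_separation_px`
#' (both members), are discarded.
#'
#' @param filtered_frame DoG-filtered frame used for thresholding.
#' @param raw_frame raw frame used for the local-maximum test.
#' @param params a [detection_params].
#' @return integer matrix with columns `row`, `col` (0-based), possibly empty.
#' @export
find_candidates <- function(filtered_frame, raw_frame, params = detection_params()) {
  stopifnot(all(dim(filtered_frame) == dim(raw_frame)))
  v <- as.vector(filtered_frame)
  thr <- median(v) + params$threshold_k * mad(v)
  cand <- which(filtered_frame > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(row = integer(0), col = integer(0)))
  nr <- nrow(raw_frame); nc <- ncol(raw_frame)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (i == 1 || i == nr || j == 1 || j == nc) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- raw_frame[i + di, j + dj]
      if (nb > raw_frame[i, j]) { ok <- FALSE }
      # plateau tie: earlier (row-major by row, then col) neighbour wins
      if (nb == raw_frame[i, j] && (di < 0 || (di == 0 && dj < 0))) ok <- FALSE
    }
    keep[k] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(cbind(row = integer(0), col = integer(0)))
  # 0-based output, border exclusion
  rows <- cand[, 1] - 1L; cols <- cand[, 2] - 1L
  b <- params$min_border_px
  inb <- rows >= b & rows < nr - b & cols >= b & cols < nc - b
  rows <- rows[inb]; cols <- cols[inb]
  if (length(rows) > 1 && params$min_separation_px > 0) {
    dd <- as.matrix(dist(cbind(rows, cols)))
    diag(dd) <- Inf
    crowded <- apply(dd < params$min_separation_px, 1, any)
    rows <- rows[!crowded]; cols <- cols[!crowded]
  }
  ord <- order(rows, cols)
  cbind(row = rows[ord], col = cols[ord])
}

#' Phasor sub-pixel localization of a single ROI
#'
#' Computes the first-order discrete Fourier coefficients of the ROI along
#' each axis; the phase angle of each encodes the centre of mass of a
#' periodic intensity distribution, converted to a sub-pixel offset relative
#' to the ROI centre. A PSF centred on the ROI centre returns `(0, 0)`; a
#' delta at integer pixel `(u0, v0)` (col, row, 0-based) returns exactly
#' `(u0 - h, v0 - h)`.
#'
#' @param roi square matrix of odd side `2h + 1`, local background already
#'   subtracted (non-negative).
#' @return list `dx`, `dy` (px offsets from ROI centre, x = columns),
#'   `magnitude` (`|Fx| + |Fy|`, a fit-quality score), `degenerate` (TRUE
#'   when both first-order magnitudes vanish, e.g. a constant ROI).
#' @export
phasor_localize <- function(roi) {
  stopifnot(is.matrix(roi), nrow(roi) == ncol(roi), nrow(roi) %% 2 == 1)
  N <- nrow(roi)
  h <- (N - 1L) %/% 2L
  u <- 0:(N - 1)
  wx <- exp(-2i * pi * u / N)
  # roi[v+1, u+1]: v = row index, u = col index
  Fx <- sum(colSums(roi) * wx)
  Fy <- sum(rowSums(roi) * wx)
  magx <- Mod(Fx); magy <- Mod(Fy)
  if (magx < 1e-12 && magy < 1e-12)
    return(list(dx = NA_real_, dy = NA_real_, magnitude = 0, degenerate = TRUE))
  pos_from_phase <- function(F) {
    p <- -Arg(F) * N / (2 * pi)   # position in 0..N (mod N)
    p <- p %% N
    p - h
  }
  list(dx = pos_from_phase(Fx), dy = pos_from_phase(Fy),
       magnitude = magx + magy, degenerate = FALSE)
}

#' Localize all emitters in a movie
#'
#' Detection runs per frame on the filtered movie (output of
#' [temporal_median_filter], or the raw movie when `filtered` is `NULL`);
#' fitting ROIs are cut from the raw movie, their local background (ROI
#' minimum) subtracted, and each localized by [phasor_localize]. Positions
#' follow the pixel-centre convention:
#' `x = col_peak + 0.5 + dx`, `y = row_peak + 0.5 + dy`.
#'
#' @param raw the raw [smlm_movie] (ROIs are cut from it).
#' @param filtered background-subtracted movie for detection, or `NULL`.
#' @param params a [detection_params].
#' @return a `loc_table` sorted by frame; `intensity` is the
#'   background-subtracted ROI sum.
#' @export
localize_movie <- function(raw, filtered = NULL, params = detection_params()) {
  stopifnot(inherits(raw, "smlm_movie"))
  if (is.null(filtered)) filtered <- raw
  if (!all(dim(filtered$data) == dim(raw$data)))
    stop("filtered and raw movies must have identical shape")
  h <- params$roi_halfsize
  nf <- n_frames(raw)
  fr <- integer(0); xs <- numeric(0); ys <- numeric(0); ins <- numeric(0)
  for (t in seq_len(nf)) {
    det_frame <- filtered$data[, , t]
    raw_frame <- raw$data[, , t]
    dog <- dog_filter(det_frame, params$dog_sigma_small, params$dog_sigma_large)
    peaks <- find_candidates(dog, raw_frame, params)
    for (k in seq_len(nrow(peaks))) {
      r <- peaks[k, 1]; cc <- peaks[k, 2]       # 0-based
      roi <- raw_frame[(r - h + 1):(r + h + 1), (cc - h + 1):(cc + h + 1)]
      roi <- roi - min(roi)
      ph <- phasor_localize(roi)
      if (ph$degenerate) next
      fr <- c(fr, t - 1L)
      xs <- c(xs, cc + 0.5 + ph$dx)
      ys <- c(ys, r + 0.5 + ph$dy)
      ins <- c(ins, sum(roi))
    }
  }
  loc_table(frame = fr, x = xs, y = ys, intensity = ins,
            pixel_size_nm = raw$pixel_size_nm,
            frame_interval_s = raw$frame_interval_s)
}
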
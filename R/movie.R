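#' SMLM movie container
#'
#' A movie is a stack of grayscale camera frames with physical calibration.
#' Pixel `(row i, col j)` (0-based) covers the half-open square
#' `[j, j+1) x [i, i+1)` in `(x, y)` camera-pixel coordinates, so the centre
#' of pixel `(0, 0)` is at `(0.5, 0.5)`. Frames are indexed from 0.
#'
#' @param data numeric array of dimension `(rows, cols, frames)` (a matrix is
#'   promoted to a single-frame movie); intensities must be non-negative
#'   finite camera counts.
#' @param pixel_size_nm physical size of one camera pixel in nanometres.
#' @param frame_interval_s time per frame in seconds.
#' @return An object of class `smlm_movie`: a list with elements `data`,
#'   `pixel_size_nm`, `frame_interval_s`.
#' @export
smlm_movie <- function(data, pixel_size_nm = 100, frame_interval_s = 0.03) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("movie data must be a (rows, cols, frames) array")
  if (any(dim(data) < 1L)) stop("all movie dimensions must be >= 1")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be > 0")
  structure(list(data = data,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "smlm_movie")
}

#' Number of frames in a movie
#' @param movie an `smlm_movie`.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[3L]

#' Extract one frame as a matrix
#' @param movie an `smlm_movie`.
#' @param frame 0-based frame index.
#' @return numeric matrix (rows x cols).
#' @export
get_frame <- function(movie, frame) {
  stopifnot(frame >= 0, frame < n_frames(movie))
  movie$data[, , frame + 1L]
}

#' @export
print.smlm_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("smlm_movie: %d frame(s) of %d x %d px, %.1f nm/px, %.4g s/frame\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$frame_interval_s))
  invisible(x)
}

#' Read a grayscale TIFF stack as a movie
#'
#' Reads a single- or multi-page grayscale TIFF. Integer sample values are
#' preserved bit-exact (the 0..1 normalisation of the TIFF reader is undone
#' using the file's declared bit depth).
#'
#' @param path path to a TIFF file.
#' @param pixel_size_nm,frame_interval_s calibration attached to the movie.
#' @return an [smlm_movie].
#' @export
read_movie <- function(path, pixel_size_nm = 100, frame_interval_s = 0.03) {
  if (!file.exists(path)) stop("cannot read movie: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("unsupported TIFF: multi-sample (RGB/RGBA) pages are not grayscale movies")
  data <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) data[, , i] <- pages[[i]]
  smlm_movie(data, pixel_size_nm, frame_interval_s)
}

#' Write a movie as a multi-page TIFF
#'
#' Intensities are stored as integer grayscale counts (rounded and clamped
#' at zero, matching camera output); 16-bit pages when the maximum fits,
#' 32-bit otherwise. Integer movies round-trip bit-exact through
#' [read_movie].
#'
#' @param movie an [smlm_movie].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "smlm_movie"))
  d <- round(movie$data)
  d[d < 0] <- 0
  mx <- max(d)
  if (mx >= 2^31) stop("intensities exceed the 32-bit TIFF range")
  frames <- lapply(seq_len(dim(d)[3]), function(i) d[, , i])
  if (mx <= 65535) {
    tiff::writeTIFF(lapply(frames, function(f) f / 65535), path,
                    bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(lapply(frames, function(f) f / (2^32 - 1)), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}
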
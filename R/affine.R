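#' 2D affine transform
#'
#' Maps `(x, y)` to `(a*x + b*y + tx, c*x + d*y + ty)` in camera-pixel units.
#'
#' @param a,b,c,d linear part (row-major 2x2).
#' @param tx,ty translation.
#' @return an `affine2d` object.
#' @export
affine2d <- function(a = 1, b = 0, c = 0, d = 1, tx = 0, ty = 0) {
  det <- a * d - b * c
  if (abs(det) <= 1e-12) stop("affine linear part is singular")
  structure(list(a = a, b = b, c = c, d = d, tx = tx, ty = ty),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d: [%.6g %.6g; %.6g %.6g] + (%.6g, %.6g)\n",
              x$a, x$b, x$c, x$d, x$tx, x$ty))
  invisible(x)
}

#' Apply an affine transform to point coordinates
#' @param T an `affine2d`.
#' @param x,y coordinate vectors.
#' @return list with transformed `x`, `y`.
#' @export
affine_apply_xy <- function(T, x, y) {
  list(x = T$a * x + T$b * y + T$tx,
       y = T$c * x + T$d * y + T$ty)
}

#' Invert an affine transform
#' @param T an `affine2d`.
#' @return the inverse `affine2d`.
#' @export
affine_invert <- function(T) {
  det <- T$a * T$d - T$b * T$c
  ia <- T$d / det; ib <- -T$b / det; ic <- -T$c / det; id <- T$a / det
  affine2d(ia, ib, ic, id,
           tx = -(ia * T$tx + ib * T$ty),
           ty = -(ic * T$tx + id * T$ty))
}

#' Serialize / deserialize an affine transform as JSON
#' @param T an `affine2d`.
#' @param path file path.
#' @return `read_affine` returns an `affine2d`; `write_affine` returns `path`.
#' @export
write_affine <- function(T, path) {
  jsonlite::write_json(unclass(T), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine2d(v$a, v$b, v$c, v$d, v$tx, v$ty)
}

#' Per-frame drift trace
#'
#' Lateral displacement `(dx, dy)` of the sample per frame, in camera-pixel
#' units, with the displacement at `reference_frame` defined as `(0, 0)`.
#'
#' @param dx,dy numeric vectors, one entry per frame (frame 0 first).
#' @param reference_frame 0-based index whose displacement is zero.
#' @return a `drift_trace` object.
#' @export
drift_trace <- function(dx, dy, reference_frame = 0L) {
  stopifnot(length(dx) == length(dy), length(dx) >= 1)
  if (reference_frame < 0 || reference_frame >= length(dx))
    stop("reference_frame out of range")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 reference_frame = as.integer(reference_frame)),
            class = "drift_trace")
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("drift_trace: %d frames, ref %d, max |d| = %.3g px\n",
              length(x$dx), x$reference_frame,
              max(sqrt(x$dx^2 + x$dy^2))))
  invisible(x)
}

#' Write / read a drift trace CSV (frame, dx, dy)
#' @param trace a `drift_trace`.
#' @param path file path.
#' @return `read_drift_trace` returns a `drift_trace`.
#' @export
write_drift_trace <- function(trace, path) {
  utils::write.csv(data.frame(frame = seq_along(trace$dx) - 1L,
                              dx = trace$dx, dy = trace$dy),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_drift_trace
#' @export
read_drift_trace <- function(path) {
  df <- utils::read.csv(path)
  drift_trace(df$dx, df$dy)
}
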
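#' Rendered super-resolution image container
#'
#' @param data 2D non-negative matrix (render pixels).
#' @param zoom sub-pixels per camera pixel.
#' @param origin `(xmin, ymin)` of the raster in camera px.
#' @return a `rendered_image`.
#' @export
rendered_image <- function(data, zoom, origin) {
  structure(list(data = data, zoom = zoom, origin = as.numeric(origin)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d render px, zoom %g, origin (%.3g, %.3g), sum %.6g\n",
              nrow(x$data), ncol(x$data), x$zoom, x$origin[1], x$origin[2],
              sum(x$data)))
  invisible(x)
}

render_extent <- function(df, extent) {
  if (is.null(extent)) {
    if (nrow(df) == 0)
      stop("cannot infer a rendering extent from an empty table")
    extent <- c(floor(min(df$x)) - 1, ceiling(max(df$x)) + 1,
                floor(min(df$y)) - 1, ceiling(max(df$y)) + 1)
  }
  extent
}

#' Render a localization table as a sub-pixel 2D histogram
#'
#' Each localization adds one count to the render bin containing it
#' (half-open binning, `floor((x - xmin) * zoom)`). The render-bin centre of
#' bin `(r, c)` is at `(xmin + (c + 0.5)/zoom, ymin + (r + 0.5)/zoom)`,
#' consistent with the global pixel-centre convention.
#'
#' @param table a `loc_table`.
#' @param zoom sub-pixels per camera pixel; ~10-15 is typical. Much finer
#'   zoom than the localization precision suggests non-existing detail.
#' @param extent optional `(xmin, xmax, ymin, ymax)` in camera px; inferred
#'   from the data (padded by 1 camera px) when absent. Localizations
#'   outside the extent are dropped (count reported as attribute
#'   `n_dropped`).
#' @return a [rendered_image].
#' @export
render_histogram <- function(table, zoom = 10, extent = NULL) {
  df <- as.data.frame(table)
  extent <- render_extent(df, extent)
  ncol_r <- as.integer(round((extent[2] - extent[1]) * zoom))
  nrow_r <- as.integer(round((extent[4] - extent[3]) * zoom))
  img <- matrix(0, nrow_r, ncol_r)
  dropped <- 0L
  if (nrow(df)) {
    cx <- floor((df$x - extent[1]) * zoom) + 1L
    cy <- floor((df$y - extent[3]) * zoom) + 1L
    ok <- cx >= 1 & cx <= ncol_r & cy >= 1 & cy <= nrow_r
    dropped <- sum(!ok)
    img <- matrix(tabulate((cx[ok] - 1L) * nrow_r + cy[ok],
                           nbins = nrow_r * ncol_r), nrow_r, ncol_r)
  }
  out <- rendered_image(img, zoom, c(extent[1], extent[3]))
  attr(out, "n_dropped") <- dropped
  out
}

#' Render by bilinear interpolation onto the sub-pixel raster
#'
#' Each localization's unit weight is split over the four render bins whose
#' centres surround it, with bilinear weights summing to one, populating
#' neighbouring bins according to the distance from the localization to the
#' main bin centre.
#'
#' @inheritParams render_histogram
#' @return a [rendered_image].
#' @export
render_bilinear <- function(table, zoom = 10, extent = NULL) {
  df <- as.data.frame(table)
  extent <- render_extent(df, extent)
  ncol_r <- as.integer(round((extent[2] - extent[1]) * zoom))
  nrow_r <- as.integer(round((extent[4] - extent[3]) * zoom))
  img <- matrix(0, nrow_r, ncol_r)
  dropped <- 0L
  for (i in seq_len(nrow(df))) {
    gx <- (df$x[i] - extent[1]) * zoom - 0.5   # in bin-centre coordinates
    gy <- (df$y[i] - extent[3]) * zoom - 0.5
    c0 <- floor(gx); r0 <- floor(gy)
    wx <- gx - c0; wy <- gy - r0
    if (gx < -0.5 || gy < -0.5 || gx > ncol_r - 0.5 || gy > nrow_r - 0.5) {
      dropped <- dropped + 1L
      next
    }
    for (dc in 0:1) for (dr in 0:1) {
      cc <- c0 + dc + 1L; rr <- r0 + dr + 1L
      w <- (if (dc == 0) 1 - wx else wx) * (if (dr == 0) 1 - wy else wy)
      if (cc >= 1 && cc <= ncol_r && rr >= 1 && rr <= nrow_r)
        img[rr, cc] <- img[rr, cc] + w
    }
  }
  out <- rendered_image(img, zoom, c(extent[1], extent[3]))
  attr(out, "n_dropped") <- dropped
  out
}

#' Render each localization as a 2D Gaussian
#'
#' Every localization contributes a unit-integral, isotropic 2D Gaussian
#' evaluated on the render-bin centres and truncated at 4 sigma. The width
#' should match the localization precision; note that this visualisation
#' convolves the localization error with the render kernel, so a rendered
#' point source is broadened by sqrt(2) when `sigma` equals the precision.
#'
#' @inheritParams render_histogram
#' @param sigma_render_px Gaussian sd in render pixels (localization
#'   precision in camera px times `zoom`, typically).
#' @return a [rendered_image]; total weight within ~1 percent of the
#'   localization count (truncation loss).
#' @export
render_gaussian <- function(table, zoom = 10, sigma_render_px, extent = NULL) {
  stopifnot(sigma_render_px > 0)
  df <- as.data.frame(table)
  extent <- render_extent(df, extent)
  ncol_r <- as.integer(round((extent[2] - extent[1]) * zoom))
  nrow_r <- as.integer(round((extent[4] - extent[3]) * zoom))
  img <- matrix(0, nrow_r, ncol_r)
  rad <- ceiling(4 * sigma_render_px)
  for (i in seq_len(nrow(df))) {
    gx <- (df$x[i] - extent[1]) * zoom - 0.5
    gy <- (df$y[i] - extent[3]) * zoom - 0.5
    cols <- max(0, floor(gx) - rad):min(ncol_r - 1, ceiling(gx) + rad)
    rows <- max(0, floor(gy) - rad):min(nrow_r - 1, ceiling(gy) + rad)
    if (!length(cols) || !length(rows)) next
    kx <- exp(-0.5 * ((cols - gx) / sigma_render_px)^2)
    ky <- exp(-0.5 * ((rows - gy) / sigma_render_px)^2)
    # unit integral before truncation: normalise by the analytic total
    norm <- 2 * pi * sigma_render_px^2
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] +
      (ky %o% kx) / norm
  }
  rendered_image(img, zoom, c(extent[1], extent[3]))
}

#' Render dispatcher
#'
#' @inheritParams render_histogram
#' @param method one of `"histogram"`, `"bilinear"`, `"gaussian"`.
#' @param sigma_render_px Gaussian width for `method = "gaussian"`.
#' @return a [rendered_image].
#' @export
render_locs <- function(table, method = c("histogram", "bilinear", "gaussian"),
                        zoom = 10, sigma_render_px = NULL, extent = NULL) {
  method <- match.arg(method)
  switch(method,
         histogram = render_histogram(table, zoom, extent),
         bilinear = render_bilinear(table, zoom, extent),
         gaussian = render_gaussian(table, zoom, sigma_render_px, extent))
}
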
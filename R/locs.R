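#' Localization table
#'
#' The canonical localization container: a `data.frame` with columns
#' `frame` (0-based integer), `x`, `y` (camera-pixel units, pixel-centre
#' convention: the centre of pixel `(0,0)` is `(0.5, 0.5)`), `intensity`
#' (summed photon/count estimate), `track_id` (integer linkage label,
#' -1 = unassigned) and `channel` (integer colour channel, 0 default).
#' Calibration travels as attributes `pixel_size_nm`, `frame_interval_s`.
#'
#' @param frame,x,y,intensity,track_id,channel column vectors (recycled where
#'   length 1).
#' @param pixel_size_nm,frame_interval_s calibration metadata.
#' @return a `loc_table` (also a `data.frame`).
#' @export
loc_table <- function(frame = integer(), x = numeric(), y = numeric(),
                      intensity = numeric(), track_id = -1L, channel = 0L,
                      pixel_size_nm = 100, frame_interval_s = 0.03) {
  n <- max(length(frame), length(x), length(y), length(intensity))
  if (n > 0) {
    if (length(intensity) == 0) intensity <- rep(0, n)
    df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                     y = as.numeric(y), intensity = as.numeric(intensity),
                     track_id = as.integer(rep_len(track_id, n)),
                     channel = as.integer(rep_len(channel, n)))
  } else {
    df <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                     intensity = numeric(), track_id = integer(),
                     channel = integer())
  }
  if (n > 0) {
    if (any(df$frame < 0)) stop("frame indices must be >= 0")
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("x and y must be finite")
    if (any(df$intensity < 0)) stop("intensity must be >= 0")
  }
  attr(df, "pixel_size_nm") <- as.numeric(pixel_size_nm)
  attr(df, "frame_interval_s") <- as.numeric(frame_interval_s)
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Coerce a data.frame to a localization table
#' @param df data.frame with at least `frame`, `x`, `y` columns.
#' @param pixel_size_nm,frame_interval_s calibration metadata.
#' @return a `loc_table`.
#' @export
as_loc_table <- function(df, pixel_size_nm = 100, frame_interval_s = 0.03) {
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  loc_table(frame = df$frame, x = df$x, y = df$y,
            intensity = if ("intensity" %in% names(df)) df$intensity else rep(0, nrow(df)),
            track_id = if ("track_id" %in% names(df)) df$track_id else -1L,
            channel = if ("channel" %in% names(df)) df$channel else 0L,
            pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s)
}

keep_loc_attrs <- function(df, template) {
  attr(df, "pixel_size_nm") <- attr(template, "pixel_size_nm")
  attr(df, "frame_interval_s") <- attr(template, "frame_interval_s")
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("loc_table: %d localization(s), %s nm/px\n", nrow(x),
              format(attr(x, "pixel_size_nm"))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Read a localization CSV
#'
#' Reads ThunderSTORM/RapidSTORM-style CSV exports into the canonical schema.
#' The dialect maps foreign column names onto `frame`, `x`, `y`, `intensity`
#' and declares position units; nm positions are converted to camera pixels.
#'
#' @param path CSV file with a header row.
#' @param dialect named list: `frame`, `x`, `y`, `intensity` give the source
#'   column names (defaults accept both canonical names and common
#'   `"x [nm]"`-style headers); `units` is `"px"` or `"nm"`;
#'   `one_based_frames` subtracts 1 from frame indices on input;
#'   `shift_px` is added to both coordinates after unit conversion (use
#'   0.5 for exports whose pixel (0,0) centre sits at (0,0) rather than
#'   this package's (0.5, 0.5) convention).
#' @param pixel_size_nm,frame_interval_s calibration; `pixel_size_nm` is used
#'   for the nm-to-px conversion.
#' @return a `loc_table`.
#' @export
read_localizations <- function(path, dialect = list(),
                               pixel_size_nm = 100, frame_interval_s = 0.03) {
  if (!file.exists(path)) stop("cannot read localizations: file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  units <- dialect$units %||% "px"
  pick <- function(canon, candidates) {
    want <- dialect[[canon]] %||% candidates
    hit <- intersect(want, names(raw))
    if (length(hit)) hit[1] else NA_character_
  }
  cf <- pick("frame", c("frame", "frame_ix", "t"))
  cx <- pick("x", c("x", "x [nm]", "x [px]", "x_nm", "x_px"))
  cy <- pick("y", c("y", "y [nm]", "y [px]", "y_nm", "y_px"))
  ci <- pick("intensity", c("intensity", "intensity [photon]", "N", "photons"))
  if (any(is.na(c(cf, cx, cy))))
    stop("schema error: could not locate mandatory columns frame/x/y in ", path)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v) & !is.na(raw[[col]]) & nzchar(as.character(raw[[col]])))
    bad2 <- which(is.na(v))
    if (length(bad2)) stop(sprintf("parse error: non-numeric '%s' value at data row %d",
                                   name, bad2[1]))
    v
  }
  if (nrow(raw) == 0) {
    return(loc_table(pixel_size_nm = pixel_size_nm,
                     frame_interval_s = frame_interval_s))
  }
  frame <- num(cf, "frame")
  if (isTRUE(dialect$one_based_frames)) frame <- frame - 1
  x <- num(cx, "x"); y <- num(cy, "y")
  if (identical(units, "nm")) { x <- x / pixel_size_nm; y <- y / pixel_size_nm }
  if (!is.null(dialect$shift_px)) {
    x <- x + dialect$shift_px
    y <- y + dialect$shift_px
  }
  inten <- if (!is.na(ci)) num(ci, "intensity") else rep(0, nrow(raw))
  loc_table(frame = frame, x = x, y = y, intensity = inten,
            track_id = if ("track_id" %in% names(raw)) raw$track_id else -1L,
            channel = if ("channel" %in% names(raw)) raw$channel else 0L,
            pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s)
}

#' Write a localization table as CSV
#'
#' Writes the canonical header `frame,x,y,intensity,track_id,channel` with
#' rows sorted by frame (stable within a frame). Positions are written in
#' camera-pixel units.
#'
#' @param table a `loc_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)[, c("frame", "x", "y", "intensity", "track_id", "channel")]
  df <- df[order(df$frame), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
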
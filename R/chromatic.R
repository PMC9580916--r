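#' Estimate an affine chromatic correction from paired control points
#'
#' Least-squares solution of the six affine parameters mapping the moving
#' channel onto the reference channel, from paired control points (e.g.
#' bead or DNA-origami sites imaged in both colours). With
#' `translation_only = TRUE` only the offset is fitted (dual-view
#' registration).
#'
#' @param ref two-column matrix/data.frame of reference `(x, y)` in px.
#' @param mov matching moving-channel points, same number of rows.
#' @param translation_only fit a pure translation instead of a full affine.
#' @return list with `transform` (an [affine2d] mapping moving -> reference),
#'   `residuals` (per-pair residual distance, px) and `rms` (root mean
#'   square residual).
#' @export
estimate_affine <- function(ref, mov, translation_only = FALSE) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov)) stop("ref and mov must pair up row by row")
  n <- nrow(ref)
  if (translation_only) {
    if (n < 1) stop("need at least 1 pair for translation estimation")
    T <- affine2d(tx = mean(ref[, 1] - mov[, 1]),
                  ty = mean(ref[, 2] - mov[, 2]))
  } else {
    if (n < 3) stop("need at least 3 point pairs for affine estimation")
    X <- cbind(mov[, 1], mov[, 2], 1)
    if (kappa(crossprod(X)) > 1e8)
      stop("degenerate control points (collinear or coincident)")
    bx <- solve(crossprod(X), crossprod(X, ref[, 1]))
    by <- solve(crossprod(X), crossprod(X, ref[, 2]))
    T <- affine2d(a = bx[1], b = bx[2], c = by[1], d = by[2],
                  tx = bx[3], ty = by[3])
  }
  fit <- affine_apply_xy(T, mov[, 1], mov[, 2])
  res <- sqrt((fit$x - ref[, 1])^2 + (fit$y - ref[, 2])^2)
  list(transform = T, residuals = res, rms = sqrt(mean(res^2)))
}

#' Apply an affine transform to a localization table
#'
#' Maps every position through `T` (typically the chromatic correction of
#' the moving channel onto the reference channel).
#'
#' @param table a `loc_table`.
#' @param T an [affine2d].
#' @return the transformed table.
#' @export
apply_affine <- function(table, T) {
  df <- as.data.frame(table)
  if (nrow(df)) {
    p <- affine_apply_xy(T, df$x, df$y)
    df$x <- p$x; df$y <- p$y
  }
  out <- keep_loc_attrs(df, table)
  attr(out, "chromatic_transform") <- unclass(T)
  out
}

#' Automatic control-point pairing by mutual nearest neighbours
#'
#' Replaces hand-picking of channel pairs: points in the two channels are
#' paired when each is the other's nearest neighbour and their distance is
#' below `radius_px`.
#'
#' @param ref,mov two-column matrices of `(x, y)` candidate points.
#' @param radius_px maximum pairing distance.
#' @return list of matched `ref` and `mov` matrices (same row count).
#' @export
pair_mutual_nn <- function(ref, mov, radius_px) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) == 0 || nrow(mov) == 0)
    return(list(ref = ref[0, , drop = FALSE], mov = mov[0, , drop = FALSE]))
  d <- outer(ref[, 1], mov[, 1], "-")^2 + outer(ref[, 2], mov[, 2], "-")^2
  nn_rm <- apply(d, 1, which.min)
  nn_mr <- apply(d, 2, which.min)
  i <- which(nn_mr[nn_rm] == seq_len(nrow(ref)) &
               sqrt(d[cbind(seq_len(nrow(ref)), nn_rm)]) <= radius_px)
  list(ref = ref[i, , drop = FALSE], mov = mov[nn_rm[i], , drop = FALSE])
}

#' Read control-point pairs from CSV
#'
#' Expects columns `x_ref,y_ref,x_mov,y_mov` in camera-pixel units.
#'
#' @param path CSV file.
#' @return list of `ref` and `mov` matrices.
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_ref", "y_ref", "x_mov", "y_mov")
  if (!all(need %in% names(df)))
    stop("pair file must have columns x_ref,y_ref,x_mov,y_mov")
  list(ref = as.matrix(df[, c("x_ref", "y_ref")]),
       mov = as.matrix(df[, c("x_mov", "y_mov")]))
}
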
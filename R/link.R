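#' Linking parameters
#'
#' @param max_jump_px maximum allowed displacement between linked
#'   localizations (px).
#' @param max_gap_frames number of dark (blinked) frames a link may span:
#'   0 links only consecutive frames, 1 allows one missing frame, etc.
#'   Typical values: 1-2 for merging, user-chosen for tracking.
#' @return a `link_params` list.
#' @export
link_params <- function(max_jump_px, max_gap_frames = 0L) {
  stopifnot(max_jump_px > 0, max_gap_frames >= 0)
  structure(list(max_jump_px = max_jump_px,
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "link_params")
}

#' Gap-tolerant nearest-neighbour linking
#'
#' Processes frames in order. Each open trajectory head is matched to its
#' nearest unclaimed localization within `max_jump_px`, trying frame `t+1`
#' first and only falling back to larger gaps (up to
#' `t + 1 + max_gap_frames`) for heads left unmatched at smaller gaps.
#' Within a frame pair, matches are resolved globally greedily in ascending
#' distance order (ties broken by lower row index), which removes the
#' input-order dependence of a naive per-localization loop. Every
#' localization ends up in exactly one track; singletons get fresh ids.
#' Track ids are consecutive integers from 0 in order of track start.
#'
#' @param table a `loc_table` sorted by frame.
#' @param params a [link_params].
#' @param auto_sort sort by frame with a warning instead of erroring on
#'   unsorted input.
#' @return the table with `track_id` assigned.
#' @export
link_localizations <- function(table, params, auto_sort = FALSE) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(table)
  if (is.unsorted(df$frame)) {
    if (auto_sort) {
      warning("input not sorted by frame; sorting")
      df <- df[order(df$frame), , drop = FALSE]
    } else stop("localization table must be sorted by frame")
  }
  n <- nrow(df)
  track <- rep(NA_integer_, n)
  # open heads: row index of the last localization of each live track
  frames <- sort(unique(df$frame))
  rows_by_frame <- split(seq_len(n), df$frame)
  head_rows <- integer(0)            # row indices that may still be extended
  next_id <- 0L
  maxgap <- params$max_gap_frames
  for (f in frames) {
    rows_f <- rows_by_frame[[as.character(f)]]
    unclaimed <- rows_f
    # gap priority: heads last seen at f-1 first, then f-2, ...
    for (g in 0:maxgap) {
      if (!length(unclaimed)) break
      hs <- head_rows[df$frame[head_rows] == f - 1L - g]
      if (!length(hs)) next
      dx <- outer(df$x[hs], df$x[unclaimed], "-")
      dy <- outer(df$y[hs], df$y[unclaimed], "-")
      dmat <- sqrt(dx^2 + dy^2)
      cand <- which(dmat <= params$max_jump_px, arr.ind = TRUE)
      if (!nrow(cand)) next
      dvals <- dmat[cand]
      ord <- order(dvals, unclaimed[cand[, 2]], hs[cand[, 1]])
      used_h <- logical(length(hs)); used_c <- logical(length(unclaimed))
      taken <- integer(0)
      for (k in ord) {
        ih <- cand[k, 1]; ic <- cand[k, 2]
        if (used_h[ih] || used_c[ic]) next
        used_h[ih] <- TRUE; used_c[ic] <- TRUE
        hrow <- hs[ih]; crow <- unclaimed[ic]
        track[crow] <- track[hrow]
        head_rows[head_rows == hrow] <- crow
        taken <- c(taken, ic)
      }
      if (length(taken)) unclaimed <- unclaimed[-taken]
    }
    # leftover localizations start new tracks (row order)
    for (r in setdiff(rows_f, head_rows)) {
      if (is.na(track[r])) {
        track[r] <- next_id
        next_id <- next_id + 1L
        head_rows <- c(head_rows, r)
      }
    }
    # drop heads too old to ever match again
    head_rows <- head_rows[df$frame[head_rows] >= f - maxgap]
  }
  df$track_id <- track
  keep_loc_attrs(df, table)
}

#' Merge linked localizations
#'
#' Collapses every track to a single localization with the
#' intensity-weighted mean position, the minimum frame value and the summed
#' intensity, recovering one event per fluorophore emission burst and
#' boosting effective photon count (precision scales as 1/sqrt(N)). Tracks
#' whose id is in `exclude_ids` (e.g. fiducial markers) pass through
#' unchanged. Zero-total-intensity tracks fall back to the unweighted mean
#' with a warning. On high-density data a warning is raised when many merges
#' have suspiciously large internal steps, indicating likely cross-linking
#' of distinct fluorophores.
#'
#' @param table a `loc_table` with `track_id` assigned.
#' @param exclude_ids integer vector of track ids left unmerged.
#' @param max_jump_px optional; when given, used for the high-density
#'   diagnostic (warn if > 5 percent of merged tracks have mean step
#'   > `max_jump_px / 2`).
#' @return a `loc_table` with one row per track (plus excluded rows),
#'   sorted by frame.
#' @export
merge_linked <- function(table, exclude_ids = integer(0), max_jump_px = NULL) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(table)
  if (any(df$track_id < 0)) stop("merge_linked requires assigned track ids")
  excl <- df$track_id %in% exclude_ids
  kept <- df[excl, , drop = FALSE]
  mg <- df[!excl, , drop = FALSE]
  out <- kept
  if (nrow(mg)) {
    grp <- split(seq_len(nrow(mg)), mg$track_id)
    big_step <- 0L
    rows <- lapply(grp, function(ix) {
      N <- mg$intensity[ix]
      W <- sum(N)
      if (W <= 0) {
        warning("track with zero total intensity; using unweighted mean")
        w <- rep(1 / length(ix), length(ix))
      } else w <- N / W
      if (!is.null(max_jump_px) && length(ix) > 1) {
        steps <- sqrt(diff(mg$x[ix])^2 + diff(mg$y[ix])^2)
        if (mean(steps) > max_jump_px / 2) big_step <<- big_step + 1L
      }
      data.frame(frame = min(mg$frame[ix]),
                 x = sum(w * mg$x[ix]), y = sum(w * mg$y[ix]),
                 intensity = W, track_id = mg$track_id[ix[1]],
                 channel = mg$channel[ix[1]])
    })
    if (!is.null(max_jump_px) && length(grp) > 0 &&
        big_step / length(grp) > 0.05)
      warning("more than 5% of merged tracks have large internal steps; ",
              "possible cross-linking at high density")
    out <- rbind(out, do.call(rbind, rows))
  }
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  keep_loc_attrs(out, table)
}
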
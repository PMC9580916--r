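#' DBSCAN clustering of localizations
#'
#' Density-based clustering over all frames: a point is a *core* point when
#' at least `min_points` localizations (including itself by default) lie
#' within radius `eps`; an *edge* point is a non-core point within `eps` of
#' a core point; everything else is *noise*. Clusters are the connected
#' components of the core-core adjacency graph, grown by an iterative
#' worklist (equivalent to the textbook recursive expansion but without a
#' stack-depth limit). Labels are deterministic: components are numbered by
#' their smallest contained row index and an edge point adjacent to several
#' clusters joins the lowest-labeled one — the classic order-dependence of
#' DBSCAN edge assignment is removed by this rule.
#'
#' @param table a `loc_table` (or data.frame with `x`, `y`).
#' @param eps neighbourhood radius; in camera px by default, in nm when
#'   `units = "nm"` (positions are then scaled by the table's
#'   `pixel_size_nm`).
#' @param min_points minimum neighbour count for a core point.
#' @param count_self include the point itself in its neighbour count
#'   (standard convention; default TRUE).
#' @param units `"px"` or `"nm"`.
#' @return a `cluster_result`: list with `label` (cluster id >= 0, noise
#'   -1), `role` (`"core"`, `"edge"`, `"noise"`), `eps`, `min_points`,
#'   `units`.
#' @export
dbscan_locs <- function(table, eps, min_points, count_self = TRUE,
                        units = c("px", "nm")) {
  units <- match.arg(units)
  stopifnot(eps > 0, min_points >= 1)
  df <- as.data.frame(table)
  n <- nrow(df)
  if (n == 0)
    return(structure(list(label = integer(0), role = character(0),
                          eps = eps, min_points = min_points, units = units),
                     class = "cluster_result"))
  scale <- if (units == "nm") (attr(table, "pixel_size_nm") %||% 1) else 1
  xy <- cbind(df$x, df$y) * scale
  dd <- as.matrix(dist(xy))
  nb <- dd <= eps
  if (!count_self) diag(nb) <- FALSE
  counts <- rowSums(nb)
  core <- counts >= min_points
  label <- rep(-1L, n)
  role <- rep("noise", n)
  role[core] <- "core"
  next_label <- 0L
  for (seed in seq_len(n)) {
    if (!core[seed] || label[seed] >= 0) next
    # iterative worklist expansion of one core-connected component
    label[seed] <- next_label
    work <- seed
    while (length(work)) {
      p <- work[[1]]; work <- work[-1]
      nbrs <- which(nb[p, ] & core & label < 0)
      label[nbrs] <- next_label
      work <- c(work, nbrs)
    }
    next_label <- next_label + 1L
  }
  # edge points: non-core within eps of a core; lowest adjacent label wins
  for (p in which(!core)) {
    adj <- label[nb[p, ] & core]
    if (length(adj)) {
      label[p] <- min(adj)
      role[p] <- "edge"
    }
  }
  structure(list(label = label, role = role, eps = eps,
                 min_points = min_points, units = units),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  k <- length(unique(x$label[x$label >= 0]))
  cat(sprintf("cluster_result: %d point(s), %d cluster(s), %d noise (eps %g %s, minPts %d)\n",
              length(x$label), k, sum(x$label < 0), x$eps, x$units,
              x$min_points))
  invisible(x)
}

#' Per-cluster summary statistics
#'
#' @param result a `cluster_result` from [dbscan_locs].
#' @param table the clustered `loc_table` (same row order).
#' @return data.frame with one row per cluster: `cluster`, `n_points`,
#'   `centroid_x`, `centroid_y`, `radius_gyration`, bounding box. Noise is
#'   excluded.
#' @export
summarize_clusters <- function(result, table) {
  df <- as.data.frame(table)
  stopifnot(length(result$label) == nrow(df))
  ids <- sort(unique(result$label[result$label >= 0]))
  if (!length(ids))
    return(data.frame(cluster = integer(0), n_points = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      radius_gyration = numeric(0),
                      xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0)))
  do.call(rbind, lapply(ids, function(id) {
    i <- which(result$label == id)
    cx <- mean(df$x[i]); cy <- mean(df$y[i])
    rg <- sqrt(mean((df$x[i] - cx)^2 + (df$y[i] - cy)^2))
    data.frame(cluster = id, n_points = length(i),
               centroid_x = cx, centroid_y = cy, radius_gyration = rg,
               xmin = min(df$x[i]), xmax = max(df$x[i]),
               ymin = min(df$y[i]), ymax = max(df$y[i]))
  }))
}
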
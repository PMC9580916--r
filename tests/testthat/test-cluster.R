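test_that("basic DBSCAN roles are assigned correctly", {
  # 3 points pairwise within eps, min_points 3: all core, one cluster
  tab <- loc_table(frame = 0L, x = c(0, 0.5, 0.25), y = c(0, 0, 0.4),
                   intensity = 1)
  r <- dbscan_locs(tab, eps = 1, min_points = 3)
  expect_true(all(r$role == "core"))
  expect_true(all(r$label == 0L))
  # isolated point with min_points >= 2 is noise
  iso <- loc_table(frame = 0L, x = c(0, 10), y = c(0, 0), intensity = 1)
  r2 <- dbscan_locs(iso, eps = 1, min_points = 2)
  expect_true(all(r2$label == -1L))
  expect_true(all(r2$role == "noise"))
})

test_that("edge points attach to an adjacent core's cluster", {
  # dense blob + one point within eps of the blob boundary only
  tab <- loc_table(frame = 0L, x = c(0, 0.1, 0.2, 0.45), y = rep(0, 4),
                   intensity = 1)
  r <- dbscan_locs(tab, eps = 0.3, min_points = 3)
  expect_equal(r$role, c("core", "core", "core", "edge"))
  expect_equal(r$label[4], r$label[1])
})

test_that("DBSCAN matches the brute-force oracle over random cases", {
  for (trial in 1:20) {
    set.seed(trial)
    n <- sample(50:200, 1)
    xy <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    eps <- runif(1, 0.2, 1.5)
    mp <- sample(2:8, 1)
    tab <- loc_table(frame = 0L, x = xy[, 1], y = xy[, 2], intensity = 1)
    r <- dbscan_locs(tab, eps, mp)
    expect_identical(r$label, oracle_dbscan(xy, eps, mp))
  }
})

test_that("count_self flag shifts the core threshold by one neighbour", {
  tab <- loc_table(frame = 0L, x = c(0, 0.1, 0.2), y = rep(0, 3), intensity = 1)
  with_self <- dbscan_locs(tab, 0.5, 3, count_self = TRUE)
  without <- dbscan_locs(tab, 0.5, 3, count_self = FALSE)
  expect_true(all(with_self$role == "core"))
  expect_false(any(without$role == "core"))
})

test_that("row permutation changes labels only via the documented rule", {
  set.seed(30)
  n <- 120
  xy <- cbind(runif(n, 0, 8), runif(n, 0, 8))
  tab <- loc_table(frame = 0L, x = xy[, 1], y = xy[, 2], intensity = 1)
  r1 <- dbscan_locs(tab, 0.6, 4)
  perm <- sample(n)
  tab2 <- loc_table(frame = 0L, x = xy[perm, 1], y = xy[perm, 2], intensity = 1)
  r2 <- dbscan_locs(tab2, 0.6, 4)
  # the core/edge/noise partition is permutation invariant
  expect_identical(r2$role, r1$role[perm])
  # cluster memberships agree up to relabeling
  both <- r1$label[perm] >= 0 & r2$label >= 0
  expect_true(all((r1$label[perm] >= 0) == (r2$label >= 0)))
  map <- tapply(r2$label[both], r1$label[perm][both],
                function(v) length(unique(v)))
  expect_true(all(map == 1))
})

test_that("increasing eps never demotes a core point", {
  set.seed(31)
  tab <- rand_table(150, box = 8, seed = 31)
  r_small <- dbscan_locs(tab, 0.4, 4)
  r_large <- dbscan_locs(tab, 0.8, 4)
  expect_true(all(which(r_small$role == "core") %in%
                    which(r_large$role == "core")))
})

test_that("cluster summaries have closed-form values on a unit square", {
  tab <- loc_table(frame = 0L, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                   intensity = 1)
  r <- dbscan_locs(tab, eps = 1.5, min_points = 3)
  s <- summarize_clusters(r, tab)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_points, 4L)
  expect_equal(c(s$centroid_x, s$centroid_y), c(0.5, 0.5))
  expect_equal(s$radius_gyration, sqrt(0.5))
  # empty result summarizes to an empty frame
  noise <- dbscan_locs(loc_table(frame = 0L, x = 0, y = 0, intensity = 1),
                       0.1, 5)
  expect_equal(nrow(summarize_clusters(noise,
                                       loc_table(frame = 0L, x = 0, y = 0,
                                                 intensity = 1))), 0)
})

test_that("well-separated simulated clusters are recovered exactly", {
  set.seed(32)
  k <- 10
  centres <- cbind(5 + 8 * (0:(k - 1) %% 5), 5 + 8 * (0:(k - 1) %/% 5))
  pts <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(30, centres[i, 1], 0.2), rnorm(30, centres[i, 2], 0.2))))
  noise <- cbind(runif(20, 0, 45), runif(20, 0, 25))
  all_pts <- rbind(pts, noise)
  tab <- loc_table(frame = 0L, x = all_pts[, 1], y = all_pts[, 2],
                   intensity = 1)
  r <- dbscan_locs(tab, eps = 0.8, min_points = 5)
  s <- summarize_clusters(r, tab)
  expect_equal(nrow(s), k)
  expect_true(all(s$n_points >= 28))
})

test_that("nm units scale the radius through the pixel size", {
  tab <- loc_table(frame = 0L, x = c(0, 0.4), y = c(0, 0), intensity = 1,
                   pixel_size_nm = 100)
  # 0.4 px = 40 nm apart: eps 50 nm links them, eps 30 nm does not
  r1 <- dbscan_locs(tab, 50, 2, units = "nm")
  r2 <- dbscan_locs(tab, 30, 2, units = "nm")
  expect_true(all(r1$label == 0))
  expect_true(all(r2$label == -1))
})
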
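test_that("close localizations in consecutive frames share a track", {
  tab <- loc_table(frame = c(0, 1), x = c(0, 0.1), y = c(0, 0), intensity = 1)
  out <- link_localizations(tab, link_params(0.5, 0))
  expect_equal(out$track_id[1], out$track_id[2])
  far <- loc_table(frame = c(0, 1), x = c(0, 2), y = c(0, 0), intensity = 1)
  out2 <- link_localizations(far, link_params(0.5, 0))
  expect_equal(sort(unique(out2$track_id)), c(0L, 1L))
})

test_that("gap tolerance controls linking across dark frames", {
  tab <- loc_table(frame = c(0, 2), x = c(0, 0.05), y = c(0, 0), intensity = 1)
  expect_equal(length(unique(link_localizations(tab, link_params(1, 1))$track_id)), 1)
  expect_equal(length(unique(link_localizations(tab, link_params(1, 0))$track_id)), 2)
  # frame t+1 has priority over t+2
  tri <- loc_table(frame = c(0, 1, 2), x = c(0, 0.3, 0.01), y = c(0, 0, 0),
                   intensity = 1)
  out <- link_localizations(tri, link_params(1, 1))
  expect_equal(out$track_id[1], out$track_id[2])  # linked to nearer-in-time
})

test_that("greedy ascending-distance assignment matches exhaustive reasoning", {
  # heads A(0,0), B(1,0); candidates C1(0.1,0), C2(0.0,0.12)
  # pair distances: A-C1 0.1, A-C2 0.12, B-C1 0.9, B-C2 ~1.007
  # greedy: A-C1 first, then B-C1 taken -> B-C2
  tab <- loc_table(frame = c(0, 0, 1, 1), x = c(0, 1, 0.1, 0.0),
                   y = c(0, 0, 0, 0.12), intensity = 1)
  out <- link_localizations(tab, link_params(2, 0))
  expect_equal(out$track_id[3], out$track_id[1])  # A gets C1
  expect_equal(out$track_id[4], out$track_id[2])  # B gets C2
  # distance tie broken by lower candidate row index
  tie <- loc_table(frame = c(0, 1, 1), x = c(0, 0.1, -0.1), y = c(0, 0, 0),
                   intensity = 1)
  out2 <- link_localizations(tie, link_params(1, 0))
  expect_equal(out2$track_id[2], out2$track_id[1])
})

test_that("track ids are consecutive from 0 in order of track start", {
  tab <- loc_table(frame = c(0, 0, 1, 3), x = c(0, 5, 0.1, 9),
                   y = c(0, 0, 0, 0), intensity = 1)
  out <- link_localizations(tab, link_params(0.5, 0))
  expect_equal(out$track_id, c(0L, 1L, 0L, 2L))
})

test_that("unsorted input errors unless auto_sort", {
  tab <- loc_table(frame = c(1, 0), x = c(0, 0), y = c(0, 0), intensity = 1)
  expect_error(link_localizations(tab, link_params(1, 0)), "sorted")
  expect_warning(out <- link_localizations(tab, link_params(1, 0),
                                           auto_sort = TRUE), "sorting")
  expect_equal(length(unique(out$track_id)), 1)
})

test_that("merging computes intensity-weighted means and conserves intensity", {
  tab <- loc_table(frame = c(1, 2), x = c(0.0, 0.2), y = c(1, 1),
                   intensity = c(100, 300), track_id = 0L)
  m <- merge_linked(tab)
  expect_equal(nrow(m), 1)
  expect_equal(m$frame, 1L)
  expect_equal(m$x, 0.15)
  expect_equal(m$intensity, 400)
  # singleton passes through
  s <- loc_table(frame = 5, x = 2, y = 3, intensity = 7, track_id = 1L)
  expect_equal(as.data.frame(merge_linked(s)), as.data.frame(s))
})

test_that("merging conserves total intensity and counts tracks", {
  set.seed(8)
  tab <- rand_table(200, seed = 8)
  linked <- link_localizations(tab, link_params(1.5, 1))
  m <- merge_linked(linked)
  expect_equal(sum(m$intensity), sum(tab$intensity), tolerance = 1e-9)
  expect_equal(nrow(m), length(unique(linked$track_id)))
})

test_that("excluded (fiducial) tracks pass through unmerged", {
  tab <- loc_table(frame = c(0, 1, 0, 1), x = c(0, 0.05, 5, 5.05),
                   y = c(0, 0, 0, 0), intensity = 10,
                   track_id = c(0L, 0L, 1L, 1L))
  m <- merge_linked(tab, exclude_ids = 1L)
  expect_equal(nrow(m), 3)   # track 0 merged, track 1 kept as 2 rows
  expect_equal(sum(m$track_id == 1), 2)
})

test_that("zero-intensity tracks merge with an unweighted mean and warning", {
  tab <- loc_table(frame = c(0, 1), x = c(0, 1), y = c(0, 0), intensity = 0,
                   track_id = 0L)
  expect_warning(m <- merge_linked(tab), "zero total intensity")
  expect_equal(m$x, 0.5)
})

test_that("merging a blinking emitter improves precision ~ sqrt(n)", {
  sigma <- 0.08; n_rep <- 200
  set.seed(21)
  merged_x <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    # 3 on-periods of 4 frames each, gaps of 2 dark frames (within tolerance)
    frames <- c(0:3, 6:9, 12:15)
    tab <- loc_table(frame = frames, x = 10 + rnorm(12, 0, sigma),
                     y = 10 + rnorm(12, 0, sigma), intensity = 1000)
    linked <- link_localizations(tab, link_params(1, 2))
    m <- merge_linked(linked)
    expect_equal(nrow(m), 1)
    merged_x[i] <- m$x
  }
  ratio <- sigma / sd(merged_x)
  expect_gt(ratio, sqrt(12) * 0.75)
  expect_lt(ratio, sqrt(12) * 1.35)
})
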
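test_that("a rendered Gaussian spot is detected at sub-pixel accuracy", {
  f <- spot_frame(100, 120, xs = 60, ys = 40)
  d <- detect_cells(f)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 60)^2 + (d$y - 40)^2), 0.5)
  # off-grid position
  f2 <- spot_frame(100, 120, xs = 33.4, ys = 71.8)
  d2 <- detect_cells(f2)
  expect_lt(sqrt((d2$x - 33.4)^2 + (d2$y - 71.8)^2), 0.5)
  # blank frames give zero detections, not an error
  expect_equal(nrow(detect_cells(matrix(0, 50, 50))), 0)
  expect_error(detect_cells(f, min_area = 0), "min_area")
})

test_that("spot pairs split or merge with their separation", {
  sigma <- 2  # detection smoothing; spots are point-like (narrower)
  # separation > 4 sigma: two detections
  f_far <- spot_frame(80, 80, xs = c(30, 30 + 4.5 * sigma), ys = c(40, 40),
                      sigma = 1)
  expect_equal(nrow(detect_cells(f_far, sigma_px = sigma)), 2)
  # separation < 1 sigma: one merged detection
  f_near <- spot_frame(80, 80, xs = c(30, 30 + 0.8 * sigma), ys = c(40, 40),
                       sigma = 1)
  expect_equal(nrow(detect_cells(f_near, sigma_px = sigma)), 1)
  # detections come ordered by (y, x)
  f3 <- spot_frame(80, 80, xs = c(60, 10, 40), ys = c(10, 10, 60))
  d3 <- detect_cells(f3)
  expect_equal(order(d3$y, d3$x), seq_len(nrow(d3)))
})

test_that("stationary and parallel movers link without identity swaps", {
  det <- do.call(rbind, lapply(0:20, function(t) {
    data.frame(time_index = t, x = 10, y = 10)
  }))
  tr <- link_tracks(det, gate_px = 5)
  expect_equal(length(unique(tr$id)), 1)
  expect_equal(nrow(tr), 21)
  expect_equal(path_length(tr, voxel_geometry(1, 1, 1, 1), mode = "2d"), 0)

  det2 <- do.call(rbind, lapply(0:10, function(t) {
    data.frame(time_index = t, x = 10 + 2 * t, y = c(10, 60))
  }))
  tr2 <- link_tracks(det2, gate_px = 5)
  expect_equal(length(unique(tr2$id)), 2)
  for (i in unique(tr2$id)) {
    expect_equal(length(unique(tr2$y[tr2$id == i])), 1)  # no swap across lanes
  }
})

test_that("gaps bridge up to max_gap and terminate beyond it", {
  present <- setdiff(0:8, 4)
  det <- do.call(rbind, lapply(present, function(t) {
    data.frame(time_index = t, x = 2 * t, y = 0)
  }))
  tr <- link_tracks(det, gate_px = 5, max_gap = 1)
  expect_equal(length(unique(tr$id)), 1)
  expect_equal(tr$status[tr$time_index == 4], "gap-filled")
  expect_equal(tr$x[tr$time_index == 4], 8)  # linear interpolation
  # absence of max_gap + 1 frames starts a new id
  det2 <- do.call(rbind, lapply(setdiff(0:8, 4:5), function(t) {
    data.frame(time_index = t, x = 2 * t, y = 0)
  }))
  tr2 <- link_tracks(det2, gate_px = 8, max_gap = 1)
  expect_equal(length(unique(tr2$id)), 2)
  expect_true(all(tr2$status == "detected"))
  expect_identical(nrow(link_tracks(det[0, ], gate_px = 5)), 0L)
})

test_that("linking equals the brute-force assignment oracle", {
  set.seed(33)
  for (case in 1:25) {
    n_frames <- sample(2:6, 1)
    det_list <- lapply(seq_len(n_frames) - 1L, function(t) {
      n <- sample(0:5, 1)
      data.frame(time_index = rep(t, n), x = runif(n, 0, 40),
                 y = runif(n, 0, 40))
    })
    gate <- runif(1, 5, 25)
    got <- link_tracks(det_list, gate_px = gate, max_gap = 0)
    want <- bf_link(det_list, gate)
    expect_equal(partition_signature(got), bf_partition_signature(want))
  }
})

test_that("seeded tracking follows spots and stops on background", {
  frames <- lapply(0:5, function(t) spot_frame(100, 120, 60, 40))
  st <- seeded_track(c(0, 60, 40), frames)
  expect_equal(nrow(st), 6)
  expect_true(all(sqrt((st$x - 60)^2 + (st$y - 40)^2) < 0.5))
  expect_false(attr(st, "terminated")[["1"]])
  # seed on background: length-1 track flagged terminated
  st_bg <- seeded_track(c(0, 5, 5), frames)
  expect_equal(nrow(st_bg), 1)
  expect_true(attr(st_bg, "terminated")[["1"]])
  expect_error(seeded_track(c(0, 500, 5), frames), "bounds")
  # seeded and automatic tracking agree on an isolated mover
  mover <- lapply(0:5, function(t) spot_frame(100, 120, 40 + 3 * t, 50 + 2 * t))
  auto <- link_tracks(lapply(seq_along(mover) - 1L, function(t) {
    detect_cells(mover[[t + 1]], time_index = t)
  }), gate_px = 10)
  sd_tr <- seeded_track(c(0, 40, 50), mover)
  m <- merge(auto, sd_tr, by = "time_index")
  expect_true(all(sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2) < 1))
})

test_that("manual track import is verbatim, sorted, and validated", {
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = c("a", "a", "a", "b"), time_index = c(2, 0, 1, 0),
                   x = c(3, 1, 2, 9), y = c(30, 10, 20, 90))
  write.csv(df, csv, row.names = FALSE)
  tr <- import_manual_track(csv)
  expect_s3_class(tr, "tracks2d")
  expect_equal(tr$time_index[tr$id == "a"], 0:2)
  expect_equal(tr$x[tr$id == "a"], c(1, 2, 3))  # values preserved, reordered
  expect_true(all(tr$status == "manual"))
  # 1 id x 21 rows
  big <- data.frame(id = 1, time_index = 0:20, x = 1:21, y = 0)
  expect_equal(nrow(import_manual_track(big)), 21)
  dup <- rbind(df, df[1, ])
  expect_error(import_manual_track(dup), "format error")
  expect_error(import_manual_track(df[, -1]), "format error")
})
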
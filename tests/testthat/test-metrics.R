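g_def <- voxel_geometry()
g_unit <- voxel_geometry(1, 1, 1, 1)

test_that("path length follows anisotropic closed forms", {
  # 10 steps of +1 px in x at default geometry
  tr <- data.frame(id = 1, time_index = 0:10, x = 0:10, y = 0, z = 0,
                   status = "detected")
  expect_equal(path_length(tr, g_def), 10 * 0.589)
  # one step of (1 px, 0, 1 slice)
  tr2 <- data.frame(id = 1, time_index = 0:1, x = c(0, 1), y = 0, z = c(0, 1),
                    status = "detected")
  expect_equal(path_length(tr2, g_def), sqrt(0.589^2 + 2^2))
  # stationary
  tr3 <- data.frame(id = 1, time_index = 0:20, x = 5, y = 5, z = 5,
                    status = "detected")
  expect_equal(path_length(tr3, g_def), 0)
  # single point
  expect_equal(path_length(tr3[1, ], g_def), 0)
  # 2D mode ignores z
  expect_equal(path_length(tr2, g_def, mode = "2d"), 0.589)
  # gap-filled points excluded by default, included on demand
  tr4 <- data.frame(id = 1, time_index = 0:2, x = c(0, 5, 1), y = 0, z = 0,
                    status = c("detected", "gap-filled", "detected"))
  expect_equal(path_length(tr4, g_unit), 1)
  expect_equal(path_length(tr4, g_unit, include_gapfilled = TRUE), 9)
})

test_that("distance from origin mirrors out-and-back trajectories", {
  out_back <- data.frame(id = 1, time_index = 0:8,
                         x = c(0:4, 3:0), y = 0, z = 0, status = "detected")
  d <- distance_from_origin(out_back, g_unit)
  expect_equal(d$dist_um[1], 0)
  expect_equal(d$dist_um[9], 0)            # returned to start
  expect_equal(path_length(out_back, g_unit), 8)  # yet the path is long
  # straight mover: strictly increasing, equals cumulative path
  straight <- data.frame(id = 1, time_index = 0:5, x = 0:5, y = 0, z = 0,
                         status = "detected")
  ds <- distance_from_origin(straight, g_def)
  expect_true(all(diff(ds$dist_um) > 0))
  expect_equal(ds$dist_um[6], path_length(straight, g_def))
  expect_equal(distance_from_origin(straight[1, ], g_def)$dist_um, 0)
})

test_that("speeds scale with step length and frame interval", {
  tr <- data.frame(id = 1, time_index = 0:1, x = c(0, 2), y = 0, z = 0,
                   status = "detected")
  sp <- speeds(tr, g_def)
  expect_equal(sp$mean_um_min, 2 * 0.589 / 30)
  expect_equal(sp$instantaneous$speed_um_min, 2 * 0.589 / 30)
  # stationary: all zeros
  trs <- data.frame(id = 1, time_index = 0:4, x = 1, y = 1, z = 1,
                    status = "detected")
  expect_true(all(speeds(trs, g_def)$instantaneous$speed_um_min == 0))
  # doubling dt halves all speeds
  g2 <- voxel_geometry(dt = 60)
  expect_equal(speeds(tr, g2)$mean_um_min, sp$mean_um_min / 2)
  # single point
  sp1 <- speeds(tr[1, ], g_def)
  expect_equal(sp1$mean_um_min, 0)
  expect_equal(nrow(sp1$instantaneous), 0)
})

test_that("metric invariants hold on random tracks", {
  set.seed(51)
  for (case in 1:60) {
    tr <- random_track(sample(2:25, 1))
    d <- distance_from_origin(tr, g_def)
    cum <- c(0, cumsum(tracker3d:::step_lengths_um(tr, g_def, "3d")))
    expect_true(all(d$dist_um <= cum + 1e-9))
    tm <- track_metrics(tr, g_def)
    expect_lte(tm$net_disp_um, tm$path_length_um + 1e-9)
    expect_gte(tm$straightness, 0)
    expect_lte(tm$straightness, 1 + 1e-12)
    # translation invariance
    tr2 <- tr; tr2$x <- tr2$x + 100; tr2$y <- tr2$y - 50; tr2$z <- tr2$z + 7
    expect_equal(track_metrics(tr2, g_def)[, -1], tm[, -1], tolerance = 1e-9)
    # time reversal preserves path length
    tr3 <- tr; tr3$time_index <- rev(tr3$time_index)
    expect_equal(path_length(tr3, g_def), tm$path_length_um)
  }
})

test_that("cohort averages follow symmetry and identical-copy rules", {
  tr <- random_track(10)
  copies <- rbind(tr, transform(tr, id = 2), transform(tr, id = 3))
  cs <- cohort_summary(copies, g_def)
  one <- distance_from_origin(tr, g_def)
  expect_equal(cs$average$mean_dist_origin_um, one$dist_um)
  expect_equal(unname(cs$dist_origin["2", ]), one$dist_um)
  # mirror movers: the average distance curve equals either one's
  a <- data.frame(id = 1, time_index = 0:5, x = 0:5, y = 0, z = 0,
                  status = "detected")
  b <- transform(a, id = 2, x = -x)
  cs2 <- cohort_summary(rbind(a, b), g_unit)
  expect_equal(cs2$average$mean_dist_origin_um,
               distance_from_origin(a, g_unit)$dist_um)
  # tracks only average where defined
  short <- transform(a[1:3, ], id = 3)
  cs3 <- cohort_summary(rbind(a, short), g_unit)
  expect_equal(cs3$average$n_tracks, c(2, 2, 2, 1, 1, 1))
})
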
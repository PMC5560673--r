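test_that("an integer (5, 3, 2)-voxel translation is recovered exactly", {
  set.seed(21)
  base <- array(rpois(48 * 40 * 20, 50), c(48, 40, 20))
  base[20:25, 15:20, 8:12] <- base[20:25, 15:20, 8:12] + 500
  moved <- roll_stack(base, dy = 3, dx = 5, dz = 2)
  tl <- timelapse(list(base, moved))
  res <- align_timelapse(tl, reference_index = 0)
  tr <- res$transforms[[2]]
  expect_equal(c(tr$dx, tr$dy, tr$dz), c(5, 3, 2))
  expect_true(tracker3d:::is_identity_transform(res$transforms[[1]]))
})

test_that("self-alignment yields identity transforms and is idempotent", {
  set.seed(22)
  s <- array(rpois(30 * 30 * 10, 80), c(30, 30, 10))
  s[10:14, 10:14, 4:6] <- 900
  tl <- timelapse(rep(list(s), 4))
  res <- align_timelapse(tl)
  for (tr in res$transforms) {
    expect_true(tracker3d:::is_identity_transform(tr))
  }
  # aligning the aligned time-lapse changes nothing
  res2 <- align_timelapse(res$timelapse)
  shifts <- vapply(res2$transforms,
                   function(t) max(abs(c(t$dx, t$dy, t$dz))), numeric(1))
  expect_lt(max(shifts), 0.5)
  # single frame: one identity transform
  one <- align_timelapse(timelapse(list(s)))
  expect_length(one$transforms, 1)
  expect_true(tracker3d:::is_identity_transform(one$transforms[[1]]))
})

test_that("rigid transforms compose with their inverse to the identity", {
  tr <- rigid_transform(2.5, -1.25, 0.5, rotation_deg = 17)
  inv <- invert_transform(tr)
  # composite mapping of sample points must return them unchanged
  a <- tr$rotation_deg * pi / 180
  map <- function(t, p) {
    c(cos(t$rotation_deg * pi / 180) * p[1] - sin(t$rotation_deg * pi / 180) * p[2] + t$dx,
      sin(t$rotation_deg * pi / 180) * p[1] + cos(t$rotation_deg * pi / 180) * p[2] + t$dy,
      p[3] + t$dz)
  }
  for (p in list(c(0, 0, 0), c(3, -2, 1), c(-7.5, 4.25, 9))) {
    expect_equal(map(inv, map(tr, p)), p, tolerance = 1e-6)
  }
})

test_that("integer shifts resample exactly and zero-fill the frame edge", {
  set.seed(23)
  s <- array(runif(10 * 12 * 6, 1, 2), c(10, 12, 6))
  out <- apply_transform(s, rigid_transform(2, 1, 1))
  expect_equal(out[1:9, 1:10, 1:5], s[2:10, 3:12, 2:6])
  expect_true(all(out[10, , ] == 0))
  expect_true(all(out[, 11:12, ] == 0))
  expect_true(all(out[, , 6] == 0))
  # identity transform returns input unchanged
  expect_identical(apply_transform(s, rigid_transform()), s)
})

test_that("low-confidence registration falls back to zero shift", {
  set.seed(24)
  a <- array(rpois(20 * 20 * 5, 100), c(20, 20, 5))
  b <- array(rpois(20 * 20 * 5, 100), c(20, 20, 5))  # unrelated noise
  tl <- timelapse(list(a, b))
  expect_warning(res <- align_timelapse(tl, min_confidence = 0.9),
                 "confidence")
  tr <- res$transforms[[2]]
  expect_equal(c(tr$dx, tr$dy), c(0, 0))
})
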
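test_that("a known vignetting field is recovered from shaded planes", {
  set.seed(7)
  ny <- 60; nx <- 80
  G <- vignetting_field(dims = c(ny, nx), strength = 0.4)
  O <- matrix(5, ny, nx)
  planes <- lapply(1:30, function(k) G * (50 + runif(1, 0, 100)) + O)
  m <- estimate_illumination(planes)
  expect_gt(cor(as.vector(m$gain), as.vector(G)), 0.95)
  expect_equal(mean(m$gain), 1, tolerance = 1e-8)
  expect_true(all(m$gain > 0))
  # offset never exceeds the per-pixel minimum of the training planes
  pmin_all <- Reduce(pmin, planes)
  expect_true(all(m$offset <= pmin_all + 1e-9))
})

test_that("correction inverts the model exactly on noiseless input", {
  set.seed(8)
  G <- vignetting_field(dims = c(40, 50), strength = 0.3)
  m <- structure(list(gain = G, offset = matrix(3, 40, 50)),
                 class = "illumination_model")
  img <- m$gain * 50 + m$offset
  expect_equal(correct_illumination(img, m), matrix(50, 40, 50),
               tolerance = 1e-12)
  # identity model leaves input untouched
  id <- structure(list(gain = matrix(1, 40, 50), offset = matrix(0, 40, 50)),
                  class = "illumination_model")
  x <- matrix(runif(2000, 0, 100), 40, 50)
  expect_identical(correct_illumination(x, id), x)
  # 3D applies per slice
  st <- array(runif(40 * 50 * 3, 10, 100), c(40, 50, 3))
  cor3 <- correct_illumination(st, id)
  expect_identical(cor3, st)
  expect_error(correct_illumination(matrix(1, 10, 10), m), "10x10")
})

test_that("degenerate collections follow the documented conventions", {
  planes <- lapply(1:5, function(k) matrix(100, 12, 12))
  m <- estimate_illumination(planes)
  expect_equal(m$gain, matrix(1, 12, 12))
  expect_equal(m$offset, matrix(100, 12, 12))
  expect_error(estimate_illumination(planes[1]), "insufficient")
  expect_error(estimate_illumination(list(matrix(1, 3, 3), matrix(1, 4, 4))),
               "shape")
})

test_that("correction flattens vignetted planes of varying brightness", {
  # the offset/gain decomposition is identifiable when the training
  # collection spans a range of brightness down to near-dark planes, as
  # the edge slices of a real z-stack do
  set.seed(9)
  ny <- 64; nx <- 64
  G <- vignetting_field(dims = c(ny, nx), strength = 0.5)
  S <- c(runif(27, 60, 260), runif(3, 0, 5))
  O <- matrix(20, ny, nx)
  planes <- lapply(S, function(s) {
    matrix(rpois(ny * nx, as.vector(G * s + O)), ny, nx)
  })
  m <- estimate_illumination(planes)
  corrected <- lapply(planes, correct_illumination, model = m)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(median(vapply(corrected, cv, numeric(1))),
            median(vapply(planes, cv, numeric(1))))
  # on noiseless planes from the same model, correction recovers the clean
  # signal up to a per-plane scale (relative RMSE < 5%)
  clean <- lapply(S, function(s) G * s + O)
  m2 <- estimate_illumination(clean)
  bright <- which(S > 50)
  rel_rmse <- vapply(lapply(clean[bright], correct_illumination, model = m2),
                     function(p) {
    s <- mean(p)
    sqrt(mean((p - s)^2)) / s
  }, numeric(1))
  expect_lt(median(rel_rmse), 0.05)
})

test_that("illumination model survives a save/load round trip", {
  set.seed(10)
  m <- estimate_illumination(lapply(1:6, function(k) {
    matrix(runif(400, 50, 150), 20, 20)
  }))
  path <- withr::local_tempfile(fileext = ".tif")
  write_illumination(m, path)
  m2 <- read_illumination(path)
  expect_equal(m2$gain, m$gain, tolerance = 1e-6)
  expect_equal(m2$offset, m$offset, tolerance = 1e-6)
})
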
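test_that("surface walks respect the sphere and closed forms", {
  cfg <- sim_config(sphere_diameter_um = 100, volume_px = c(220, 220, 70),
                    n_cells = 5, n_frames = 15, step_um = 6,
                    persistence = 1, seed = 5)
  tru <- simulate_tracks(cfg)
  ctr <- tracker3d:::volume_center_um(cfg)
  r <- 50
  rad <- sqrt((tru$tracks$x_um - ctr[1])^2 + (tru$tracks$y_um - ctr[2])^2 +
                (tru$tracks$z_um - ctr[3])^2)
  expect_lt(max(abs(rad - r)), 1e-6)
  # persistence 1: path length exactly k * s ...
  g <- cfg$geometry
  for (i in unique(tru$tracks$id)) {
    tr <- tru$tracks[tru$tracks$id == i, ]
    expect_equal(path_length(tr, g), 14 * 6, tolerance = 1e-9)
    # ... and distance from origin the chord of the accumulated arc
    theta <- 2 * asin(6 / (2 * r))
    d <- distance_from_origin(tr, g)
    expect_equal(d$dist_um[15], 2 * r * sin(14 * theta / 2), tolerance = 1e-9)
  }
})

test_that("persistence separates directed from undirected motion", {
  mk <- function(pers, seed) {
    cfg <- sim_config(sphere_diameter_um = 240, volume_px = c(512, 512, 150),
                      n_cells = 12, n_frames = 21, step_um = 10,
                      persistence = pers, seed = seed)
    tru <- simulate_tracks(cfg)
    mean(vapply(split(tru$tracks, tru$tracks$id), function(tr) {
      d <- distance_from_origin(tr, cfg$geometry)
      d$dist_um[nrow(d)]
    }, numeric(1)))
  }
  directed <- mk(0.9, 61)
  undirected <- mk(0, 61)
  expect_gte(directed / undirected, 2)
})

test_that("simulation is reproducible and validates its config", {
  cfg <- sim_config(sphere_diameter_um = 60, volume_px = c(128, 128, 40),
                    n_cells = 3, n_frames = 4, seed = 9)
  t1 <- simulate_tracks(cfg)
  t2 <- simulate_tracks(cfg)
  expect_identical(t1$tracks, t2$tracks)
  r1 <- render_timelapse(t1, cfg)
  r2 <- render_timelapse(t2, cfg)
  expect_identical(get_stack(r1, 2), get_stack(r2, 2))
  # empty cohort
  cfg0 <- sim_config(n_cells = 0, n_frames = 3,
                     sphere_diameter_um = 60, volume_px = c(128, 128, 40))
  expect_equal(nrow(simulate_tracks(cfg0)$tracks), 0)
  # invalid configs
  expect_error(sim_config(sphere_diameter_um = 400,
                          volume_px = c(512, 512, 150)), "does not fit")
  expect_error(sim_config(vignetting_strength = 1), "\\[0, 1\\)")
  expect_error(simulate_tracks(
    sim_config(sphere_diameter_um = 60, volume_px = c(128, 128, 40),
               step_um = 40)), "radius")
})

test_that("rendering degenerates to pure background without cells or noise", {
  cfg <- sim_config(n_cells = 0, n_frames = 2, sphere_diameter_um = 40,
                    volume_px = c(80, 80, 24), background_level = 77,
                    poisson = FALSE, read_sigma = 0, vignetting_strength = 0,
                    shell_amplitude = 0)
  tl <- render_timelapse(simulate_tracks(cfg), cfg)
  expect_true(all(get_stack(tl, 0) == 77))
  expect_true(all(get_stack(tl, 1) == 77))
})

test_that("a noiseless rendered cell is recovered at its true slice", {
  cfg <- sim_config(sphere_diameter_um = 50, volume_px = c(96, 96, 40),
                    n_cells = 1, n_frames = 3, step_um = 4, poisson = FALSE,
                    read_sigma = 0, vignetting_strength = 0,
                    shell_amplitude = 0, seed = 13)
  tru <- simulate_tracks(cfg)
  tl <- render_timelapse(tru, cfg)
  z <- recover_z(tru$tracks[, c("id", "time_index", "x", "y")], tl)
  expect_true(all(abs(z$z - round(tru$tracks$z)) <= 1))
  expect_equal(round(z$z), round(tru$tracks$z))
})

test_that("the vignetting field follows its algebra and is recoverable", {
  flat <- vignetting_field(dims = c(32, 48), strength = 0)
  expect_equal(flat, matrix(1, 32, 48))
  g <- vignetting_field(dims = c(65, 65), strength = 0.5)  # odd: centre on-grid
  expect_equal(mean(g), 1)
  # centre/corner ratio 2 before normalization survives normalization
  raw_ratio <- max(g) / min(g)
  expect_equal(raw_ratio, 2, tolerance = 1e-9)
  expect_error(vignetting_field(dims = c(10, 10), strength = 1), "\\[0, 1\\)")
  # cross-module: estimate_illumination recovers the field
  set.seed(15)
  planes <- lapply(1:25, function(k) g * runif(1, 60, 140))
  est <- estimate_illumination(planes)
  expect_gt(cor(as.vector(est$gain), as.vector(g)), 0.95)
})

test_that("disk-backed rendering matches in-memory rendering", {
  cfg <- sim_config(sphere_diameter_um = 25, volume_px = c(48, 48, 20),
                    n_cells = 2, n_frames = 3, step_um = 3, seed = 19)
  tru <- simulate_tracks(cfg)
  mem <- render_timelapse(tru, cfg)
  dir <- withr::local_tempdir()
  dsk <- render_timelapse(tru, cfg, out_dir = dir)
  expect_null(dsk$stacks)
  for (t in 0:2) {
    expect_equal(get_stack(dsk, t), get_stack(mem, t))
  }
})
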
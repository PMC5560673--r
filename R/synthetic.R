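#' Configuration for the synthetic microcarrier simulation
#'
#' The generator emulates a light-sheet time-lapse of point-like
#' fluorescent cells moving on the surface of a spherical microcarrier:
#' 21 frames at 30-minute intervals, 0.589 um lateral sampling and a 2 um
#' z-interval, a ~400 um carrier, anisotropic Gaussian cell profiles over
#' a uniform background, shot (Poisson) noise plus Gaussian read noise,
#' and a smooth radial vignetting gain field. When `volume_px` is omitted
#' it is sized so the carrier fits with a 25% margin.
#'
#' @param sphere_diameter_um Carrier diameter, um.
#' @param n_cells Number of simulated cells.
#' @param n_frames Number of time points.
#' @param geometry A [voxel_geometry()].
#' @param volume_px Integer `c(n_x, n_y, n_z)`; `NULL` = auto-fit.
#' @param step_um Step length per frame, um (the chord moved between
#'   consecutive frames).
#' @param persistence Directional persistence in `[0, 1]`: 0 = undirected
#'   random walk (cells wander and return), values near 1 = directed,
#'   nearly geodesic trajectories.
#' @param motion_mode `"surface"` (cells confined to the carrier surface)
#'   or `"free"` (persistent random walk in the volume, for unit tests).
#' @param psf_sigma_um `c(lateral, axial)` Gaussian widths of a rendered
#'   cell, um.
#' @param cell_amplitude,background_level Intensity units (16-bit range).
#' @param poisson Apply shot noise?
#' @param read_sigma Gaussian read-noise sigma, intensity units.
#' @param vignetting_strength Radial gain fall-off in `[0, 1)`; 0 disables.
#' @param shell_amplitude Amplitude of the faint carrier-shell rendering
#'   (0 = off). The carrier is visible in real acquisitions, and its static
#'   structure is what anchors rigid alignment; the default renders it at a
#'   fraction of the cell amplitude.
#' @param seed Integer seed; a fixed seed makes simulation and rendering
#'   fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sphere_diameter_um = 400, n_cells = 15, n_frames = 21,
                       geometry = voxel_geometry(), volume_px = NULL,
                       step_um = 10, persistence = 0.5,
                       motion_mode = c("surface", "free"),
                       psf_sigma_um = c(2, 4), cell_amplitude = 3000,
                       background_level = 100, poisson = TRUE,
                       read_sigma = 5, vignetting_strength = 0.3,
                       shell_amplitude = 40, seed = 1L) {
  motion_mode <- match.arg(motion_mode)
  geometry <- as_voxel_geometry(geometry)
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (persistence < 0 || persistence > 1) stop("persistence must be in [0, 1]")
  if (vignetting_strength < 0 || vignetting_strength >= 1) {
    stop("vignetting_strength must be in [0, 1)")
  }
  if (is.null(volume_px)) {
    fit <- 1.25 * sphere_diameter_um
    volume_px <- c(ceiling(fit / geometry$dx), ceiling(fit / geometry$dy),
                   ceiling(fit / geometry$dz))
  }
  volume_px <- as.integer(volume_px)
  ext <- c(volume_px[1] * geometry$dx, volume_px[2] * geometry$dy,
           volume_px[3] * geometry$dz)
  if (motion_mode == "surface" && sphere_diameter_um > min(ext)) {
    stop(sprintf("sphere (%g um) does not fit inside the rendered volume (%g x %g x %g um)",
                 sphere_diameter_um, ext[1], ext[2], ext[3]))
  }
  structure(list(sphere_diameter_um = sphere_diameter_um,
                 n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames), geometry = geometry,
                 volume_px = volume_px, step_um = step_um,
                 persistence = persistence, motion_mode = motion_mode,
                 psf_sigma_um = psf_sigma_um,
                 cell_amplitude = cell_amplitude,
                 background_level = background_level, poisson = poisson,
                 read_sigma = read_sigma,
                 vignetting_strength = vignetting_strength,
                 shell_amplitude = shell_amplitude, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("simulation: %d cell(s) on a %g um carrier, %d frame(s), %d x %d x %d voxels (%s motion)\n",
              x$n_cells, x$sphere_diameter_um, x$n_frames, x$volume_px[1],
              x$volume_px[2], x$volume_px[3], x$motion_mode))
  invisible(x)
}

#' Desk-scale validation fixture
#'
#' The configuration used throughout the test suite for end-to-end
#' validation: 15 cells, 21 frames, a 512 x 512 x 150 voxel volume at the
#' default acquisition geometry, and a 240 um carrier (scaled down from
#' the ~400 um original so that it fits this volume).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_fixture_config <- function(seed = 1L, ...) {
  sim_config(sphere_diameter_um = 240, volume_px = c(512L, 512L, 150L),
             seed = seed, ...)
}

# centre of the volume in um, voxel-centre convention
volume_center_um <- function(config) {
  g <- config$geometry
  c((config$volume_px[1] - 1) / 2 * g$dx,
    (config$volume_px[2] - 1) / 2 * g$dy,
    (config$volume_px[3] - 1) / 2 * g$dz)
}

#' Simulate ground-truth cell trajectories
#'
#' Cells are initialized uniformly at random on the carrier sphere. Each
#' frame the cell moves along a great circle by a fixed chord length
#' `step_um`, in a direction that mixes the previous (parallel-transported)
#' direction with a uniform random tangent direction, weighted by
#' `persistence`. Persistence 0 gives an undirected surface walk;
#' persistence 1 gives an exact geodesic, so the path length after k steps
#' is exactly `k * step_um` and the distance from origin is the chord of
#' the accumulated arc, `2 r sin(k asin(step / 2r))`.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: list with `tracks` (data
#'   frame `id`, `time_index`, `x`, `y`, `z` in voxels, `x_um`, `y_um`,
#'   `z_um`, `t_min`) and `config`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$sphere_diameter_um / 2
  s <- config$step_um
  if (config$motion_mode == "surface" && s > r) {
    stop("step_um larger than the sphere radius")
  }
  g <- config$geometry
  ctr <- volume_center_um(config)
  tracks <- withr::with_seed(config$seed, {
    out <- vector("list", config$n_cells)
    for (i in seq_len(config$n_cells)) {
      pos <- matrix(NA_real_, config$n_frames, 3)
      if (config$motion_mode == "surface") {
        p <- r * random_unit_vector()
        tang <- random_tangent(p)
        theta <- 2 * asin(s / (2 * r))
        pos[1, ] <- p
        for (k in seq_len(config$n_frames - 1L)) {
          u <- random_tangent(p)
          d <- config$persistence * tang + (1 - config$persistence) * u
          d <- d - sum(d * p) * p / sum(p * p)   # keep tangent
          nd <- sqrt(sum(d^2))
          if (nd < 1e-12) d <- u else d <- d / nd
          p_new <- cos(theta) * p + sin(theta) * r * d
          tang <- cos(theta) * d - sin(theta) * p / r
          p <- p_new * (r / sqrt(sum(p_new^2)))
          pos[k + 1L, ] <- p
        }
        pos <- sweep(pos, 2, ctr, "+")
      } else {
        ext <- c(config$volume_px[1] * g$dx, config$volume_px[2] * g$dy,
                 config$volume_px[3] * g$dz)
        margin <- 4 * max(config$psf_sigma_um)
        p <- margin + stats::runif(3) * (ext - 2 * margin)
        d <- random_unit_vector()
        pos[1, ] <- p
        for (k in seq_len(config$n_frames - 1L)) {
          u <- random_unit_vector()
          dd <- config$persistence * d + (1 - config$persistence) * u
          nd <- sqrt(sum(dd^2))
          d <- if (nd < 1e-12) u else dd / nd
          p <- p + s * d
          # reflect at the walls
          for (ax in 1:3) {
            if (p[ax] < margin) { p[ax] <- 2 * margin - p[ax]; d[ax] <- -d[ax] }
            hi <- ext[ax] - margin
            if (p[ax] > hi) { p[ax] <- 2 * hi - p[ax]; d[ax] <- -d[ax] }
          }
          pos[k + 1L, ] <- p
        }
      }
      out[[i]] <- data.frame(id = i, time_index = seq_len(config$n_frames) - 1L,
                             x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(id = integer(0), time_index = integer(0), x_um = numeric(0),
                 y_um = numeric(0), z_um = numeric(0))
  })
  tracks$x <- tracks$x_um / g$dx
  tracks$y <- tracks$y_um / g$dy
  tracks$z <- tracks$z_um / g$dz
  tracks$t_min <- tracks$time_index * g$dt
  tracks <- tracks[, c("id", "time_index", "x", "y", "z",
                       "x_um", "y_um", "z_um", "t_min")]
  structure(list(tracks = tracks, config = config), class = "ground_truth")
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  rho <- sqrt(1 - z^2)
  c(rho * cos(phi), rho * sin(phi), z)
}

random_tangent <- function(p) {
  repeat {
    v <- random_unit_vector()
    t <- v - sum(v * p) * p / sum(p * p)
    n <- sqrt(sum(t^2))
    if (n > 1e-8) return(t / n)
  }
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d track(s) x %d frame(s)\n",
              length(unique(x$tracks$id)), x$config$n_frames))
  invisible(x)
}

#' Radial vignetting gain field
#'
#' `gain = 1 - strength * (r / r_max)^2` with `r_max` the centre-to-corner
#' distance, normalized to unit mean. Before normalization the
#' centre-to-corner gain ratio is `1 / (1 - strength)`.
#'
#' @param config A [sim_config()], or `NULL` if `dims` is given.
#' @param dims Optional `c(ny, nx)` overriding the config's lateral size.
#' @param strength Optional override of `vignetting_strength`.
#' @return `ny` x `nx` gain matrix with mean 1.
#' @export
vignetting_field <- function(config = NULL, dims = NULL, strength = NULL) {
  if (is.null(strength)) strength <- config$vignetting_strength
  if (strength < 0 || strength >= 1) stop("strength must be in [0, 1)")
  if (is.null(dims)) dims <- c(config$volume_px[2], config$volume_px[1])
  ny <- dims[1]; nx <- dims[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+")
  g <- 1 - strength * r2 / max(r2, 1e-12)
  g / mean(g)
}

#' Render a ground truth as a fluorescence time-lapse
#'
#' Each cell becomes an anisotropic 3D Gaussian of amplitude
#' `cell_amplitude` over `background_level`; each z-plane is multiplied by
#' the vignetting field; Poisson shot noise is drawn on the expected
#' counts, Gaussian read noise added, and the result quantized to 16 bit.
#' Rendering is frame by frame, so arbitrarily long time-lapses fit in
#' memory; with `out_dir` set, frames are written as multi-page TIFFs and
#' a disk-backed [timelapse()] is returned.
#'
#' @param truth A [simulate_tracks()] result.
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @param out_dir Optional directory for per-frame TIFFs.
#' @return A `timelapse` (disk-backed iff `out_dir` is given).
#' @export
render_timelapse <- function(truth, config = truth$config, out_dir = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  g <- config$geometry
  nx <- config$volume_px[1]; ny <- config$volume_px[2]; nz <- config$volume_px[3]
  if (config$motion_mode == "surface" &&
      config$sphere_diameter_um > min(nx * g$dx, ny * g$dy, nz * g$dz)) {
    stop("volume too small for the sphere")
  }
  sig <- c(config$psf_sigma_um[1] / g$dx, config$psf_sigma_um[1] / g$dy,
           config$psf_sigma_um[2] / g$dz)
  gain <- if (config$vignetting_strength > 0) {
    vignetting_field(config)
  } else NULL
  # static part of the expected counts (background + carrier shell, already
  # vignetted) is shared by all frames; only the cells change
  base <- array(config$background_level, c(ny, nx, nz))
  if (config$shell_amplitude > 0) base <- base + shell_profile(config)
  if (!is.null(gain)) {
    for (z in seq_len(nz)) base[, , z] <- base[, , z] * gain
  }
  tr <- truth$tracks
  paths <- character(0)
  stacks <- if (is.null(out_dir)) vector("list", config$n_frames) else NULL
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  withr::with_seed(config$seed + 1L, {
    for (t in seq_len(config$n_frames) - 1L) {
      expected <- base + 0  # fresh copy; spots are added in place below
      pts <- tr[tr$time_index == t, , drop = FALSE]
      for (i in seq_len(nrow(pts))) {
        sp <- spot_patch(pts$x[i], pts$y[i], pts$z[i], sig,
                         config$cell_amplitude, c(ny, nx, nz), gain)
        for (k in seq_along(sp$zr)) {
          expected[sp$yr + 1L, sp$xr + 1L, sp$zr[k] + 1L] <-
            expected[sp$yr + 1L, sp$xr + 1L, sp$zr[k] + 1L] +
            sp$plane * sp$gz[k]
        }
      }
      v <- if (config$poisson) {
        stats::rpois(length(expected), expected)
      } else expected
      if (config$read_sigma > 0) {
        v <- v + stats::rnorm(length(v), 0, config$read_sigma)
        v <- round(v)
      } else if (config$poisson) {
        # integer already
      } else {
        v <- round(v)
      }
      if (min(v) < 0) v <- pmax(v, 0)
      if (max(v) > 65535) v <- pmin(v, 65535)
      dim(v) <- c(ny, nx, nz)
      if (is.null(out_dir)) {
        stacks[[t + 1L]] <- v
      } else {
        p <- file.path(out_dir, sprintf("sim_t%03d.tif", t))
        write_stack_tiff(v, p, 16)
        paths <- c(paths, p)
      }
    }
  })
  if (is.null(out_dir)) {
    timelapse(stacks, g, channel = "synthetic", bit_depth = 16)
  } else {
    read_timelapse(paths, g, lazy = TRUE, channel = "synthetic")
  }
}

# separable Gaussian spot clipped to a +-4 sigma box; coords 0-based voxels.
# Returns the in-plane patch (already attenuated by the vignetting gain, so
# the expected image equals gain * (background + shell + cells)) and its
# destination indices; the caller adds it slice by slice, which avoids
# copying the full volume per spot.
spot_patch <- function(x, y, z, sigma, amplitude, d, gain = NULL) {
  xr <- max(0L, floor(x - 4 * sigma[1])):min(d[2] - 1L, ceiling(x + 4 * sigma[1]))
  yr <- max(0L, floor(y - 4 * sigma[2])):min(d[1] - 1L, ceiling(y + 4 * sigma[2]))
  zr <- max(0L, floor(z - 4 * sigma[3])):min(d[3] - 1L, ceiling(z + 4 * sigma[3]))
  gx <- exp(-((xr - x)^2) / (2 * sigma[1]^2))
  gy <- exp(-((yr - y)^2) / (2 * sigma[2]^2))
  gz <- exp(-((zr - z)^2) / (2 * sigma[3]^2))
  plane <- amplitude * (gy %o% gx)
  if (!is.null(gain)) plane <- plane * gain[yr + 1L, xr + 1L]
  list(xr = xr, yr = yr, zr = zr, gz = gz, plane = plane)
}

# faint carrier shell: Gaussian ridge at the sphere radius, 2 um wide
shell_profile <- function(config) {
  g <- config$geometry
  nx <- config$volume_px[1]; ny <- config$volume_px[2]; nz <- config$volume_px[3]
  ctr <- volume_center_um(config)
  r <- config$sphere_diameter_um / 2
  width <- 2
  rho2 <- outer(((seq_len(ny) - 1) * g$dy - ctr[2])^2,
                ((seq_len(nx) - 1) * g$dx - ctr[1])^2, "+")
  out <- array(0, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    dz2 <- ((z - 1) * g$dz - ctr[3])^2
    dist <- sqrt(rho2 + dz2)
    out[, , z] <- config$shell_amplitude * exp(-(dist - r)^2 / (2 * width^2))
  }
  out
}
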
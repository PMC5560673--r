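#' Voxel and frame calibration
#'
#' Ties voxel indices to physical micrometres and frame indices to minutes.
#' The defaults are typical of light-sheet time-lapse acquisitions of
#' microcarrier cultures: 0.589 um lateral sampling, 2 um z-interval and a
#' 30-minute frame interval.
#'
#' @param dx,dy Lateral pixel size, um/pixel.
#' @param dz Axial slice spacing, um/slice.
#' @param dt Frame interval, minutes/frame.
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry()
#' physical_extent(g, n_x = 1920, n_y = 1920, n_z = 500)
#' @export
voxel_geometry <- function(dx = 0.589, dy = 0.589, dz = 2.0, dt = 30) {
  v <- c(dx = dx, dy = dy, dz = dz, dt = dt)
  if (!all(is.finite(v)) || any(v <= 0)) {
    stop("voxel geometry values must be strictly positive and finite")
  }
  structure(list(dx = dx, dy = dy, dz = dz, dt = dt), class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: %g x %g x %g um/voxel, %g min/frame\n",
              x$dx, x$dy, x$dz, x$dt))
  invisible(x)
}

as_voxel_geometry <- function(x) {
  if (inherits(x, "voxel_geometry")) return(x)
  if (is.list(x) && all(c("dx", "dy", "dz", "dt") %in% names(x))) {
    return(voxel_geometry(x$dx, x$dy, x$dz, x$dt))
  }
  stop("cannot interpret 'geometry'; use voxel_geometry()")
}

#' Physical extent of an image volume
#'
#' Converts voxel counts to the physical size of the imaged volume, rounded
#' to the nearest integer micrometre (the convention used when reporting
#' acquisition volumes, e.g. 1920 px x 0.589 um/px -> 1131 um).
#'
#' @param geometry A [voxel_geometry()].
#' @param n_x,n_y,n_z Voxel counts along x, y, z (each >= 1).
#' @return Named numeric vector `c(x =, y =, z =)` in um.
#' @export
physical_extent <- function(geometry, n_x, n_y, n_z) {
  geometry <- as_voxel_geometry(geometry)
  n <- c(n_x, n_y, n_z)
  if (any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("voxel counts must be positive integers")
  }
  c(x = round(n_x * geometry$dx),
    y = round(n_y * geometry$dy),
    z = round(n_z * geometry$dz))
}

#' Convert voxel coordinates to physical units
#'
#' Voxel coordinates follow the image-processing convention: the centre of
#' the first voxel is (0, 0, 0) and coordinates are real-valued (sub-voxel
#' positions are meaningful). `time_index` 0 is the start of the
#' acquisition, so frame k is at k * dt minutes.
#'
#' @param point Numeric vector `c(t, x, y, z)` or a matrix/data.frame with
#'   columns `t`, `x`, `y`, `z` (voxel/frame units).
#' @param geometry A [voxel_geometry()].
#' @return Same shape as `point`, components in (minutes, um, um, um).
#' @export
to_physical <- function(point, geometry) {
  geometry <- as_voxel_geometry(geometry)
  s <- c(t = geometry$dt, x = geometry$dx, y = geometry$dy, z = geometry$dz)
  if (is.data.frame(point) || is.matrix(point)) {
    out <- point
    for (nm in names(s)) out[, nm] <- point[, nm] * s[[nm]]
    return(out)
  }
  if (length(point) != 4 || any(!is.finite(point))) {
    stop("'point' must be a finite (t, x, y, z) vector")
  }
  if (point[1] < 0) stop("time index must be >= 0")
  unname(point * s)
}
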
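#' Lift 2D tracks to 3D by axial intensity argmax
#'
#' For every tracked point, the axial coordinate is the z-plane whose
#' intensity at the tracked (x, y) position is largest: the score of slice
#' z is the mean intensity within a disk of `window_radius_px` around
#' (x, y) on that slice, and z is the lowest slice attaining the maximum
#' score (deterministic tie-break). `window_radius_px = 0` gives the
#' literal per-pixel argmax of the stack column at the rounded (x, y).
#'
#' Optional sub-slice refinement fits a parabola through the scores at
#' (z - 1, z, z + 1) when z is interior and the curvature is negative; the
#' refined offset is clamped to half a slice and flagged in `z_refined`.
#'
#' @param tracks A `tracks2d` data frame (columns `id`, `time_index`, `x`,
#'   `y`, `status`).
#' @param tl The [timelapse()] the tracks were measured on (aligned and
#'   corrected, if those stages ran).
#' @param window_radius_px Disk radius in pixels (>= 0; default 3).
#' @param refine If `TRUE`, apply parabolic sub-slice refinement.
#' @return A data frame of class `tracks3d`: the input columns plus `z`
#'   (0-based slice, real-valued when refined), `z_confidence` (best-plane
#'   score divided by the median score along the column), `z_refined`
#'   (logical) and `z_ok` (`FALSE` for points whose (x, y) fell outside the
#'   image; their z is `NA`). Physical columns `t_min`, `x_um`, `y_um`,
#'   `z_um` follow the time-lapse geometry.
#' @export
recover_z <- function(tracks, tl, window_radius_px = 3, refine = FALSE) {
  stopifnot(inherits(tl, "timelapse"))
  if (window_radius_px < 0) stop("window_radius_px must be >= 0")
  df <- as.data.frame(tracks)
  stopifnot(all(c("id", "time_index", "x", "y") %in% names(df)))
  if (!"status" %in% names(df)) df$status <- "detected"
  n <- nrow(df)
  z <- rep(NA_real_, n); conf <- rep(NA_real_, n)
  refined <- rep(FALSE, n); ok <- rep(FALSE, n)
  ny <- tl$dim[1]; nx <- tl$dim[2]; nz <- tl$dim[3]

  for (t in sort(unique(df$time_index))) {
    if (t < 0 || t > tl$n_frames - 1L) {
      stop(sprintf("track frame %d not present in the time-lapse", t))
    }
    stack <- get_stack(tl, t)
    rows <- which(df$time_index == t)
    for (i in rows) {
      px <- df$x[i]; py <- df$y[i]
      if (!is.finite(px) || !is.finite(py) ||
          px < 0 || px > nx - 1 || py < 0 || py > ny - 1) next
      prof <- column_profile(stack, px, py, window_radius_px)
      z0 <- which.max(prof)  # first maximum = lowest slice
      zi <- z0 - 1L
      med <- stats::median(prof)
      conf[i] <- if (med > 0) prof[z0] / med else NA_real_
      zz <- as.numeric(zi)
      if (refine && z0 > 1L && z0 < nz) {
        pm <- prof[z0 - 1L]; p0 <- prof[z0]; pp <- prof[z0 + 1L]
        denom <- pm - 2 * p0 + pp
        if (denom < 0) {
          dz <- 0.5 * (pm - pp) / denom
          zz <- zi + max(-0.5, min(0.5, dz))
          refined[i] <- TRUE
        }
      }
      z[i] <- zz
      ok[i] <- TRUE
    }
  }
  g <- tl$geometry
  out <- df
  out$z <- z
  out$z_confidence <- conf
  out$z_refined <- refined
  out$z_ok <- ok
  out$t_min <- out$time_index * g$dt
  out$x_um <- out$x * g$dx
  out$y_um <- out$y * g$dy
  out$z_um <- out$z * g$dz
  rownames(out) <- NULL
  class(out) <- c("tracks3d", "data.frame")
  out
}

# mean-intensity z-profile within a disk around 0-based (x, y);
# radius 0 reads the single column at the rounded position
column_profile <- function(stack, x, y, radius) {
  d <- dim(stack)
  if (radius == 0) {
    cx <- min(max(round(x), 0), d[2] - 1L) + 1L
    cy <- min(max(round(y), 0), d[1] - 1L) + 1L
    return(stack[cy, cx, ])
  }
  dsk <- disk_pixels(x, y, radius, d[1], d[2])
  rect_y <- sort(unique(dsk$y)); rect_x <- sort(unique(dsk$x))
  m <- stack[rect_y + 1L, rect_x + 1L, , drop = FALSE]
  dim(m) <- c(length(rect_y) * length(rect_x), d[3])
  in_disk <- outer(rect_y, rect_x,
                   function(yy, xx) (xx - x)^2 + (yy - y)^2 <= radius^2)
  colMeans(m[as.vector(in_disk), , drop = FALSE])
}
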
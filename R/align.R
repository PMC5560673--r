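#' Rigid transform of a z-stack
#'
#' A translation `(dx, dy, dz)` in voxels (real-valued) plus an in-plane
#' rotation about the image centre. A transform describes how a frame is
#' displaced relative to the reference; [apply_transform()] undoes the
#' displacement by sampling the frame at the transformed coordinates.
#'
#' @param dx,dy,dz Displacement of the frame relative to the reference,
#'   voxels.
#' @param rotation_deg In-plane rotation (counter-clockwise, degrees) about
#'   the image centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, dz = 0, rotation_deg = 0) {
  v <- c(dx, dy, dz, rotation_deg)
  if (any(!is.finite(v))) stop("transform parameters must be finite")
  structure(list(dx = dx, dy = dy, dz = dz, rotation_deg = rotation_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: shift (%.3f, %.3f, %.3f) vox, rotation %.3f deg\n",
              x$dx, x$dy, x$dz, x$rotation_deg))
  invisible(x)
}

is_identity_transform <- function(tr, tol = 1e-9) {
  abs(tr$dx) < tol && abs(tr$dy) < tol && abs(tr$dz) < tol &&
    abs(tr$rotation_deg) < tol
}

#' @rdname rigid_transform
#' @param tr A `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  a <- -tr$rotation_deg * pi / 180
  s <- c(tr$dx, tr$dy)
  rigid_transform(dx = -(cos(a) * s[1] - sin(a) * s[2]),
                  dy = -(sin(a) * s[1] + cos(a) * s[2]),
                  dz = -tr$dz,
                  rotation_deg = -tr$rotation_deg)
}

#' Resample a stack under a rigid transform
#'
#' Brings a displaced frame back to the reference frame: the output at
#' voxel `p` is the input sampled (trilinearly) at `R(p - c) + c + shift`,
#' where `c` is the in-plane image centre. Out-of-frame voxels are filled
#' with 0. Integer shifts with no rotation reproduce the input exactly
#' (interpolation weights collapse to 0/1).
#'
#' @param stack 3D array `[y, x, z]` (a matrix is treated as single-slice).
#' @param tr A [rigid_transform()].
#' @return Transformed array of the input shape.
#' @export
apply_transform <- function(stack, tr) {
  was_matrix <- is.matrix(stack)
  if (was_matrix) dim(stack) <- c(dim(stack), 1L)
  if (is_identity_transform(tr)) {
    if (was_matrix) dim(stack) <- dim(stack)[1:2]
    return(stack)
  }
  d <- dim(stack)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  a <- tr$rotation_deg * pi / 180
  gx <- rep(seq_len(nx), each = ny) - cx
  gy <- rep(seq_len(ny), times = nx) - cy
  xs <- cos(a) * gx - sin(a) * gy + cx + tr$dx
  ys <- sin(a) * gx + cos(a) * gy + cy + tr$dy

  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- array(0, d)
  # bilinear in-plane weights, shared across z
  corner <- function(slice, yy, xx) {
    ok <- xx >= 1 & xx <= nx & yy >= 1 & yy <= ny
    v <- numeric(length(xx))
    v[ok] <- slice[cbind(yy[ok], xx[ok])]
    v
  }
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy;       w11 <- fx * fy
  sample_plane <- function(slice) {
    w00 * corner(slice, y0, x0) + w10 * corner(slice, y0, x0 + 1) +
      w01 * corner(slice, y0 + 1, x0) + w11 * corner(slice, y0 + 1, x0 + 1)
  }
  zs <- seq_len(nz) + tr$dz
  z0 <- floor(zs); fz <- zs - z0
  plane_cache <- vector("list", nz + 2L)
  get_plane <- function(zi) {
    if (zi < 1 || zi > nz) return(numeric(ny * nx))
    if (is.null(plane_cache[[zi]])) {
      plane_cache[[zi]] <<- sample_plane(stack[, , zi])
    }
    plane_cache[[zi]]
  }
  for (z in seq_len(nz)) {
    lo <- get_plane(z0[z])
    v <- if (fz[z] > 0) (1 - fz[z]) * lo + fz[z] * get_plane(z0[z] + 1L)
         else lo
    out[, , z] <- v
  }
  if (was_matrix) dim(out) <- d[1:2]
  out
}

# Circular 2D cross-correlation between equally-sized matrices.
# Returns list(dx, dy, confidence): mov[y, x] ~ ref[y - dy, x - dx].
# Both images are intensity-clipped at the pooled `clip_q` quantile before
# correlating, so that sparse bright movers (the cells) cannot out-vote the
# extended static structure the registration should lock onto. Confidence
# is the normalized correlation coefficient at the peak (~1 for a pure
# shift of identical content). Ties among equal peaks break towards the
# smallest-magnitude shift.
phase_correlate_2d <- function(ref, mov, clip_q = 0.8) {
  stopifnot(identical(dim(ref), dim(mov)))
  cap <- stats::quantile(c(ref, mov), clip_q, names = FALSE)
  a <- pmin(ref, cap); b <- pmin(mov, cap)
  a <- a - mean(a); b <- b - mean(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa < 1e-12 || sb < 1e-12) return(list(dx = 0, dy = 0, confidence = 1))
  r <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)),
                     inverse = TRUE)) / length(a)
  pk <- max(r)
  idx <- which(r >= pk - 1e-9 * max(abs(pk), 1e-12), arr.ind = TRUE)
  dyc <- wrap_shift(idx[, 1] - 1L, nrow(ref))
  dxc <- wrap_shift(idx[, 2] - 1L, ncol(ref))
  best <- order(dxc^2 + dyc^2, abs(dyc), abs(dxc))[1]
  list(dx = unname(dxc[best]), dy = unname(dyc[best]),
       confidence = pk / (length(a) * sa * sb))
}

# Circular 1D cross-covariance of axial profiles: mov[z] ~ ref[z - dz].
cross_correlate_1d <- function(ref, mov) {
  stopifnot(length(ref) == length(mov))
  n <- length(ref)
  if (n == 1) return(0)
  a <- mov - mean(mov); b <- ref - mean(ref)
  r <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n
  pk <- max(r)
  lags <- wrap_shift(which(r >= pk - 1e-9 * max(abs(pk), 1e-12)) - 1L, n)
  lags[order(abs(lags))][1]
}

wrap_shift <- function(k, n) ifelse(k > n / 2, k - n, k)

# Axial mean-intensity profile with the same bright-mover clipping as the
# lateral registration: intensities are capped at the stack's `clip_q`
# quantile (estimated on a deterministic subsample) so that a handful of
# bright moving cells cannot shift the profile of the static scene.
axial_profile <- function(stack, clip_q = 0.98) {
  v <- stack[seq(1, length(stack), by = 17L)]
  cap <- stats::quantile(v, clip_q, names = FALSE)
  colMeans(matrix(pmin(stack, cap), ncol = dim(stack)[3]))
}

#' Align a time-lapse to a global reference frame
#'
#' Estimates, per frame, the lateral displacement by circular
#' cross-correlation between the frame's maximum-intensity projection and
#' the reference frame's (intensities clipped at the 80th percentile so the
#' moving cells cannot dominate the static scene), and the axial
#' displacement by circular cross-correlation of the axial mean-intensity
#' profiles. An optional user-supplied in-plane rotation is applied to
#' every frame first. Stacks are resampled with linear interpolation
#' ([apply_transform()]); out-of-frame voxels are 0.
#'
#' @param tl A [timelapse()].
#' @param reference_index Frame (0-based) defining the reference; its
#'   transform is the identity.
#' @param rotation_deg Rotation applied to all frames before shift
#'   estimation (manual override; default 0).
#' @param min_confidence Correlation coefficient at the peak below which
#'   the estimated shift is distrusted: a warning is raised and a zero
#'   shift used for that frame.
#' @return A list with `timelapse` (aligned, in-memory) and `transforms`
#'   (list of [rigid_transform()], one per frame).
#' @export
align_timelapse <- function(tl, reference_index = 0, rotation_deg = 0,
                            min_confidence = 0.3) {
  stopifnot(inherits(tl, "timelapse"))
  if (tl$n_frames < 1) stop("empty time-lapse")
  ref_k <- as.integer(reference_index)
  if (ref_k < 0 || ref_k >= tl$n_frames) stop("invalid reference_index")

  rot <- rigid_transform(rotation_deg = rotation_deg)
  stacks <- lapply(seq_len(tl$n_frames) - 1L, function(t) {
    s <- get_stack(tl, t)
    if (rotation_deg != 0) s <- apply_transform(s, rot) else s
  })
  mips <- lapply(stacks, stack_max_project)
  profiles <- lapply(stacks, axial_profile)

  transforms <- vector("list", tl$n_frames)
  aligned <- vector("list", tl$n_frames)
  for (k in seq_len(tl$n_frames)) {
    if (k == ref_k + 1L) {
      tr <- rigid_transform(rotation_deg = rotation_deg)
      aligned[[k]] <- stacks[[k]]
      transforms[[k]] <- tr
      next
    }
    pc <- phase_correlate_2d(mips[[ref_k + 1L]], mips[[k]])
    if (pc$confidence < min_confidence) {
      warning(sprintf("frame %d: correlation peak %.3f below confidence %.3f; using zero shift",
                      k - 1L, pc$confidence, min_confidence))
      pc$dx <- 0; pc$dy <- 0
    }
    dz <- cross_correlate_1d(profiles[[ref_k + 1L]], profiles[[k]])
    tr <- rigid_transform(dx = pc$dx, dy = pc$dy, dz = dz,
                          rotation_deg = rotation_deg)
    aligned[[k]] <- apply_transform(stacks[[k]],
                                    rigid_transform(pc$dx, pc$dy, dz))
    transforms[[k]] <- tr
  }
  list(timelapse = timelapse(aligned, tl$geometry, tl$channel, tl$bit_depth),
       transforms = transforms)
}

stack_max_project <- function(stack) {
  d <- dim(stack)
  m <- stack
  dim(m) <- c(d[1] * d[2], d[3])
  out <- m[, 1]
  for (z in seq_len(d[3])[-1]) out <- pmax(out, m[, z])
  matrix(out, d[1], d[2])
}

#' Export rigid transforms as CSV
#'
#' Columns: `frame` (0-based), `dx`, `dy`, `dz` (voxels), `rot_deg`.
#'
#' @param transforms List of [rigid_transform()].
#' @param path Output CSV path.
#' @export
write_transforms <- function(transforms, path) {
  df <- data.frame(
    frame = seq_along(transforms) - 1L,
    dx = vapply(transforms, `[[`, numeric(1), "dx"),
    dy = vapply(transforms, `[[`, numeric(1), "dy"),
    dz = vapply(transforms, `[[`, numeric(1), "dz"),
    rot_deg = vapply(transforms, `[[`, numeric(1), "rotation_deg"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
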
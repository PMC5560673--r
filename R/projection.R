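#' Maximum-intensity projection with depth provenance
#'
#' Reduces a z-stack to the 2D image of per-pixel maxima along z, recording
#' for every pixel the slice index attaining the maximum (`argmax_z`,
#' 0-based; ties break to the lowest slice). The argmax map is what later
#' allows the axial coordinate of a tracked cell to be recovered.
#'
#' @param stack 3D array `[y, x, z]` (a matrix is a single-slice stack).
#' @param time_index Frame ordinal carried along for bookkeeping.
#' @return An object of class `projected_frame`: list with `image` (2D
#'   matrix), `argmax_z` (2D integer matrix, 0-based) and `time_index`.
#' @examples
#' s <- array(0, c(4, 4, 3)); s[2, 2, 2] <- 9
#' p <- max_intensity_projection(s)
#' p$image[2, 2]     # 9
#' p$argmax_z[2, 2]  # 1 (0-based slice)
#' @export
max_intensity_projection <- function(stack, time_index = 0L) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  stopifnot(is.array(stack), length(dim(stack)) == 3, dim(stack)[3] >= 1)
  d <- dim(stack)
  m <- stack
  dim(m) <- c(d[1] * d[2], d[3])
  if (d[3] == 1L) {
    img <- matrix(m[, 1], d[1], d[2])
    amz <- matrix(0L, d[1], d[2])
  } else {
    idx <- max.col(m, ties.method = "first")
    img <- matrix(m[cbind(seq_len(nrow(m)), idx)], d[1], d[2])
    amz <- matrix(idx - 1L, d[1], d[2])
  }
  structure(list(image = img, argmax_z = amz,
                 time_index = as.integer(time_index)),
            class = "projected_frame")
}

#' @export
print.projected_frame <- function(x, ...) {
  cat(sprintf("projected frame t=%d: %d x %d, z range [%d, %d]\n",
              x$time_index, nrow(x$image), ncol(x$image),
              min(x$argmax_z), max(x$argmax_z)))
  invisible(x)
}

#' Extended depth-of-field (full-focus) projection
#'
#' An alternative to the maximum-intensity projection: each output pixel is
#' taken from the slice that is locally most in focus, with focus scored as
#' the local intensity variance within a `patch` x `patch` window. The
#' winning-slice label map is median-filtered (same window) before sampling,
#' so the selection is spatially coherent.
#'
#' @param stack 3D array `[y, x, z]`.
#' @param patch Odd window size >= 3.
#' @return 2D image matrix.
#' @export
extended_depth_of_field <- function(stack, patch = 5) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (patch < 3 || patch %% 2 == 0) stop("'patch' must be odd and >= 3")
  d <- dim(stack)
  if (d[3] == 1L) return(stack[, , 1])

  box <- matrix(1 / patch^2, patch, patch)
  score <- matrix(0, d[1] * d[2], d[3])
  for (z in seq_len(d[3])) {
    s <- stack[, , z]
    mu <- EBImage::filter2(s, box, boundary = "replicate")
    mu2 <- EBImage::filter2(s^2, box, boundary = "replicate")
    score[, z] <- as.vector(pmax(mu2 - mu^2, 0))
  }
  label <- max.col(score, ties.method = "first")  # 1-based slice per pixel
  lab_img <- matrix(label, d[1], d[2])
  # smooth the label map; medianFilter works on [0,1] grayscale
  half <- (patch - 1) / 2
  sm <- EBImage::medianFilter(lab_img / d[3], size = half)
  lab_sm <- pmin(pmax(round(as.matrix(sm) * d[3]), 1L), d[3])
  m <- stack
  dim(m) <- c(d[1] * d[2], d[3])
  matrix(m[cbind(seq_len(nrow(m)), as.vector(lab_sm))], d[1], d[2])
}

#' Project every frame of a time-lapse
#'
#' @param tl A [timelapse()].
#' @param method `"mip"` (default) or `"edf"`.
#' @param patch Window size for the EDF method.
#' @return List of [max_intensity_projection()] frames (for `"edf"` the
#'   `image` field holds the full-focus image and `argmax_z` the MIP's
#'   argmax map, still used for z-recovery provenance).
#' @export
project_timelapse <- function(tl, method = c("mip", "edf"), patch = 5) {
  method <- match.arg(method)
  stopifnot(inherits(tl, "timelapse"))
  lapply(seq_len(tl$n_frames) - 1L, function(t) {
    s <- get_stack(tl, t)
    p <- max_intensity_projection(s, time_index = t)
    if (method == "edf") p$image <- extended_depth_of_field(s, patch)
    p
  })
}
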
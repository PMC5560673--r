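#' Retrospective illumination (vignetting) model
#'
#' Microscope images show a smooth multiplicative fall-off of brightness away
#' from the optical centre ("vignetting") plus an additive dark-level offset.
#' [estimate_illumination()] fits a per-pixel gain/offset model
#' retrospectively from a collection of image planes, and
#' [correct_illumination()] inverts it: `corrected = (image - offset) / gain`.
#'
#' The estimator is intentionally simple and fully documented:
#' * `offset` = per-pixel 5% quantile across the collection (type-1
#'   order-statistic, index `ceiling(q * n)`), Gaussian-smoothed, then clamped
#'   at the per-pixel minimum so corrected training pixels cannot go negative.
#' * `gain` = per-pixel median of `plane - offset`, Gaussian-smoothed and
#'   normalized to unit mean (for even n, the lower median is used).
#' * Smoothing sigma = `sigma_frac` of the image diagonal (default 2%).
#'
#' A constant collection degenerates gracefully: the residual after the
#' offset is zero everywhere, and the gain is defined as 1.
#'
#' @param planes A list of equally-sized matrices, or a 3D array `[y, x, n]`,
#'   sampling many z-slices / time points (n >= 2).
#' @param q Offset quantile (default 0.05).
#' @param sigma_frac Smoothing sigma as a fraction of the image diagonal.
#' @return An object of class `illumination_model` with fields `gain`
#'   (positive, unit mean) and `offset` (non-negative), both matrices of the
#'   plane shape.
#' @export
estimate_illumination <- function(planes, q = 0.05, sigma_frac = 0.02) {
  if (is.array(planes) && length(dim(planes)) == 3) {
    a <- planes
    planes <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
  }
  if (!is.list(planes) || length(planes) < 2) {
    stop("insufficient data: need at least 2 planes to estimate illumination")
  }
  d <- dim(planes[[1]])
  for (p in planes) {
    if (!identical(dim(p), d)) stop("all planes must share one shape")
  }
  n <- length(planes)
  m <- matrix(unlist(planes, use.names = FALSE), nrow = prod(d), ncol = n)

  k_off <- max(1L, ceiling(q * n))
  offset_raw <- row_kth_smallest(m, k_off)
  per_pixel_min <- row_kth_smallest(m, 1L)

  sigma <- sigma_frac * sqrt(sum(d^2))
  offset <- gauss_blur(matrix(offset_raw, d[1], d[2]), sigma)
  offset <- pmin(offset, matrix(per_pixel_min, d[1], d[2]))
  offset <- pmax(offset, 0)

  k_med <- ceiling(n / 2)
  gain_raw <- row_kth_smallest(m - as.vector(offset), k_med)
  if (mean(gain_raw) <= 1e-12 * max(1, mean(m))) {
    gain <- matrix(1, d[1], d[2])
  } else {
    gain <- gauss_blur(matrix(gain_raw, d[1], d[2]), sigma)
    gain <- pmax(gain, 1e-6 * mean(gain))
    gain <- gain / mean(gain)
  }
  structure(list(gain = gain, offset = offset), class = "illumination_model")
}

#' @export
print.illumination_model <- function(x, ...) {
  cat(sprintf("illumination model: %d x %d, gain range [%.3f, %.3f], offset range [%.1f, %.1f]\n",
              nrow(x$gain), ncol(x$gain), min(x$gain), max(x$gain),
              min(x$offset), max(x$offset)))
  invisible(x)
}

#' Correct an image or stack for uneven illumination
#'
#' Applies `(image - offset) / gain` per plane (per z-slice for 3D input) and
#' clips the result at zero.
#'
#' @param image A 2D matrix or 3D array `[y, x, z]` whose plane shape matches
#'   the model.
#' @param model An `illumination_model`.
#' @return Real-valued corrected array of the input shape.
#' @export
correct_illumination <- function(image, model) {
  stopifnot(inherits(model, "illumination_model"))
  d <- dim(model$gain)
  if (is.matrix(image)) {
    if (!identical(dim(image), d)) {
      stop(sprintf("image is %s, model is %s",
                   paste(dim(image), collapse = "x"), paste(d, collapse = "x")))
    }
    return(pmax((image - model$offset) / model$gain, 0))
  }
  if (is.array(image) && length(dim(image)) == 3) {
    if (!identical(dim(image)[1:2], d)) {
      stop(sprintf("stack planes are %s, model is %s",
                   paste(dim(image)[1:2], collapse = "x"),
                   paste(d, collapse = "x")))
    }
    # plane fields recycle exactly across z (column-major layout)
    out <- (image - as.vector(model$offset)) / as.vector(model$gain)
    out[out < 0] <- 0
    return(out)
  }
  stop("'image' must be a 2D matrix or 3D array")
}

#' Save / load an illumination model
#'
#' The gain and offset fields are written as a 2-page 32-bit float TIFF
#' (values rescaled to `[0, 1]`), with the rescaling recorded in a JSON
#' sidecar so the model round-trips.
#'
#' @param model An `illumination_model`.
#' @param path Path of the TIFF file; the JSON sidecar is `<path>.json`.
#' @return `write_illumination` invisibly returns `path`;
#'   `read_illumination` returns the model.
#' @export
write_illumination <- function(model, path) {
  stopifnot(inherits(model, "illumination_model"))
  g_max <- max(model$gain, 1e-12)
  o_max <- max(model$offset, 1e-12)
  tiff::writeTIFF(list(model$gain / g_max, model$offset / o_max), path,
                  bits.per.sample = 32, compression = "none")
  jsonlite::write_json(
    list(pages = c("gain", "offset"), gain_scale = g_max, offset_scale = o_max,
         shape = dim(model$gain)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_illumination
#' @export
read_illumination <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  structure(list(gain = pages[[1]] * meta$gain_scale,
                 offset = pages[[2]] * meta$offset_scale),
            class = "illumination_model")
}

# k-th smallest per row of a matrix, vectorized over rows (k passes of
# row-argmin). n columns is small (tens of planes), so this is O(k) fast
# column scans rather than an apply() over every pixel.
row_kth_smallest <- function(m, k) {
  if (k == 1L) return(do.call(pmin, asplit(m, 2)))
  w <- m
  for (i in seq_len(k - 1L)) {
    j <- max.col(-w, ties.method = "first")
    w[cbind(seq_len(nrow(w)), j)] <- Inf
  }
  do.call(pmin, asplit(w, 2))
}

# Gaussian blur with replicate boundary handling; sigma in pixels.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0.05) return(img)
  # EBImage's kernel radius must fit inside the image; shrink if needed.
  radius <- 2 * ceiling(3 * sigma) + 1
  max_radius <- min(dim(img)) - 1 - (min(dim(img)) %% 2 == 0)
  if (radius > max_radius) radius <- max(1, max_radius)
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = radius,
                           boundary = "replicate"))
}
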
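#' Time-lapse of calibrated z-stacks
#'
#' A `timelapse` holds an ordered sequence of 3D intensity stacks sharing one
#' voxel geometry. Stacks are numeric arrays indexed `[y, x, z]` (row, column,
#' slice). Frame `time_index` runs 0..T-1 with no gaps; frame k corresponds to
#' k * dt minutes of elapsed time. A time-lapse can be fully in memory or
#' disk-backed (a list of TIFF paths read on demand), which is how volumes too
#' large to hold in RAM are processed.
#'
#' @param stacks A list of 3D arrays `[y, x, z]` (2D matrices are promoted to
#'   single-slice stacks), or a single 4D array `[y, x, z, t]`.
#' @param geometry A [voxel_geometry()].
#' @param channel Free-text channel label.
#' @param bit_depth Declared bit depth, 8 or 16.
#' @return An object of class `timelapse`.
#' @export
timelapse <- function(stacks, geometry = voxel_geometry(), channel = "",
                      bit_depth = 16) {
  geometry <- as_voxel_geometry(geometry)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (is.array(stacks) && length(dim(stacks)) == 4) {
    a <- stacks
    stacks <- lapply(seq_len(dim(a)[4]), function(k) a[, , , k, drop = TRUE])
  }
  if (!is.list(stacks) || length(stacks) == 0) {
    stop("'stacks' must be a non-empty list of 3D arrays or a 4D array")
  }
  stacks <- lapply(stacks, function(s) {
    if (is.matrix(s)) dim(s) <- c(dim(s), 1L)
    if (!is.array(s) || length(dim(s)) != 3) stop("each stack must be 3D")
    if (any(s < 0, na.rm = TRUE)) stop("intensities must be non-negative")
    if (max(s) > 2^bit_depth - 1) {
      stop(sprintf("intensities exceed declared %d-bit range", bit_depth))
    }
    s
  })
  d0 <- dim(stacks[[1]])
  for (k in seq_along(stacks)) {
    if (!identical(dim(stacks[[k]]), d0)) {
      stop(sprintf("stack %d has dimensions %s, expected %s", k,
                   paste(dim(stacks[[k]]), collapse = "x"),
                   paste(d0, collapse = "x")))
    }
  }
  structure(list(stacks = stacks, paths = NULL, dim = d0,
                 n_frames = length(stacks), geometry = geometry,
                 channel = channel, bit_depth = as.integer(bit_depth)),
            class = "timelapse")
}

#' Read a time-lapse from multi-page TIFF files
#'
#' One file per time point; stack order follows the input order and
#' intensities are preserved bit-exactly (`as.is` reading). All files must
#' share page dimensions and page counts.
#'
#' @param paths Ordered character vector of TIFF paths.
#' @param geometry A [voxel_geometry()].
#' @param lazy If `TRUE`, stacks are not loaded; [get_stack()] reads frames on
#'   demand (file headers are still validated up front).
#' @inheritParams timelapse
#' @return A `timelapse`.
#' @export
read_timelapse <- function(paths, geometry = voxel_geometry(), lazy = FALSE,
                           channel = "", bit_depth = 16) {
  geometry <- as_voxel_geometry(geometry)
  if (length(paths) == 0) stop("no input files")
  d0 <- NULL
  stacks <- if (lazy) NULL else vector("list", length(paths))
  for (k in seq_along(paths)) {
    s <- read_stack_tiff(paths[k])
    if (is.null(d0)) d0 <- dim(s)
    if (!identical(dim(s), d0)) {
      stop(sprintf("dimension mismatch in '%s': %s, expected %s", paths[k],
                   paste(dim(s), collapse = "x"), paste(d0, collapse = "x")))
    }
    if (!lazy) stacks[[k]] <- s
  }
  structure(list(stacks = stacks, paths = if (lazy) paths else NULL, dim = d0,
                 n_frames = length(paths), geometry = geometry,
                 channel = channel, bit_depth = as.integer(bit_depth)),
            class = "timelapse")
}

read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2) {
      stop(sprintf("'%s' is not single-channel grayscale", path))
    }
  }
  d <- dim(pages[[1]])
  for (p in pages) {
    if (!identical(dim(p), d)) {
      stop(sprintf("pages of '%s' differ in size", path))
    }
  }
  array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
}

#' Write a time-lapse as multi-page TIFFs
#'
#' @param tl A `timelapse`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_t000.tif`, ...
#' @return Invisibly, the written paths.
#' @export
write_timelapse <- function(tl, dir, prefix = "frame") {
  stopifnot(inherits(tl, "timelapse"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_t%03d.tif", prefix,
                                  seq_len(tl$n_frames) - 1L))
  for (k in seq_len(tl$n_frames)) {
    write_stack_tiff(get_stack(tl, k - 1L), paths[k], tl$bit_depth)
  }
  invisible(paths)
}

write_stack_tiff <- function(stack, path, bit_depth = 16) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  scale <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(stack)[3]), function(z) {
    pmin(pmax(stack[, , z], 0), scale) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "none")
  invisible(path)
}

#' Extract one frame's z-stack
#'
#' @param tl A `timelapse`.
#' @param time_index Frame index, 0-based (0..T-1).
#' @return A 3D array `[y, x, z]`.
#' @export
get_stack <- function(tl, time_index) UseMethod("get_stack")

#' @export
get_stack.timelapse <- function(tl, time_index) {
  k <- as.integer(time_index) + 1L
  if (k < 1 || k > tl$n_frames) {
    stop(sprintf("time_index %s outside 0..%d", time_index, tl$n_frames - 1L))
  }
  if (!is.null(tl$stacks)) return(tl$stacks[[k]])
  read_stack_tiff(tl$paths[k])
}

#' @export
print.timelapse <- function(x, ...) {
  backing <- if (is.null(x$stacks)) "disk-backed" else "in-memory"
  cat(sprintf("timelapse: %d frame(s) of %d x %d x %d (y,x,z), %d-bit, %s\n",
              x$n_frames, x$dim[1], x$dim[2], x$dim[3], x$bit_depth, backing))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.timelapse <- function(x) c(x$dim, x$n_frames)
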
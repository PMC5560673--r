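#' Detect fluorescent cells in a 2D frame
#'
#' Detection is smooth / threshold / label: Gaussian smoothing
#' (`sigma_px`), global thresholding (Otsu by default), 8-connected
#' component labeling, area filtering, and intensity-weighted centroids
#' computed on the smoothed image. Coordinates are 0-based (centre of the
#' first pixel is (0, 0)); detections are ordered by (y, x).
#'
#' @param frame 2D intensity matrix.
#' @param sigma_px Gaussian smoothing sigma in pixels.
#' @param threshold_mode `"otsu"` or `"absolute"`.
#' @param threshold_value Threshold intensity when `threshold_mode =
#'   "absolute"` (on the smoothed image).
#' @param min_area,max_area Component area limits in pixels.
#' @param time_index Frame ordinal stored with each detection.
#' @return A data frame of class `detections` with columns `time_index`,
#'   `x`, `y`, `intensity` (peak raw intensity in the component) and
#'   `area`. A blank frame yields zero rows, not an error.
#' @export
detect_cells <- function(frame, sigma_px = 2,
                         threshold_mode = c("otsu", "absolute"),
                         threshold_value = NULL,
                         min_area = 4, max_area = Inf, time_index = 0L) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.matrix(frame), nrow(frame) > 0, ncol(frame) > 0)
  if (min_area <= 0 || min_area > max_area) {
    stop("need 0 < min_area <= max_area")
  }
  empty <- data.frame(time_index = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0), area = integer(0))
  class(empty) <- c("detections", "data.frame")

  sm <- gauss_blur(frame, sigma_px)
  mx <- max(sm)
  if (mx <= 0) return(empty)
  thr <- if (threshold_mode == "otsu") {
    EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  } else {
    if (is.null(threshold_value)) stop("threshold_value required for absolute mode")
    threshold_value
  }
  bw <- sm > thr
  if (!any(bw)) return(empty)
  lab <- label_components8(bw)
  nlab <- max(lab)
  labv <- lab[lab > 0L]
  w <- sm[lab > 0L]
  raw <- frame[lab > 0L]
  pos <- which(lab > 0L)
  yy <- ((pos - 1L) %% nrow(frame))          # 0-based row
  xx <- ((pos - 1L) %/% nrow(frame))         # 0-based col
  area <- tabulate(labv, nlab)
  wsum <- rowsum_by(w, labv, nlab)
  cx <- rowsum_by(w * xx, labv, nlab) / wsum
  cy <- rowsum_by(w * yy, labv, nlab) / wsum
  peak <- vapply(seq_len(nlab), function(l) max(raw[labv == l]), numeric(1))
  keep <- which(area >= min_area & area <= max_area)
  if (!length(keep)) return(empty)
  out <- data.frame(time_index = as.integer(time_index), x = cx[keep],
                    y = cy[keep], intensity = peak[keep],
                    area = as.integer(area[keep]))
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("detections", "data.frame")
  out
}

rowsum_by <- function(v, g, n) {
  out <- numeric(n)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# 8-connected component labeling of a logical matrix (0 = background).
label_components8 <- function(bw) {
  d <- dim(bw)
  idx <- which(bw)
  lab <- matrix(0L, d[1], d[2])
  if (!length(idx)) return(lab)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% d[1]) + 1L
  cc <- ((idx - 1L) %/% d[1]) + 1L
  from <- integer(0); to <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- r + off[1]; ccn <- cc + off[2]
    ok <- rr >= 1L & rr <= d[1] & ccn >= 1L & ccn <= d[2]
    nidx <- (ccn - 1L) * d[1] + rr
    hit <- ok
    hit[ok] <- pos[nidx[ok]] > 0L
    from <- c(from, pos[idx[hit]])
    to <- c(to, pos[nidx[hit]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Optimal one-to-one assignment on a gated cost matrix. Maximizes the number
# of matched pairs, then minimizes total cost among maximal matchings
# (unmatch penalty U exceeds any feasible matched cost, disallowed >> 2U).
# Returns an integer vector: for each row, the matched column or NA.
gated_assignment <- function(cost, allowed) {
  n <- nrow(cost); m <- ncol(cost)
  match_j <- rep(NA_integer_, n)
  if (n == 0 || m == 0 || !any(allowed)) return(match_j)
  U <- sum(cost[allowed]) + 1
  BIG <- 10 * (n + m) * U
  s <- n + m
  S <- matrix(BIG, s, s)
  S[seq_len(n), seq_len(m)] <- ifelse(allowed, cost, BIG)
  S[cbind(seq_len(n), m + seq_len(n))] <- U
  S[cbind(n + seq_len(m), seq_len(m))] <- U
  S[n + seq_len(m), m + seq_len(n)] <- 0
  sol <- as.integer(clue::solve_LSAP(S))
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && allowed[i, j]) match_j[i] <- j
  }
  match_j
}

#' Link per-frame detections into 2D tracks
#'
#' Frame-to-frame gated optimal assignment: candidate pairs are those whose
#' displacement does not exceed `gate_px` per elapsed frame, and among the
#' gated pairs the assignment maximizes the number of links and minimizes
#' total squared displacement (Hungarian algorithm). Unmatched detections
#' start new tracks. A track missing for up to `max_gap` frames may be
#' re-linked, with the gap bridged by linearly interpolated points flagged
#' `gap-filled`; longer absences terminate it.
#'
#' @param detections A `detections` data frame spanning several frames, or a
#'   list of per-frame detection data frames.
#' @param gate_px Maximum displacement per elapsed frame, pixels.
#' @param max_gap Maximum number of consecutive missed frames bridged.
#' @return A data frame of class `tracks2d` with columns `id`,
#'   `time_index`, `x`, `y`, `status` (`detected` or `gap-filled`).
#' @export
link_tracks <- function(detections, gate_px, max_gap = 0) {
  if (gate_px <= 0) stop("gate_px must be > 0")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(detections, as.data.frame))
  }
  if (is.null(detections) || nrow(detections) == 0) return(empty_tracks2d())
  stopifnot(all(c("time_index", "x", "y") %in% names(detections)))

  frames <- seq(min(detections$time_index), max(detections$time_index))
  tracks <- list()   # each: list(id, t, x, y, status, last_t, last_x, last_y, open)
  next_id <- 1L
  for (t in frames) {
    det <- detections[detections$time_index == t, , drop = FALSE]
    open <- which(vapply(tracks, function(tr) {
      tr$open && (t - tr$last_t) <= max_gap + 1L
    }, logical(1)))
    matched_det <- integer(0)
    if (length(open) && nrow(det)) {
      lastx <- vapply(tracks[open], `[[`, numeric(1), "last_x")
      lasty <- vapply(tracks[open], `[[`, numeric(1), "last_y")
      lastt <- vapply(tracks[open], `[[`, numeric(1), "last_t")
      dx <- outer(lastx, det$x, "-")
      dy <- outer(lasty, det$y, "-")
      cost <- dx^2 + dy^2
      gate <- gate_px * (t - lastt)
      allowed <- sqrt(cost) <= matrix(gate, nrow(cost), ncol(cost))
      mj <- gated_assignment(cost, allowed)
      for (i in seq_along(open)) {
        j <- mj[i]
        if (is.na(j)) next
        k <- open[i]
        tr <- tracks[[k]]
        span <- t - tr$last_t
        if (span > 1L) {  # bridge the gap with interpolated points
          for (g in seq_len(span - 1L)) {
            f <- g / span
            tr$t <- c(tr$t, tr$last_t + g)
            tr$x <- c(tr$x, tr$last_x + f * (det$x[j] - tr$last_x))
            tr$y <- c(tr$y, tr$last_y + f * (det$y[j] - tr$last_y))
            tr$status <- c(tr$status, "gap-filled")
          }
        }
        tr$t <- c(tr$t, t); tr$x <- c(tr$x, det$x[j]); tr$y <- c(tr$y, det$y[j])
        tr$status <- c(tr$status, "detected")
        tr$last_t <- t; tr$last_x <- det$x[j]; tr$last_y <- det$y[j]
        tracks[[k]] <- tr
        matched_det <- c(matched_det, j)
      }
    }
    # terminate tracks whose absence can no longer be bridged
    for (k in seq_along(tracks)) {
      if (tracks[[k]]$open && (t - tracks[[k]]$last_t) > max_gap) {
        tracks[[k]]$open <- FALSE
      }
    }
    if (nrow(det)) {
      for (j in setdiff(seq_len(nrow(det)), matched_det)) {
        tracks[[length(tracks) + 1L]] <- list(
          id = next_id, t = t, x = det$x[j], y = det$y[j],
          status = "detected", last_t = t, last_x = det$x[j],
          last_y = det$y[j], open = TRUE)
        next_id <- next_id + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = tr$id, time_index = as.integer(tr$t), x = tr$x, y = tr$y,
               status = tr$status)
  }))
  out <- out[order(out$id, out$time_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tracks2d", "data.frame")
  out
}

empty_tracks2d <- function() {
  out <- data.frame(id = integer(0), time_index = integer(0), x = numeric(0),
                    y = numeric(0), status = character(0))
  class(out) <- c("tracks2d", "data.frame")
  out
}

#' Semi-automatic (seeded) tracking
#'
#' Each seed is followed forward in time: at every subsequent frame the new
#' position is the intensity-weighted centroid of the pixels within
#' `search_radius_px` of the previous position. The track stops when the
#' local intensity maximum inside the search disk falls below the detection
#' threshold (per-frame Otsu by default). The seed point itself is always
#' recorded, so a seed on background yields a length-1 track.
#'
#' @param seeds Data frame with columns `time_index`, `x`, `y` (0-based
#'   pixel coordinates), or a numeric `c(time_index, x, y)` for one seed.
#' @param frames List of projected frames ([max_intensity_projection()]) or
#'   2D matrices, ordered by frame, frame k at `time_index` k - 1.
#' @param search_radius_px Search disk radius, pixels (> 0).
#' @inheritParams detect_cells
#' @return A `tracks2d` data frame (status `seeded`), with an attribute
#'   `terminated`: named logical, `TRUE` for tracks stopped by the
#'   threshold rule before the last frame.
#' @export
seeded_track <- function(seeds, frames, search_radius_px = 8,
                         threshold_mode = c("otsu", "absolute"),
                         threshold_value = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (search_radius_px <= 0) stop("search_radius_px must be > 0")
  if (is.numeric(seeds) && is.null(dim(seeds))) {
    seeds <- data.frame(time_index = seeds[1], x = seeds[2], y = seeds[3])
  }
  stopifnot(all(c("time_index", "x", "y") %in% names(seeds)))
  imgs <- lapply(frames, function(f) {
    if (inherits(f, "projected_frame")) f$image else f
  })
  T_ <- length(imgs)
  ny <- nrow(imgs[[1]]); nx <- ncol(imgs[[1]])
  thr <- vapply(imgs, function(im) {
    if (threshold_mode == "absolute") return(threshold_value)
    mx <- max(im)
    if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(im / mx),
                                        range = c(0, 1)) * mx
  }, numeric(1))

  res <- list(); terminated <- logical(0)
  for (s in seq_len(nrow(seeds))) {
    t0 <- as.integer(seeds$time_index[s])
    px <- seeds$x[s]; py <- seeds$y[s]
    if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 || t0 < 0 || t0 > T_ - 1) {
      stop(sprintf("seed %d outside image/time bounds", s))
    }
    t <- t0; xs <- px; ys <- py; ts <- t0
    stopped <- FALSE
    while (t < T_ - 1L) {
      t <- t + 1L
      im <- imgs[[t + 1L]]
      dsk <- disk_pixels(px, py, search_radius_px, ny, nx)
      vals <- im[dsk$lin]
      if (max(vals) < thr[t + 1L]) { stopped <- TRUE; break }
      wsum <- sum(vals)
      px <- sum(vals * dsk$x) / wsum
      py <- sum(vals * dsk$y) / wsum
      xs <- c(xs, px); ys <- c(ys, py); ts <- c(ts, t)
    }
    if (length(ts) == 1L) stopped <- TRUE
    res[[s]] <- data.frame(id = s, time_index = as.integer(ts), x = xs, y = ys,
                           status = "seeded")
    terminated <- c(terminated, stopped)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("tracks2d", "data.frame")
  names(terminated) <- as.character(seq_len(nrow(seeds)))
  attr(out, "terminated") <- terminated
  out
}

# pixels within a disk of radius r around 0-based (x, y); returns 0-based
# coords and 1-based linear indices into the [ny, nx] matrix
disk_pixels <- function(x, y, r, ny, nx) {
  x0 <- max(0L, floor(x - r)); x1 <- min(nx - 1L, ceiling(x + r))
  y0 <- max(0L, floor(y - r)); y1 <- min(ny - 1L, ceiling(y + r))
  gx <- rep(x0:x1, each = y1 - y0 + 1L)
  gy <- rep(y0:y1, times = x1 - x0 + 1L)
  ok <- (gx - x)^2 + (gy - y)^2 <= r^2
  gx <- gx[ok]; gy <- gy[ok]
  list(x = gx, y = gy, lin = gx * ny + gy + 1L)
}

#' Import manually annotated tracks
#'
#' Reads a CSV (or data frame) with columns `id`, `time_index`, `x`, `y`
#' and converts it verbatim into a `tracks2d` object with status `manual`.
#' Rows are sorted by time within each id; a duplicated `(id, time_index)`
#' pair is a format error.
#'
#' @param x CSV path or data frame.
#' @return A `tracks2d` data frame.
#' @export
import_manual_track <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("id", "time_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop(sprintf("format error: missing column(s) %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (anyDuplicated(df[, c("id", "time_index")])) {
    stop("format error: duplicate (id, time_index) rows")
  }
  ids <- unique(df$id)
  df$..ord <- match(df$id, ids)
  df <- df[order(df$..ord, df$time_index), , drop = FALSE]
  out <- data.frame(id = df$id, time_index = as.integer(df$time_index),
                    x = df$x, y = df$y, status = "manual")
  rownames(out) <- NULL
  class(out) <- c("tracks2d", "data.frame")
  out
}

#' Export tracks as CSV
#'
#' @param tracks A `tracks2d` or `tracks3d` data frame.
#' @param path Output path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}
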
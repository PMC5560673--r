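# Shared fixture builders. Everything is generated in code; no binary data.

# 2D frame with Gaussian spots at 0-based (x, y) positions
spot_frame <- function(ny, nx, xs, ys, sigma = 2, amp = 1000, bg = 10) {
  img <- matrix(bg, ny, nx)
  for (k in seq_along(xs)) {
    gx <- exp(-((seq_len(nx) - 1 - xs[k])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(ny) - 1 - ys[k])^2) / (2 * sigma^2))
    img <- img + amp * (gy %o% gx)
  }
  img
}

# 3D stack with one Gaussian spot at 0-based (x, y, z)
spot_stack <- function(ny, nx, nz, x, y, z, sigma_xy = 2, sigma_z = 1.5,
                       amp = 1000, bg = 10) {
  s <- array(bg, c(ny, nx, nz))
  gx <- exp(-((seq_len(nx) - 1 - x)^2) / (2 * sigma_xy^2))
  gy <- exp(-((seq_len(ny) - 1 - y)^2) / (2 * sigma_xy^2))
  gz <- exp(-((seq_len(nz) - 1 - z)^2) / (2 * sigma_z^2))
  for (k in seq_len(nz)) s[, , k] <- s[, , k] + amp * gz[k] * (gy %o% gx)
  s
}

# circularly roll a stack: content moves by +dy rows, +dx cols, +dz slices
roll_stack <- function(s, dy, dx, dz) {
  d <- dim(s)
  s[((seq_len(d[1]) - 1 - dy) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 - dx) %% d[2]) + 1,
    ((seq_len(d[3]) - 1 - dz) %% d[3]) + 1]
}

# brute-force gated-assignment oracle: enumerate every injective partial
# matching restricted to allowed pairs; maximize matches, then minimize
# total cost. Independent of the package's Hungarian-based implementation.
bf_assignment <- function(cost, allowed) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(matches = -1L, cost = Inf, match_j = rep(NA_integer_, n))
  recurse <- function(i, used, match_j, k, total) {
    if (i > n) {
      if (k > best$matches || (k == best$matches && total < best$cost)) {
        best <<- list(matches = k, cost = total, match_j = match_j)
      }
      return(invisible())
    }
    recurse(i + 1L, used, match_j, k, total)  # row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        match_j[i] <- j
        recurse(i + 1L, used, match_j, k + 1L, total + cost[i, j])
        used[j] <- FALSE
        match_j[i] <- NA_integer_
      }
    }
  }
  recurse(1L, rep(FALSE, m), rep(NA_integer_, n), 0L, 0)
  best
}

# sequential frame-to-frame linking using the brute-force oracle, mirroring
# the linker's protocol (no gap bridging: max_gap = 0)
bf_link <- function(det_list, gate_px) {
  tracks <- list()
  for (t in seq_along(det_list) - 1L) {
    det <- det_list[[t + 1L]]
    open <- which(vapply(tracks, function(tr) tr$last_t == t - 1L, logical(1)))
    matched <- integer(0)
    if (length(open) && nrow(det)) {
      cost <- outer(vapply(tracks[open], `[[`, numeric(1), "last_x"), det$x, "-")^2 +
        outer(vapply(tracks[open], `[[`, numeric(1), "last_y"), det$y, "-")^2
      allowed <- sqrt(cost) <= gate_px
      bf <- bf_assignment(cost, allowed)
      for (i in seq_along(open)) {
        j <- bf$match_j[i]
        if (is.na(j)) next
        tr <- tracks[[open[i]]]
        tr$pts <- rbind(tr$pts, c(t, det$x[j], det$y[j]))
        tr$last_t <- t; tr$last_x <- det$x[j]; tr$last_y <- det$y[j]
        tracks[[open[i]]] <- tr
        matched <- c(matched, j)
      }
    }
    if (nrow(det)) {
      for (j in setdiff(seq_len(nrow(det)), matched)) {
        tracks[[length(tracks) + 1L]] <- list(
          pts = matrix(c(t, det$x[j], det$y[j]), 1), last_t = t,
          last_x = det$x[j], last_y = det$y[j])
      }
    }
  }
  tracks
}

# canonical signature of a track partition: sorted per-track point strings,
# invariant to id relabeling
partition_signature <- function(df) {
  sig <- vapply(split(df[, c("time_index", "x", "y")], df$id), function(p) {
    p <- p[order(p$time_index), ]
    paste(sprintf("%d:%.6f:%.6f", p$time_index, p$x, p$y), collapse = ";")
  }, character(1))
  sort(unname(sig))
}

bf_partition_signature <- function(tracks) {
  sig <- vapply(tracks, function(tr) {
    p <- tr$pts[order(tr$pts[, 1]), , drop = FALSE]
    paste(sprintf("%d:%.6f:%.6f", p[, 1], p[, 2], p[, 3]), collapse = ";")
  }, character(1))
  sort(unname(sig))
}

# random walk track in voxel coordinates for metric property tests
random_track <- function(n, id = 1L, step_sd = 3, z = TRUE) {
  data.frame(id = id, time_index = seq_len(n) - 1L,
             x = cumsum(rnorm(n, 0, step_sd)),
             y = cumsum(rnorm(n, 0, step_sd)),
             z = if (z) abs(cumsum(rnorm(n, 0, step_sd / 3))) else 0,
             status = "detected")
}
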
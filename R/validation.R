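#' Compare recovered tracks against simulation ground truth
#'
#' Matches recovered tracks to ground-truth tracks one-to-one by minimizing
#' the mean lateral distance over co-observed frames (optimal assignment),
#' then scores the match per point: a recovered point keeps its identity if
#' its matched ground-truth cell is also the nearest ground-truth cell at
#' that frame and lies within `tolerance_px` laterally.
#'
#' @param tracks Recovered tracks (`tracks2d` or `tracks3d` data frame,
#'   voxel coordinates).
#' @param truth A [simulate_tracks()] result (or its `tracks` data frame).
#' @param tolerance_px Lateral identity tolerance in pixels.
#' @return A list:
#' * `matching` — data frame `id`, `true_id`, `mean_dist_px`, `n_overlap`;
#' * `point_match_frac` — fraction of non-gap-filled recovered points with
#'   correct identity;
#' * `points` — per-point table with lateral (`err_xy_px`, `err_xy_um`)
#'   and axial (`err_z_slices`) errors and the camera-side flag of the
#'   true position (`facing`, z at or above the volume-centre slice being
#'   `FALSE`);
#' * `paths` — per-matched-track comparison of recovered vs true path
#'   length (um, 3D, computed with the same geometry).
#' @export
evaluate_against_truth <- function(tracks, truth, tolerance_px = 10) {
  tt <- if (inherits(truth, "ground_truth")) truth$tracks else as.data.frame(truth)
  geometry <- if (inherits(truth, "ground_truth")) truth$config$geometry
              else voxel_geometry()
  rec <- as.data.frame(tracks)
  stopifnot(nrow(rec) > 0, nrow(tt) > 0)
  rid <- unique(rec$id); tid <- unique(tt$id)

  cost <- matrix(Inf, length(rid), length(tid))
  for (i in seq_along(rid)) {
    a <- rec[rec$id == rid[i], ]
    for (j in seq_along(tid)) {
      b <- tt[tt$id == tid[j], ]
      m <- merge(a[, c("time_index", "x", "y")],
                 b[, c("time_index", "x", "y")], by = "time_index")
      if (nrow(m) == 0) next
      cost[i, j] <- mean(sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2))
    }
  }
  mj <- gated_assignment(ifelse(is.finite(cost), cost, 0), is.finite(cost))
  matching <- data.frame(id = rid, true_id = tid[mj],
                         mean_dist_px = cost[cbind(seq_along(rid),
                                                   ifelse(is.na(mj), 1L, mj))])
  matching$mean_dist_px[is.na(mj)] <- NA_real_
  matching$n_overlap <- vapply(seq_along(rid), function(i) {
    if (is.na(mj[i])) return(0L)
    sum(rec$id == rid[i] &
          rec$time_index %in% tt$time_index[tt$id == tid[mj[i]]])
  }, integer(1))

  z_mid <- (max(tt$z) + min(tt$z)) / 2
  pts <- NULL
  n_match <- 0L; n_tot <- 0L
  for (i in seq_along(rid)) {
    if (is.na(mj[i])) next
    a <- rec[rec$id == rid[i], ]
    if ("status" %in% names(a)) a <- a[a$status != "gap-filled", ]
    b <- tt[tt$id == tid[mj[i]], ]
    for (k in seq_len(nrow(a))) {
      t <- a$time_index[k]
      bt <- tt[tt$time_index == t, ]
      if (nrow(bt) == 0) next
      d_all <- sqrt((bt$x - a$x[k])^2 + (bt$y - a$y[k])^2)
      nearest <- bt$id[which.min(d_all)]
      row_b <- b[b$time_index == t, ]
      n_tot <- n_tot + 1L
      okid <- nrow(row_b) == 1 && nearest == tid[mj[i]] &&
        min(d_all) <= tolerance_px
      if (okid) n_match <- n_match + 1L
      if (nrow(row_b) == 1) {
        err_xy <- sqrt((a$x[k] - row_b$x)^2 + (a$y[k] - row_b$y)^2)
        err_z <- if ("z" %in% names(a) && is.finite(a$z[k])) {
          abs(a$z[k] - row_b$z)
        } else NA_real_
        pts <- rbind(pts, data.frame(
          id = rid[i], true_id = tid[mj[i]], time_index = t,
          err_xy_px = err_xy,
          err_xy_um = err_xy * sqrt(geometry$dx * geometry$dy),
          err_z_slices = err_z, identity_ok = okid,
          facing = row_b$z <= z_mid))
      }
    }
  }
  paths <- NULL
  for (i in seq_along(rid)) {
    if (is.na(mj[i])) next
    a <- rec[rec$id == rid[i], ]
    b <- tt[tt$id == tid[mj[i]], ]
    b <- b[b$time_index %in% a$time_index, ]
    if (nrow(a) < 2 || nrow(b) < 2) next
    pl_rec <- tryCatch(path_length(a, geometry), error = function(e) NA_real_)
    pl_true <- path_length(b, geometry)
    paths <- rbind(paths, data.frame(
      id = rid[i], true_id = tid[mj[i]], n_points = nrow(a),
      path_rec_um = pl_rec, path_true_um = pl_true,
      rel_err = abs(pl_rec - pl_true) / pl_true,
      facing = mean(b$z <= z_mid) >= 0.5))
  }
  list(matching = matching,
       point_match_frac = if (n_tot > 0) n_match / n_tot else NA_real_,
       points = pts, paths = paths)
}
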
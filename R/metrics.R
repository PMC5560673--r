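#' Motility measures for 3D cell tracks
#'
#' All measures are computed in physical units by anisotropic scaling of
#' the voxel coordinates (dx, dy lateral, dz axial, dt minutes). Gap-filled
#' points are excluded by default so that interpolated positions do not
#' fabricate motion; points whose z could not be recovered are likewise
#' dropped in 3D mode.
#'
#' * path length: sum of Euclidean step distances along the track, um
#' * distance from origin: distance from the first retained point, um
#' * speed: instantaneous (step / elapsed minutes) and mean
#'   (path length / elapsed minutes), um/min
#' * straightness: net displacement / path length (1 for a stationary or
#'   perfectly straight track)
#'
#' @param track One track: a data frame with columns `time_index`, `x`,
#'   `y` and (for 3D mode) `z`, in voxel units, plus optional `status` /
#'   `z_ok` flags.
#' @param geometry A [voxel_geometry()].
#' @param mode `"3d"` (default) includes the axial component; `"2d"`
#'   ignores z.
#' @param include_gapfilled If `TRUE`, gap-filled points contribute.
#' @return `path_length()`: total length in um (0 for a single point).
#' @name track-metrics
NULL

retained_points <- function(track, mode, include_gapfilled) {
  df <- as.data.frame(track)
  keep <- rep(TRUE, nrow(df))
  if (!include_gapfilled && "status" %in% names(df)) {
    keep <- keep & df$status != "gap-filled"
  }
  if (mode == "3d" && "z" %in% names(df)) keep <- keep & is.finite(df$z)
  if (mode == "3d" && "z_ok" %in% names(df)) keep <- keep & df$z_ok
  df <- df[keep, , drop = FALSE]
  df[order(df$time_index), , drop = FALSE]
}

step_lengths_um <- function(df, geometry, mode) {
  n <- nrow(df)
  if (n < 2) return(numeric(0))
  dx <- diff(df$x) * geometry$dx
  dy <- diff(df$y) * geometry$dy
  dz <- if (mode == "3d" && "z" %in% names(df)) diff(df$z) * geometry$dz else 0
  sqrt(dx^2 + dy^2 + dz^2)
}

#' @rdname track-metrics
#' @export
path_length <- function(track, geometry, mode = c("3d", "2d"),
                        include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  df <- retained_points(track, mode, include_gapfilled)
  if (nrow(df) < 1) stop("track has no retained points")
  sum(step_lengths_um(df, geometry, mode))
}

#' @rdname track-metrics
#' @return `distance_from_origin()`: data frame `time_index`, `t_min`,
#'   `dist_um` (first value 0).
#' @export
distance_from_origin <- function(track, geometry, mode = c("3d", "2d"),
                                 include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  df <- retained_points(track, mode, include_gapfilled)
  if (nrow(df) < 1) stop("track has no retained points")
  ddx <- (df$x - df$x[1]) * geometry$dx
  ddy <- (df$y - df$y[1]) * geometry$dy
  ddz <- if (mode == "3d" && "z" %in% names(df)) (df$z - df$z[1]) * geometry$dz
         else 0
  data.frame(time_index = df$time_index, t_min = df$time_index * geometry$dt,
             dist_um = sqrt(ddx^2 + ddy^2 + ddz^2))
}

#' @rdname track-metrics
#' @return `speeds()`: list with `mean_um_min` and `instantaneous` (data
#'   frame `time_index`, `speed_um_min`, the speed of the step ending at
#'   each time point).
#' @export
speeds <- function(track, geometry, mode = c("3d", "2d"),
                   include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  df <- retained_points(track, mode, include_gapfilled)
  if (nrow(df) < 1) stop("track has no retained points")
  if (nrow(df) < 2) {
    return(list(mean_um_min = 0,
                instantaneous = data.frame(time_index = integer(0),
                                           speed_um_min = numeric(0))))
  }
  steps <- step_lengths_um(df, geometry, mode)
  dtm <- diff(df$time_index) * geometry$dt
  elapsed <- (df$time_index[nrow(df)] - df$time_index[1]) * geometry$dt
  list(mean_um_min = sum(steps) / elapsed,
       instantaneous = data.frame(time_index = df$time_index[-1],
                                  speed_um_min = steps / dtm))
}

#' Per-track summary metrics
#'
#' @param tracks A `tracks3d` (or `tracks2d`) data frame covering one or
#'   more ids.
#' @inheritParams track-metrics
#' @return Data frame: `id`, `n_points`, `path_length_um`, `net_disp_um`,
#'   `mean_speed_um_min`, `straightness`.
#' @export
track_metrics <- function(tracks, geometry, mode = c("3d", "2d"),
                          include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  df <- as.data.frame(tracks)
  ids <- unique(df$id)
  rows <- lapply(ids, function(i) {
    tr <- df[df$id == i, , drop = FALSE]
    rp <- retained_points(tr, mode, include_gapfilled)
    if (nrow(rp) < 1) {
      return(data.frame(id = i, n_points = 0L, path_length_um = NA_real_,
                        net_disp_um = NA_real_, mean_speed_um_min = NA_real_,
                        straightness = NA_real_))
    }
    pl <- sum(step_lengths_um(rp, geometry, mode))
    dfo <- distance_from_origin(rp, geometry, mode, include_gapfilled = TRUE)
    net <- dfo$dist_um[nrow(dfo)]
    sp <- speeds(rp, geometry, mode, include_gapfilled = TRUE)
    data.frame(id = i, n_points = nrow(rp), path_length_um = pl,
               net_disp_um = net, mean_speed_um_min = sp$mean_um_min,
               straightness = if (pl > 0) net / pl else 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary: per-time averages across tracks
#'
#' Builds track-by-time matrices of the distance from origin and the
#' cumulative path length, and their per-time arithmetic mean over the
#' tracks defined at each time point (no imputation) — the "average curve"
#' drawn as a dotted line through per-cell motility plots.
#'
#' @inheritParams track_metrics
#' @return List with `dist_origin` and `cum_path` (matrices, rows = track
#'   ids, columns = time 0..T-1, `NA` where a track is undefined) and
#'   `average` (data frame `time_index`, `t_min`, `mean_dist_origin_um`,
#'   `mean_cum_path_um`, `n_tracks`).
#' @export
cohort_summary <- function(tracks, geometry, mode = c("3d", "2d"),
                           include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  df <- as.data.frame(tracks)
  if (nrow(df) < 1) stop("need at least one track")
  ids <- unique(df$id)
  times <- seq(0L, max(df$time_index))
  dmat <- matrix(NA_real_, length(ids), length(times),
                 dimnames = list(as.character(ids), as.character(times)))
  pmat <- dmat
  for (k in seq_along(ids)) {
    rp <- retained_points(df[df$id == ids[k], , drop = FALSE], mode,
                          include_gapfilled)
    if (nrow(rp) < 1) next
    dfo <- distance_from_origin(rp, geometry, mode, include_gapfilled = TRUE)
    cum <- c(0, cumsum(step_lengths_um(rp, geometry, mode)))
    ti <- as.character(rp$time_index)
    dmat[k, ti] <- dfo$dist_um
    pmat[k, ti] <- cum
  }
  n_def <- colSums(!is.na(dmat))
  avg <- data.frame(
    time_index = times, t_min = times * geometry$dt,
    mean_dist_origin_um = ifelse(n_def > 0, colMeans(dmat, na.rm = TRUE), NA),
    mean_cum_path_um = ifelse(n_def > 0, colMeans(pmat, na.rm = TRUE), NA),
    n_tracks = n_def)
  rownames(avg) <- NULL
  list(dist_origin = dmat, cum_path = pmat, average = avg)
}

#' Export tracks and metrics to CSV, XLSX and JSON
#'
#' Writes, into `out_dir`:
#' * `tracks3d.csv` — the full point table (id, t, voxel and um coordinates,
#'   z confidence, status);
#' * `metrics.csv` — long table `id`, `t_min`, `dist_origin_um`,
#'   `cum_path_um`, `inst_speed_um_min`;
#' * `summary.csv` — per-track summary ([track_metrics()] columns);
#' * `metrics.xlsx` — one worksheet per metric plus the summary;
#' * `manifest.json` — inputs, parameters, package version and seed, the
#'   structured machine-readable companion of the tabular exports.
#'
#' Re-exporting the same tracks with the same parameters is byte-identical.
#'
#' @param tracks A `tracks3d` data frame.
#' @param geometry A [voxel_geometry()].
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (may be `NULL`).
#' @param params Named list of parameters recorded in the manifest.
#' @inheritParams track_metrics
#' @return Invisibly, the paths written.
#' @export
export_tracks <- function(tracks, geometry, out_dir, seed = NULL,
                          params = list(), mode = c("3d", "2d"),
                          include_gapfilled = FALSE) {
  mode <- match.arg(mode)
  geometry <- as_voxel_geometry(geometry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot write to '%s'", out_dir))
  df <- as.data.frame(tracks)

  p_tracks <- file.path(out_dir, "tracks3d.csv")
  utils::write.csv(df, p_tracks, row.names = FALSE)

  long <- data.frame(id = numeric(0), t_min = numeric(0),
                     dist_origin_um = numeric(0), cum_path_um = numeric(0),
                     inst_speed_um_min = numeric(0))
  summ <- data.frame(id = numeric(0), path_length_um = numeric(0),
                     net_disp_um = numeric(0), mean_speed_um_min = numeric(0),
                     straightness = numeric(0))
  if (nrow(df) > 0) {
    for (i in unique(df$id)) {
      rp <- retained_points(df[df$id == i, , drop = FALSE], mode,
                            include_gapfilled)
      if (nrow(rp) < 1) next
      dfo <- distance_from_origin(rp, geometry, mode, include_gapfilled = TRUE)
      cum <- c(0, cumsum(step_lengths_um(rp, geometry, mode)))
      sp <- speeds(rp, geometry, mode, include_gapfilled = TRUE)
      inst <- c(NA, sp$instantaneous$speed_um_min)
      long <- rbind(long, data.frame(id = i, t_min = dfo$t_min,
                                     dist_origin_um = dfo$dist_um,
                                     cum_path_um = cum,
                                     inst_speed_um_min = inst))
    }
    tm <- track_metrics(df, geometry, mode, include_gapfilled)
    summ <- tm[, c("id", "path_length_um", "net_disp_um",
                   "mean_speed_um_min", "straightness")]
  }
  p_metrics <- file.path(out_dir, "metrics.csv")
  p_summary <- file.path(out_dir, "summary.csv")
  utils::write.csv(long, p_metrics, row.names = FALSE)
  utils::write.csv(summ, p_summary, row.names = FALSE)

  p_xlsx <- file.path(out_dir, "metrics.xlsx")
  write_minimal_xlsx(list(tracks = df, metrics = long, summary = summ),
                     p_xlsx)

  p_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(software = "tracker3d",
         version = as.character(utils::packageVersion("tracker3d")),
         seed = seed,
         geometry = list(dx_um = geometry$dx, dy_um = geometry$dy,
                         dz_um = geometry$dz, dt_min = geometry$dt),
         mode = mode, include_gapfilled = include_gapfilled,
         n_tracks = length(unique(df$id)), n_points = nrow(df),
         params = params),
    p_manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(c(p_tracks, p_metrics, p_summary, p_xlsx, p_manifest))
}
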
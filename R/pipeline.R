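#' Pipeline configuration
#'
#' Collects every stage's toggles and parameters. A run is fully
#' determined by its inputs and this configuration, which is serialized
#' verbatim into the run manifest.
#'
#' @param illumination Estimate and apply retrospective illumination
#'   correction?
#' @param n_illumination_planes How many z-planes (sampled evenly across
#'   frames and slices) train the illumination model.
#' @param alignment Estimate and apply rigid alignment to the reference
#'   frame?
#' @param reference_index Reference frame (0-based) for alignment.
#' @param rotation_deg Manual in-plane rotation override for alignment.
#' @param min_confidence Registration confidence below which a frame's
#'   estimated shift is replaced by zero (with a warning).
#' @param projection `"mip"` or `"edf"`.
#' @param edf_patch Window size for the EDF projection.
#' @param mode Tracking mode: `"auto"` (detect + link), `"seeded"`
#'   (semi-automatic, from `seeds`), or `"manual"` (import `manual_tracks`).
#' @param seeds Data frame of seeds for `"seeded"` mode (see
#'   [seeded_track()]).
#' @param manual_tracks CSV path or data frame for `"manual"` mode.
#' @param sigma_px,threshold_mode,threshold_value,min_area,max_area
#'   Detection parameters ([detect_cells()]).
#' @param gate_px,max_gap Linking parameters ([link_tracks()]).
#' @param search_radius_px Search radius for seeded tracking.
#' @param window_radius_px Disk radius for z-recovery ([recover_z()]).
#' @param refine_z Parabolic sub-slice refinement in z-recovery?
#' @param metrics_mode `"3d"` (default) or `"2d"` (ignore z in measures).
#' @param keep_intermediate Write projections, transforms and the
#'   illumination model into the output directory?
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents provenance of simulated inputs).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(illumination = TRUE, n_illumination_planes = 40,
                            alignment = TRUE, reference_index = 0,
                            rotation_deg = 0, min_confidence = 0.3,
                            projection = c("mip", "edf"), edf_patch = 5,
                            mode = c("auto", "seeded", "manual"),
                            seeds = NULL, manual_tracks = NULL,
                            sigma_px = 2, threshold_mode = "otsu",
                            threshold_value = NULL, min_area = 4,
                            max_area = Inf, gate_px = 30, max_gap = 2,
                            search_radius_px = 8, window_radius_px = 3,
                            refine_z = FALSE,
                            metrics_mode = c("3d", "2d"),
                            keep_intermediate = FALSE, seed = NULL) {
  structure(list(
    illumination = illumination,
    n_illumination_planes = n_illumination_planes,
    alignment = alignment, reference_index = reference_index,
    rotation_deg = rotation_deg, min_confidence = min_confidence,
    projection = match.arg(projection),
    edf_patch = edf_patch, mode = match.arg(mode), seeds = seeds,
    manual_tracks = manual_tracks, sigma_px = sigma_px,
    threshold_mode = threshold_mode, threshold_value = threshold_value,
    min_area = min_area, max_area = max_area, gate_px = gate_px,
    max_gap = max_gap, search_radius_px = search_radius_px,
    window_radius_px = window_radius_px, refine_z = refine_z,
    metrics_mode = match.arg(metrics_mode),
    keep_intermediate = keep_intermediate, seed = seed),
    class = "pipeline_config")
}

#' Run the full 3D tracking pipeline
#'
#' Executes illumination correction, rigid alignment, projection,
#' 2D tracking (automatic, seeded or manual), z-recovery and metric
#' computation, and writes `tracks3d.csv`, `metrics.csv`, `summary.csv`,
#' `metrics.xlsx` and `manifest.json` into `out_dir`. Stacks are visited
#' frame by frame, so disk-backed time-lapses of arbitrary length are
#' processed in bounded memory. A stage failure aborts with an error
#' naming the stage and leaves a `FAILED` marker next to any partial
#' outputs.
#'
#' @param input A [timelapse()], or a character vector of TIFF paths.
#' @param config A [pipeline_config()].
#' @param geometry Voxel geometry, used when `input` is a path vector.
#' @param out_dir Output directory.
#' @param verbose Log stage progress and timings?
#' @return An object of class `tracker3d_run`: list with `tracks`
#'   (`tracks3d`), `summary` (per-track metrics), `cohort`
#'   ([cohort_summary()]), `transforms`, `illumination`, `config`,
#'   `out_dir`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         geometry = voxel_geometry(), out_dir = tempfile("run"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  tl <- stage("input", {
    if (inherits(input, "timelapse")) input
    else read_timelapse(input, geometry, lazy = TRUE)
  })
  nz <- tl$dim[3]

  illum <- NULL
  if (config$illumination) {
    illum <- stage("illumination", {
      planes <- sample_planes(tl, config$n_illumination_planes)
      estimate_illumination(planes)
    })
  }
  prep <- function(t) {
    s <- get_stack(tl, t)
    if (!is.null(illum)) s <- correct_illumination(s, illum)
    s
  }

  # first pass: projections (MIP always, for alignment) + axial profiles
  pass1 <- stage("projection", {
    proj <- vector("list", tl$n_frames)
    prof <- vector("list", tl$n_frames)
    for (t in seq_len(tl$n_frames) - 1L) {
      s <- prep(t)
      proj[[t + 1L]] <- max_intensity_projection(s, time_index = t)
      prof[[t + 1L]] <- axial_profile(s)
      if (config$projection == "edf") {
        proj[[t + 1L]]$image <- extended_depth_of_field(s, config$edf_patch)
      }
    }
    list(proj = proj, prof = prof)
  })
  projections <- pass1$proj

  transforms <- rep(list(rigid_transform()), tl$n_frames)
  if (config$alignment && tl$n_frames > 1) {
    transforms <- stage("alignment", {
      ref <- as.integer(config$reference_index) + 1L
      out <- vector("list", tl$n_frames)
      for (k in seq_len(tl$n_frames)) {
        if (k == ref) { out[[k]] <- rigid_transform(
          rotation_deg = config$rotation_deg); next }
        pc <- phase_correlate_2d(projections[[ref]]$image,
                                 projections[[k]]$image)
        if (pc$confidence < config$min_confidence) {
          warning(sprintf("frame %d: registration confidence %.2f below %.2f; using zero shift",
                          k - 1L, pc$confidence, config$min_confidence))
          pc$dx <- 0; pc$dy <- 0
        }
        dz <- cross_correlate_1d(pass1$prof[[ref]], pass1$prof[[k]])
        out[[k]] <- rigid_transform(pc$dx, pc$dy, dz,
                                    rotation_deg = config$rotation_deg)
      }
      out
    })
    # re-project any frame that actually moved
    for (k in seq_len(tl$n_frames)) {
      if (!is_identity_transform(transforms[[k]])) {
        s <- apply_transform(prep(k - 1L), transforms[[k]])
        projections[[k]] <- max_intensity_projection(s, time_index = k - 1L)
        if (config$projection == "edf") {
          projections[[k]]$image <- extended_depth_of_field(s, config$edf_patch)
        }
      }
    }
  }

  tracks2d <- stage("tracking", {
    switch(config$mode,
      auto = {
        dets <- lapply(projections, function(p) {
          detect_cells(p$image, sigma_px = config$sigma_px,
                       threshold_mode = config$threshold_mode,
                       threshold_value = config$threshold_value,
                       min_area = config$min_area, max_area = config$max_area,
                       time_index = p$time_index)
        })
        link_tracks(dets, gate_px = config$gate_px, max_gap = config$max_gap)
      },
      seeded = {
        if (is.null(config$seeds)) stop("mode 'seeded' needs seeds")
        seeded_track(config$seeds, projections,
                     search_radius_px = config$search_radius_px,
                     threshold_mode = config$threshold_mode,
                     threshold_value = config$threshold_value)
      },
      manual = {
        if (is.null(config$manual_tracks)) {
          stop("mode 'manual' needs manual_tracks")
        }
        import_manual_track(config$manual_tracks)
      })
  })

  tracks3d <- stage("z-recovery", {
    any_moved <- any(!vapply(transforms, is_identity_transform, logical(1)))
    src <- if (any_moved) {
      transformed_timelapse(tl, transforms, prep)
    } else if (!is.null(illum)) {
      corrected_timelapse(tl, prep)
    } else tl
    recover_z(tracks2d, src, window_radius_px = config$window_radius_px,
              refine = config$refine_z)
  })

  result <- stage("metrics", {
    summ <- track_metrics(tracks3d, tl$geometry, mode = config$metrics_mode)
    coh <- if (nrow(tracks3d) > 0) {
      cohort_summary(tracks3d, tl$geometry, mode = config$metrics_mode)
    } else NULL
    export_tracks(tracks3d, tl$geometry, out_dir, seed = config$seed,
                  params = config_manifest(config), mode = config$metrics_mode)
    if (config$keep_intermediate) {
      write_transforms(transforms, file.path(out_dir, "transforms.csv"))
      if (!is.null(illum)) {
        write_illumination(illum, file.path(out_dir, "illumination.tif"))
      }
      proj_dir <- file.path(out_dir, "projections")
      dir.create(proj_dir, showWarnings = FALSE)
      for (p in projections) {
        write_stack_tiff(p$image,
                         file.path(proj_dir, sprintf("mip_t%03d.tif",
                                                     p$time_index)), 16)
        write_stack_tiff(p$argmax_z,
                         file.path(proj_dir, sprintf("argmaxz_t%03d.tif",
                                                     p$time_index)), 16)
      }
    }
    list(summary = summ, cohort = coh)
  })
  say("pipeline done in %.1f s", proc.time()[["elapsed"]] - t_start)

  structure(list(tracks = tracks3d, summary = result$summary,
                 cohort = result$cohort, transforms = transforms,
                 illumination = illum, config = config, out_dir = out_dir),
            class = "tracker3d_run")
}

config_manifest <- function(config) {
  p <- unclass(config)
  p$seeds <- if (!is.null(p$seeds)) "supplied" else NULL
  p$manual_tracks <- if (!is.null(p$manual_tracks)) "supplied" else NULL
  p$max_area <- if (is.finite(p$max_area)) p$max_area else "Inf"
  p
}

# evenly sample up to n planes across frames and slices
sample_planes <- function(tl, n) {
  nz <- tl$dim[3]
  total <- tl$n_frames * nz
  n <- max(2L, min(n, total))
  pick <- unique(round(seq(1, total, length.out = n)))
  planes <- list()
  by_frame <- split(pick, (pick - 1L) %/% nz)
  for (fr in names(by_frame)) {
    s <- get_stack(tl, as.integer(fr))
    for (p in by_frame[[fr]]) {
      z <- (p - 1L) %% nz + 1L
      planes[[length(planes) + 1L]] <- s[, , z]
    }
  }
  planes
}

# wrap a lazy timelapse so get_stack() returns corrected /transformed stacks
corrected_timelapse <- function(tl, prep) {
  out <- tl
  out$stacks <- NULL
  out$prep <- prep
  class(out) <- c("timelapse_view", class(tl))
  out
}

transformed_timelapse <- function(tl, transforms, prep) {
  out <- tl
  out$stacks <- NULL
  out$prep <- function(t) apply_transform(prep(t), transforms[[t + 1L]])
  class(out) <- c("timelapse_view", class(tl))
  out
}

#' @export
get_stack.timelapse_view <- function(tl, time_index) tl$prep(time_index)

#' @export
print.tracker3d_run <- function(x, ...) {
  cat(sprintf("tracker3d run: %d track(s), outputs in %s\n",
              nrow(x$summary), x$out_dir))
  invisible(x)
}

#' @export
summary.tracker3d_run <- function(object, ...) {
  cat(sprintf("tracker3d run (%s mode, %s metrics)\n", object$config$mode,
              object$config$metrics_mode))
  cat(sprintf("  %d track(s), %d point(s)\n", nrow(object$summary),
              nrow(object$tracks)))
  if (nrow(object$summary) > 0) {
    cat(sprintf("  mean path length     %8.1f um\n",
                mean(object$summary$path_length_um, na.rm = TRUE)))
    cat(sprintf("  mean net displacement%8.1f um\n",
                mean(object$summary$net_disp_um, na.rm = TRUE)))
    cat(sprintf("  mean speed           %8.3f um/min\n",
                mean(object$summary$mean_speed_um_min, na.rm = TRUE)))
  }
  invisible(object$summary)
}

#' Per-cell motility curves with the cohort average
#'
#' Draws the per-track distance-from-origin (or cumulative path length)
#' curves in colour with the per-time cohort average as a black dotted
#' line, the standard way per-cell motility is presented.
#'
#' @param x A `tracker3d_run`.
#' @param which `"dist_origin"` or `"cum_path"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tracker3d_run <- function(x, which = c("dist_origin", "cum_path"), ...) {
  which <- match.arg(which)
  if (is.null(x$cohort)) stop("no tracks to plot")
  m <- x$cohort[[which]]
  avg <- x$cohort$average
  tmin <- avg$t_min
  ylab <- if (which == "dist_origin") "distance from origin (um)"
          else "path length (um)"
  graphics::matplot(tmin, t(m), type = "l", lty = 1, xlab = "time (min)",
                    ylab = ylab, ...)
  avg_col <- if (which == "dist_origin") avg$mean_dist_origin_um
             else avg$mean_cum_path_um
  graphics::lines(tmin, avg_col, lty = 3, lwd = 2, col = "black")
  invisible(x)
}
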
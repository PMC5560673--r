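make_tracks3d <- function() {
  set.seed(71)
  rbind(
    cbind(random_track(10, id = 1), z_ok = TRUE, z_confidence = 2,
          z_refined = FALSE),
    cbind(random_track(7, id = 2), z_ok = TRUE, z_confidence = 2,
          z_refined = FALSE))
}

test_that("export writes consistent CSV, XLSX and JSON artifacts", {
  tr <- make_tracks3d()
  dir <- withr::local_tempdir()
  paths <- export_tracks(tr, voxel_geometry(), dir, seed = 123,
                         params = list(gate_px = 30))
  expect_true(all(file.exists(paths)))
  got <- read.csv(file.path(dir, "tracks3d.csv"))
  expect_equal(nrow(got), nrow(tr))
  summ <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(names(summ), c("id", "path_length_um", "net_disp_um",
                              "mean_speed_um_min", "straightness"))
  expect_equal(summ$path_length_um,
               c(path_length(tr[tr$id == 1, ], voxel_geometry()),
                 path_length(tr[tr$id == 2, ], voxel_geometry())))
  long <- read.csv(file.path(dir, "metrics.csv"))
  expect_equal(names(long), c("id", "t_min", "dist_origin_um", "cum_path_um",
                              "inst_speed_um_min"))
  expect_equal(sum(long$id == 1), 10)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 123)
  expect_equal(man$n_tracks, 2)
  expect_equal(man$params$gate_px, 30)
  expect_equal(man$geometry$dx_um, 0.589)
})

test_that("the XLSX workbook round-trips through an independent reader", {
  skip_if_not_installed("readxl")
  tr <- make_tracks3d()
  dir <- withr::local_tempdir()
  export_tracks(tr, voxel_geometry(), dir)
  xl <- file.path(dir, "metrics.xlsx")
  expect_setequal(readxl::excel_sheets(xl), c("tracks", "metrics", "summary"))
  summ_csv <- read.csv(file.path(dir, "summary.csv"))
  summ_xl <- as.data.frame(readxl::read_excel(xl, sheet = "summary"))
  expect_equal(summ_xl$path_length_um, summ_csv$path_length_um,
               tolerance = 1e-12)
  expect_equal(names(summ_xl), names(summ_csv))
})

test_that("re-export is byte-identical and empty input exports headers", {
  tr <- make_tracks3d()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_tracks(tr, voxel_geometry(), d1, seed = 5)
  export_tracks(tr, voxel_geometry(), d2, seed = 5)
  for (f in c("tracks3d.csv", "metrics.csv", "summary.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  d0 <- withr::local_tempdir()
  export_tracks(tr[0, ], voxel_geometry(), d0)
  summ <- read.csv(file.path(d0, "summary.csv"))
  expect_equal(nrow(summ), 0)
  expect_equal(names(summ), c("id", "path_length_um", "net_disp_um",
                              "mean_speed_um_min", "straightness"))
})
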
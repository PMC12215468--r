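# Fixture access, colorization, I/O roundtrips and study orchestration.

test_that("fixture loads with the published design counts and spot values", {
  fx <- load_fixture_tables()
  expect_identical(nrow(fx), 96L)
  expect_identical(sum(fx$dataset == "patient"), 16L)
  expect_identical(sum(fx$dataset == "cadaver_single"), 40L)
  expect_identical(sum(fx$dataset == "cadaver_bilateral"), 40L)
  expect_equal(fx$mean_mm[fx$dataset == "patient" & fx$subject == 1 &
                            fx$bone == "fibula"], -0.35)
  expect_equal(fx$mean_mm[fx$dataset == "cadaver_single" & fx$subject == 9 &
                            fx$bone == "patella"], -0.20)
  g1 <- fixture_group_means(fx, "patient+single")
  g2 <- fixture_group_means(fx, "patient+bilateral")
  expect_length(g1, 56L)
  expect_length(g2, 56L)
  expect_identical(fmt_mm(mean(g1)), "-0.06")
  expect_identical(fmt_mm(mean(g2)), "-0.07")
  # corrupting any value trips the checksum
  bad <- fx
  bad$mean_mm[10] <- bad$mean_mm[10] + 0.01
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_fixture_tables(path), "corrupt fixture")
})

test_that("color map is odd-symmetric, clamped and light at zero", {
  r <- 1.0
  d <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  rgb <- colorize_distances(d, range = r)
  expect_identical(rgb[4, 1], rgb[4, 3])          # midpoint is neutral
  expect_true(all(rgb[4, ] >= 240))               # and light
  # channel mirror between +d and -d
  expect_identical(rgb[5, ], rgb[3, c(3, 2, 1)])
  expect_identical(rgb[6, ], rgb[2, c(3, 2, 1)])
  # clamping beyond the range
  expect_identical(rgb[7, ], rgb[6, ])
  expect_identical(rgb[1, ], rgb[2, ])
  # intensity grows with |d| on the red side
  reds <- colorize_distances(c(0.2, 0.5, 0.9), 1)
  expect_true(all(diff(reds[, 1] - reds[, 3]) > 0))
  expect_error(colorize_distances(0.5, range = 0), "range")
})

test_that("mask I/O roundtrips through NIfTI and MetaImage", {
  g <- sphere_grid(5, c(0.3, 0.3, 0.6), pad = 1)
  nii <- tempfile(fileext = ".nii.gz")
  mha <- tempfile(fileext = ".mha")
  on.exit(unlink(c(nii, mha)))
  write_nifti_mask(g, nii)
  back <- read_nifti_mask(nii)
  expect_identical(back$mask, g$mask)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(back$origin, g$origin, tolerance = 1e-4)
  write_mha_mask(g, mha)
  back2 <- read_mha_mask(mha)
  expect_identical(back2$mask, g$mask)
  expect_equal(back2$spacing, g$spacing, tolerance = 1e-12)
  expect_equal(back2$origin, g$origin, tolerance = 1e-12)
})

test_that("PLY and STL writers roundtrip geometry, scalars and colors", {
  m <- bone_mesh("patella", scale = 0.4, spacing = 0.8)
  sc <- seq_len(nrow(m$vertices)) / nrow(m$vertices) - 0.5
  rgb <- colorize_distances(sc, 1)
  ply <- tempfile(fileext = ".ply")
  stl <- tempfile(fileext = ".stl")
  on.exit(unlink(c(ply, stl)))
  write_ply(m, ply, scalar = sc, rgb = rgb)
  back <- read_ply(ply)
  expect_equal(back$vertices, unname(m$vertices), tolerance = 1e-6)
  expect_identical(back$faces, m$faces)
  expect_equal(back$scalar, sc, tolerance = 1e-6)
  expect_identical(attr(back, "rgb"), rgb)
  write_stl(m, stl)
  info <- file.info(stl)
  expect_identical(as.integer(info$size), as.integer(84 + 50 * nrow(m$faces)))
})

test_that("fixture-only study reproduces the published statistics layer", {
  rep0 <- run_study(study_config(fixture_only = TRUE))
  tost <- rep0$stats$tost
  expect_identical(nrow(tost), 2L)
  expect_true(all(tost$equivalent))
  expect_true(all(tost$n == 56L))
  expect_identical(fmt_mm(tost$mean), c("-0.06", "-0.07"))
  norm <- rep0$stats$normality
  expect_true(all(norm$normal))
  expect_identical(nrow(rep0$stats$summary), 12L)
})

test_that("phantom study runs end to end, deterministically, surviving failures", {
  specs <- knee_study_specs(n_subjects = 2, bones = c("patella", "fibula"),
                            delta = 0, sigma_noise = 0.05, scale = 0.5, seed = 9)
  cfg <- study_config(phantom = specs, seed = 9)
  rep1 <- run_study(cfg)
  expect_length(rep1$pairs, 4L)
  expect_length(rep1$failures, 0L)
  expect_true(all(abs(rep1$means$mean_mm) < 0.1))
  dir1 <- tempfile()
  dir2 <- tempfile()
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  write_report(rep1, dir1)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_identical(sum(grepl("\\.ply$", list.files(dir1))), 4L)
  rep2 <- run_study(cfg)
  write_report(rep2, dir2)
  for (f in c("per_scan_means.csv", "summary_table.csv", "tost_table.csv"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  # a deliberately empty mask fails its pair only
  bad <- specs
  bad[[2]] <- phantom_spec("patella", size = 1e-3, scale = 0.5, seed = 10)
  cfg_bad <- study_config(phantom = bad, seed = 9)
  expect_message(rep3 <- run_study(cfg_bad), "failed")
  expect_length(rep3$failures, 1L)
  expect_length(rep3$pairs, 3L)
})

test_that("YAML configuration drives the phantom study", {
  yml <- tempfile(fileext = ".yaml")
  on.exit(unlink(yml))
  writeLines(c("phantom:", "  subjects: 1", "  bones: [patella]",
               "  delta: 0.1", "  noise: 0.0", "  scale: 0.5",
               "margin: 0.2", "seed: 3"), yml)
  cfg <- read_study_config(yml)
  expect_length(cfg$phantom, 1L)
  expect_identical(cfg$phantom[[1]]$bone, "patella")
  expect_equal(cfg$phantom[[1]]$delta, 0.1)
  expect_equal(cfg$margin, 0.2)
})
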
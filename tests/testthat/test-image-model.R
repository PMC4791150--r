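test_that("16-bit TIFF round trip is bit-identical, extremes preserved", {
  set.seed(21)
  m <- matrix(sample(0:65535, 64 * 48, replace = TRUE), 64, 48)
  m[1, 1] <- 65535; m[2, 2] <- 0
  f <- tempfile(fileext = ".tif")
  write_linear_image(m, f)
  back <- load_linear_image(f, channel_name = "vG")
  expect_identical(unclass(back)[seq_along(m)], as.integer(m))
  expect_equal(max(back), 65535)
  expect_equal(attr(back, "channel_name"), "vG")
})

test_that("8-bit input is rejected naming the bit depth", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), f, bits.per.sample = 8L)
  expect_error(load_linear_image(f), "bit depth 8")
  fp <- tempfile(fileext = ".png")
  png::writePNG(matrix((0:15) / 255, 4, 4), fp)
  expect_error(load_linear_image(fp), "bit depth 8")
  expect_error(load_linear_image(tempfile(fileext = ".nef")), "cannot read")
  f2 <- tempfile(fileext = ".nef"); writeLines("x", f2)
  expect_error(load_linear_image(f2), "RAW file")
})

test_that("region rasterisation matches a brute-force point-in-polygon oracle", {
  dims <- c(20, 25)
  # overlapping pooled squares: union area counted once
  r1 <- rect_region("p", 2, 3, 10, 8, pool = "pooled")
  r2 <- rect_region("p2", 8, 6, 10, 8, pool = "pooled")
  # brute-force: pixel centres inside either axis-aligned rectangle
  oracle <- 0L
  for (r in seq_len(dims[1])) for (c in seq_len(dims[2])) {
    x <- c - 0.5; y <- r - 0.5
    in1 <- x > 2 && x < 12 && y > 3 && y < 11
    in2 <- x > 8 && x < 18 && y > 6 && y < 14
    if (in1 || in2) oracle <- oracle + 1L
  }
  stk <- mspec_stack(list(g = matrix(7, dims[1], dims[2])))
  meas <- measure_regions(stk, list(r1, r2))
  expect_equal(unique(meas$region), "pooled")
  expect_equal(meas$n, oracle)
  expect_equal(meas$mean, 7)
  expect_equal(meas$sd, 0)
})

test_that("regions fully outside the image error; degenerate regions rejected", {
  stk <- mspec_stack(list(g = matrix(1, 10, 10)))
  far <- rect_region("far", 100, 100, 5, 5)
  expect_error(measure_regions(stk, list(far)), "outside|no pixel centres")
  expect_error(region("", matrix(0, 3, 2)), "non-empty")
  expect_error(region("x", matrix(0, 2, 2)), ">= 3 vertices")
})

test_that("scale bars give pixels-per-mm from the drawn line", {
  p <- mspec_project(list(vG = "g.tif"))
  p <- set_scale_bar(p, c(0, 0), c(0, 100), 10)
  expect_equal(project_px_per_mm(p), 10)
  p <- set_scale_bar(p, c(0, 0), c(30, 40), 5)
  expect_equal(project_px_per_mm(p), 10)
  expect_error(set_scale_bar(p, c(1, 1), c(1, 1), 5), "zero-length")
  expect_error(set_scale_bar(p, c(0, 0), c(1, 0), 0), "> 0")
})

make_disk_project <- function(dir, seed = 1, misalign = NULL) {
  scene <- synthetic_scene(64, 64, list(
    list(label = "std_99", rect = c(4, 4, 16, 16), stated_percent = 99),
    list(label = "std_20", rect = c(28, 4, 16, 16), stated_percent = 20),
    list(label = "bright", rect = c(4, 28, 24, 24),
         reflectance = flat_reflectance(150))),
    misalignment = misalign)
  # exposure 0.5 keeps the 150% specular patch below 16-bit saturation
  write_synthetic_project(scene, quiet_camera(), dir, exposure = 0.5,
                          seed = seed)
}

test_that("projects round trip through JSON and rebuild identical stacks", {
  dir <- withr::local_tempdir()
  pp <- make_disk_project(dir)
  proj <- read_project(pp)
  stk1 <- build_stack(proj, base_dir = dir)
  # serialize -> parse -> rebuild must be pixelwise identical
  pp2 <- file.path(dir, "copy.mspec.json")
  write_project(proj, pp2)
  stk2 <- build_stack(read_project(pp2), base_dir = dir)
  expect_identical(stk1$channels, stk2$channels)
  expect_true(stk1$normalized)
})

test_that("normalised stacks preserve >100% reflectance without clipping", {
  dir <- withr::local_tempdir()
  pp <- make_disk_project(dir)
  stk <- build_stack(read_project(pp), base_dir = dir)
  m <- measure_regions(stk, list(rect_region("b", 6, 30, 20, 20)))
  expect_true(all(abs(m$mean - 1.5) < 0.01))
  # standard region mean is the stated reflectance by construction
  ms <- measure_regions(stk, list(rect_region("s", 6, 6, 12, 12)))
  expect_true(all(abs(ms$mean - 0.99) < 0.005))
})

test_that("stored alignment offsets shift channels as an independent oracle predicts", {
  dir <- withr::local_tempdir()
  pp <- make_disk_project(dir, seed = 5)
  proj <- read_project(pp)
  raw <- build_stack(proj, base_dir = dir, normalize = FALSE)
  proj$alignment <- list(vR = list(dx = 7, dy = -13, scale = 1))
  shifted <- build_stack(proj, base_dir = dir, normalize = FALSE)
  src <- raw$channels$vR
  expected <- matrix(NA_real_, 64, 64)
  for (r in 1:64) for (c in 1:64) {
    sr <- r + 13; sc <- c - 7
    if (sr >= 1 && sr <= 64 && sc >= 1 && sc <= 64)
      expected[r, c] <- src[sr, sc]
  }
  expect_equal(shifted$channels$vR, expected)
  expect_identical(shifted$channels$vG, raw$channels$vG)
})

test_that("missing sources and incomplete channel maps are reported", {
  proj <- mspec_project(list(vG = "does_not_exist.tif"))
  expect_error(build_stack(proj, base_dir = tempdir()), "missing source")
})
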
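test_that("single-standard model reproduces the proportional rule exactly", {
  st <- standard_measurement(99, c(vG = 60000))
  m <- fit_normalization(st)
  expect_equal(m$method, "single")
  expect_identical(unname(m$intercept), 0)
  # pixel equal to the standard mean maps to 99%; on the 16-bit export
  # scale that is 0.99 * 65535 = 64879.65
  expect_equal(predict_reflectance(m, 60000, "vG"), 0.99)
  expect_equal(predict_reflectance(m, 60000, "vG") * 65535, 64879.65)
  # proportionality: half the standard pixel value is half the reflectance
  st2 <- fit_normalization(standard_measurement(20, c(vG = 48000)))
  expect_equal(predict_reflectance(st2, 24000, "vG"), 0.10)
})

test_that("two standards give the closed-form two-point line", {
  m <- fit_normalization(list(
    standard_measurement(80, c(vG = 50000)),
    standard_measurement(20, c(vG = 14000))))
  # independent oracle: slope/intercept of the line through two points
  slope <- (0.80 - 0.20) / (50000 - 14000)
  intercept <- 0.20 - slope * 14000
  expect_equal(unname(m$slope), slope)
  expect_equal(unname(m$intercept), intercept)
  expect_equal(predict_reflectance(m, 32000, "vG"),
               intercept + slope * 32000)
  # with exact standards the fitted line passes through every point
  expect_equal(predict_reflectance(m, 50000, "vG"), 0.80)
  expect_equal(predict_reflectance(m, 14000, "vG"), 0.20)
})

test_that("noise-free multi-standard fits pass through all standards", {
  set.seed(31)
  slope0 <- 1 / 60000; int0 <- 0.013
  G <- c(1000, 9000, 24000, 43000, 59000)
  S <- (int0 + slope0 * G) * 100
  stds <- lapply(seq_along(G), function(i)
    standard_measurement(S[i], c(vR = G[i], vB = G[i] * 0.8)))
  m <- fit_normalization(stds)
  for (i in seq_along(G))
    expect_equal(predict_reflectance(m, G[i], "vR"), S[i] / 100,
                 tolerance = 1e-9)
  expect_equal(unname(m$r2), c(1, 1), tolerance = 1e-12)
})

test_that("poor linearisation with >=3 standards warns but returns a model", {
  stds <- list(standard_measurement(5, c(vG = 20000)),
               standard_measurement(50, c(vG = 30000)),
               standard_measurement(99, c(vG = 62000)))
  expect_warning_code(m <- fit_normalization(stds),
                      "multispec_poor_linearisation")
  expect_s3_class(m, "norm_model")
  expect_true(m$r2[["vG"]] < 0.98)
})

test_that("degenerate and non-monotonic standards are flagged", {
  expect_error(fit_normalization(list(
    standard_measurement(20, c(vG = 30000)),
    standard_measurement(80, c(vG = 30000)))), "identical mean pixel")
  # a locally non-increasing standard sequence warns but still fits when
  # the overall trend is positive
  expect_warning_code(
    m <- fit_normalization(list(
      standard_measurement(20, c(vG = 30000)),
      standard_measurement(50, c(vG = 29000)),
      standard_measurement(80, c(vG = 60000)))),
    "multispec_nonmonotonic_standards")
  expect_true(m$slope[["vG"]] > 0)
  # a fully inverted response cannot give a positive slope
  expect_error(suppressWarnings(fit_normalization(list(
    standard_measurement(20, c(vG = 40000)),
    standard_measurement(80, c(vG = 30000))))), "non-positive slope")
})

test_that("normalisation is affine, order preserving and never clips", {
  m <- fit_normalization(list(
    standard_measurement(80, c(vG = 50000)),
    standard_measurement(20, c(vG = 14000))))
  px <- matrix(c(0, 500, 64000, 65535), 2, 2)
  stk <- apply_normalization(mspec_stack(list(vG = px)), m)
  expect_true(stk$normalized)
  expect_true(stk$channels$vG[1, 1] < 0)        # intercept preserved
  expect_true(stk$channels$vG[2, 2] > 1)        # >100% preserved
  expect_equal(order(stk$channels$vG), order(px))
  expect_error(apply_normalization(mspec_stack(list(uB = px)), m),
               "do not match")
})

test_that("dark-point estimation recovers a veiling-glare intercept", {
  glare <- 900
  scene <- synthetic_scene(96, 96, list(
    list(label = "std_80", rect = c(4, 4, 30, 30), stated_percent = 80),
    list(label = "black", rect = c(40, 40, 40, 40),
         reflectance = flat_reflectance(0.5))),
    background = flat_reflectance(10))
  cam <- synthetic_camera(noise_additive = 1, noise_proportional = 0.002,
                          glare_offset = glare)
  rend <- render_scene(scene, cam, seed = 9)
  px <- matrix(as.numeric(rend$images$vG), 96, 96)
  reg <- scene_patch_region(scene, "std_80")
  G <- mean(px[rasterize_region(reg, c(96, 96))])
  m <- estimate_dark_point(px, standard_measurement(80, c(vG = G)))
  # ideal line: pixel = k*R + glare  =>  intercept = -glare * slope
  expect_equal(unname(m$intercept), -glare * unname(m$slope),
               tolerance = 0.12)
  expect_equal(m$method, "histogram-dark-point")

  # glare-free render: intercept ~ 0 relative to the full scale
  cam0 <- synthetic_camera(noise_additive = 1, noise_proportional = 0.002)
  px0 <- matrix(as.numeric(render_scene(scene, cam0, seed = 9)$images$vG),
                96, 96)
  G0 <- mean(px0[rasterize_region(reg, c(96, 96))])
  m0 <- estimate_dark_point(px0, standard_measurement(80, c(vG = G0)))
  expect_lt(abs(unname(m0$intercept)), 0.004)

  expect_error(estimate_dark_point(matrix(5000, 20, 20),
                                   standard_measurement(80, c(vG = 5000))),
               "dark anchor")
  expect_error(estimate_dark_point(rep(1, 50),
                                   standard_measurement(80, c(vG = 100))),
               ">= 200 pixels")
})

test_that("normalisation commutes with exposure", {
  dir <- withr::local_tempdir()
  scene <- standard_scene()
  cam <- synthetic_camera()   # default 1% proportional noise
  p1 <- write_synthetic_project(scene, cam, file.path(dir, "a"),
                                exposure = 1, seed = 3)
  p2 <- write_synthetic_project(scene, cam, file.path(dir, "b"),
                                exposure = 0.4, seed = 4)
  s1 <- build_stack(read_project(p1), base_dir = dirname(p1))
  s2 <- build_stack(read_project(p2), base_dir = dirname(p2))
  # same scene normalised against its own in-image standards agrees
  # pixelwise within the noise floor
  d <- abs(s1$channels$vG - s2$channels$vG)
  expect_lt(stats::median(d), 0.02)
})

test_that("the sequential method uses a separate standard photograph", {
  dir <- withr::local_tempdir()
  scene <- standard_scene()
  cam <- quiet_camera()
  pt <- write_synthetic_project(scene, cam, file.path(dir, "t"),
                                name = "target", exposure = 0.5, seed = 1)
  ps <- write_synthetic_project(scene, cam, file.path(dir, "s"),
                                name = "standard", exposure = 0.5, seed = 1)
  target <- read_project(pt); standard <- read_project(ps)
  res <- sequential_normalize(target, standard,
                              target_dir = dirname(pt),
                              standard_dir = dirname(ps))
  expect_equal(res$model$method, "sequential")
  # identical photographs: identical to in-image normalisation
  inimg <- build_stack(target, base_dir = dirname(pt))
  expect_equal(res$stack$channels, inimg$channels, tolerance = 1e-12)

  # a 2x-brighter standard photograph biases reflectances by 0.5:
  # the documented failure mode when lighting changes between frames
  ps2 <- write_synthetic_project(scene, cam, file.path(dir, "s2"),
                                 name = "bright", exposure = 1, seed = 1)
  res2 <- sequential_normalize(target, read_project(ps2),
                               target_dir = dirname(pt),
                               standard_dir = dirname(ps2))
  m99 <- measure_regions(res2$stack,
                         list(scene_patch_region(scene, "std_99")))
  expect_equal(m99$mean, rep(0.99 * 0.5, nrow(m99)), tolerance = 0.01)

  bad <- standard
  names(bad$sources)[1] <- "zz"
  expect_error(sequential_normalize(target, bad, dirname(pt), dirname(ps)),
               "channel sets differ")
})
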
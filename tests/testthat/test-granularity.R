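test_that("constant images carry no band energy and undefined stats", {
  sp <- granularity_spectrum(matrix(3.2, 64, 64), band_sizes = c(2, 4, 8, 16))
  expect_equal(sp$energy, rep(0, 4), tolerance = 1e-12)
  expect_warning_code(ps <- pattern_stats(sp), "multispec_zero_pattern")
  expect_true(is.na(ps$dominant_size_px))
})

test_that("a sine grating concentrates energy in its period's band", {
  n <- 128; a <- 3
  img <- matrix(rep(a * sin(2 * pi * (1:n) / 16), each = n), n, n)
  sp <- granularity_spectrum(img)
  dom <- sp$size_px[which.max(sp$energy)]
  expect_equal(dom, 16)
  # space-domain oracle: the grating passes its band untouched, so the
  # band energy is the plain standard deviation of the image, ~ a/sqrt(2)
  expect_equal(max(sp$energy), stats::sd(img), tolerance = 1e-9)
  expect_equal(max(sp$energy), a / sqrt(2), tolerance = 1e-3)
  expect_lt(sum(sp$energy) - max(sp$energy), 1e-9)
  st <- pattern_stats(sp)
  expect_equal(st$dominant_size_px, 16)
  expect_equal(st$proportion_dominant, 1, tolerance = 1e-9)
})

test_that("band energies equal the explicit frequency-mask oracle", {
  set.seed(14)
  img <- matrix(rnorm(128 * 128), 128, 128)
  bands <- 2^(1:6)
  sp <- granularity_spectrum(img, band_sizes = bands)
  expect_equal(sp$energy, oracle_band_energies(img, bands),
               tolerance = 1e-6)
})

test_that("energies of well-separated gratings are additive per band", {
  n <- 128
  g1 <- matrix(rep(2 * sin(2 * pi * (1:n) / 8), each = n), n, n)
  g2 <- matrix(rep(5 * sin(2 * pi * (1:n) / 64), each = n), n, n)
  bands <- 2^(1:7)
  solo1 <- granularity_spectrum(g1, band_sizes = bands)$energy
  solo2 <- granularity_spectrum(g2, band_sizes = bands)$energy
  both <- granularity_spectrum(g1 + g2, band_sizes = bands)$energy
  i8 <- which(bands == 8); i64 <- which(bands == 64)
  expect_equal(both[i8], solo1[i8], tolerance = 0.05 * solo1[i8])
  expect_equal(both[i64], solo2[i64], tolerance = 0.05 * solo2[i64])
})

test_that("pattern stats and differences follow their definitions", {
  mk <- function(e) structure(data.frame(size_px = 2^seq_along(e),
                                         energy = e,
                                         reliable = TRUE),
                              class = c("band_energy_spectrum", "data.frame"))
  one <- mk(c(0, 4, 0))
  st <- pattern_stats(one)
  expect_equal(st$proportion_dominant, 1)
  expect_equal(st$dominant_size_px, 4)
  unif <- mk(rep(2, 5))
  expect_equal(pattern_stats(unif)$proportion_dominant, 1 / 5)
  # ties break toward the smaller band size
  expect_equal(pattern_stats(mk(c(3, 3, 1)))$dominant_size_px, 2)

  expect_equal(pattern_difference(one, one), 0)
  a <- mk(c(1, 2, 3)); b <- mk(c(2, 2, 1))
  expect_equal(pattern_difference(a, b), 3)
  expect_equal(pattern_difference(b, a), 3)
  set.seed(5)
  x <- mk(runif(4)); y <- mk(runif(4))
  expect_equal(pattern_difference(x, y), pattern_difference(y, x))
  expect_error(pattern_difference(mk(1:3), mk(1:4)), "band sets differ")
})

test_that("regions restrict measurement; small regions are rejected", {
  n <- 96
  img <- matrix(rep(sin(2 * pi * (1:n) / 8), each = n), n, n)
  reg <- rect_region("r", 8, 8, 48, 48)
  sp <- granularity_spectrum(img, region = reg, band_sizes = 2^(1:5))
  expect_equal(sp$size_px[which.max(sp$energy)], 8)
  tiny <- rect_region("tiny", 2, 2, 4, 4)
  expect_error(granularity_spectrum(img, region = tiny), ">= 64")
  # bands beyond the region extent are flagged, not dropped
  expect_warning_code(
    spw <- granularity_spectrum(img, region = reg, band_sizes = c(4, 8, 64)),
    "multispec_band_unreliable")
  expect_equal(spw$reliable, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(spw), 3)
})

test_that("uniform rescaling preserves pattern structure across scales", {
  n <- 128
  per <- function(p, n) matrix(rep(sin(2 * pi * (1:n) / p), each = n), n, n)
  stk <- mspec_stack(list(g = per(50, n)), normalized = TRUE, px_per_mm = 10)
  expect_identical(rescale_to_uniform(stk, 10)$channels$g, stk$channels$g)
  up <- rescale_to_uniform(stk, 20)
  expect_equal(dim(up), c(256, 256))
  expect_equal(up$px_per_mm, 20)
  # a 2x upsample doubles the grating's pixel period
  spu <- granularity_spectrum(up$channels$g, band_sizes = c(25, 50, 100, 200))
  expect_equal(spu$size_px[which.max(spu$energy)], 100)

  # the same physical pattern captured at two scales agrees after
  # rescaling to a common px/mm (energy-bearing bands within 10%)
  fine <- mspec_stack(list(g = per(20, n)), normalized = TRUE, px_per_mm = 20)
  coarse <- mspec_stack(list(g = per(10, 64)), normalized = TRUE, px_per_mm = 10)
  bands <- c(5, 10, 20, 40)
  e1 <- granularity_spectrum(rescale_to_uniform(fine, 10)$channels$g,
                             band_sizes = bands, px_per_mm = 10)
  e2 <- granularity_spectrum(coarse$channels$g, band_sizes = bands,
                             px_per_mm = 10)
  i <- which.max(e2$energy)
  expect_equal(e1$size_px[which.max(e1$energy)], e2$size_px[i])
  expect_lt(abs(e1$energy[i] - e2$energy[i]) / e2$energy[i], 0.10)
  expect_lt(pattern_difference(e1, e2), 0.1 * sum(e2$energy))

  expect_error(rescale_to_uniform(mspec_stack(list(g = per(10, 32))), 5),
               "no recorded scale")
})
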
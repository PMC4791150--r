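test_that("term expansion produces the documented polynomial structure", {
  t2 <- polynomial_terms(c("R", "G", "B"), 2)
  expect_equal(unname(expand_terms(c(R = 2, G = 3, B = 4), t2)),
               c(2, 3, 4, 6, 8, 12))
  # any channel at zero annihilates every term containing it
  v <- expand_terms(c(R = 0, G = 3, B = 4), t2)
  expect_equal(unname(v[c("R", "R*G", "R*B")]), c(0, 0, 0))
  # level 1 is the identity on the channel vector
  t1 <- polynomial_terms(c("R", "G"), 1)
  expect_equal(unname(expand_terms(c(R = 5, G = 7), t1)), c(5, 7))
  # level 3 + squares matches the ten-term classic form
  t3 <- polynomial_terms(c("R", "G", "B"), 3, squares = TRUE)
  expect_equal(t3$labels, c("R", "G", "B", "R*G", "R*B", "G*B",
                            "R*G*B", "R^2", "G^2", "B^2"))
  expect_error(expand_terms(c(R = 1), t1), "missing channel G")
  expect_error(polynomial_terms(c("R", "R"), 1), "duplicate")
})

test_that("training tables pair normalised camera and receptor quanta", {
  cam <- quiet_camera()$bank
  rec <- avian_receptors()
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(15, seed = 2)
  tab <- build_training_table(cam, rec, ill, lib)
  expect_equal(dim(tab), c(15, length(cam) + length(rec)))
  expect_equal(attr(tab, "camera_channels"), cam$channel_names)

  # flat 50% grey: every normalised quantum is exactly 0.5
  grey <- reflectance_library(list(flat_reflectance(50)))
  tg <- build_training_table(cam, rec, ill, grey)
  expect_equal(unname(as.numeric(tg[1, ])), rep(0.5, ncol(tg)),
               tolerance = 1e-12)

  # hand-computed toy: 3-wavelength grid, catches summed by hand
  l1 <- toy_curve(c(1, 2, 1), "c1"); l2 <- toy_curve(c(0, 1, 2), "c2")
  r1 <- toy_curve(c(2, 1, 0), "r1")
  ill3 <- toy_curve(c(1, 1, 1), "I")
  q <- toy_curve(c(0.5, 0.25, 0.25), "q")
  tt <- build_training_table(sensitivity_bank(list(l1, l2)),
                             sensitivity_bank(list(r1)), ill3,
                             reflectance_library(list(q)))
  # raw catches: c1: .5+.5+.25=1.25, white 4 -> 0.3125
  expect_equal(tt$c1, 1.25 / 4)
  expect_equal(tt$c2, (0.25 + 0.5) / 3)
  expect_equal(tt$r1, (1 + 0.25) / 3)

  expect_error(build_training_table(sensitivity_bank(list(l1)),
                                    sensitivity_bank(list(r1, l2)), ill3,
                                    reflectance_library(list(q))),
               "equal to or greater")
})

test_that("least squares recovers identity and closed-form coefficients", {
  cam <- quiet_camera()$bank
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(60, seed = 5)
  tab <- build_training_table(cam, cam, ill, lib)
  m <- fit_cone_map(tab, polynomial_terms(cam$channel_names, 1))
  for (i in seq_along(cam$channel_names)) {
    co <- m$receptors[[i]]$coefficients
    expect_equal(unname(co[cam$channel_names[i]]), 1, tolerance = 1e-6)
    expect_equal(unname(sum(abs(co[-match(cam$channel_names[i],
                                          names(co))]))), 0,
                 tolerance = 1e-6)
    expect_equal(m$receptors[[i]]$r2, 1, tolerance = 1e-9)
  }

  # hand-checkable exact system: y = 2*A + 3*B, solved in closed form
  tab2 <- data.frame(A = c(1, 0, 2, 1), B = c(0, 1, 1, 2))
  tab2$y <- 2 * tab2$A + 3 * tab2$B
  attr(tab2, "camera_channels") <- c("A", "B")
  attr(tab2, "receptor_channels") <- "y"
  # oracle: direct solve of the normal equations
  X <- as.matrix(tab2[c("A", "B")])
  beta <- solve(t(X) %*% X, t(X) %*% tab2$y)
  m2 <- fit_cone_map(tab2, polynomial_terms(c("A", "B"), 1))
  expect_equal(unname(m2$receptors$y$coefficients), as.numeric(beta),
               tolerance = 1e-10)
  expect_equal(unname(m2$receptors$y$coefficients), c(2, 3),
               tolerance = 1e-10)
})

test_that("stepwise simplification prunes uninformative channels", {
  set.seed(8)
  cam <- quiet_camera()$bank
  rec <- avian_receptors()
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(120, seed = 9)
  tab <- build_training_table(cam, rec, ill, lib)
  # append a pure-noise (zero-mean) camera channel
  tab$junk <- rnorm(nrow(tab), 0, 0.3)
  attr(tab, "camera_channels") <- c(cam$channel_names, "junk")
  attr(tab, "receptor_channels") <- rec$channel_names
  terms <- polynomial_terms(c(cam$channel_names, "junk"), 1)
  mb <- fit_cone_map(tab, terms, simplification = "BIC")
  for (r in mb$receptors)
    expect_false("junk" %in% r$terms)
})

test_that("model hierarchy: R2 non-decreasing in interaction level, BIC <= AIC terms", {
  cam <- quiet_camera()$bank
  rec <- avian_receptors()
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(150, seed = 4)
  tab <- build_training_table(cam, rec, ill, lib)
  r2s <- sapply(1:3, function(lv)
    mean(cone_map_r2(fit_cone_map(tab,
                                  polynomial_terms(cam$channel_names, lv)))))
  expect_true(all(diff(r2s) >= -1e-12))

  # BIC removes at least as many terms as AIC on average (>= 20 fits)
  naic <- nbic <- 0
  for (s in 1:5) {
    libs <- generate_spectra_library(90, seed = 100 + s)
    tabs <- build_training_table(cam, rec, ill, libs)
    terms <- polynomial_terms(cam$channel_names, 2)
    ma <- fit_cone_map(tabs, terms, simplification = "AIC")
    mb <- fit_cone_map(tabs, terms, simplification = "BIC")
    naic <- naic + sum(sapply(ma$receptors, function(r) length(r$terms)))
    nbic <- nbic + sum(sapply(mb$receptors, function(r) length(r$terms)))
  }
  expect_lte(nbic, naic)
})

test_that("cone-catch images reproduce ground truth on rendered scenes", {
  cam <- quiet_camera()
  rec <- avian_receptors()
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(200, seed = 6)
  tab <- build_training_table(cam$bank, rec, ill, lib)
  model <- fit_cone_map(tab, polynomial_terms(cam$bank$channel_names, 2))

  # flat grey scene: every receptor channel ~= 0.5
  grey <- mspec_stack(lapply(
    stats::setNames(cam$bank$channel_names, cam$bank$channel_names),
    function(nm) matrix(0.5, 8, 8)), normalized = TRUE)
  cc <- apply_cone_map(grey, model)
  for (ch in cc$channels)
    expect_equal(as.numeric(ch), rep(0.5, 64), tolerance = 0.01)

  # identity model (receptors = camera channels) reproduces the input
  idm <- fit_cone_map(build_training_table(cam$bank, cam$bank, ill, lib),
                      polynomial_terms(cam$bank$channel_names, 1))
  back <- apply_cone_map(grey, idm)
  expect_equal(back$channels$vR, grey$channels$vR, tolerance = 1e-6)

  # unnormalised stacks are rejected
  raw <- mspec_stack(list(vR = matrix(1, 4, 4), vG = matrix(1, 4, 4),
                          vB = matrix(1, 4, 4), uB = matrix(1, 4, 4),
                          uR = matrix(1, 4, 4)), normalized = FALSE)
  expect_error(apply_cone_map(raw, model), "normalised")
})

test_that("cone-map models survive a JSON round trip", {
  cam <- quiet_camera()$bank
  ill <- daylight_illuminant()
  lib <- generate_spectra_library(80, seed = 3)
  tab <- build_training_table(cam, avian_receptors(), ill, lib)
  m <- fit_cone_map(tab, polynomial_terms(cam$channel_names, 2),
                    simplification = "BIC")
  f <- tempfile(fileext = ".json")
  write_cone_map(m, f)
  back <- read_cone_map(f)
  expect_equal(cone_map_r2(back), cone_map_r2(m))
  expect_equal(back$receptors$u$coefficients, m$receptors$u$coefficients)
  stk <- mspec_stack(lapply(stats::setNames(cam$channel_names,
                                            cam$channel_names),
                            function(nm) matrix(runif(16), 4, 4)),
                     normalized = TRUE)
  expect_equal(apply_cone_map(stk, back)$channels,
               apply_cone_map(stk, m)$channels)
})
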
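# Synthetic cameras, scenes and spectra.
#
# A physically consistent renderer stands in for real photographs: patch
# reflectances and camera sensitivities are spectral curves, pixel values
# are quantum catches times exposure and gain plus veiling glare, with
# signal-proportional Gaussian noise, quantised to 16 bits with
# saturation. Ground-truth reflectance and receptor-catch images are
# emitted alongside, so every pipeline stage can be validated end to end
# without camera hardware.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

gaussian_sensitivity <- function(center, width, name,
                                 wl_start = 300, wl_end = 700) {
  wl <- seq.int(wl_start, wl_end)
  spectral_curve(exp(-0.5 * ((wl - center) / width)^2), wl_start, wl_end,
                 name = name)
}

#' Broad daylight-like illuminant
#'
#' A smooth broadband illuminant resembling mid-day daylight: a 6500 K
#' Planck radiator over the requested range, normalised to peak 1. Real
#' measured illuminant spectra can be substituted via
#' [read_spectra_csv()].
#'
#' @param wl_start,wl_end range in nm.
#' @return A `spectral_curve` named `"daylight-6500K"`.
#' @export
daylight_illuminant <- function(wl_start = 300, wl_end = 700) {
  wl <- seq.int(wl_start, wl_end)
  c2 <- 1.4388e7   # nm K
  b <- wl^-5 / (exp(c2 / (wl * 6500)) - 1)
  spectral_curve(b / max(b), wl_start, wl_end, name = "daylight-6500K")
}

#' Synthetic five-channel visible + UV camera
#'
#' Smooth unimodal channel sensitivities following the filter-prefix
#' naming convention: visible-filter red/green/blue (`vR`, `vG`, `vB`)
#' and UV-filter blue and red (`uB`, `uR`). Rendered output is linear in
#' scene radiance before quantisation.
#'
#' @param channels subset of the default channel names to include.
#' @param noise_additive,noise_proportional Gaussian pixel noise
#'   `sd = noise_additive + noise_proportional * signal` (digital counts).
#' @param glare_offset veiling-glare offset added to every pixel (counts).
#' @param response_gamma power applied to the scaled linear response
#'   (1 = linear camera; other values deliberately break linearity for
#'   negative-control experiments).
#' @param target_dn digital count a 100% flat white maps to at exposure 1
#'   (exposure is auto-calibrated per channel, emulating a correctly
#'   exposed photograph).
#' @return An object of class `synthetic_camera` wrapping a
#'   [sensitivity_bank()].
#' @export
synthetic_camera <- function(channels = c("vR", "vG", "vB", "uB", "uR"),
                             noise_additive = 2, noise_proportional = 0.01,
                             glare_offset = 0, response_gamma = 1,
                             target_dn = 60000) {
  defs <- list(vR = c(600, 45), vG = c(535, 40), vB = c(460, 35),
               uB = c(370, 22), uR = c(345, 20))
  unknown <- setdiff(channels, names(defs))
  if (length(unknown))
    stop("synthetic_camera: unknown channel(s) ",
         paste(unknown, collapse = ", "))
  curves <- lapply(channels, function(nm)
    gaussian_sensitivity(defs[[nm]][1], defs[[nm]][2], nm))
  structure(list(bank = sensitivity_bank(curves, channels),
                 noise_additive = noise_additive,
                 noise_proportional = noise_proportional,
                 glare_offset = glare_offset,
                 response_gamma = response_gamma,
                 target_dn = target_dn, bit_depth = 16L),
            class = "synthetic_camera")
}

#' Avian-like tetrachromatic receptor set
#'
#' Four smooth single cone sensitivities (UV-sensitive, short-, medium-
#' and long-wave) loosely resembling a UVS bird retina; channel names
#' `u`, `s`, `m`, `l`.
#'
#' @return A [sensitivity_bank()].
#' @export
avian_receptors <- function() {
  sensitivity_bank(list(gaussian_sensitivity(372, 25, "u"),
                        gaussian_sensitivity(455, 30, "s"),
                        gaussian_sensitivity(540, 35, "m"),
                        gaussian_sensitivity(605, 40, "l")))
}

#' Generate a smooth synthetic reflectance library
#'
#' Natural reflectance spectra tend to be smooth; each synthetic spectrum
#' is a logistic transform of a random sum of broad Gaussian bumps over
#' the wavelength range, guaranteeing values in [0, 1]. This library is a
#' synthetic stand-in for measured natural-spectra databases; real CSV
#' libraries can be loaded with [read_spectra_csv()].
#'
#' @param n number of spectra.
#' @param seed RNG seed; identical seeds give identical libraries.
#' @param smoothness minimum Gaussian bump width in nm (larger =
#'   smoother); widths are drawn from `[smoothness, 3 * smoothness]`.
#' @param wl_start,wl_end range in nm.
#' @return A [reflectance_library()].
#' @export
generate_spectra_library <- function(n, seed = 1, smoothness = 40,
                                     wl_start = 300, wl_end = 700) {
  stopifnot(n >= 1)
  wl <- seq.int(wl_start, wl_end)
  with_seed(seed, {
    spectra <- lapply(seq_len(n), function(i) {
      k <- sample(2:5, 1)
      centers <- stats::runif(k, wl_start - 50, wl_end + 50)
      widths <- stats::runif(k, smoothness, 3 * smoothness)
      amps <- stats::rnorm(k, 0, 2)
      f <- stats::rnorm(1, 0, 1)
      for (j in seq_len(k))
        f <- f + amps[j] * exp(-0.5 * ((wl - centers[j]) / widths[j])^2)
      spectral_curve(stats::plogis(f), wl_start, wl_end,
                     name = sprintf("synthetic_%04d", i))
    })
    reflectance_library(spectra, source = "synthetic")
  })
}

#' Flat grey reflectance spectrum
#' @param percent reflectance in percent.
#' @param wl_start,wl_end range in nm.
#' @return A `spectral_curve`.
#' @export
flat_reflectance <- function(percent, wl_start = 300, wl_end = 700)
  spectral_curve(rep(percent / 100, wl_end - wl_start + 1L),
                 wl_start, wl_end, name = sprintf("flat_%g", percent))

#' Define a synthetic patch scene
#'
#' A canvas with rectangular patches of uniform spectral reflectance.
#' Patches with a `stated_percent` are grey standards (their reflectance
#' is flat at that level).
#'
#' @param width,height canvas size in pixels.
#' @param patches list of `list(label, rect = c(x, y, w, h),
#'   reflectance = spectral_curve)` or, for standards,
#'   `list(label, rect, stated_percent = ...)`.
#' @param illuminant a `spectral_curve` (default [daylight_illuminant()]).
#' @param background reflectance curve filling unpatched pixels (default
#'   flat 10% grey).
#' @param misalignment optional named list, channel ->
#'   `list(dx, dy, scale)` applied to that rendered channel (emulating
#'   camera knocks and refocus zoom between filter exposures).
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(width, height, patches,
                            illuminant = daylight_illuminant(),
                            background = flat_reflectance(10),
                            misalignment = NULL) {
  for (p in patches) {
    if (is.null(p$label) || is.null(p$rect))
      stop("synthetic_scene: each patch needs label and rect")
    if (is.null(p$reflectance) && is.null(p$stated_percent))
      stop("synthetic_scene: patch '", p$label,
           "' needs reflectance or stated_percent")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 patches = patches, illuminant = illuminant,
                 background = background, misalignment = misalignment),
            class = "synthetic_scene")
}

#' The eight-standard calibration scene
#'
#' A row of eight flat grey standard patches at the classic Spectralon
#' reflectance levels 2, 5, 10, 20, 40, 60, 80 and 99 percent.
#'
#' @param levels reflectance percentages.
#' @param patch_px patch side length in pixels.
#' @param gap_px gap between patches.
#' @param ... passed to [synthetic_scene()].
#' @return A `synthetic_scene`; standard patches are labelled
#'   `std_<level>`.
#' @export
standard_scene <- function(levels = c(2, 5, 10, 20, 40, 60, 80, 99),
                           patch_px = 24, gap_px = 8, ...) {
  patches <- lapply(seq_along(levels), function(i) {
    x <- gap_px + (i - 1) * (patch_px + gap_px)
    list(label = sprintf("std_%g", levels[i]),
         rect = c(x, gap_px, patch_px, patch_px),
         stated_percent = levels[i])
  })
  width <- gap_px + length(levels) * (patch_px + gap_px)
  synthetic_scene(width, patch_px + 2 * gap_px, patches, ...)
}

scene_patch_reflectance <- function(scene, p) {
  if (!is.null(p$reflectance)) p$reflectance
  else flat_reflectance(p$stated_percent, scene$illuminant$wl_start,
                        scene$illuminant$wl_end)
}

scene_id_map <- function(scene) {
  # patch index per pixel, 0 = background; later patches overwrite earlier
  m <- matrix(0L, scene$height, scene$width)
  for (i in seq_along(scene$patches)) {
    r <- scene$patches[[i]]$rect
    rows <- seq.int(max(1, floor(r[2]) + 1), min(scene$height, floor(r[2] + r[4])))
    cols <- seq.int(max(1, floor(r[1]) + 1), min(scene$width, floor(r[1] + r[3])))
    if (length(rows) && length(cols)) m[rows, cols] <- i
  }
  m
}

#' Region of interest over a scene patch
#'
#' Polygon inset by one pixel from the patch edge so rendered edge pixels
#' never leak into measurements.
#'
#' @param scene a `synthetic_scene`.
#' @param label a patch label.
#' @param pool optional pooling tag.
#' @return An [region()].
#' @export
scene_patch_region <- function(scene, label, pool = NULL) {
  for (p in scene$patches)
    if (p$label == label) {
      r <- p$rect
      return(rect_region(label, r[1] + 1, r[2] + 1, r[3] - 2, r[4] - 2,
                         pool = pool))
    }
  stop("scene_patch_region: no patch labelled '", label, "'")
}

#' Render a synthetic scene through a synthetic camera
#'
#' Per channel, each pixel's linear signal is the quantum catch of its
#' patch times exposure and channel gain, plus the veiling-glare offset,
#' with Gaussian noise (`sd = a + b * signal`) applied and the result
#' quantised to 16 bits with saturation at 65535. Channel gain is
#' auto-calibrated so a 100% white maps to the camera's `target_dn` at
#' exposure 1 (a correctly exposed photograph). Per-channel misalignment
#' stored on the scene is applied to the rendered image.
#'
#' @param scene a [synthetic_scene()].
#' @param camera a [synthetic_camera()].
#' @param exposure relative integration time (> 0).
#' @param seed RNG seed for the noise.
#' @param receptors optional [sensitivity_bank()]; when given, ground
#'   truth receptor-catch images are emitted.
#' @return List with `images` (named list of 16-bit integer matrices),
#'   `truth` (list: `reflectance` -- von-Kries-normalised camera quanta
#'   per channel, i.e. the ideal normalised stack; `receptors` -- ideal
#'   normalised receptor-catch images, when `receptors` given), and
#'   `scene`, `camera`, `exposure`.
#' @export
render_scene <- function(scene, camera, exposure = 1, seed = NULL,
                         receptors = NULL) {
  stopifnot(exposure > 0)
  idm <- scene_id_map(scene)
  illum <- scene$illuminant
  refls <- c(list(scene$background),
             lapply(scene$patches, scene_patch_reflectance, scene = scene))
  # per patch (incl. background at index 1) quanta per camera channel
  wr <- white_reference(camera$bank, illum)
  q <- vapply(refls, function(rf)
    bank_catches(camera$bank, rf, illum)$quanta,
    numeric(length(camera$bank)))   # channels x patches
  norm_q <- q / wr$quanta           # von-Kries normalised ground truth
  gains <- camera$target_dn / wr$quanta
  images <- list(); truth_refl <- list()
  for (ci in seq_along(camera$bank$channel_names)) {
    nm <- camera$bank$channel_names[ci]
    signal <- matrix(q[ci, idm + 1L] * exposure * gains[ci],
                     scene$height, scene$width)
    truth_refl[[nm]] <- matrix(norm_q[ci, idm + 1L],
                               scene$height, scene$width)
    if (camera$response_gamma != 1)
      signal <- 65535 * pmin(signal / 65535, 1)^camera$response_gamma
    signal <- signal + camera$glare_offset
    mis <- scene$misalignment[[nm]]
    if (!is.null(mis)) {
      signal <- transform_channel(signal, dx = mis$dx %||% 0,
                                  dy = mis$dy %||% 0,
                                  scale = mis$scale %||% 1)
      bg <- q[ci, 1L] * exposure * gains[ci] + camera$glare_offset
      signal[is.na(signal)] <- bg
    }
    noisy <- with_seed(if (is.null(seed)) NULL else seed + ci, {
      sd <- camera$noise_additive + camera$noise_proportional * signal
      signal + stats::rnorm(length(signal), 0, sd)
    })
    img <- matrix(pmin(pmax(round(noisy), 0), 65535), scene$height,
                  scene$width)
    storage.mode(img) <- "integer"
    images[[nm]] <- structure(img, channel_name = nm, source = "synthetic",
                              class = c("linear_image", "matrix", "array"))
  }
  truth <- list(reflectance = truth_refl)
  if (!is.null(receptors)) {
    rwr <- white_reference(receptors, illum)
    rq <- vapply(refls, function(rf)
      bank_catches(receptors, rf, illum)$quanta,
      numeric(length(receptors)))
    rq <- rq / rwr$quanta
    truth$receptors <- lapply(seq_along(receptors$channel_names), function(ri)
      matrix(rq[ri, idm + 1L], scene$height, scene$width))
    names(truth$receptors) <- receptors$channel_names
  }
  list(images = images, truth = truth, scene = scene, camera = camera,
       exposure = exposure)
}

#' Write a rendered scene to disk as a reloadable project
#'
#' Renders the scene, writes one 16-bit TIFF per channel plus a project
#' JSON whose standards are the scene's stated-reflectance patches and
#' whose regions are the remaining patches.
#'
#' @inheritParams render_scene
#' @param dir output directory (created if needed).
#' @param name project base name.
#' @return Path to the written project JSON, invisibly.
#' @export
write_synthetic_project <- function(scene, camera, dir, name = "scene",
                                    exposure = 1, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rend <- render_scene(scene, camera, exposure = exposure, seed = seed)
  sources <- list()
  for (nm in names(rend$images)) {
    fn <- sprintf("%s_%s.tif", name, nm)
    write_linear_image(rend$images[[nm]], file.path(dir, fn))
    sources[[nm]] <- list(path = fn, plane = 1L)
  }
  standards <- list(); regions <- list()
  for (p in scene$patches) {
    reg <- scene_patch_region(scene, p$label)
    if (!is.null(p$stated_percent))
      standards[[length(standards) + 1L]] <-
        list(reflectance_percent = p$stated_percent, region = reg)
    else regions[[length(regions) + 1L]] <- reg
  }
  proj <- mspec_project(sources, standards = standards, regions = regions)
  path <- file.path(dir, paste0(name, ".mspec.json"))
  write_project(proj, path)
  invisible(path)
}

#' Camera linearity validation experiment
#'
#' Renders the eight-standard scene at several exposures, measures each
#' standard's mean pixel value per channel, and regresses observed pixel
#' values on expected values. The expected value of a standard is its
#' stated reflectance multiplied by the pooled average standard pixel
#' response for that photograph and channel, which controls for intensity
#' differences between exposures while preserving the actual pixel scale,
#' so nonlinearity at specific pixel levels remains detectable. A linear
#' sensor yields R-squared near 1 in every channel.
#'
#' @param camera a [synthetic_camera()].
#' @param exposures at least 3 relative exposures.
#' @param seed RNG seed for rendering noise.
#' @param levels standard reflectance percentages.
#' @return Data frame with one row per channel: `channel`, `r2`, `n`
#'   (points used). Saturated standards are excluded with a warning.
#' @export
linearity_experiment <- function(camera, exposures = c(0.25, 0.5, 1),
                                 seed = 1,
                                 levels = c(2, 5, 10, 20, 40, 60, 80, 99)) {
  if (length(exposures) < 3)
    stop("linearity_experiment: need >= 3 exposures")
  scene <- standard_scene(levels = levels)
  chans <- camera$bank$channel_names
  obs <- list()
  for (ei in seq_along(exposures)) {
    rend <- render_scene(scene, camera, exposure = exposures[ei],
                         seed = seed + 1000 * ei)
    stk <- mspec_stack(lapply(rend$images, function(im)
      matrix(as.numeric(im), nrow(im), ncol(im))))
    regs <- lapply(levels, function(l)
      scene_patch_region(scene, sprintf("std_%g", l)))
    meas <- measure_regions(stk, regs)
    meas$stated <- levels[match(meas$region,
                                sprintf("std_%g", levels))] / 100
    meas$exposure_index <- ei
    obs[[ei]] <- meas
  }
  obs <- do.call(rbind, obs)
  sat <- obs$mean >= 65400
  if (any(sat)) {
    ms_warn("multispec_saturated_standards",
            sum(sat), " saturated standard measurement(s) excluded")
    obs <- obs[!sat, ]
  }
  out <- lapply(chans, function(ch) {
    d <- obs[obs$channel == ch, ]
    pooled <- stats::ave(d$mean, d$exposure_index, FUN = mean)
    expected <- d$stated * pooled
    data.frame(channel = ch, r2 = stats::cor(d$mean, expected)^2,
               n = nrow(d))
  })
  do.call(rbind, out)
}
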
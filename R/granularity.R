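# Granularity (spatial-frequency band energy) pattern analysis.
#
# An image channel is decomposed by Fourier bandpass filtering into a
# geometric series of spatial-frequency bands; the "energy" of each band
# is the standard deviation of the bandpass-filtered image over the
# measured region. The resulting band-energy spectrum summarises marking
# size (dominant band), contrast (total energy) and diversity. Pattern
# comparisons between photographs require a common pixels-per-mm scale.

band_boundaries <- function(band_sizes) {
  # wavelength (px) boundaries at geometric means of adjacent band sizes;
  # outermost edges extended by the same ratio as the neighbouring gap
  s <- band_sizes
  if (length(s) < 2) stop("granularity: need >= 2 band sizes")
  if (any(diff(s) <= 0)) stop("granularity: band sizes must be increasing")
  inner <- sqrt(s[-length(s)] * s[-1])
  lo <- c(s[1]^2 / inner[1], inner)
  hi <- c(inner, s[length(s)]^2 / inner[length(inner)])
  cbind(lo = lo, hi = hi)
}

radial_wavelength <- function(nr, nc) {
  # per-FFT-element spatial wavelength (px); DC -> Inf
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  if (nr == 1) fy <- 0
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  if (nc == 1) fx <- 0
  f <- sqrt(outer(fy^2, fx^2, "+"))
  w <- matrix(Inf, nr, nc)
  w[f > 0] <- 1 / f[f > 0]
  w
}

#' Band-energy (granularity) spectrum of an image region
#'
#' For each band, an isotropic ideal bandpass filter (an annulus in
#' frequency space between the geometric means of adjacent band sizes)
#' is applied via the FFT, and the band's energy is the standard
#' deviation of the filtered pixels inside the region. Pixels outside a
#' non-rectangular region are replaced by the region mean before the
#' transform to avoid edge ringing. Bands larger than the region's extent
#' are kept but flagged unreliable.
#'
#' @param channel numeric matrix (one stack channel).
#' @param region optional [region()] restricting the measurement; the
#'   rasterised region must cover at least 64 pixels.
#' @param band_sizes increasing vector of band pass sizes in px
#'   (default octave series 2, 4, ..., 512, truncated to the image).
#' @param px_per_mm optional scale recorded on the result; pattern
#'   comparisons require matching scales (see [rescale_to_uniform()]).
#' @return A `band_energy_spectrum`: data frame with columns `size_px`,
#'   `size_mm` (if scaled), `energy`, `reliable`.
#' @export
granularity_spectrum <- function(channel, region = NULL,
                                 band_sizes = NULL, px_per_mm = NULL) {
  nr <- nrow(channel); nc <- ncol(channel)
  if (is.null(band_sizes)) {
    band_sizes <- 2^(1:9)
    band_sizes <- band_sizes[band_sizes <= max(nr, nc)]
  }
  if (is.null(region)) {
    mask <- matrix(TRUE, nr, nc)
  } else {
    mask <- rasterize_region(region, c(nr, nc))
    if (sum(mask) < 64)
      stop("granularity_spectrum: region rasterises to ", sum(mask),
           " px; >= 64 required")
  }
  img <- channel
  img[!mask] <- mean(channel[mask])
  ft <- stats::fft(img)
  wl <- radial_wavelength(nr, nc)
  bb <- band_boundaries(band_sizes)
  extent <- max(sum(apply(mask, 1, any)), sum(apply(mask, 2, any)))
  energies <- numeric(length(band_sizes))
  for (i in seq_along(band_sizes)) {
    keep <- wl > bb[i, "lo"] & wl <= bb[i, "hi"]
    filt <- Re(stats::fft(ft * keep, inverse = TRUE)) / (nr * nc)
    energies[i] <- stats::sd(filt[mask])
  }
  out <- data.frame(size_px = band_sizes, energy = energies,
                    reliable = band_sizes <= extent)
  if (any(!out$reliable))
    ms_warn("multispec_band_unreliable",
            "band size(s) ", paste(band_sizes[!out$reliable], collapse = ", "),
            " px exceed the region extent (", extent, " px)")
  if (!is.null(px_per_mm)) out$size_mm <- out$size_px / px_per_mm
  structure(out, px_per_mm = px_per_mm,
            class = c("band_energy_spectrum", "data.frame"))
}

#' Descriptive pattern statistics from a band-energy spectrum
#'
#' Interprets the spectrum as: total energy (pattern contrast), dominant
#' band size (characteristic marking size; ties broken toward the smaller
#' size), the proportion of energy in the dominant band, and a diversity
#' descriptor (the number of bands holding at least half the dominant
#' band's energy -- broad-band patterns score high, single-scale patterns
#' score 1).
#'
#' @param spectrum a `band_energy_spectrum`.
#' @return A one-row data frame: `total_energy`, `dominant_size_px`,
#'   `proportion_dominant`, `diversity`.
#' @export
pattern_stats <- function(spectrum) {
  e <- spectrum$energy
  if (all(e == 0)) {
    ms_warn("multispec_zero_pattern", "all band energies are zero; ",
            "pattern statistics undefined")
    return(data.frame(total_energy = 0, dominant_size_px = NA_real_,
                      proportion_dominant = NA_real_, diversity = NA_real_))
  }
  dom <- which(e == max(e))[1]   # ties -> smaller band size (sizes increasing)
  data.frame(total_energy = sum(e),
             dominant_size_px = spectrum$size_px[dom],
             proportion_dominant = e[dom] / sum(e),
             diversity = sum(e >= e[dom] / 2))
}

#' Pairwise pattern difference between two band-energy spectra
#'
#' Sum of absolute per-band energy differences; symmetric, zero only for
#' identical spectra. Both spectra must share the band set and the
#' pixels-per-mm scale.
#'
#' @param a,b `band_energy_spectrum` objects.
#' @return A non-negative number.
#' @export
pattern_difference <- function(a, b) {
  if (!isTRUE(all.equal(a$size_px, b$size_px)))
    stop("pattern_difference: band sets differ")
  sa <- attr(a, "px_per_mm"); sb <- attr(b, "px_per_mm")
  if (xor(is.null(sa), is.null(sb)) ||
      (!is.null(sa) && !isTRUE(all.equal(sa, sb))))
    stop("pattern_difference: px/mm scales differ; rescale to a uniform ",
         "scale first")
  sum(abs(a$energy - b$energy))
}

#' Rescale a stack to a uniform pixels-per-mm scale
#'
#' Pattern analysis across photographs requires the same number of pixels
#' per unit length; this bilinearly resamples every channel so the
#' recorded scale equals `target_px_per_mm`.
#'
#' @param stack an [mspec_stack()] with a recorded scale.
#' @param target_px_per_mm the batch's common scale.
#' @return The rescaled [mspec_stack()].
#' @export
rescale_to_uniform <- function(stack, target_px_per_mm) {
  if (is.null(stack$px_per_mm))
    stop("rescale_to_uniform: stack has no recorded scale (set a scale bar)")
  factor <- target_px_per_mm / stack$px_per_mm
  if (isTRUE(all.equal(factor, 1))) return(stack)
  ch <- lapply(stack$channels, resize_channel, factor = factor)
  mspec_stack(ch, normalized = stack$normalized,
              px_per_mm = target_px_per_mm)
}

#' Rescale a region's polygon to match a rescaled stack
#' @param reg an [region()].
#' @param factor the same scale factor applied to the image.
#' @return The rescaled region.
#' @export
rescale_region <- function(reg, factor)
  region(reg$label, reg$vertices * factor, pool = reg$pool)
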
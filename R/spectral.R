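#' Spectral curve on a 1-nm wavelength grid
#'
#' A spectral curve holds one value per nanometre over a closed integer
#' wavelength range. The same container is used for receptor and camera
#' sensitivities, illuminant radiance spectra, and sample reflectance
#' spectra (reflectance on a 0-1 scale; values above 1 are permitted only
#' for fluorescent/emissive samples, see [reflectance_library()]).
#'
#' @param values numeric vector, one value per nm, finite and non-negative.
#' @param wl_start,wl_end integer wavelength range (nm), inclusive at both
#'   ends; `length(values)` must equal `wl_end - wl_start + 1`.
#' @param name label used in error messages and CSV headers.
#' @return An object of class `spectral_curve`.
#' @examples
#' flat <- spectral_curve(rep(1, 401), 300, 700, name = "white")
#' @export
spectral_curve <- function(values, wl_start, wl_end = wl_start + length(values) - 1L,
                           name = "") {
  wl_start <- as.integer(wl_start)
  wl_end <- as.integer(wl_end)
  values <- as.numeric(values)
  if (length(values) != wl_end - wl_start + 1L)
    stop("spectral_curve: need one value per nm: got ", length(values),
         " values for range [", wl_start, ", ", wl_end, "]")
  if (anyNA(values) || any(!is.finite(values)))
    stop("spectral_curve: values must be finite")
  if (any(values < 0))
    stop("spectral_curve: values must be non-negative (", name, ")")
  structure(list(wl_start = wl_start, wl_end = wl_end, values = values,
                 name = as.character(name)),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve '%s': %d-%d nm, peak %.4g>\n",
              x$name, x$wl_start, x$wl_end, max(x$values)))
  invisible(x)
}

#' Wavelength grid of a spectral curve
#' @param curve a `spectral_curve`.
#' @return integer vector of wavelengths (nm).
#' @export
wavelengths <- function(curve) seq.int(curve$wl_start, curve$wl_end)

same_grid <- function(a, b) a$wl_start == b$wl_start && a$wl_end == b$wl_end

#' Resample a spectral curve onto a target 1-nm grid
#'
#' Linear interpolation inside the overlap of the curve's measured range
#' and the requested range; wavelengths outside the measured range are set
#' to zero (sensitivities are physically zero outside their band, and no
#' extrapolation rule is assumed).
#'
#' @param curve a `spectral_curve`.
#' @param start_nm,end_nm target range (nm, inclusive).
#' @return A `spectral_curve` on `[start_nm, end_nm]`.
#' @export
resample_to_grid <- function(curve, start_nm, end_nm) {
  start_nm <- as.integer(start_nm); end_nm <- as.integer(end_nm)
  if (start_nm > end_nm) stop("resample_to_grid: empty target range")
  if (end_nm < curve$wl_start || start_nm > curve$wl_end)
    stop("resample_to_grid: no overlap between curve range [",
         curve$wl_start, ", ", curve$wl_end, "] and target range [",
         start_nm, ", ", end_nm, "]")
  wl <- seq.int(start_nm, end_nm)
  out <- numeric(length(wl))
  inside <- wl >= curve$wl_start & wl <= curve$wl_end
  if (curve$wl_start == curve$wl_end) {
    out[inside] <- curve$values
  } else {
    out[inside] <- stats::approx(wavelengths(curve), curve$values,
                                 xout = wl[inside], method = "linear")$y
  }
  spectral_curve(out, start_nm, end_nm, name = curve$name)
}

#' Bank of sensitivity curves sharing one wavelength grid
#'
#' Channel names follow the filter-prefix/sensor-suffix convention used in
#' multispectral photography: a lower-case prefix for the filter (e.g. `v`
#' visible, `u` ultraviolet) and an upper-case suffix for the sensor
#' channel, giving names such as `vR`, `vG`, `vB`, `uB`, `uR`.
#'
#' @param curves list of [spectral_curve()] objects on a common grid.
#' @param channel_names optional character vector; defaults to curve names.
#' @return An object of class `sensitivity_bank`.
#' @export
sensitivity_bank <- function(curves, channel_names = NULL) {
  if (!length(curves)) stop("sensitivity_bank: no curves")
  if (is.null(channel_names))
    channel_names <- vapply(curves, function(cv) cv$name, character(1))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != length(curves))
    stop("sensitivity_bank: one name per curve required")
  if (anyDuplicated(channel_names))
    stop("sensitivity_bank: duplicate channel names: ",
         paste(channel_names[duplicated(channel_names)], collapse = ", "))
  for (cv in curves[-1])
    if (!same_grid(curves[[1]], cv))
      stop("sensitivity_bank: curves must share one wavelength grid")
  names(curves) <- channel_names
  structure(list(curves = curves, channel_names = channel_names),
            class = "sensitivity_bank")
}

#' @export
print.sensitivity_bank <- function(x, ...) {
  cat(sprintf("<sensitivity_bank: %d channels (%s), %d-%d nm>\n",
              length(x$curves), paste(x$channel_names, collapse = ", "),
              x$curves[[1]]$wl_start, x$curves[[1]]$wl_end))
  invisible(x)
}

#' @export
length.sensitivity_bank <- function(x) length(x$curves)

#' Library of reflectance spectra
#'
#' Reflectance values are on a 0-1 scale. Values above 1 are rejected
#' unless the spectrum is tagged fluorescent/emissive, since ordinary
#' diffuse reflectance cannot exceed the white reference.
#'
#' @param spectra list of [spectral_curve()] on a common grid.
#' @param source character vector of source tags (recycled).
#' @param fluorescent logical vector flagging spectra allowed to exceed 1.
#' @return An object of class `reflectance_library`.
#' @export
reflectance_library <- function(spectra, source = "unknown",
                                fluorescent = FALSE) {
  if (!length(spectra)) stop("reflectance_library: no spectra")
  for (cv in spectra[-1])
    if (!same_grid(spectra[[1]], cv))
      stop("reflectance_library: spectra must share one wavelength grid")
  fluorescent <- rep_len(fluorescent, length(spectra))
  for (i in seq_along(spectra))
    if (!fluorescent[i] && any(spectra[[i]]$values > 1 + 1e-12))
      stop("reflectance_library: spectrum ", i,
           " exceeds 1 but is not flagged fluorescent")
  structure(list(spectra = spectra,
                 source = rep_len(as.character(source), length(spectra)),
                 fluorescent = fluorescent),
            class = "reflectance_library")
}

#' @export
length.reflectance_library <- function(x) length(x$spectra)

#' @export
print.reflectance_library <- function(x, ...) {
  cat(sprintf("<reflectance_library: %d spectra, %d-%d nm>\n",
              length(x$spectra), x$spectra[[1]]$wl_start, x$spectra[[1]]$wl_end))
  invisible(x)
}

#' Read spectral curves from CSV
#'
#' Expected layout: first column wavelength in nm, one curve per subsequent
#' column, header row of names. Lines starting with `#` are comments.
#' Curves are resampled to a 1-nm grid spanning the file's wavelength range
#' by linear interpolation if the file is coarser than 1 nm.
#'
#' @param path CSV file path.
#' @return Named list of [spectral_curve()] objects.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) < 2) stop("read_spectra_csv: need wavelength + >=1 curve column")
  wl <- df[[1]]
  if (is.unsorted(wl, strictly = TRUE))
    stop("read_spectra_csv: wavelength column must be strictly increasing")
  start <- as.integer(ceiling(min(wl))); end <- as.integer(floor(max(wl)))
  grid <- seq.int(start, end)
  out <- lapply(names(df)[-1], function(nm) {
    v <- stats::approx(wl, df[[nm]], xout = grid, method = "linear")$y
    spectral_curve(v, start, end, name = nm)
  })
  names(out) <- names(df)[-1]
  out
}

#' Write spectral curves to CSV
#' @param curves named list of `spectral_curve` on a shared grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(curves, path) {
  for (cv in curves[-1])
    if (!same_grid(curves[[1]], cv))
      stop("write_spectra_csv: curves must share one wavelength grid")
  df <- data.frame(wavelength = wavelengths(curves[[1]]))
  for (nm in names(curves)) df[[nm]] <- curves[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cone-catch quantum of one receptor viewing one sample
#'
#' The quantum catch is the wavelength-by-wavelength sum of receptor (or
#' camera channel) sensitivity times sample reflectance times illuminant
#' radiance over the shared 1-nm grid: `sum(l * Q * I)`. It is linear in
#' each argument.
#'
#' @param sensitivity,reflectance,illuminant `spectral_curve` objects on an
#'   identical grid.
#' @return A single non-negative number.
#' @export
cone_catch <- function(sensitivity, reflectance, illuminant) {
  if (!same_grid(sensitivity, reflectance) || !same_grid(sensitivity, illuminant))
    stop("cone_catch: curves must share an identical wavelength grid (",
         "sensitivity [", sensitivity$wl_start, ",", sensitivity$wl_end, "], ",
         "reflectance [", reflectance$wl_start, ",", reflectance$wl_end, "], ",
         "illuminant [", illuminant$wl_start, ",", illuminant$wl_end, "])")
  sum(sensitivity$values * reflectance$values * illuminant$values)
}

#' Vector of cone-catch quanta across receptors or camera channels
#' @param quanta non-negative numeric vector.
#' @param receptor_names labels, one per quantum.
#' @param normalized `TRUE` if quanta are von Kries normalised against a
#'   white reference ([von_kries_normalize()]).
#' @return An object of class `cone_catch_vector`.
#' @export
cone_catch_vector <- function(quanta, receptor_names = NULL,
                              normalized = FALSE) {
  if (is.null(receptor_names)) receptor_names <- names(quanta)
  quanta <- as.numeric(quanta)
  if (is.null(receptor_names)) stop("cone_catch_vector: receptor names required")
  if (length(receptor_names) != length(quanta))
    stop("cone_catch_vector: one name per quantum required")
  if (any(quanta < 0))
    stop("cone_catch_vector: quanta must be non-negative")
  names(quanta) <- receptor_names
  structure(list(receptor_names = as.character(receptor_names),
                 quanta = quanta, normalized = isTRUE(normalized)),
            class = "cone_catch_vector")
}

#' @export
print.cone_catch_vector <- function(x, ...) {
  cat(sprintf("<cone_catch_vector%s>\n", if (x$normalized) " (von Kries)" else ""))
  print(x$quanta)
  invisible(x)
}

#' Quantum catches of a sensitivity bank for one sample
#' @param bank a [sensitivity_bank()].
#' @param reflectance,illuminant `spectral_curve` on the bank's grid.
#' @return A [cone_catch_vector()] (raw, not normalised).
#' @export
bank_catches <- function(bank, reflectance, illuminant) {
  q <- vapply(bank$curves, cone_catch, numeric(1),
              reflectance = reflectance, illuminant = illuminant)
  cone_catch_vector(q, bank$channel_names, normalized = FALSE)
}

#' von Kries chromatic adaptation of cone-catch quanta
#'
#' Divides each receptor's quantum catch by the catch of the same receptor
#' viewing a white reference under the same illuminant, so that a grey
#' (spectrally flat) surface yields equal values in every receptor. This
#' is the coefficient-law colour-constancy step standard in receptor
#' modelling.
#'
#' @param raw a [cone_catch_vector()] of raw quanta.
#' @param white_reference a [cone_catch_vector()] for the white reference,
#'   same receptors, all quanta strictly positive.
#' @return A normalised [cone_catch_vector()].
#' @export
von_kries_normalize <- function(raw, white_reference) {
  if (!identical(raw$receptor_names, white_reference$receptor_names))
    stop("von_kries_normalize: receptor lists differ")
  zero <- white_reference$quanta <= 0
  if (any(zero))
    stop("von_kries_normalize: zero white-reference quantum in receptor ",
         paste(raw$receptor_names[zero], collapse = ", "))
  cone_catch_vector(raw$quanta / white_reference$quanta,
                    raw$receptor_names, normalized = TRUE)
}

#' White-reference quanta of a bank under an illuminant
#'
#' Catch of a spectrally flat, 100% reflectance (ideal Lambertian white)
#' surface; the denominator of von Kries normalisation.
#'
#' @inheritParams bank_catches
#' @return A [cone_catch_vector()].
#' @export
white_reference <- function(bank, illuminant) {
  flat <- spectral_curve(rep(1, illuminant$wl_end - illuminant$wl_start + 1L),
                         illuminant$wl_start, illuminant$wl_end, name = "white")
  bank_catches(bank, flat, illuminant)
}
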
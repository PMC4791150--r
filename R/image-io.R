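#' Load a 16-bit linear image channel
#'
#' Reads one channel of a linear 16-bit TIFF or PNG as integer pixel values
#' in [0, 65535], with no gamma, white balance, rescaling or clipping.
#' Linearity is a contract of the upstream decoder: camera RAW files must
#' first be converted externally (dcraw or equivalent, configured for
#' linear output, no auto-brightening, white balance disabled, 16-bit) and
#' the resulting TIFF fed to this function. RAW formats are not parsed
#' here.
#'
#' @param path a 16-bit TIFF or PNG file.
#' @param channel which plane to extract from a multi-plane file: integer
#'   index or one of `"R"`, `"G"`, `"B"` (planes 1-3). Single-plane files
#'   ignore this.
#' @param channel_name label stored on the result (defaults to `channel`).
#' @return A `linear_image`: integer matrix (rows x cols) with attributes
#'   `channel_name` and `source`.
#' @export
load_linear_image <- function(path, channel = 1L, channel_name = NULL) {
  if (!file.exists(path)) stop("load_linear_image: cannot read ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nef", "cr2", "crw", "dng", "arw", "raf", "orf", "rw2"))
    stop("load_linear_image: '", path, "' is a camera RAW file; decode it ",
         "externally to a linear 16-bit TIFF first (linear output, no ",
         "auto-brightening, white balance disabled)")
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 16L)
      stop("load_linear_image: ", path, " has bit depth ", bits,
           "; 16-bit linear input required")
    if (is.null(bits) && max(img) <= 255)
      stop("load_linear_image: ", path,
           " has bit depth 8 (or lower); 16-bit linear input required")
  } else if (ext == "png") {
    raw <- png::readPNG(path)
    # readPNG scales to [0,1]; an 8-bit file quantises on 1/255 steps
    if (max(raw) > 0 && all(abs(raw * 255 - round(raw * 255)) < 1e-9))
      stop("load_linear_image: ", path, " has bit depth 8",
           "; 16-bit linear input required")
    img <- round(raw * 65535)
    storage.mode(img) <- "integer"
  } else {
    stop("load_linear_image: unsupported format '", ext,
         "'; expected 16-bit TIFF or PNG")
  }
  if (length(dim(img)) == 3L) {
    idx <- channel
    if (is.character(channel)) {
      idx <- match(channel, c("R", "G", "B"))
      if (is.na(idx)) stop("load_linear_image: unknown channel '", channel, "'")
    }
    if (idx > dim(img)[3])
      stop("load_linear_image: ", path, " has ", dim(img)[3],
           " planes; channel ", idx, " requested")
    img <- img[, , idx]
  }
  storage.mode(img) <- "integer"
  structure(img,
            channel_name = if (is.null(channel_name)) as.character(channel)
                           else channel_name,
            source = path,
            class = c("linear_image", class(img)))
}

#' Write a 16-bit linear image
#' @param pixels numeric/integer matrix in [0, 65535].
#' @param path output path; `.tif`/`.tiff` (16-bit TIFF is the only
#'   lossless 16-bit writer available).
#' @return `path`, invisibly.
#' @export
write_linear_image <- function(pixels, path) {
  pixels <- pmin(pmax(round(unclass(pixels)), 0), 65535)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff"))
    stop("write_linear_image: unsupported extension '", ext,
         "'; use .tif/.tiff")
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
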
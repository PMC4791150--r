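#' Multispectral image stack
#'
#' A named set of co-registered 2-D channels held as 32-bit-style floating
#' point matrices. Normalised stacks hold reflectance on a 0-1 scale where
#' 1 is the 100% reflectance level; values above 1 (specular, fluorescent
#' or emissive surfaces) and below 0 (possible with an intercept model)
#' are preserved, never clipped.
#'
#' Coordinates are 0-based, origin top-left, x along columns, y along rows;
#' matrix element `[r, c]` has pixel-centre `(x, y) = (c - 0.5, r - 0.5)`.
#'
#' @param channels named list of numeric matrices, all the same dimensions.
#' @param normalized `TRUE` once pixel values are reflectance.
#' @param px_per_mm optional scale (pixels per mm) from a scale bar.
#' @param alignment named list per channel of `list(dx, dy, scale)` already
#'   applied to that channel.
#' @return An object of class `mspec_stack`.
#' @export
mspec_stack <- function(channels, normalized = FALSE, px_per_mm = NULL,
                        alignment = NULL) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("mspec_stack: channels must be a non-empty named list")
  dims <- dim(channels[[1]])
  for (ch in channels) {
    if (!is.matrix(ch)) stop("mspec_stack: each channel must be a matrix")
    if (!identical(dim(ch), dims))
      stop("mspec_stack: all channels must share dimensions after alignment")
  }
  channels <- lapply(channels, function(m) { storage.mode(m) <- "double"; m })
  structure(list(channels = channels, channel_names = names(channels),
                 normalized = isTRUE(normalized), px_per_mm = px_per_mm,
                 alignment = alignment),
            class = "mspec_stack")
}

#' @export
print.mspec_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mspec_stack: %d x %d, channels %s%s%s>\n", d[1], d[2],
              paste(x$channel_names, collapse = ", "),
              if (x$normalized) ", normalized" else "",
              if (!is.null(x$px_per_mm))
                sprintf(", %.4g px/mm", x$px_per_mm) else ""))
  invisible(x)
}

#' @export
dim.mspec_stack <- function(x) dim(x$channels[[1]])

#' Polygonal region of interest
#'
#' @param label non-empty label string.
#' @param vertices n x 2 matrix of (x, y) pixel coordinates (0-based,
#'   origin top-left), n >= 3.
#' @param pool optional pooling-group tag; regions sharing a tag are
#'   unified (overlap counted once) before measurement.
#' @return An object of class `mspec_region`.
#' @export
region <- function(label, vertices, pool = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 2)
  if (!nzchar(label)) stop("region: label must be non-empty")
  if (nrow(vertices) < 3) stop("region: need >= 3 vertices")
  structure(list(label = as.character(label), vertices = vertices,
                 pool = if (is.null(pool)) NULL else as.character(pool)),
            class = "mspec_region")
}

#' Rectangular region helper
#' @param label label string.
#' @param x,y top-left corner (0-based pixel coordinates).
#' @param w,h width and height in pixels.
#' @param pool optional pooling-group tag.
#' @return An `mspec_region`.
#' @export
rect_region <- function(label, x, y, w, h, pool = NULL) {
  region(label, rbind(c(x, y), c(x + w, y), c(x + w, y + h), c(x, y + h)),
         pool = pool)
}

#' Rasterise a region to a logical pixel mask
#'
#' A pixel belongs to the region when its centre falls inside the polygon
#' (even-odd rule).
#'
#' @param reg an [region()].
#' @param dims `c(nrow, ncol)` of the target image.
#' @return Logical matrix.
#' @export
rasterize_region <- function(reg, dims) {
  nr <- dims[1]; nc <- dims[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  inside <- mgcv::in.out(rbind(reg$vertices, reg$vertices[1, ]),
                         cbind(cx, cy))
  matrix(inside, nr, nc)
}

pool_masks <- function(regions, dims) {
  # returns named list of logical masks; pooled groups unified (union)
  masks <- list(); labels <- character(0)
  for (reg in regions) {
    key <- if (is.null(reg$pool)) reg$label else reg$pool
    m <- rasterize_region(reg, dims)
    if (key %in% labels) masks[[key]] <- masks[[key]] | m
    else { masks[[key]] <- m; labels <- c(labels, key) }
  }
  masks
}

#' Measure per-channel statistics over regions of interest
#'
#' Regions sharing a pooling tag are combined prior to measurement, with
#' overlapping pixels counted once. With no regions the whole image is
#' measured as region `"whole_image"`.
#'
#' @param stack an [mspec_stack()].
#' @param regions list of [region()] objects (or a single region).
#' @return A data frame with columns `region`, `channel`, `mean`, `sd`,
#'   `n` (pixel count).
#' @export
measure_regions <- function(stack, regions = list()) {
  dims <- dim(stack)
  if (inherits(regions, "mspec_region")) regions <- list(regions)
  if (!length(regions)) {
    masks <- list(whole_image = matrix(TRUE, dims[1], dims[2]))
  } else {
    masks <- pool_masks(regions, dims)
  }
  out <- list()
  for (key in names(masks)) {
    m <- masks[[key]]
    if (!any(m))
      stop("measure_regions: region '", key,
           "' contains no pixel centres inside the image")
    for (ch in stack$channel_names) {
      v <- stack$channels[[ch]][m]
      v <- v[!is.na(v)]
      if (!length(v))
        stop("measure_regions: region '", key, "' empty in channel ", ch)
      out[[length(out) + 1L]] <- data.frame(
        region = key, channel = ch, mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
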
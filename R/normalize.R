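# Grey-standard reflectance normalisation.
#
# Linear pixel values are mapped to reflectance per channel. Internally
# reflectance is on a 0-1 scale (1 = the 100% level); the 16-bit maximum
# 65535 enters only when exporting 16-bit previews, so the classic
# single-standard rule Vnorm = Vlinear * (S/100) * (65535/G) corresponds
# here to slope = (S/100)/G with zero intercept.

ms_warn <- function(code, ...) {
  warning(warningCondition(paste0("[", code, "] ", ...),
                           class = c(code, "multispec_warning")))
}

#' Measured grey standard
#'
#' @param stated_reflectance_percent the standard's calibrated reflectance
#'   in percent, in (0, 100].
#' @param mean_pixel named numeric vector of mean linear pixel values for
#'   the standard, one per channel.
#' @param region optional label of the region the mean came from.
#' @return An object of class `standard_measurement`.
#' @export
standard_measurement <- function(stated_reflectance_percent, mean_pixel,
                                 region = NULL) {
  s <- as.numeric(stated_reflectance_percent)
  if (s <= 0 || s > 100)
    stop("standard_measurement: stated reflectance must be in (0, 100]")
  if (is.null(names(mean_pixel)) || any(!nzchar(names(mean_pixel))))
    stop("standard_measurement: mean_pixel must be named per channel")
  structure(list(stated_reflectance_percent = s,
                 mean_pixel = mean_pixel, region = region),
            class = "standard_measurement")
}

new_norm_model <- function(channels, slope, intercept, r2, method) {
  if (any(slope <= 0))
    stop("normalization: non-positive slope for channel ",
         paste(channels[slope <= 0], collapse = ", "),
         " (pixel value must increase with reflectance)")
  structure(list(channels = channels,
                 slope = stats::setNames(slope, channels),
                 intercept = stats::setNames(intercept, channels),
                 r2 = stats::setNames(r2, channels), method = method),
            class = "norm_model")
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("<norm_model (%s)>\n", x$method))
  print(data.frame(channel = x$channels, slope = x$slope,
                   intercept = x$intercept, r2 = x$r2, row.names = NULL))
  invisible(x)
}

#' Fit a per-channel normalisation model from grey standards
#'
#' With one standard the model is the classic proportional rule (line
#' through the origin). With two or more, an ordinary least squares
#' regression of reflectance on pixel value gives slope plus intercept per
#' channel, which additionally estimates the photograph's black point
#' (veiling glare). With three or more standards the fit R-squared is
#' recorded and a warning (`multispec_poor_linearisation`) is emitted when
#' any channel's R-squared falls below 0.98; the model is still returned.
#'
#' @param standards list of [standard_measurement()] (or a single one);
#'   all must cover the same channels.
#' @param force_zero_intercept fit through the origin even with multiple
#'   standards (reduces to the single-standard rule when exact).
#' @return A `norm_model` mapping pixel value to reflectance (0-1 scale).
#' @export
fit_normalization <- function(standards, force_zero_intercept = FALSE) {
  if (inherits(standards, "standard_measurement")) standards <- list(standards)
  if (!length(standards)) stop("fit_normalization: no standards")
  channels <- names(standards[[1]]$mean_pixel)
  for (st in standards)
    if (!identical(names(st$mean_pixel), channels))
      stop("fit_normalization: standards cover different channels")
  S <- vapply(standards, function(st) st$stated_reflectance_percent,
              numeric(1)) / 100
  G <- matrix(unlist(lapply(standards, function(st)
    as.numeric(st$mean_pixel))), nrow = length(standards),
    ncol = length(channels), byrow = TRUE,
    dimnames = list(NULL, channels))   # standards x channels
  n <- length(standards)
  if (n == 1L) {
    slope <- S[1] / G[1, ]
    return(new_norm_model(channels, slope, rep(0, length(channels)),
                          rep(NA_real_, length(channels)), "single"))
  }
  ord <- order(S)
  slope <- intercept <- r2 <- numeric(length(channels))
  for (j in seq_along(channels)) {
    g <- G[, j]
    if (anyDuplicated(g))
      stop("fit_normalization: two standards have identical mean pixel ",
           "values in channel ", channels[j])
    if (any(diff(g[ord]) <= 0))
      ms_warn("multispec_nonmonotonic_standards",
              "pixel value does not increase with stated reflectance in ",
              "channel ", channels[j])
    if (force_zero_intercept) {
      fit <- stats::lm.fit(cbind(pixel = g), S)
      slope[j] <- fit$coefficients[1]; intercept[j] <- 0
      tss <- sum(S^2)
    } else {
      fit <- stats::lm.fit(cbind(1, pixel = g), S)
      intercept[j] <- fit$coefficients[1]; slope[j] <- fit$coefficients[2]
      tss <- sum((S - mean(S))^2)
    }
    r2[j] <- 1 - sum(fit$residuals^2) / tss
  }
  if (n >= 3 && any(r2 < 0.98))
    ms_warn("multispec_poor_linearisation",
            "linearisation fit below 0.98 in channel ",
            paste(channels[r2 < 0.98], collapse = ", "),
            " (min R^2 = ", format(min(r2), digits = 4), ")")
  new_norm_model(channels, slope, intercept,
                 if (n >= 3) r2 else rep(NA_real_, length(channels)),
                 if (force_zero_intercept) "single" else "multi")
}

#' Predict reflectance from linear pixel values
#' @param model a `norm_model`.
#' @param pixels numeric vector/matrix of linear pixel values.
#' @param channel channel name.
#' @return Reflectance on the 0-1 scale (same shape as `pixels`).
#' @export
predict_reflectance <- function(model, pixels, channel) {
  if (!channel %in% model$channels)
    stop("predict_reflectance: model has no channel '", channel, "'")
  model$intercept[[channel]] + model$slope[[channel]] * pixels
}

#' Normalise a multispectral stack to reflectance
#'
#' Applies the per-channel affine map. Output values are floating point
#' reflectance; values above 1 (shiny/fluorescent surfaces) and negative
#' values (possible with an intercept model) are preserved, never clipped.
#'
#' @param stack an unnormalised [mspec_stack()] of linear pixel values.
#' @param model a `norm_model` whose channels match the stack's.
#' @return A normalised [mspec_stack()].
#' @export
apply_normalization <- function(stack, model) {
  if (!setequal(stack$channel_names, model$channels))
    stop("apply_normalization: model channels (",
         paste(model$channels, collapse = ", "), ") do not match stack (",
         paste(stack$channel_names, collapse = ", "), ")")
  ch <- lapply(stats::setNames(stack$channel_names, stack$channel_names),
               function(nm) predict_reflectance(model, stack$channels[[nm]], nm))
  mspec_stack(ch, normalized = TRUE, px_per_mm = stack$px_per_mm,
              alignment = stack$alignment)
}

#' Estimate the black point from the pixel histogram
#'
#' When only one standard is available but veiling glare is a concern, the
#' channel's dark point is estimated by assuming the lowest 0.5% of pixels
#' have a reflectance of 0.5%. The dark anchor is the mean of the pixels
#' at or below the 0.5th percentile (the absolute lowest pixel value is
#' not used alone, being highly susceptible to noise), and the channel's
#' line is drawn through the dark anchor and the standard.
#'
#' @param pixels the channel's linear pixel values (matrix or vector),
#'   at least 200 pixels so the 0.5% tail is populated.
#' @param standard a [standard_measurement()].
#' @param channel channel name (selects the element of the standard's
#'   `mean_pixel`; defaults to its only channel).
#' @return A single-channel `norm_model` with method
#'   `"histogram-dark-point"`.
#' @export
estimate_dark_point <- function(pixels, standard, channel = NULL) {
  v <- as.numeric(pixels)
  v <- v[!is.na(v)]
  if (length(v) < 200)
    stop("estimate_dark_point: need >= 200 pixels to populate the 0.5% tail")
  if (is.null(channel)) {
    if (length(standard$mean_pixel) != 1L)
      stop("estimate_dark_point: specify channel for multi-channel standard")
    channel <- names(standard$mean_pixel)
  }
  G <- as.numeric(standard$mean_pixel[[channel]])
  S <- standard$stated_reflectance_percent / 100
  q <- stats::quantile(v, 0.005, names = FALSE)
  dark <- mean(v[v <= q])
  if (dark >= G)
    stop("estimate_dark_point: dark anchor (", format(dark),
         ") not below the standard mean (", format(G),
         "); channel has no usable dark tail")
  slope <- (S - 0.005) / (G - dark)
  intercept <- 0.005 - slope * dark
  new_norm_model(channel, slope, intercept, NA_real_, "histogram-dark-point")
}

#' Normalise a photograph against a standard in a separate photograph
#'
#' The sequential method: the grey standard(s) are measured in a separate
#' photograph taken under identical lighting and camera settings, and the
#' resulting model is applied to the target. The caller asserts identical
#' conditions; any intensity difference between the two frames biases all
#' recovered reflectances by that factor.
#'
#' @param target_project,standard_project [mspec_project()] objects with
#'   identical channel sets; the standard project must define standards.
#' @param target_dir,standard_dir directories resolving each project's
#'   relative source paths.
#' @return List with `model` (the fitted `norm_model`, method tag
#'   `"sequential"`) and `stack` (the normalised target stack).
#' @export
sequential_normalize <- function(target_project, standard_project,
                                 target_dir = ".", standard_dir = target_dir) {
  if (!setequal(names(target_project$sources), names(standard_project$sources)))
    stop("sequential_normalize: channel sets differ between projects")
  std_stack <- build_stack(standard_project, base_dir = standard_dir,
                           normalize = FALSE)
  model <- fit_project_standards(standard_project, std_stack)
  model$method <- "sequential"
  tgt_stack <- build_stack(target_project, base_dir = target_dir,
                           normalize = FALSE)
  list(model = model, stack = apply_normalization(tgt_stack, model))
}

#' Export a normalised channel as 16-bit values
#'
#' Maps reflectance 1.0 to the 16-bit 100% level 65535 and rounds with
#' clipping, matching the classic normalised-pixel convention. Only for
#' preview export; analysis stays in floating point.
#'
#' @param reflectance numeric matrix (0-1 scale).
#' @return Integer matrix in [0, 65535].
#' @export
reflectance_to_16bit <- function(reflectance) {
  out <- pmin(pmax(round(reflectance * 65535), 0), 65535)
  storage.mode(out) <- "integer"
  out
}
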
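# Receptor-noise-limited (RNL) colour discrimination.
#
# Distances between cone-catch samples are expressed in just-noticeable
# differences (JND): values near or above 1 indicate the visual system can
# discriminate the two stimuli. Receptor signals are log-transformed
# quantum catches and noise is neural (independent of light level), the
# standard form used with photographic cone-catch estimates. Weber
# fractions are user-supplied properties of the modelled visual system,
# not outputs of this package.

#' Receptor noise specification
#'
#' Noise per receptor channel, either given directly as Weber fractions,
#' or derived from relative receptor abundances: the noise of channel i is
#' `e_i = weber_ref * sqrt(eta_ref / eta_i)`, anchored to a named
#' reference receptor (conventionally the most abundant, typically the
#' long-wave channel).
#'
#' @param receptor_names channel labels, in cone-catch vector order.
#' @param weber numeric Weber fractions per receptor (recycled), or `NULL`
#'   to derive from abundances.
#' @param weber_ref,abundance reference Weber fraction and per-receptor
#'   relative abundances (used when `weber` is `NULL`).
#' @param reference name of the receptor `weber_ref` refers to; default
#'   the most abundant.
#' @return An object of class `receptor_noise` with field `e` (noise per
#'   receptor).
#' @export
receptor_noise <- function(receptor_names, weber = NULL, weber_ref = NULL,
                           abundance = NULL, reference = NULL) {
  receptor_names <- as.character(receptor_names)
  if (!is.null(weber)) {
    e <- rep_len(as.numeric(weber), length(receptor_names))
  } else {
    if (is.null(weber_ref) || is.null(abundance))
      stop("receptor_noise: give either weber, or weber_ref + abundance")
    abundance <- rep_len(as.numeric(abundance), length(receptor_names))
    if (any(abundance <= 0)) stop("receptor_noise: abundances must be > 0")
    if (is.null(reference))
      reference <- receptor_names[which.max(abundance)]
    ri <- match(reference, receptor_names)
    if (is.na(ri)) stop("receptor_noise: unknown reference receptor ", reference)
    e <- weber_ref * sqrt(abundance[ri] / abundance)
  }
  if (any(e <= 0)) stop("receptor_noise: noise values must be > 0")
  structure(list(receptor_names = receptor_names,
                 e = stats::setNames(e, receptor_names)),
            class = "receptor_noise")
}

#' @export
print.receptor_noise <- function(x, ...) {
  cat("<receptor_noise>\n"); print(x$e); invisible(x)
}

#' Log receptor contrasts between two cone-catch samples
#'
#' `df_i = ln(q_i^a / q_i^b)` per receptor; antisymmetric under swapping
#' the stimuli. Quanta must be strictly positive (apply the normalisation
#' flooring policy upstream; true zeros are rejected).
#'
#' @param a,b [cone_catch_vector()] objects over the same receptors.
#' @return Named numeric vector of log contrasts.
#' @export
receptor_contrasts <- function(a, b) {
  if (!identical(a$receptor_names, b$receptor_names))
    stop("receptor_contrasts: receptor lists differ")
  bad <- a$quanta <= 0 | b$quanta <= 0
  if (any(bad))
    stop("receptor_contrasts: non-positive quantum in receptor ",
         paste(a$receptor_names[bad], collapse = ", "))
  log(a$quanta / b$quanta)
}

#' Chromatic JND between two stimuli
#'
#' The receptor-noise-limited distance for di-, tri- and tetrachromatic
#' systems. For a dichromat `dS = |df1 - df2| / sqrt(e1^2 + e2^2)`; the
#' tri- and tetrachromatic forms are the corresponding quadratic forms in
#' the pairwise contrast differences weighted by the complementary noise
#' products.
#'
#' @param df log receptor contrasts from [receptor_contrasts()] (or any
#'   numeric vector of 2-4 contrasts in receptor order).
#' @param noise a [receptor_noise()] with matching receptor count.
#' @return A `jnd_result`: list with `delta_s` (JND units), `channel`
#'   (`"chromatic"`), `n_receptors`.
#' @export
chromatic_jnd <- function(df, noise) {
  e <- noise$e
  n <- length(df)
  if (length(e) != n)
    stop("chromatic_jnd: ", n, " contrasts but ", length(e), " noise values")
  if (n < 2 || n > 4)
    stop("chromatic_jnd: 2-4 receptors supported, got ", n)
  if (n == 2) {
    ds2 <- (df[1] - df[2])^2 / (e[1]^2 + e[2]^2)
  } else if (n == 3) {
    num <- e[1]^2 * (df[3] - df[2])^2 +
           e[2]^2 * (df[3] - df[1])^2 +
           e[3]^2 * (df[1] - df[2])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    ds2 <- num / den
  } else {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
           (e[1] * e[3])^2 * (df[4] - df[2])^2 +
           (e[1] * e[4])^2 * (df[3] - df[2])^2 +
           (e[2] * e[3])^2 * (df[4] - df[1])^2 +
           (e[2] * e[4])^2 * (df[3] - df[1])^2 +
           (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
           (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    ds2 <- num / den
  }
  structure(list(delta_s = sqrt(as.numeric(ds2)), channel = "chromatic",
                 n_receptors = n),
            class = "jnd_result")
}

#' @export
print.jnd_result <- function(x, ...) {
  cat(sprintf("<jnd: %.4f (%s)>\n", x$delta_s, x$channel))
  invisible(x)
}

#' Achromatic (luminance) JND
#'
#' Weber-fraction luminance discrimination:
#' `dS = |ln(a / b)| / weber_fraction`; symmetric in the two stimuli.
#'
#' @param a_lum,b_lum luminance (or double-cone catch) values, > 0.
#' @param weber_fraction the luminance channel's Weber fraction, > 0.
#' @return A `jnd_result` with `channel = "achromatic"`.
#' @export
achromatic_jnd <- function(a_lum, b_lum, weber_fraction) {
  if (a_lum <= 0 || b_lum <= 0)
    stop("achromatic_jnd: luminances must be > 0")
  if (weber_fraction <= 0) stop("achromatic_jnd: weber_fraction must be > 0")
  structure(list(delta_s = abs(log(a_lum / b_lum)) / weber_fraction,
                 channel = "achromatic", n_receptors = 1L),
            class = "jnd_result")
}

#' Pairwise chromatic JND matrix over measured regions
#'
#' Convenience wrapper: takes the per-region means of a cone-catch stack
#' (from [measure_regions()]) and returns the symmetric JND matrix.
#'
#' @param measurements data frame from [measure_regions()] on a cone-catch
#'   stack (columns `region`, `channel`, `mean`).
#' @param noise a [receptor_noise()] over the stack's receptor channels.
#' @return Symmetric numeric matrix of JNDs, regions as dimnames.
#' @export
jnd_matrix <- function(measurements, noise) {
  regions <- unique(measurements$region)
  q <- lapply(regions, function(r) {
    m <- measurements[measurements$region == r, ]
    stats::setNames(m$mean, m$channel)[noise$receptor_names]
  })
  out <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  for (i in seq_along(regions)) for (j in seq_len(i - 1L)) {
    df <- log(q[[i]] / q[[j]])
    out[i, j] <- out[j, i] <- chromatic_jnd(df, noise)$delta_s
  }
  out
}
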
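# Geometric resampling primitives shared by alignment and pattern rescaling.
# Bilinear sampling with NA outside the source footprint; scale is applied
# about the image centre so that scale search does not also translate.

bilinear_sample <- function(img, x, y) {
  # x, y: matrix coordinates in pixel-centre space (x along columns,
  # y along rows, 0-based; centre of img[r, c] is (c - 0.5, r - 0.5)).
  nr <- nrow(img); nc <- ncol(img)
  cx <- x + 0.5; cy <- y + 0.5        # 1-based fractional col/row
  c0 <- floor(cx); r0 <- floor(cy)
  fc <- cx - c0; fr <- cy - r0
  # neighbours clamped; validity requires the sample inside [0.5, n-0.5]
  valid <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
  c0c <- pmin(pmax(c0, 1L), nc); c1c <- pmin(c0c + 1L, nc)
  r0c <- pmin(pmax(r0, 1L), nr); r1c <- pmin(r0c + 1L, nr)
  idx <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fr) * ((1 - fc) * idx(r0c, c0c) + fc * idx(r0c, c1c)) +
       fr       * ((1 - fc) * idx(r1c, c0c) + fc * idx(r1c, c1c))
  v[!valid] <- NA_real_
  v
}

#' Translate and scale a channel (bilinear)
#'
#' Scales the image about its centre by `scale`, then shifts it by
#' `(dx, dy)` pixels (x along columns, y along rows, positive right/down).
#' Output has the input's dimensions; pixels whose source falls outside
#' the input are `NA`.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels applied to the image content.
#' @param scale magnification factor (> 0) about the image centre.
#' @return Numeric matrix, same dimensions, `NA` outside the footprint.
#' @export
transform_channel <- function(img, dx = 0, dy = 0, scale = 1) {
  stopifnot(scale > 0)
  nr <- nrow(img); nc <- ncol(img)
  if (dx == 0 && dy == 0 && scale == 1) return(img)
  ocx <- nc / 2; ocy <- nr / 2
  # output pixel centre (x,y); source location inverts shift then scale
  xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
  sx <- (xs - dx - ocx) / scale + ocx
  sy <- (ys - dy - ocy) / scale + ocy
  if (scale == 1 && dx == round(dx) && dy == round(dy)) {
    # integer shift: exact gather, no interpolation blur
    sc <- seq_len(nc) - as.integer(dx)
    sr <- seq_len(nr) - as.integer(dy)
    out <- matrix(NA_real_, nr, nc)
    okc <- sc >= 1 & sc <= nc; okr <- sr >= 1 & sr <= nr
    out[okr, okc] <- img[sr[okr], sc[okc]]
    return(out)
  }
  matrix(bilinear_sample(img, sx, sy), nr, nc)
}

#' Resize a channel by a scale factor (bilinear)
#' @param img numeric matrix.
#' @param factor output size = `round(dim * factor)`.
#' @return Resized matrix.
#' @export
resize_channel <- function(img, factor) {
  stopifnot(factor > 0)
  nr2 <- max(1L, as.integer(round(nrow(img) * factor)))
  nc2 <- max(1L, as.integer(round(ncol(img) * factor)))
  # map output pixel centres onto the source grid
  xs <- matrix(rep((seq_len(nc2) - 0.5) * ncol(img) / nc2, each = nr2), nr2, nc2)
  ys <- matrix(rep((seq_len(nr2) - 0.5) * nrow(img) / nr2, times = nc2), nr2, nc2)
  out <- matrix(bilinear_sample(img, xs, ys), nr2, nc2)
  # edge samples fall half a pixel outside the source centres; clamp there
  if (anyNA(out)) {
    xs2 <- pmin(pmax(xs, 0.5), ncol(img) - 0.5)
    ys2 <- pmin(pmax(ys, 0.5), nrow(img) - 0.5)
    out[is.na(out)] <- bilinear_sample(img, xs2, ys2)[is.na(out)]
  }
  out
}
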
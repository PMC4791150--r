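# Independent oracle: explicit frequency-mask bandpass built from scratch
# (its own frequency grid and band boundaries), against which the
# package's band energies are compared.
oracle_band_energies <- function(img, band_sizes) {
  nr <- nrow(img); nc <- ncol(img)
  freq_axis <- function(n) {
    k <- seq_len(n) - 1
    k[k > n / 2] <- k[k > n / 2] - n
    k / n
  }
  fy <- freq_axis(nr); fx <- freq_axis(nc)
  fmat <- sqrt(outer(fy^2, fx^2, "+"))
  gm <- sqrt(band_sizes[-length(band_sizes)] * band_sizes[-1])
  lo_edge <- c(band_sizes[1]^2 / gm[1], gm)
  hi_edge <- c(gm, band_sizes[length(band_sizes)]^2 / gm[length(gm)])
  ft <- stats::fft(img)
  sapply(seq_along(band_sizes), function(i) {
    mask <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      f <- fmat[r, c]
      if (f > 0) {
        wl <- 1 / f
        if (wl > lo_edge[i] && wl <= hi_edge[i]) mask[r, c] <- TRUE
      }
    }
    filt <- Re(stats::fft(ft * mask, inverse = TRUE)) / (nr * nc)
    stats::sd(filt)
  })
}

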
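# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures ship with the package.

# Smooth random texture with correlation length ~L px (Gaussian-filtered
# white noise, standardised), the kind of structured scene the channel
# alignment is designed for.
smooth_texture <- function(n, seed, L = 12) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  ft <- stats::fft(z)
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  f <- sqrt(outer(fr^2, fr^2, "+"))
  x <- Re(stats::fft(ft * exp(-(f * L)^2), inverse = TRUE)) / (n * n)
  (x - mean(x)) / stats::sd(x)
}

# A pair of crops of one larger texture whose contents differ by an
# integer displacement d = c(dx, dy); aligning moving onto fixed should
# recover exactly d (content everywhere, no padded borders).
shifted_pair <- function(seed, d, n = 64, pad = 16, L = 12) {
  big <- smooth_texture(n + 2 * pad, seed, L) * 1000 + 5000
  rows <- (pad + 1):(pad + n); cols <- (pad + 1):(pad + n)
  list(fixed = big[rows, cols],
       moving = big[rows + d[2], cols + d[1]])
}

# Toy 3-sample curves on a tiny grid for hand-checked quantum catches.
toy_curve <- function(values, name = "toy") {
  spectral_curve(values, 500, 500 + length(values) - 1L, name = name)
}

# Noise-free camera for exactness tests.
quiet_camera <- function(...)
  synthetic_camera(noise_additive = 0, noise_proportional = 0, ...)

expect_warning_code <- function(expr, code)
  expect_warning(expr, class = code)
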
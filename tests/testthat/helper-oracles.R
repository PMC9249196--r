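# Independent brute-force oracles used to cross-check the package's fast
# implementations. These deliberately use naive nested loops / direct formulas
# and share no code with the implementation paths they verify.

# Polynomial multiplication oracle for 1-D linear convolution.
poly_mult_oracle <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
    }
  }
  out
}

# Direct DTFT magnitude by explicit summation over lags.
dtft_mag_oracle <- function(taps, center, omega) {
  acc <- 0 + 0i
  for (i in seq_along(taps)) {
    acc <- acc + taps[i] * exp(-1i * omega * (i - center))
  }
  Mod(acc)
}

# Brute-force 2-D convolution with symmetric padding; quadruple loop.
conv2_sym_oracle <- function(image, kernel) {
  n <- nrow(image); m <- ncol(image)
  k <- nrow(kernel); p <- (k - 1) %/% 2
  ctr <- p + 1
  reflect <- function(i, n) {
    # symmetric padding that repeats the border sample
    if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i
  }
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- 0
      for (a in -p:p) {
        for (b in -p:p) {
          ii <- reflect(i - a, n)
          jj <- reflect(j - b, m)
          s <- s + kernel[ctr + a, ctr + b] * image[ii, jj]
        }
      }
      out[i, j] <- s
    }
  }
  out
}
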
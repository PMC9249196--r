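#' One-dimensional FIR filter with an explicit zero-lag tap
#'
#' A `filter1d` holds an odd-length finite impulse response together with the
#' index of its zero-lag (center) tap. The prototype filters used to build the
#' directional bank all have coefficients that are exact multiples of 1/16, so
#' taps are stored as integer numerators over a power-of-two denominator and
#' only converted to double on demand; dyadic rationals are exact in binary
#' floating point, which keeps the downstream kernel constructions bit-exact.
#'
#' @param num integer numerators, odd length.
#' @param den common denominator (a power of two for the built-in prototypes).
#' @return A `filter1d` object: list with `taps` (double), `num`, `den`,
#'   `center` (1-based index of the zero-lag tap).
#' @export
filter1d <- function(num, den = 1L) {
  stopifnot(length(num) %% 2 == 1, den != 0)
  structure(
    list(
      taps = as.numeric(num) / as.numeric(den),
      num = as.numeric(num),
      den = as.numeric(den),
      center = (length(num) + 1L) %/% 2L
    ),
    class = "filter1d"
  )
}

#' @export
print.filter1d <- function(x, ...) {
  lags <- seq_along(x$taps) - x$center
  cat("<filter1d> ", length(x$taps), " taps, center lag 0 at index ",
      x$center, "\n", sep = "")
  cat(paste0("  h[", lags, "] = ", x$num, "/", x$den), sep = "\n")
  invisible(x)
}

#' Half-band Lagrange maximally flat lowpass prototype
#'
#' The 7th-order half-band lowpass with transfer function
#' \deqn{H_{lp}(z) = 1 + \tfrac{9}{16}(z + z^{-1}) - \tfrac{1}{16}(z^3 + z^{-3}),}
#' i.e. impulse response \{-1/16, 0, 9/16, 1, 9/16, 0, -1/16\}. Its DC gain is
#' 2 and, by the half-band property, its gain at \eqn{\omega = \pi/2} is
#' exactly 1 (half of DC).
#'
#' @return A [filter1d] with 7 taps centered at lag 0.
#' @export
#' @examples
#' h <- lagrange_halfband_lowpass()
#' sum(h$taps)  # DC gain 2
lagrange_halfband_lowpass <- function() {
  filter1d(c(-1, 0, 9, 16, 9, 0, -1), 16)
}

#' Smoothing lowpass \{1, 2, 1\}
#'
#' The short binomial lowpass convolved onto the high-pass prototype to tame
#' its gain near \eqn{\omega = \pi}, turning it into a band-pass filter.
#'
#' @return A [filter1d] with taps \{1, 2, 1\}.
#' @export
binomial_smoother <- function() filter1d(c(1, 2, 1), 1)

#' Modulate a filter to its high-pass mirror
#'
#' Applies the transformation \eqn{H_{hp}(z) = H_{lp}(-z)}, which multiplies
#' tap \eqn{h[n]} by \eqn{(-1)^n} with \eqn{n} measured from the center tap.
#'
#' @param f a [filter1d] (odd length).
#' @return A [filter1d] of the same length.
#' @export
#' @examples
#' modulate_to_highpass(lagrange_halfband_lowpass())
modulate_to_highpass <- function(f) {
  stopifnot(inherits(f, "filter1d"))
  lags <- seq_along(f$num) - f$center
  filter1d(f$num * (-1)^abs(lags), f$den)
}

#' Band-pass prototype by smoothing a high-pass filter
#'
#' Full linear convolution \eqn{h_{bp} = h_c * h_{hp}}. The output length is
#' `length(f_hp) + length(f_c) - 1` and the zero-lag position is preserved
#' (both inputs are centered, so the result is too).
#'
#' @param f_hp high-pass [filter1d].
#' @param f_c smoothing [filter1d] (defaults to [binomial_smoother()]).
#' @return A [filter1d].
#' @export
#' @examples
#' h_bp <- smooth_bandpass(modulate_to_highpass(lagrange_halfband_lowpass()))
#' h_bp$taps * 16  # 1, 2, -8, -2, 14, -2, -8, 2, 1
smooth_bandpass <- function(f_hp, f_c = binomial_smoother()) {
  stopifnot(inherits(f_hp, "filter1d"), inherits(f_c, "filter1d"))
  # exact shift-and-add convolution (FFT-based routines would break the
  # dyadic-rational exactness of the prototype coefficients)
  num <- numeric(length(f_hp$num) + length(f_c$num) - 1)
  for (j in seq_along(f_c$num)) {
    span <- j:(j + length(f_hp$num) - 1)
    num[span] <- num[span] + f_hp$num * f_c$num[j]
  }
  filter1d(num, f_hp$den * f_c$den)
}

#' The directional-bank band-pass prototype
#'
#' Convenience constructor for the 9-tap band-pass
#' \{1, 2, -8, -2, 14, -2, -8, 2, 1\}/16 obtained by modulating the half-band
#' lowpass to high-pass and smoothing with \{1,2,1\}. Its frequency response
#' has gain 2 at \eqn{\omega = \pi/2} and gain 0 at \eqn{\omega = 0} and
#' \eqn{\pi}.
#'
#' @return A [filter1d] with 9 taps.
#' @export
bandpass_prototype <- function() {
  smooth_bandpass(modulate_to_highpass(lagrange_halfband_lowpass()))
}

#' Magnitude of the frequency response by direct summation
#'
#' Evaluates \eqn{|\sum_n h[n] e^{-j\omega n}|} for a 1-D filter, or
#' \eqn{|\sum_{n_1,n_2} h[n_1,n_2] e^{-j(\omega_1 n_1 + \omega_2 n_2)}|} for a
#' 2-D kernel, with lags measured from the center tap. `n1` indexes columns
#' (the horizontal axis) and `n2` rows, matching the kernel convention of
#' [build_directional_kernel()].
#'
#' @param f a [filter1d] or a 2-D kernel matrix (as built by
#'   [build_directional_kernel()]).
#' @param omega radian frequency in \eqn{[-\pi, \pi]}; for a kernel, a length-2
#'   vector `c(omega1, omega2)`.
#' @return A tibble with columns `omega` (list-column for 2-D) and `magnitude`.
#' @export
#' @examples
#' frequency_response(bandpass_prototype(), pi / 2)$magnitude  # 2
frequency_response <- function(f, omega) {
  if (inherits(f, "filter1d")) {
    stopifnot(all(abs(omega) <= pi + 1e-12))
    lags <- seq_along(f$taps) - f$center
    mag <- vapply(
      omega,
      function(w) Mod(sum(f$taps * exp(-1i * w * lags))),
      numeric(1)
    )
    return(tibble::tibble(omega = omega, magnitude = mag))
  }
  w <- as.matrix(f)
  stopifnot(length(omega) == 2, all(abs(omega) <= pi + 1e-12))
  cr <- (nrow(w) + 1L) %/% 2L
  cc <- (ncol(w) + 1L) %/% 2L
  n2 <- row(w) - cr  # rows
  n1 <- col(w) - cc  # columns
  mag <- Mod(sum(w * exp(-1i * (omega[1] * n1 + omega[2] * n2))))
  tibble::tibble(omega = list(omega), magnitude = mag)
}
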
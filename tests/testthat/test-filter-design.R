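test_that("half-band lowpass prototype has the stated taps and gains", {
  h <- lagrange_halfband_lowpass()
  expect_s3_class(h, "filter1d")
  expect_length(h$taps, 7)
  expect_identical(h$center, 4L)
  expect_identical(h$taps, c(-1, 0, 9, 16, 9, 0, -1) / 16)
  # DC gain H(1) = 2
  expect_identical(sum(h$taps), 2)
  # half-band symmetry forces |H(pi/2)| = H(0)/2 = 1
  expect_equal(frequency_response(h, pi / 2)$magnitude, 1, tolerance = 1e-12)
})

test_that("modulation to high-pass flips alternate taps", {
  h_hp <- modulate_to_highpass(lagrange_halfband_lowpass())
  expect_identical(h_hp$taps, c(1, 0, -9, 16, -9, 0, 1) / 16)
  expect_equal(sum(h_hp$taps), 0, tolerance = 1e-15)  # H_lp(-1) = 0
  # an impulse is invariant
  expect_identical(modulate_to_highpass(filter1d(1))$taps, 1)
  # involution: modulating twice restores the filter
  expect_identical(modulate_to_highpass(h_hp)$taps,
                   lagrange_halfband_lowpass()$taps)
})

test_that("band-pass smoothing equals the polynomial-multiplication oracle", {
  h_hp <- modulate_to_highpass(lagrange_halfband_lowpass())
  h_bp <- smooth_bandpass(h_hp)
  expect_length(h_bp$taps, 9)
  expect_identical(h_bp$center, 5L)
  expect_identical(h_bp$taps, c(1, 2, -8, -2, 14, -2, -8, 2, 1) / 16)
  expect_equal(h_bp$taps, poly_mult_oracle(h_hp$taps, c(1, 2, 1)),
               tolerance = 1e-15)
  # convolving with the unit impulse is the identity
  expect_identical(smooth_bandpass(h_hp, filter1d(1))$taps, h_hp$taps)
  # random-coefficient property check against the oracle
  set.seed(11)
  for (i in 1:5) {
    a <- filter1d(rnorm(5))
    b <- filter1d(rnorm(3))
    expect_equal(smooth_bandpass(a, b)$taps, poly_mult_oracle(a$taps, b$taps),
                 tolerance = 1e-12)
  }
})

test_that("band-pass frequency response matches the published gain anchors", {
  h_bp <- bandpass_prototype()
  expect_equal(frequency_response(h_bp, pi / 2)$magnitude, 2, tolerance = 1e-12)
  expect_equal(frequency_response(h_bp, 0)$magnitude, 0, tolerance = 1e-12)
  expect_equal(frequency_response(h_bp, pi)$magnitude, 0, tolerance = 1e-12)
  # smoothing lowpass has DC gain 4 (sum of taps)
  expect_equal(frequency_response(binomial_smoother(), 0)$magnitude, 4)
  # |H| symmetric in omega; band-pass shaped (small near 0 and pi, large at
  # pi/2) on a 1024-point grid
  grid <- seq(-pi, pi, length.out = 1024)
  mags <- frequency_response(h_bp, grid)$magnitude
  expect_equal(mags, rev(mags), tolerance = 1e-10)
  expect_gt(min(frequency_response(h_bp, pi / 2)$magnitude), 1.99)
  expect_lt(max(mags[abs(grid) < 0.3]), 0.5)
  expect_lt(max(mags[abs(grid) > pi - 0.3]), 0.5)
  # cross-check a few points against the independent DTFT oracle
  for (w in c(0.3, 1.1, 2.5)) {
    expect_equal(frequency_response(h_bp, w)$magnitude,
                 dtft_mag_oracle(h_bp$taps, h_bp$center, w),
                 tolerance = 1e-12)
  }
})

test_that("directional kernels follow the sparse-rotation construction", {
  h_bp <- bandpass_prototype()
  ctr <- 5L
  k45 <- build_directional_kernel(45)
  for (k in -4:4) {
    expect_identical(k45[ctr + k, ctr + k], h_bp$taps[ctr + k])
  }
  expect_identical(sum(k45 != 0), sum(h_bp$taps != 0))
  # 90 degrees is the transpose of 0 degrees, for any prototype
  bare <- function(k) matrix(as.numeric(k), nrow(k))
  proto <- filter1d(c(1, -3, 4, -3, 1))
  expect_identical(
    bare(build_directional_kernel(90, proto, 7)),
    t(bare(build_directional_kernel(0, proto, 7)))
  )
  # slope-1/2 kernel: per-column sums reproduce the prototype exactly
  k26 <- build_directional_kernel(26.56)
  expect_identical(colSums(unclass(k26)), h_bp$taps)
  expect_identical(colSums(unclass(build_directional_kernel(-26.56))),
                   h_bp$taps)
  # slope-2 kernels: per-row sums reproduce the prototype
  expect_identical(rowSums(unclass(build_directional_kernel(63.43))),
                   h_bp$taps)
  expect_identical(rowSums(unclass(build_directional_kernel(-63.43))),
                   h_bp$taps)
  # unsupported angles are rejected
  expect_error(build_directional_kernel(30), "theta_deg")
})

test_that("default bank has 8 zero-DC kernels in the printed angle order", {
  bank <- build_bank()
  expect_length(bank, 8)
  expect_identical(attr(bank, "angles_deg"),
                   c(-63.43, -45, -26.56, 0, 26.56, 45, 63.43, 90))
  for (k in bank) expect_identical(sum(k), 0)
  # -45 kernel is the 45 kernel mirrored across the vertical axis
  bare <- function(k) matrix(as.numeric(k), nrow(k))
  k45 <- bare(bank[[which(attr(bank, "angles_deg") == 45)]])
  km45 <- bare(bank[[which(attr(bank, "angles_deg") == -45)]])
  expect_identical(km45, k45[, ncol(k45):1])
  # 7x7 variant built on the high-pass prototype stays zero-DC
  bank7 <- build_bank(prototype = modulate_to_highpass(lagrange_halfband_lowpass()))
  expect_identical(dim(bank7[[1]]), c(7L, 7L))
  for (k in bank7) expect_equal(sum(k), 0, tolerance = 1e-15)
  expect_error(build_bank(angles = c(0, 0)), "duplicate")
})

test_that("bank application equals the brute-force convolution oracle", {
  bank <- build_bank()
  set.seed(42)
  for (sz in list(c(16, 16), c(13, 21), c(32, 9))) {
    img <- matrix(runif(prod(sz)), sz[1], sz[2])
    out <- apply_bank(img, bank)
    for (ch in seq_along(bank)) {
      expect_lt(max(abs(out[, , ch] - conv2_sym_oracle(img, unclass(bank[[ch]])))),
                1e-10)
    }
  }
  # constant image: every channel is identically zero
  out <- apply_bank(matrix(0.7, 20, 20), bank)
  expect_equal(max(abs(out)), 0, tolerance = 1e-12)
  # undersized image is rejected
  expect_error(apply_bank(matrix(0, 4, 4), bank), "smaller")
})

test_that("0-degree channel zero-crosses at a vertical step edge", {
  bank <- build_bank()
  img <- cbind(matrix(0.2, 24, 12), matrix(0.8, 24, 12))  # edge between col 12/13
  out <- apply_bank(img, bank)
  row0 <- out[12, , which(attr(bank, "angles_deg") == 0)]
  # response has both signs near the edge (zero-crossing) and is large there
  near <- row0[9:16]
  expect_gt(max(near), 0.05)
  expect_lt(min(near), -0.05)
  # and decays to zero away from the edge
  expect_lt(max(abs(row0[1:5])), 1e-12)
  # the 90-degree channel sees no vertical variation anywhere
  expect_lt(max(abs(out[, , which(attr(bank, "angles_deg") == 90)])), 1e-12)
})

test_that("bank JSON serialization round-trips bit-exactly", {
  bank <- build_bank()
  path <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, path)
  back <- read_bank(path)
  expect_identical(attr(back, "angles_deg"), attr(bank, "angles_deg"))
  for (i in seq_along(bank)) {
    expect_identical(unclass(back[[i]])[, ], unclass(bank[[i]])[, ])
    expect_identical(attr(back[[i]], "angle_deg"), attr(bank[[i]], "angle_deg"))
  }
})

test_that("2-D frequency response of the vertical kernel peaks at omega2 = pi/2", {
  k90 <- build_directional_kernel(90)
  expect_equal(frequency_response(k90, c(0, pi / 2))$magnitude, 2,
               tolerance = 1e-12)
  expect_equal(frequency_response(k90, c(0, 0))$magnitude, 0, tolerance = 1e-12)
  # separability: response factorizes into the 1-D prototype response
  h_bp <- bandpass_prototype()
  for (w in c(0.4, 1.2)) {
    expect_equal(frequency_response(k90, c(0.9, w))$magnitude,
                 frequency_response(h_bp, w)$magnitude,
                 tolerance = 1e-12)
  }
})
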
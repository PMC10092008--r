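test_that("band_scales builds the octave ladder with the cap rule", {
  expect_equal(band_scales(c(64, 64), min_px = 2, max_px = 16), c(2, 4, 8, 16))
  # a 512-px image caps the ladder at 512
  expect_equal(band_scales(c(512, 512)), 2^(1:9))
  # conventional settings on a 2048-px image: 2048 exceeds the 1200-px
  # ceiling, so the ladder stops at 1024
  sc <- band_scales(c(2048, 2048))
  expect_equal(sc, 2^(1:10))
  expect_true(all(sc <= 1200))
  expect_error(band_scales(c(1, 1)), "smaller")
  expect_error(band_scales(c(64, 64), multiplier = 1), "multiplier")
})

test_that("bandpass bands are zero-mean and localise sinusoids at the right octave", {
  n <- 256
  scales <- band_scales(c(n, n), max_px = 128)
  # constant image: all bands vanish
  bands0 <- bandpass_stack(matrix(0.5, 64, 64), c(2, 4, 8))
  expect_true(all(vapply(bands0, function(b) max(abs(b)), 0) < 1e-10))

  sine <- matrix(sin(2 * pi * (1:n) / 16), n, n, byrow = TRUE)
  bands <- bandpass_stack(sine, scales)
  expect_true(all(abs(vapply(bands, mean, 0)) < 1e-10))
  en <- vapply(bands, sd, 0)
  expect_identical(names(which.max(en)), "16")

  # sum of two sinusoids: local maxima at both periods
  s2 <- matrix(sin(2 * pi * (1:n) / 4), n, n, byrow = TRUE) +
        matrix(sin(2 * pi * (1:n) / 64), n, n, byrow = TRUE)
  en2 <- vapply(bandpass_stack(s2, scales), sd, 0)
  i4 <- which(names(en2) == "4"); i64 <- which(names(en2) == "64")
  expect_gt(en2[i4], en2[i4 - 1]); expect_gt(en2[i4], en2[i4 + 1])
  expect_gt(en2[i64], en2[i64 - 1]); expect_gt(en2[i64], en2[i64 + 1])

  expect_error(bandpass_stack(matrix(c(NA, 1, 2, 3), 2, 2), c(2)), "NA")
})

test_that("pattern energies tile the variance of white noise and find sinusoid mass", {
  set.seed(2)
  n <- 256
  wn <- matrix(rnorm(n * n), n, n)
  ps <- pattern_energy_spectrum(wn, normalize = FALSE)
  expect_lt(abs(sum(ps$energies^2) - var(as.numeric(wn))) /
              var(as.numeric(wn)), 0.15)

  # constant ROI: all energies zero, normalization skipped with a flag
  expect_warning(pc <- pattern_energy_spectrum(matrix(1, 64, 64)),
                 "zero")
  expect_true(all(pc$energies == 0))
  expect_false(pc$normalized)

  # sinusoid: normalized spectrum concentrates most mass at its scale
  sine <- matrix(sin(2 * pi * (1:n) / 32), n, n, byrow = TRUE)
  pn <- pattern_energy_spectrum(sine, normalize = TRUE,
                                scales = band_scales(c(n, n)))
  expect_gt(pn$energies[["32"]], 0.5)
  expect_equal(sum(pn$energies), 1, tolerance = 1e-9)
})

test_that("ROI masking measures only the labelled pixels", {
  n <- 128
  left <- matrix(sin(2 * pi * (1:n) / 8), n, n, byrow = TRUE)
  right <- matrix(sin(2 * pi * (1:n) / 64), n, n, byrow = TRUE)
  img <- cbind(left[, 1:(n / 2)], right[, (n / 2 + 1):n])
  mask <- roi_mask(cbind(matrix(1L, n, n / 2), matrix(2L, n, n / 2)))
  sc <- band_scales(c(n, n))
  p1 <- pattern_energy_spectrum(img, mask, 1L, scales = sc, normalize = TRUE)
  p2 <- pattern_energy_spectrum(img, mask, 2L, scales = sc, normalize = TRUE)
  expect_identical(names(which.max(p1$energies)), "8")
  expect_identical(names(which.max(p2$energies)), "64")
  expect_error(pattern_energy_spectrum(img, mask, 3L, scales = sc), "empty")
})

test_that("PED is an L1 metric on matching spectra", {
  a <- make_ps(c(0.4, 0.3, 0.2, 0.1), normalized = TRUE)
  b <- make_ps(c(0.1, 0.2, 0.3, 0.4), normalized = TRUE)
  expect_equal(ped(a, a)$ped, 0)
  # direct summation oracle: |0.3|+|0.1|+|0.1|+|0.3| = 0.8
  expect_equal(ped(a, b)$ped, 0.8, tolerance = 1e-12)
  expect_equal(ped(a, b, aggregate = "mean")$ped, 0.2, tolerance = 1e-12)
  # disjoint unit-mass spectra reach the total-variation bound of 2
  d1 <- make_ps(c(1, 0, 0, 0), normalized = TRUE)
  d2 <- make_ps(c(0, 0, 0, 1), normalized = TRUE)
  expect_equal(ped(d1, d2)$ped, 2)

  # metric properties on random triples
  set.seed(9)
  for (i in 1:50) {
    e <- replicate(3, {
      v <- runif(5); v / sum(v)
    }, simplify = FALSE)
    x <- make_ps(e[[1]], normalized = TRUE)
    y <- make_ps(e[[2]], normalized = TRUE)
    z <- make_ps(e[[3]], normalized = TRUE)
    expect_gte(ped(x, y)$ped, 0)
    expect_equal(ped(x, y)$ped, ped(y, x)$ped, tolerance = 1e-12)
    expect_lte(ped(x, z)$ped, ped(x, y)$ped + ped(y, z)$ped + 1e-12)
  }

  # mismatched scales or normalization states are refused
  expect_error(ped(a, make_ps(c(0.5, 0.5), scales = c(2, 4))), "scales")
  expect_error(ped(a, make_ps(c(0.1, 0.2, 0.3, 0.4), normalized = FALSE)),
               "normalization")
})
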
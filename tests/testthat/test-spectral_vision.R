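test_that("resample_spectrum interpolates linearly and preserves integrals", {
  # constant spectrum stays constant on any grid
  s <- flat_spectrum(0.5)
  r <- resample_spectrum(s, seq(350, 650, by = 7))
  expect_true(all(r$values == 0.5))
  expect_identical(r$kind, "reflectance")

  # linear midpoint
  s2 <- spectrum(c(400, 500), c(0, 1), "reflectance")
  expect_equal(resample_spectrum(s2, 450)$values, 0.5)

  # refining a piecewise-linear spectrum leaves the trapezoid integral
  # unchanged (trapezoid is exact on linear segments)
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  wl5 <- seq(400, 600, by = 5)
  s3 <- spectrum(wl5, 0.2 + 0.003 * (wl5 - 400), "reflectance")
  wl1 <- seq(400, 600, by = 1)
  r3 <- resample_spectrum(s3, wl1)
  expect_lt(abs(trap(wl1, r3$values) - trap(wl5, s3$values)) /
              trap(wl5, s3$values), 1e-6)

  # extrapolation is refused
  expect_error(resample_spectrum(s2, c(300, 450)), "support")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(400, 400), c(1, 1)), "increasing")
  expect_error(spectrum(c(400, 500), c(-0.1, 1)), "nonnegative")
  expect_error(spectrum(c(400, 500), c(1.2, 1)), "above 1")
  expect_silent(spectrum(c(400, 500), c(1.2, 1), allow_above_one = TRUE))
  expect_error(spectrum(400:500, 1:50), "equal length")
})

test_that("quantum_catch matches trivial white/grey points and a fine-grid oracle", {
  recs <- make_recs(3)
  ill <- flat_illum()
  white <- quantum_catch(flat_spectrum(1), ill, recs, vonkries = TRUE)
  expect_equal(unname(as.numeric(white)), rep(1, 4), tolerance = 1e-12)
  expect_true(attr(white, "adapted"))

  grey <- quantum_catch(flat_spectrum(0.5), ill, recs, vonkries = TRUE)
  expect_equal(unname(as.numeric(grey)), rep(0.5, 4), tolerance = 1e-12)

  # step reflectance x Gaussian sensitivity, flat illuminant: compare the
  # 1-nm trapezoid result against an independent 0.01-nm Riemann sum on the
  # analytic integrand
  wl <- 300:700
  sens <- spectrum(wl, exp(-((wl - 560)^2) / (2 * 40^2)), "sensitivity")
  lumc <- spectrum(wl, exp(-((wl - 550)^2) / (2 * 90^2)), "sensitivity")
  other <- spectrum(wl, exp(-((wl - 450)^2) / (2 * 40^2)), "sensitivity")
  rs <- receptor_set(list(g = sens, o = other, lum = lumc), rep(1, 3),
                     weber = rep(0.05, 3), luminance_channel = "lum")
  step_refl <- spectrum(c(300, 550, 550.001, 700), c(0, 0, 1, 1),
                        "reflectance")
  q <- quantum_catch(step_refl, ill, rs, vonkries = FALSE)
  fine <- seq(550, 700, by = 0.01)
  oracle <- sum(exp(-((fine - 560)^2) / (2 * 40^2))) * 0.01
  # 1% tolerance: the 1-nm trapezoid grid smears the reflectance step over
  # one grid cell
  expect_equal(unname(q["g"]), oracle, tolerance = 1e-2)
})

test_that("von Kries adaptation removes illuminant scale and catch is linear in reflectance", {
  recs <- make_recs(2)
  r <- gen_reflectance(seed = 11)
  q1 <- quantum_catch(r, flat_illum(1), recs, vonkries = TRUE)
  q2 <- quantum_catch(r, flat_illum(37.5), recs, vonkries = TRUE)
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-12)

  # linearity without von Kries
  r1 <- gen_reflectance(seed = 12)
  r2 <- gen_reflectance(seed = 13)
  mix <- spectrum(r1$wavelengths_nm, 0.3 * r1$values + 0.6 * r2$values,
                  "reflectance")
  ill <- flat_illum()
  qm <- as.numeric(quantum_catch(mix, ill, recs, vonkries = FALSE))
  qa <- as.numeric(quantum_catch(r1, ill, recs, vonkries = FALSE))
  qb <- as.numeric(quantum_catch(r2, ill, recs, vonkries = FALSE))
  expect_equal(qm, 0.3 * qa + 0.6 * qb, tolerance = 1e-10)
})

test_that("image_to_catch applies the channel mapping per pixel", {
  chans <- list(r = matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2),
                g = matrix(c(0.1, 0.3, 0.5, 0.7), 2, 2),
                b = matrix(c(0.9, 0.8, 0.7, 0.6), 2, 2))
  # identity mapping leaves channels unchanged
  id <- diag(3)
  rownames(id) <- names(chans)
  out <- image_to_catch(chans, id, scale_px_per_mm = 10)
  expect_equal(out$channels$r, chans$r)
  expect_equal(out$channels$b, chans$b)

  # all-zero mapping is a degenerate catch
  z <- matrix(0, 2, 3)
  expect_error(image_to_catch(chans, z, 10), "degenerate")

  # random fixed 4x3 mapping equals a per-pixel dot-product oracle
  set.seed(5)
  mp <- matrix(runif(12, 0.1, 1), 4, 3)
  out2 <- image_to_catch(chans, mp, 10)
  for (i in 1:2) for (j in 1:2) {
    px <- c(chans$r[i, j], chans$g[i, j], chans$b[i, j])
    expect_equal(vapply(out2$channels, function(m) m[i, j], 0),
                 setNames(as.numeric(mp %*% px), names(out2$channels)),
                 tolerance = 1e-12)
  }

  # shape mismatch
  expect_error(image_to_catch(chans, matrix(1, 4, 2), 10), "channels")

  # negative results are clamped with a warning (r - b is negative for
  # three of the four pixels but positive for one)
  neg <- matrix(c(1, 0, -1, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rownames(neg) <- c("a", "b", "c")
  expect_warning(out3 <- image_to_catch(chans, neg, 10), "clamped")
  expect_true(all(out3$channels$a > 0))
})

test_that("roi_mean_catch averages channels over the labelled region", {
  m1 <- matrix(1:9 / 10, 3, 3)
  img <- catch_image(list(x = m1, lum = m1 * 2), 10)
  mask <- roi_mask(matrix(c(1, 1, 0, 0, 2, 2, 0, 0, 2), 3, 3))
  q <- roi_mean_catch(img, mask, 1L)
  expect_equal(unname(q["x"]), mean(m1[1:2]))
  expect_error(roi_mean_catch(img, mask, 3L), "empty")
})

test_that("spectra and catch images round-trip through their text formats", {
  tmp <- withr::local_tempdir()
  s <- gen_reflectance(seed = 4)
  write_spectrum_csv(s, file.path(tmp, "s.csv"))
  s2 <- read_spectrum_csv(file.path(tmp, "s.csv"))
  expect_equal(s2$values, s$values, tolerance = 1e-12)

  recs <- gen_receptor_set()
  write_receptor_set(recs, file.path(tmp, "recs"))
  recs2 <- read_receptor_set(file.path(tmp, "recs"))
  expect_equal(recs2$weber, recs$weber, tolerance = 1e-9)
  expect_identical(recs2$luminance_channel, recs$luminance_channel)

  m <- matrix(sample(0:2, 20, replace = TRUE), 4, 5)
  m[1] <- 1L; m[2] <- 2L
  write_pgm(m, file.path(tmp, "mask.pgm"), maxval = 2)
  expect_identical(unclass(read_mask_pgm(file.path(tmp, "mask.pgm"))),
                   matrix(as.integer(m), 4, 5))

  img <- catch_image(list(a = matrix(runif(12), 3, 4),
                          b = matrix(runif(12), 3, 4)), 7.5)
  write_catch_image_csv(img, file.path(tmp, "img"))
  img2 <- read_catch_image_csv(file.path(tmp, "img"))
  expect_equal(img2$channels$a, img$channels$a, tolerance = 1e-12)
  expect_equal(img2$scale_px_per_mm, 7.5)
})
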
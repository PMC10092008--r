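test_that("weber_fractions scales noise by inverse sqrt abundance", {
  expect_equal(weber_fractions(c(1, 1, 1), 0.05), rep(0.05, 3))
  expect_equal(weber_fractions(c(1, 4), 0.1), c(0.2, 0.1))
  # direct arithmetic oracle on blue-tit-like densities
  ab <- c(1, 1.92, 2.68, 2.7)
  expect_equal(weber_fractions(ab, 0.05), 0.05 * sqrt(2.7 / ab),
               tolerance = 1e-15)
  expect_equal(weber_fractions(ab, 0.05)[1], 0.05 * sqrt(2.7), tolerance = 1e-15)
  expect_error(weber_fractions(c(1, 0)), "positive")
  expect_error(weber_fractions(c(1, 2), -1), "positive")
})

test_that("chromatic_jnd matches the dichromat closed form and is zero for identical stimuli", {
  recs <- make_recs(2, weber = c(0.05, 0.05))
  cc <- catches_from_df(c(0.10, -0.10), recs)
  expect_equal(chromatic_jnd(cc$a, cc$b, recs), 0.20 / sqrt(0.005),
               tolerance = 1e-12)
  expect_equal(chromatic_jnd(cc$a, cc$a, recs), 0)
  # a receptor set with fewer than two chromatic channels cannot exist
  expect_error(make_recs(1), "chromatic")
})

test_that("closed-form di/tri/tetrachromat JND equals the variational form", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(2:4, 1)
    df <- rnorm(n, 0, 0.5)
    w <- runif(n, 0.02, 0.3)
    expect_equal(camoquant:::rnl_closed_form(df, w),
                 camoquant:::rnl_variational(df, w), tolerance = 1e-9)
  }
})

test_that("JNDs are symmetric, intensity-shift invariant and illuminant-scale invariant", {
  recs <- make_recs(4, weber = c(0.08, 0.06, 0.05, 0.05))
  set.seed(7)
  for (i in 1:25) {
    df <- rnorm(4, 0, 0.4)
    cc <- catches_from_df(df, recs)
    # symmetry
    expect_equal(chromatic_jnd(cc$a, cc$b, recs),
                 chromatic_jnd(cc$b, cc$a, recs), tolerance = 1e-12)
    # adding a constant to all chromatic log contrasts changes nothing
    cc2 <- catches_from_df(df + 0.37, recs)
    expect_equal(chromatic_jnd(cc$a, cc$b, recs),
                 chromatic_jnd(cc2$a, cc2$b, recs), tolerance = 1e-9)
  }
  # achromatic symmetry
  a <- catch_vector(c(c1 = 1, c2 = 1, c3 = 1, c4 = 1, lum = 0.3))
  b <- catch_vector(c(c1 = 1, c2 = 1, c3 = 1, c4 = 1, lum = 0.25))
  expect_equal(achromatic_jnd(a, b, recs), achromatic_jnd(b, a, recs))

  # full-path illuminant-scale invariance through quantum_catch
  rA <- gen_reflectance(seed = 21); rB <- gen_reflectance(seed = 22)
  for (k in c(1, 0.2, 50)) {
    qA <- quantum_catch(rA, flat_illum(k), recs)
    qB <- quantum_catch(rB, flat_illum(k), recs)
    if (k == 1) {
      base_s <- chromatic_jnd(qA, qB, recs)
      base_l <- achromatic_jnd(qA, qB, recs)
    } else {
      expect_equal(chromatic_jnd(qA, qB, recs), base_s, tolerance = 1e-12)
      expect_equal(achromatic_jnd(qA, qB, recs), base_l, tolerance = 1e-12)
    }
  }
})

test_that("achromatic_jnd is the log luminance ratio over the Weber fraction", {
  recs <- make_recs(2, weber_lum = 0.1)
  a <- catch_vector(c(c1 = 1, c2 = 1, lum = exp(1)))
  b <- catch_vector(c(c1 = 1, c2 = 1, lum = 1))
  expect_equal(achromatic_jnd(a, b, recs), 10, tolerance = 1e-12)
  expect_equal(achromatic_jnd(b, b, recs), 0)
  recs2 <- make_recs(2, weber_lum = 0.05)
  a2 <- catch_vector(c(c1 = 1, c2 = 1, lum = 0.30))
  b2 <- catch_vector(c(c1 = 1, c2 = 1, lum = 0.25))
  expect_equal(achromatic_jnd(a2, b2, recs2), log(1.2) / 0.05,
               tolerance = 1e-12)
})

test_that("rank_spectral_match orders candidates by perceptual distance", {
  recs <- make_recs(3)
  ill <- flat_illum()
  target <- gen_reflectance(seed = 31)
  cands <- c(list(target = target),
             stats::setNames(lapply(32:35, gen_reflectance),
                             paste0("c", 32:35)))
  rk <- rank_spectral_match(target, cands, ill, recs)
  expect_identical(rk$candidate[1], "target")
  expect_equal(rk$distance[1], 0, tolerance = 1e-9)

  # flat greys: candidate closer in reflectance ratio wins
  rk2 <- rank_spectral_match(flat_spectrum(0.25),
                             list(lo = flat_spectrum(0.2),
                                  hi = flat_spectrum(0.8)), ill, recs)
  expect_identical(rk2$candidate[1], "lo")

  # ranking equals a brute-force recomputation of all distances
  qt <- quantum_catch(target, ill, recs)
  dists <- vapply(cands, function(cn) {
    qc <- quantum_catch(cn, ill, recs)
    sqrt(chromatic_jnd(qt, qc, recs)^2 + achromatic_jnd(qt, qc, recs)^2)
  }, 0)
  expect_identical(rk$candidate, names(sort(dists)))
  expect_equal(sort(rk$distance), unname(sort(dists)), tolerance = 1e-12)

  expect_error(rank_spectral_match(target, list(), ill, recs), "candidate")
})
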
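test_that("generated endmember spectra satisfy the paddy-field orderings", {
  bands <- band_set()
  for (seed in c(1, 7, 23)) {
    spectra <- generate_endmember_library(seed = seed)
    expect_named(spectra, c("TL", "BL", "TP", "BP", "DS", "WS"))
    lib <- build_library(spectra, bands)
    M <- lib$matrix
    # leaf about 7% and panicle about 5% in the blue
    expect_gt(M["TL", "b490"], 0.06)
    expect_lt(M["TL", "b490"], 0.08)
    expect_gt(M["TP", "b490"], 0.04)
    expect_lt(M["TP", "b490"], 0.06)
    # top leaf brighter than top panicle in the NIR, darker in the red
    expect_true(all(M["TL", c("b800", "b900")] > M["TP", c("b800", "b900")]))
    expect_gt(M["TP", "b670"], M["TL", "b670"])
    # shaded bottom layer darker than its top layer at every band,
    # bottom leaf still brighter than bottom panicle in the NIR
    expect_true(all(M["BL", ] < M["TL", ]))
    expect_true(all(M["BP", ] < M["TP", ]))
    expect_true(all(M["BL", c("b800", "b900")] > M["BP", c("b800", "b900")]))
    # wet soil darker than dry soil at every wavelength, not just bands
    expect_true(all(spectra$WS$reflectance < spectra$DS$reflectance))
  }
})

test_that("spectral generation is deterministic in the seed", {
  expect_identical(generate_endmember_library(seed = 5),
                   generate_endmember_library(seed = 5))
  s1 <- generate_endmember_library(seed = 1)
  s2 <- generate_endmember_library(seed = 2)
  expect_false(identical(s1$TL$reflectance, s2$TL$reflectance))
})

test_that("too-narrow wavelength coverage is rejected", {
  expect_error(generate_endmember_library(seed = 1, band_range = c(500, 900)),
               "480-910")
})

test_that("band resampling averages over the closed band interval", {
  bands <- band_set()
  flat <- continuous_spectrum("flat", 400:1000, rep(0.30, 601))
  expect_equal(resample_to_bands(flat, bands), rep(0.30, 6))
  # the mean of a linear spectrum over a symmetric interval is its midpoint
  lin <- continuous_spectrum("lin", 400:1000, (400:1000) / 1000)
  expect_equal(resample_to_bands(lin, bands), bands$centers / 1000,
               tolerance = 1e-12)
})

test_that("resampling matches a dense Riemann-sum oracle", {
  set.seed(42)
  wl <- seq(450, 950, by = 1)
  for (rep in 1:5) {
    # random smooth spectrum from a coarse spline
    knots <- seq(450, 950, length.out = 12)
    sp <- stats::splinefun(knots, runif(12, 0.02, 0.6))
    s <- continuous_spectrum("s", wl, pmax(sp(wl), 0))
    bands <- band_set()
    fine <- seq(0, 1, length.out = 20001)
    oracle <- vapply(bands$centers, function(ctr) {
      x <- ctr - bands$width / 2 + fine * bands$width
      mean(stats::approx(wl, s$reflectance, xout = x)$y)
    }, numeric(1))
    expect_equal(resample_to_bands(s, bands), oracle, tolerance = 1e-6)
  }
})

test_that("resampling is linear in the spectrum", {
  wl <- 450:950
  s1 <- continuous_spectrum("a", wl, 0.1 + 0.3 * sin(wl / 60)^2)
  s2 <- continuous_spectrum("b", wl, 0.05 + (wl - 450) / 2000)
  comb <- continuous_spectrum("c", wl, 2 * s1$reflectance + 3 * s2$reflectance)
  bands <- band_set()
  expect_equal(resample_to_bands(comb, bands),
               2 * resample_to_bands(s1, bands) +
                 3 * resample_to_bands(s2, bands),
               tolerance = 1e-12)
})

test_that("resampling reports which band lacks coverage", {
  s <- continuous_spectrum("short", 500:800, rep(0.2, 301))
  expect_error(resample_to_bands(s, band_set()), "490")
})

test_that("build_library stacks per-spectrum resampling in order", {
  spectra <- generate_endmember_library(seed = 3)
  bands <- band_set()
  lib <- build_library(spectra, bands)
  expect_equal(dim(lib$matrix), c(6, 6))
  expect_identical(lib$names, names(spectra))
  for (nm in names(spectra)) {
    expect_equal(unname(lib$matrix[nm, ]),
                 resample_to_bands(spectra[[nm]], bands))
  }
  # a one-spectrum library is representable (unmixing rejects it later)
  one <- build_library(spectra["TL"], bands)
  expect_equal(dim(one$matrix), c(1, 6))
  expect_error(build_library(spectra[c(1, 1)], bands), "duplicate")
})

test_that("spectra and library CSV round trips preserve values", {
  spectra <- generate_endmember_library(seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(spectra, f)
  back <- read_spectra_csv(f)
  expect_equal(back$TL$reflectance, spectra$TL$reflectance, tolerance = 1e-12)
  lib <- build_library(spectra)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(lib, f2)
  lib2 <- read_library_csv(f2)
  expect_equal(lib2$matrix, lib$matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(lib2$bands$centers, lib$bands$centers)
})
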
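# single-pixel image with prescribed reflectance at the six default bands
px_image <- function(r490, r550, r670, r720, r800, r900 = 0.4) {
  multiband_image(array(c(r490, r550, r670, r720, r800, r900), c(1, 1, 6)),
                  band_set(), "reflectance")
}

vi_at <- function(vi, ...) compute_vi(px_image(...), vi)$values[1, 1]

test_that("index formulas match an independent transcription", {
  set.seed(21)
  for (rep in 1:25) {
    r <- runif(6, 0.01, 0.9)
    img <- px_image(r[1], r[2], r[3], r[4], r[5], r[6])
    oracle <- c(
      SR = r[5] / r[3],
      CIrededge = r[5] / r[4] - 1,
      CIgreen = r[5] / r[2] - 1,
      NDVI = (r[5] - r[3]) / (r[5] + r[3]),
      GNDVI = (r[5] - r[2]) / (r[5] + r[2]),
      NDRE = (r[5] - r[4]) / (r[5] + r[4]),
      VARI = (r[2] - r[3]) / (r[2] + r[3]),
      MTCI = (r[5] - r[4]) / (r[4] - r[3]),
      EVI = 2.5 * (r[5] - r[3]) / (r[5] + 6 * r[3] - 7.5 * r[1] + 1),
      EVI2 = 2.5 * (r[5] - r[3]) / (r[5] + 2.4 * r[3] + 1)
    )
    for (nm in vi_names()) {
      expect_equal(compute_vi(img, nm)$values[1, 1], unname(oracle[nm]),
                   tolerance = 1e-12, label = nm)
    }
  }
})

test_that("simple index identities hold", {
  expect_equal(vi_at("NDVI", 0.1, 0.2, 0.1, 0.3, 0.5), 0.4 / 0.6,
               tolerance = 1e-12)
  # equal NIR and red-edge bands zero out the red-edge indices
  expect_equal(vi_at("NDRE", 0.1, 0.2, 0.1, 0.4, 0.4), 0)
  expect_equal(vi_at("CIrededge", 0.1, 0.2, 0.1, 0.4, 0.4), 0)
  set.seed(8)
  for (rep in 1:20) {
    r <- runif(6, 0.05, 0.8)
    ndvi <- vi_at("NDVI", r[1], r[2], r[3], r[4], r[5], r[6])
    sr <- vi_at("SR", r[1], r[2], r[3], r[4], r[5], r[6])
    expect_equal(sr, (1 + ndvi) / (1 - ndvi), tolerance = 1e-10)
    # normalised-difference indices stay within [-1, 1]
    for (nm in c("NDVI", "GNDVI", "NDRE", "VARI")) {
      v <- vi_at(nm, r[1], r[2], r[3], r[4], r[5], r[6])
      expect_true(v >= -1 && v <= 1, label = nm)
    }
  }
  # NDVI strictly increases with NIR at fixed red
  nir <- seq(0.2, 0.8, by = 0.1)
  vals <- vapply(nir, function(n) vi_at("NDVI", 0.1, 0.2, 0.1, 0.3, n),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("near-zero denominators are masked, not propagated", {
  # soil-like pixel: red-edge equals red, MTCI denominator vanishes
  img <- px_image(0.1, 0.15, 0.25, 0.25, 0.3)
  out <- compute_vi(img, "MTCI")
  expect_false(out$valid[1, 1])
  expect_true(is.na(out$values[1, 1]))
  ok <- compute_vi(img, "NDVI")
  expect_true(ok$valid[1, 1])
})

test_that("unknown indices and missing bands are reported", {
  img <- px_image(0.1, 0.2, 0.1, 0.3, 0.5)
  expect_error(compute_vi(img, "WDRVI"), "unknown")
  img3 <- multiband_image(array(0.2, c(1, 1, 3)),
                          band_set(c(490, 550, 670)), "reflectance")
  expect_error(compute_vi(img3, "NDVI"), "800")
  expect_error(compute_vi(multiband_image(array(1, c(1, 1, 6)), band_set(),
                                          "dn"), "NDVI"), "reflectance")
})

test_that("plot aggregation averages only valid pixels", {
  # 2 x 4 image; right half has a vanishing NDVI denominator
  v <- array(0, c(2, 4, 6))
  v[, 1:2, 3] <- 0.1; v[, 1:2, 5] <- 0.5   # NDVI = 2/3
  v[, 3:4, 3] <- 0.0; v[, 3:4, 5] <- 0.0   # masked
  img <- multiband_image(v, band_set(), "reflectance")
  out <- compute_vi(img, "NDVI")
  layout <- plot_layout("p1", 0, list(c(0, 0, 2, 4)))
  agg <- aggregate_vi(out, layout)
  expect_equal(agg$NDVI, 2 / 3, tolerance = 1e-12)
  expect_equal(agg$invalid_frac, 0.5)
  # uniform index aggregates to the constant, within [min, max]
  v[, , 3] <- 0.1; v[, , 5] <- 0.5
  u <- compute_vi(multiband_image(v, band_set(), "reflectance"), "NDVI")
  expect_equal(aggregate_vi(u, layout)$NDVI, 2 / 3, tolerance = 1e-12)
  # a fully masked region is an error
  v[, , 5] <- 0.1  # NDVI denominator 0.2, fine; force masking via MTCI
  v[, , 4] <- v[, , 3]
  m <- compute_vi(multiband_image(v, band_set(), "reflectance"), "MTCI")
  expect_error(aggregate_vi(m, layout), "no valid")
})

test_that("plot means lie inside the range of their pixels", {
  set.seed(13)
  v <- array(runif(8 * 10 * 6, 0.05, 0.7), c(8, 10, 6))
  img <- multiband_image(v, band_set(), "reflectance")
  layout <- plot_layout(c("a", "b"), c(0, 3),
                        list(c(0, 0, 4, 5), c(4, 5, 4, 5)))
  for (nm in c("NDVI", "SR", "EVI")) {
    out <- compute_vi(img, nm)
    agg <- aggregate_vi(out, layout)
    expect_gte(agg[[nm]][1], min(out$values[1:4, 1:5]))
    expect_lte(agg[[nm]][1], max(out$values[1:4, 1:5]))
  }
})
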
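test_that("pure endmember spectra unmix to abundance one", {
  lib <- default_library()
  for (nm in lib$names) {
    res <- fcls_pixel(lib$matrix[nm, ], lib)
    expect_equal(unname(res$abundances[nm]), 1, tolerance = 1e-6)
    expect_equal(sum(res$abundances), 1, tolerance = 1e-12)
    expect_lt(res$residual_norm, 1e-8)
  }
})

test_that("exact binary mixtures are recovered exactly", {
  lib <- default_library()
  pairs <- list(c("TL", "DS"), c("TP", "WS"), c("BL", "TP"))
  for (p in pairs) {
    mix <- 0.5 * lib$matrix[p[1], ] + 0.5 * lib$matrix[p[2], ]
    res <- fcls_pixel(mix, lib)
    expect_equal(unname(res$abundances[p]), c(0.5, 0.5), tolerance = 1e-6)
    expect_equal(sum(res$abundances[setdiff(lib$names, p)]), 0,
                 tolerance = 1e-6)
    expect_lt(res$residual_norm, 1e-8)
  }
})

test_that("solver objective never exceeds the simplex-grid oracle", {
  set.seed(101)
  lib6 <- default_library()
  lib3 <- endmember_library(lib6$names[c(1, 3, 5)],
                            lib6$matrix[c(1, 3, 5), ], lib6$bands)
  for (rep in 1:50) {
    mx <- random_mixture(lib3)
    res <- fcls_pixel(mx$spectrum, lib3)
    obj <- res$residual_norm^2
    expect_lte(obj, grid_min_objective(mx$spectrum, lib3, 0.01) + 1e-5)
    expect_true(all(res$abundances >= -1e-9 & res$abundances <= 1 + 1e-9))
    expect_equal(sum(res$abundances), 1, tolerance = 1e-6)
  }
  for (rep in 1:10) {
    mx <- random_mixture(lib6)
    res <- fcls_pixel(mx$spectrum, lib6)
    expect_lte(res$residual_norm^2,
               grid_min_objective(mx$spectrum, lib6, 0.02) + 1e-5)
  }
})

test_that("reordering library rows permutes abundances identically", {
  lib <- default_library()
  perm <- c(4, 1, 6, 2, 5, 3)
  plib <- endmember_library(lib$names[perm], lib$matrix[perm, ], lib$bands)
  set.seed(5)
  for (rep in 1:20) {
    mx <- random_mixture(lib)
    a <- fcls_pixel(mx$spectrum, lib)$abundances
    b <- fcls_pixel(mx$spectrum, plib)$abundances
    expect_equal(unname(b), unname(a[perm]), tolerance = 1e-9)
  }
})

test_that("FCLS equals sum-to-one-constrained LS when that is feasible", {
  lib <- default_library()
  E <- t(lib$matrix)  # bands x endmembers
  set.seed(9)
  found <- 0
  for (rep in 1:50) {
    mx <- random_mixture(lib, noise_sd = 0.001)
    # equality-constrained LS via KKT system (independent of the solver)
    N <- ncol(E)
    K <- rbind(cbind(2 * crossprod(E), rep(1, N)), c(rep(1, N), 0))
    sol <- solve(K, c(2 * crossprod(E, mx$spectrum), 1))[1:N]
    if (all(sol >= 0)) {
      found <- found + 1
      res <- fcls_pixel(mx$spectrum, lib)
      expect_equal(res$residual_norm,
                   sqrt(sum((mx$spectrum - E %*% sol)^2)), tolerance = 1e-8)
      expect_equal(unname(res$abundances), unname(sol), tolerance = 1e-6)
    }
  }
  expect_gte(found, 5)  # the check must actually have exercised cases
})

test_that("unmix_image maps planes in library order over every pixel", {
  lib <- default_library()
  v <- array(rep(lib$matrix["WS", ], each = 12), c(3, 4, 6))
  img <- multiband_image(v, lib$bands, "reflectance")
  am <- unmix_image(img, lib)
  expect_equal(dim(am$values), c(3, 4, 6))
  expect_identical(am$names, lib$names)
  expect_equal(max(abs(am$values[, , 6] - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(am$values[, , 1:5])), 0, tolerance = 1e-6)
})

test_that("a noiseless synthetic scene is unmixed back to its truth", {
  cfg <- noiseless_scene_config(seed = 2)
  sc <- generate_scene(cfg)
  refl <- apply_calibration(sc$dn_image, fit_empirical_line(sc$dn_image,
                                                            sc$panels))
  am <- unmix_image(refl, sc$library)
  rows <- below_panel_rows(cfg, refl)
  expect_lt(max(abs(am$values[rows, , ] - sc$true_abundance$values[rows, , ])),
            1e-6)
})

test_that("plot aggregation equals a direct masked-mean oracle", {
  set.seed(3)
  vals <- array(stats::rgamma(5 * 8 * 6, 1), c(5, 8, 6))
  tot <- array(rowSums(matrix(vals, ncol = 6)), c(5, 8))
  for (k in 1:6) vals[, , k] <- vals[, , k] / tot
  am <- abundance_map(vals, matrix(0, 5, 8),
                      c("TL", "BL", "TP", "BP", "DS", "WS"))
  layout <- plot_layout(c("a", "b"), c(0, 5),
                        list(c(0, 0, 3, 4), c(2, 4, 3, 4)))
  agg <- aggregate_abundance(am, layout)
  expect_equal(agg$TL[1], mean(vals[1:3, 1:4, 1]), tolerance = 1e-12)
  expect_equal(agg$BP[2], mean(vals[3:5, 5:8, 4]), tolerance = 1e-12)
  expect_equal(agg$Abd_L, agg$TL + agg$BL, tolerance = 1e-12)
  expect_equal(agg$Abd_P, agg$TP + agg$BP, tolerance = 1e-12)
  expect_equal(agg$Abd_LP, agg$Abd_L - agg$Abd_P, tolerance = 1e-12)
  # leaf + panicle + soil close the per-plot abundance budget
  expect_equal(agg$Abd_L + agg$Abd_P + agg$DS + agg$WS, rep(1, 2),
               tolerance = 1e-6)
  expect_true(all(agg$Abd_LP >= -1 & agg$Abd_LP <= 1))
})

test_that("a uniform abundance map aggregates to its constants", {
  vals <- array(rep(c(0.60, 0.33, 0.04, 0.02, 0.005, 0.005), each = 24),
                c(4, 6, 6))
  am <- abundance_map(vals, matrix(0, 4, 6),
                      c("TL", "BL", "TP", "BP", "DS", "WS"))
  layout <- plot_layout("p1", 8.5, list(c(0, 0, 4, 6)))
  agg <- aggregate_abundance(am, layout)
  expect_equal(agg$Abd_L, 0.93, tolerance = 1e-12)
  expect_equal(agg$Abd_P, 0.06, tolerance = 1e-12)
})

test_that("invalid unmixing inputs are rejected", {
  lib <- default_library()
  one <- endmember_library("TL", lib$matrix[1, , drop = FALSE], lib$bands)
  expect_error(fcls_pixel(lib$matrix[1, ], one), "at least 2")
  expect_error(fcls_pixel(c(0.1, 0.2), lib), "does not match")
  expect_error(fcls_pixel(c(0.1, NA, 0.3, 0.2, 0.5, 0.4), lib), "finite")
  img <- multiband_image(array(0.2, c(2, 2, 3)), band_set(c(550, 670, 800)),
                         "reflectance")
  expect_error(unmix_image(img, lib), "does not match")
})
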
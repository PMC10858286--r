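frac_grid <- function(v, nlon = 2) c4grid(matrix(v, 1, nlon), 0,
                                          seq(-10, by = 10, length.out = nlon))

test_that("two-product combination has the enumerable bootstrap limit", {
  a <- frac_grid(c(0.4, 0.3))
  b <- frac_grid(c(0.6, 0.3))
  cmb <- combine_grassland_fraction(a, b, n_boot = 4000, seed = 2)
  expect_equal(cmb$fraction$values[1, ], c(0.5, 0.3))
  # identical products: no uncertainty
  expect_equal(cmb$sd$values[1, 2], 0)
  # two-outcome draw: sd -> |a-b|/2 = 0.1 as draws grow
  expect_equal(cmb$sd$values[1, 1], 0.1, tolerance = 0.01)
  # fixed seed reproduces the sd grid exactly
  cmb2 <- combine_grassland_fraction(a, b, n_boot = 4000, seed = 2)
  expect_identical(cmb$sd$values, cmb2$sd$values)
  expect_error(combine_grassland_fraction(a, frac_grid(c(0.1, 0.2, 0.3), 3)),
               "grassland product")
  expect_error(combine_grassland_fraction(frac_grid(c(1.4, 0)), b), "\\[0, 1\\]")
})

test_that("grass abundance multiplies coverage into land-surface share with quadrature errors", {
  cov <- frac_grid(c(50, 40))
  cov_sd <- frac_grid(c(5, 0))       # 10% relative on cell 1
  fr <- frac_grid(c(0.4, 0))
  fr_sd <- frac_grid(c(0.04, 0))     # 10% relative on cell 1
  ab <- grass_abundance(cov, cov_sd, fr, fr_sd)
  expect_equal(ab$abundance$values[1, 1], 20)   # 50% of 40% of land
  expect_equal(ab$sd$values[1, 1], 20 * sqrt(2) * 0.1, tolerance = 1e-10)
  # zero fraction -> zero abundance with zero sd
  expect_equal(ab$abundance$values[1, 2], 0)
  expect_equal(ab$sd$values[1, 2], 0)
  expect_true(all(ab$abundance$values <= 100 * fr$values))
})

test_that("crop abundance carries the flat 10% uncertainty", {
  ab <- crop_abundance(frac_grid(c(0.05, 0)))
  expect_equal(ab$abundance$values[1, ], c(5, 0))
  expect_equal(ab$sd$values[1, ], c(0.5, 0))
})

test_that("total abundance is additive with quadrature uncertainty", {
  g <- grass_abundance(frac_grid(c(50, 40)), frac_grid(c(3, 4)),
                       frac_grid(c(0.4, 0.5)), frac_grid(c(0, 0)))
  c <- crop_abundance(frac_grid(c(0.05, 0.1)))
  tot <- total_abundance(g, c)
  expect_equal(tot$abundance$values,
               g$abundance$values + c$abundance$values)
  expect_equal(tot$sd$values,
               sqrt(g$sd$values^2 + c$sd$values^2))
})

test_that("global summary weights by area and converts to absolute area", {
  # uniform 10% over the mask
  g <- global_grid(30, fill = 10)
  ab <- structure(list(abundance = g, sd = global_grid(30, fill = 1),
                       component = "grass", year = NA),
                  class = "c4_abundance")
  s <- global_summary(ab)
  expect_equal(s$pct, 10)
  expect_equal(s$sd_pct, 1)
  # 10% of Earth's surface in million km2
  expect_equal(s$area_mkm2, 0.10 * 4 * pi * 6371^2 / 1e6, tolerance = 1e-6)
  # two equal-area equatorial cells 0 and 20 -> 10
  two <- c4grid(matrix(c(0, 20), 1, 2), 0, c(-90, 90))
  expect_equal(global_summary(two)$pct, 10)
  empty_mask <- grid_like(g, 0)
  expect_error(global_summary(ab, empty_mask), "mask")
})

test_that("synergy classes split the constructed four-class fixture evenly", {
  fx <- synergy_fixture()
  ch <- change_and_synergy(fx$early_grass, fx$early_crop,
                           fx$late_grass, fx$late_crop)
  expect_equal(ch$n_eligible, 4)
  expect_equal(ch$synergy_fractions, rep(0.25, 4))
  expect_equal(sum(ch$synergy_fractions), 1)
  expect_equal(ch$synergy_labels, c("++", "--", "+-", "-+"))
})

test_that("synergy eligibility excludes crop-free cells and handles uniform change", {
  fx <- synergy_fixture()
  # remove crops from one cell entirely
  fx$early_crop$abundance$values[1, 1] <- 0
  fx$late_crop$abundance$values[1, 1] <- 0
  ch <- change_and_synergy(fx$early_grass, fx$early_crop,
                           fx$late_grass, fx$late_crop)
  expect_equal(ch$n_eligible, 3)
  expect_equal(sum(ch$synergy_fractions), 1)
  # all cells grass down, crop up -> class -+ has share 1
  fx2 <- synergy_fixture()
  fx2$late_grass$abundance$values[] <- 8
  fx2$late_crop$abundance$values[] <- 6
  ch2 <- change_and_synergy(fx2$early_grass, fx2$early_crop,
                            fx2$late_grass, fx2$late_crop)
  expect_equal(ch2$synergy_fractions[ch2$synergy_labels == "-+"], 1)
})

test_that("driver attribution isolates a CO2-only change exactly", {
  lat <- c(15, 5); lon <- c(-5, 5)
  mk <- function(v, nm = "x") c4grid(matrix(v, 2, 2), lat, lon, nm)
  base <- list(tair = mk(c(28, 30, 27, 29)), vpd = mk(rep(1.5, 4)),
               par = mk(rep(1400, 4)), co2 = mk(rep(370, 4)),
               psi_soil = mk(rep(-0.4, 4)), mask = mk(rep(1, 4)))
  target <- base
  target$co2 <- mk(rep(410, 4))
  fit <- fit_coverage_curve(logistic_pairs(), n_boot = 30, seed = 6)
  fr <- mk(rep(0.5, 4)); fr_sd <- mk(rep(0, 4))
  att <- attribute_change(base, target, fit, fr, fr_sd)
  # CO2 replacement reproduces the full change; other drivers change nothing
  expect_equal(att$drivers$co2$delta_pct, att$full_delta, tolerance = 1e-10)
  expect_equal(att$drivers$tair$delta_pct, 0)
  expect_equal(att$drivers$vpd$delta_pct, 0)
  expect_equal(att$drivers$psi_soil$delta_pct, 0)
  expect_equal(att$interaction_residual,
               att$full_delta - att$sum_single, tolerance = 1e-12)
  # elevated CO2 reduces the C4 grass share
  expect_lt(att$drivers$co2$delta_pct, 0)
  # replacing a driver with identical values is exactly zero everywhere
  att0 <- attribute_change(base, base, fit, fr, fr_sd)
  for (d in names(att0$drivers))
    expect_equal(att0$drivers[[d]]$delta_pct, 0)
})
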
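test_that("synthetic truth rejects unknown fields and accepts overrides", {
  expect_error(synth_truth(not_a_field = 1), "unknown truth")
  t2 <- synth_truth(co2_trend = 3)
  expect_equal(t2$co2_trend, 3)
  expect_equal(synth_truth()$conversion_slope, 1.51)
})

test_that("climate generator is deterministic with exact configured trends", {
  truth <- synth_truth()
  a <- generate_climate_grid(truth, seed = 4, years = c(2001, 2019))
  b <- generate_climate_grid(truth, seed = 4, years = c(2001, 2019))
  for (f in names(a$climate[[1]]))
    expect_identical(a$climate[[1]][[f]]$values, b$climate[[1]][[f]]$values)
  # +2 ppm/yr -> 2019 minus 2001 = 36 ppm in every cell
  expect_equal(unique(as.vector(a$climate[[2]]$co2$values -
                                  a$climate[[1]]$co2$values)), 36)
  # equator warmer than 60 degrees in every year
  for (i in 1:2) {
    tv <- a$climate[[i]]$tair$values
    lat <- a$climate[[i]]$tair$lat
    expect_gt(mean(tv[which.min(abs(lat)), ]), mean(tv[which.min(abs(lat - 60)), ]))
  }
  # growing-season mask excludes high latitudes
  m <- a$climate[[1]]$mask
  expect_true(all(m$values[abs(m$lat) > 66, ] == 0))
  # soil water potential respects the floor
  psi <- a$climate[[1]]$psi_soil$values
  expect_true(all(psi >= -3 & psi <= 0))
})

test_that("observation generator closes the loop through the estimators", {
  truth <- synth_truth()
  clim <- generate_climate_grid(truth, seed = 6, years = 2010)
  ratio <- ac_ratio_grid(clim$climate[[1]])$ratio
  obs <- generate_observations(truth, ratio, seed = 6)
  # reproducible under the same seed
  obs2 <- generate_observations(truth, ratio, seed = 6)
  expect_identical(obs$plot_pairs, obs2$plot_pairs)
  expect_identical(obs$occurrences, obs2$occurrences)
  # contamination is removed exactly by the filter
  kept <- filter_records(obs$occurrences)
  expect_equal(sum(attr(kept, "removed")),
               sum(obs$occurrences$woody | obs$occurrences$crop))
  expect_false(any(kept$woody | kept$crop))
  # noise-free observations recover the true curve near-exactly
  truth0 <- synth_truth(dg_noise_sd = 0)
  obs0 <- generate_observations(truth0, ratio, seed = 6)
  fit0 <- fit_coverage_curve(obs0$dg, n_boot = 30, seed = 1)
  expect_equal(unname(fit0$coef["a"]), truth0$curve_a, tolerance = 0.05)
  expect_equal(unname(fit0$coef["b"]), truth0$curve_b, tolerance = 0.05)
  # plot pairs stay inside percentage bounds
  expect_true(all(obs$plot_pairs$cover_pct >= 0 & obs$plot_pairs$cover_pct <= 100))
})

test_that("fraction products bracket their truth and expand the crop area", {
  truth <- synth_truth()
  fr <- generate_fraction_products(truth, seed = 8, years = c(2001, 2019))
  for (g in list(fr$product_a, fr$product_b, fr$grass_truth))
    expect_true(all(g$values >= 0 & g$values <= 1, na.rm = TRUE))
  # zero disagreement and noise -> identical products, zero combined sd
  truth0 <- synth_truth(grass_frac_disagreement = 0, grass_frac_noise = 0)
  fr0 <- generate_fraction_products(truth0, seed = 8, years = 2001)
  expect_identical(fr0$product_a$values, fr0$product_b$values)
  cmb0 <- combine_grassland_fraction(fr0$product_a, fr0$product_b,
                                     n_boot = 100, seed = 1)
  expect_true(all(cmb0$sd$values == 0, na.rm = TRUE))
  # crop series hits the configured 2001 and 2019 global means
  mask <- grid_like(fr$grass_truth, !is.na(fr$grass_truth$values) * 1)
  crop01 <- global_summary(crop_abundance(fr$crop[["2001"]]), mask)$pct
  crop19 <- global_summary(crop_abundance(fr$crop[["2019"]]), mask)$pct
  expect_equal(crop01, truth$crop_pct_2001, tolerance = 0.02)
  expect_equal(crop19, truth$crop_pct_2019, tolerance = 0.02)
})

test_that("ensemble generator honors its configured lines and contracts", {
  truth <- synth_truth()
  ens <- generate_dgvm_ensemble(truth, seed = 12, years = 2001)
  expect_equal(sum(ens$component == "grass"), 11)
  expect_equal(sum(ens$component == "crop"), 7)   # fewer members model crops
  # areas span the configured inter-model range
  gr <- ens[ens$component == "grass", ]
  expect_equal(range(gr$area_pct), truth$constraint$grass$area_range,
               tolerance = 0.15)
  # zero scatter reproduces the true slope exactly through the fit
  truth0 <- synth_truth(constraint = local({
    cc <- synth_truth()$constraint; cc$grass$scatter <- 0; cc
  }))
  ens0 <- generate_dgvm_ensemble(truth0, seed = 12, years = 2001)
  fit0 <- fit_constraint(ens0[ens0$component == "grass", ], n_boot = 50,
                         seed = 1)
  expect_equal(fit0$slope, 1.11)
  # a 4-member ensemble is accepted, 3 rejected
  small <- ens0[ens0$component == "grass", ][1:4, ]
  expect_s3_class(fit_constraint(small, n_boot = 20, seed = 1),
                  "c4_constraint")
  expect_error(fit_constraint(small[1:3, ]), ">= 4")
})
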
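test_that("soil water retention follows the Clapp-Hornberger closed form", {
  tex <- soil_texture(theta_sat = 0.45, psi_sat = -0.002, b_ch = 4)
  # saturation identity
  expect_equal(soil_water_potential(0.45, tex), -0.002)
  # theta/theta_sat = 0.5 -> -0.002 * 0.5^-4 = -0.032 MPa
  expect_equal(soil_water_potential(0.225, tex), -0.002 * 0.5^-4)
  expect_equal(soil_water_potential(0.225, tex), -0.032)
  # deep dry end hits the -3 MPa growth floor
  tex6 <- soil_texture(0.45, -0.002, 6)
  expect_equal(soil_water_potential(0.05 * 0.45, tex6), -3)
  # above saturation clips to saturation
  expect_equal(soil_water_potential(0.6, tex), -0.002)
  expect_error(soil_water_potential(0, tex), "theta")
  expect_error(soil_texture(theta_sat = 0), "theta_sat")
  # floor property on a sweep
  theta <- seq(0.01, 0.6, by = 0.01)
  psi <- soil_water_potential(theta, tex6)
  expect_true(all(psi >= -3 & psi <= 0))
})

test_that("understory light follows Beer's law and its bounds", {
  expect_equal(understory_par(1000, 0), 1000)
  expect_equal(understory_par(1000, 2, 0.5), 1000 * exp(-1))
  expect_equal(understory_par(1000, 4, 0.5), 1000 * exp(-2))
  expect_lt(understory_par(1000, 4, 0.5), understory_par(1000, 2, 0.5))
  expect_error(understory_par(1000, -1), "lai")
  lai <- seq(0, 8, by = 0.5)
  u <- understory_par(1000, lai)
  expect_true(all(u >= 0 & u <= 1000))
  expect_true(all(u[-1] < 1000))  # equality only at lai = 0
})

test_that("nitrogen maps to capacity with the pathway Jmax/Vcmax ratios", {
  z <- nitrogen_to_capacity(0, "C3")
  expect_equal(unlist(z), c(vcmax25 = 0, jmax25 = 0))
  for (n in c(0.5, 1.7, 3)) {
    c3 <- nitrogen_to_capacity(n, "C3")
    c4 <- nitrogen_to_capacity(n, "C4")
    expect_equal(c3$jmax25 / c3$vcmax25, 2.1)
    expect_equal(c4$jmax25 / c4$vcmax25, 5.0)
  }
  n <- seq(0, 4, by = 0.5)
  expect_true(all(diff(nitrogen_to_capacity(n, "C3")$vcmax25) >= 0))
  expect_error(nitrogen_to_capacity(1, "CAM"), "arg")
})

test_that("C3 assimilation honors compensation and dark limits", {
  p <- photo_params("C3")
  env <- make_env(tair = 25)
  # gross assimilation is zero exactly at the compensation point
  gamma25 <- 42.75  # at 25 C the Arrhenius factor is 1
  rd25 <- p$rd25
  expect_equal(c3_assimilation(gamma25, env, p), -rd25)
  # dark limit: par -> 0 gives A -> -Rd at any ci
  dark <- make_env(tair = 25, par = 0)
  for (ci in c(100, 280, 600))
    expect_equal(c3_assimilation(ci, dark, p), -rd25)
  expect_error(c3_assimilation(-5, env, p), "ci")
  expect_error(c3_assimilation(100, env, photo_params("C4")), "C3")
})

test_that("C3 sub-rates match independent closed-form evaluation", {
  p <- photo_params("C3")
  env <- make_env(tair = 30, par = 1800)
  # independent evaluation of each limitation at 30 C
  arrh <- function(ea) exp(ea * 5 / (298.15 * 8.314 * 303.15))
  peak <- function(ea) {
    num <- 1 + exp((298.15 * 640 - 2e5) / (298.15 * 8.314))
    den <- 1 + exp((303.15 * 640 - 2e5) / (303.15 * 8.314))
    arrh(ea) * num / den
  }
  vc <- 50 * peak(65330); jm <- 105 * peak(43540)
  kc <- 404.9 * arrh(79430); ko <- 278.4 * arrh(36380)
  gs <- 42.75 * arrh(37830); rd <- 0.75 * arrh(46390)
  ipar <- 0.3 * 1800
  j <- (ipar + jm - sqrt((ipar + jm)^2 - 4 * 0.7 * ipar * jm)) / (2 * 0.7)
  for (ci in c(150, 300, 2000)) {
    wc <- vc * (ci - gs) / (ci + kc * (1 + 210 / ko))
    wj <- (j / 4) * (ci - gs) / (ci + 2 * gs)
    expect_equal(c3_assimilation(ci, env, p), min(wc, wj) - rd,
                 tolerance = 1e-12)
  }
  # saturating ci and par: A approaches the smaller saturated sub-rate
  # (at Jmax/Vcmax = 2.1 that is the RuBP-regeneration ceiling Jmax/4)
  sat <- c3_assimilation(1e5, make_env(tair = 30, par = 1e5), p)
  expect_equal(sat, min(vc, jm / 4) - rd, tolerance = 0.02)
  expect_lt(sat, vc - rd)
})

test_that("C4 assimilation is PEP-limited at low ci and CO2-saturated at ambient", {
  p <- photo_params("C4")
  env <- make_env(tair = 30, par = 1800)
  rd30 <- p$rd25 * 2^0.5 / (1 + exp(1.3 * (30 - 55)))  # independent closed form
  # dark limit
  expect_equal(c4_assimilation(300, make_env(tair = 30, par = 0), p), -rd30)
  # very small ci: matches the isolated PEP-limited branch kp(T) * ci - Rd
  kp30 <- p$kp25 * 2^0.5
  for (ci in c(1, 3, 8))
    expect_equal(c4_assimilation(ci, env, p), kp30 * ci - rd30)
  # CO2 saturation: doubling ambient-range ci changes A by < 5%
  a1 <- c4_assimilation(250, env, p)
  a2 <- c4_assimilation(500, env, p)
  expect_lt(abs(a2 - a1) / a1, 0.05)
  expect_error(c4_assimilation(100, env, photo_params("C3")), "C4")
})
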
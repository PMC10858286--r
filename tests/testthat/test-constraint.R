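exact_ensemble <- function(slope = 1.1, intercept = 0, n = 8) {
  area <- seq(7, 23, length.out = n)
  data.frame(model = sprintf("m%d", seq_len(n)), area_pct = area,
             gpp_pct = intercept + slope * area)
}

test_that("exact ensembles give exact slopes with zero bootstrap error", {
  fit <- fit_constraint(exact_ensemble(slope = 1.1), n_boot = 200, seed = 3)
  expect_equal(fit$slope, 1.1)
  expect_equal(fit$se_slope, 0)
  expect_equal(fit$r, 1)
  # identity ensemble
  fid <- fit_constraint(exact_ensemble(slope = 1), n_boot = 100, seed = 3)
  expect_equal(fid$slope, 1)
  expect_equal(predict(fid, 15), 15)
})

test_that("constraint fit validates ensemble size and spread", {
  expect_error(fit_constraint(exact_ensemble(n = 3)), ">= 4")
  deg <- exact_ensemble(n = 6)
  deg$area_pct <- 10
  expect_error(fit_constraint(deg), "degenerate")
  dup <- exact_ensemble(n = 6)
  dup$model[2] <- dup$model[1]
  expect_error(fit_constraint(dup), "duplicated")
})

test_that("synthetic 11-model ensemble recovers its true slope within 2 se", {
  set.seed(41)
  pts <- exact_ensemble(slope = 1.10, n = 11)
  pts$gpp_pct <- pts$gpp_pct + rnorm(11, 0, 1.5)
  fit <- fit_constraint(pts, n_boot = 1000, seed = 8)
  expect_lt(abs(fit$slope - 1.10), 2 * fit$se_slope)
  expect_lt(fit$p, 0.01)
})

test_that("slope estimator is scale-consistent", {
  set.seed(13)
  pts <- exact_ensemble(slope = 1.2, n = 9)
  pts$gpp_pct <- pts$gpp_pct + rnorm(9, 0, 1)
  f1 <- fit_constraint(pts, n_boot = 50, seed = 1)
  pts2 <- pts
  pts2$area_pct <- pts2$area_pct * 3
  f2 <- fit_constraint(pts2, n_boot = 50, seed = 1)
  expect_equal(f2$slope, f1$slope / 3, tolerance = 1e-10)
})

test_that("bootstrap se shrinks with ensemble size", {
  se_for <- function(n) {
    set.seed(101)
    pts <- exact_ensemble(slope = 1.1, n = n)
    pts$gpp_pct <- pts$gpp_pct + rnorm(n, 0, 1.5)
    fit_constraint(pts, n_boot = 500, seed = 7)$se_slope
  }
  expect_lt(se_for(40), se_for(6))
})

test_that("applying the constraint propagates both uncertainty sources", {
  fit <- fit_constraint(exact_ensemble(slope = 1.1, intercept = 2),
                        n_boot = 300, seed = 5)
  # no uncertainty anywhere -> deterministic prediction with zero se
  app0 <- apply_constraint(15, 0, fit, n_boot = 300, seed = 6)
  expect_equal(app0$gpp_pct, 2 + 1.1 * 15)
  expect_equal(app0$se, 0)
  # monotone in area under a positive slope
  expect_gt(apply_constraint(20, 1, fit, seed = 6)$gpp_pct,
            apply_constraint(10, 1, fit, seed = 6)$gpp_pct)
  # area uncertainty alone yields se ~ slope * sd(area)
  app1 <- apply_constraint(15, 1.3, fit, n_boot = 4000, seed = 6)
  expect_equal(app1$se, 1.1 * 1.3, tolerance = 0.05)
  # slope-only mode scales by the slope alone
  expect_equal(apply_constraint(15, 0, fit, seed = 6, slope_only = TRUE)$gpp_pct,
               1.1 * 15)
})

test_that("end-to-end: noisy ensemble applied to a known area recovers the line", {
  set.seed(19)
  pts <- exact_ensemble(slope = 1.10, n = 11)
  pts$gpp_pct <- pts$gpp_pct + rnorm(11, 0, 1.5)
  fit <- fit_constraint(pts, n_boot = 1000, seed = 4)
  app <- apply_constraint(14.8, 1.3, fit, n_boot = 1000, seed = 4)
  expect_lt(abs(app$gpp_pct - 1.10 * 14.8), 2 * app$se)
})

test_that("annual series tracks a declining slope and adds components", {
  truth <- synth_truth()
  ens <- generate_dgvm_ensemble(truth, seed = 33, years = 2001:2019)
  areas <- expand.grid(year = 2001:2019, component = c("grass", "crop"),
                       stringsAsFactors = FALSE)
  areas$area_pct <- ifelse(areas$component == "grass", 15, 2.8)
  areas$sd_pct <- ifelse(areas$component == "grass", 1.3, 0.28)
  ser <- annual_constraint_series(ens, areas, n_boot = 300, seed = 9)
  gr <- ser$fits[ser$fits$component == "grass", ]
  # slopes scatter around the configured 1.11 -> 1.10 line
  expect_true(all(abs(gr$slope - 1.105) < 4 * gr$se_slope + 0.05))
  # with scatter removed the configured declining series is recovered exactly
  truth_noiseless <- synth_truth(constraint = local({
    cc <- synth_truth()$constraint
    cc$grass$scatter <- 0; cc$crop$scatter <- 0
    cc
  }))
  ens_nl <- generate_dgvm_ensemble(truth_noiseless, seed = 3, years = 2001:2019)
  ser_nl <- annual_constraint_series(ens_nl, areas, n_boot = 50, seed = 2)
  gr_nl <- ser_nl$fits[ser_nl$fits$component == "grass", ]
  expect_equal(gr_nl$slope, seq(1.11, 1.10, length.out = 19), tolerance = 1e-8)
  expect_true(all(diff(gr_nl$slope) < 0))
  # grass + crop additivity with quadrature se
  ap <- ser$applied
  expect_equal(ap$total_gpp_pct, ap$grass_gpp_pct + ap$crop_gpp_pct)
  expect_equal(ap$total_se, sqrt(ap$grass_se^2 + ap$crop_se^2))
  # constant ensembles across years give constant slopes
  truth0 <- synth_truth(constraint = local({
    cc <- synth_truth()$constraint
    cc$grass$slope_2019 <- cc$grass$slope_2001
    cc$grass$scatter <- 0
    cc$crop$scatter <- 0
    cc$crop$slope_2019 <- cc$crop$slope_2001
    cc
  }))
  ens0 <- generate_dgvm_ensemble(truth0, seed = 5, years = 2001:2003)
  areas0 <- areas[areas$year <= 2003, ]
  ser0 <- annual_constraint_series(ens0, areas0, n_boot = 50, seed = 2)
  gr0 <- ser0$fits[ser0$fits$component == "grass", ]
  expect_equal(diff(range(gr0$slope)), 0, tolerance = 0.02)
  # missing years are skipped with a warning
  expect_warning(annual_constraint_series(ens[ens$year <= 2002, ],
                                          areas0, n_boot = 20, seed = 2),
                 "skipping years")
})
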
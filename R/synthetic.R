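# Synthetic world with known ground truth: climate driver grids, occurrence
# records, plot pairs, coverage observations, land-cover fraction products
# and a vegetation-model ensemble, emulating the shapes and magnitudes of the
# real pipeline inputs so every stage can be tested closed-loop offline.

#' Ground truth and configuration of the synthetic world
#'
#' All quantities the generators treat as true, fixed once: the logistic
#' ratio-to-coverage curve anchored at 5.2% coverage at ratio 1 and ~99% at
#' ratio 2.5; the 1.51 richness-to-cover conversion slope; ensemble
#' constraint lines of slope 1.11 declining to 1.10 (grass) and 1.16 to 1.15
#' (crop) with zero intercept; a +2 ppm/yr CO2 trend from 370 ppm in 2001;
#' and the observation noise levels. See the methods vignette for the
#' rationale behind each default.
#'
#' @param ... overrides for individual fields (unknown names are an error).
#' @return an object of class `synth_truth`.
#' @export
synth_truth <- function(...) {
  truth <- list(
    curve_form = "logistic", curve_a = -7.9, curve_b = 5.0,
    conversion_slope = 1.51,
    conversion_group_sd = 15,      # % cover within a richness group
    constraint = list(
      grass = list(slope_2001 = 1.11, slope_2019 = 1.10, intercept = 0,
                   area_range = c(7, 23), scatter = 1.5, n_models = 11),
      crop = list(slope_2001 = 1.16, slope_2019 = 1.15, intercept = 0,
                  area_range = c(1, 5), scatter = 0.4, n_models = 7)),
    co2_2001 = 370, co2_trend = 2,       # ppm, ppm/yr
    warming_trend = 0.03,                # degC/yr
    vpd_trend = 0.002,                   # kPa/yr
    theta_trend = -0.001,                # relative soil water /yr
    grass_frac_disagreement = 0.06,      # between the two products
    grass_frac_noise = 0.02,
    crop_pct_2001 = 2.6, crop_pct_2019 = 3.0,   # % of land surface, global
    dg_noise_sd = 5,                     # % coverage observation noise
    try_mean_species = 80,
    woody_contamination = 0.10,
    mask_lat = 65                        # growing season excluded poleward
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(truth))
  if (length(bad)) stop("unknown truth fields: ", paste(bad, collapse = ", "))
  truth[names(ov)] <- ov
  structure(truth, class = "synth_truth")
}

# True ratio -> coverage curve of the synthetic world.
truth_curve <- function(truth) {
  function(ratio) 100 / (1 + exp(-(truth$curve_a + truth$curve_b * ratio)))
}

# Smooth random field on the grid: a handful of random low-order sinusoids,
# giving spatially correlated (not white) noise.
smooth_field <- function(lat, lon, sd, seed, n_modes = 6) {
  set.seed(seed %% .Machine$integer.max)
  la <- matrix(lat, length(lat), length(lon))
  lo <- matrix(lon, length(lat), length(lon), byrow = TRUE)
  f <- matrix(0, length(lat), length(lon))
  for (k in seq_len(n_modes)) {
    p <- sample(1:4, 2, replace = TRUE)
    amp <- stats::rnorm(1) / k
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + amp * sin(2 * pi * p[1] * (la + 90) / 180 + ph[1]) *
      sin(2 * pi * p[2] * (lo + 180) / 360 + ph[2])
  }
  f * sd / max(stats::sd(as.vector(f)), 1e-12)
}

#' Generate synthetic climate driver grids
#'
#' Builds growing-season mean driver fields for each year: a latitudinal
#' temperature gradient with a warming trend, VPD tied to temperature and a
#' subtropical dryness belt, soil water potential from relative soil water
#' through the retention curve, a poleward-decreasing PAR field, leaf
#' nitrogen, an exactly linear global CO2 trend, closed-canopy tropical
#' forest cells, and a growing-season mask excluding high latitudes.
#' Spatial noise patterns are fixed across years so trends stay clean.
#'
#' @param truth a [synth_truth()].
#' @param seed RNG seed.
#' @param years simulation years.
#' @param res_deg grid resolution in degrees (default 5).
#' @return list with `years` and `climate` (one driver-grid list per year,
#'   as consumed by [ac_ratio_grid()]).
#' @export
generate_climate_grid <- function(truth = synth_truth(), seed = 1,
                                  years = 2001:2019, res_deg = 5) {
  g0 <- global_grid(res_deg)
  lat <- g0$lat; lon <- g0$lon
  absla <- matrix(abs(lat), length(lat), length(lon))
  dry <- exp(-((absla - 25) / 12)^2)            # subtropical dryness belt
  noise_t <- smooth_field(lat, lon, 1.2, seed + 11)
  noise_v <- smooth_field(lat, lon, 0.15, seed + 12)
  noise_s <- smooth_field(lat, lon, 0.06, seed + 13)
  noise_p <- smooth_field(lat, lon, 40, seed + 14)
  noise_n <- smooth_field(lat, lon, 0.15, seed + 15)
  forest_f <- smooth_field(lat, lon, 1, seed + 16)
  mask <- (absla <= truth$mask_lat) * 1
  closed <- (absla < 15 & forest_f > 0.5) * 1
  lai <- closed * 4
  tex <- soil_texture()
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    dy <- years[i] - 2001
    # growing-season (not annual) mean: flat near the equator, ~12 C at the
    # 65-degree mask edge
    tair <- 28 - 16 * (absla / truth$mask_lat)^2 + noise_t +
      truth$warming_trend * dy
    vpd <- pmax(0.1, 0.3 + 0.04 * tair + 0.8 * dry + noise_v +
                  truth$vpd_trend * dy)
    theta_rel <- pmin(pmax(0.75 - 0.3 * dry + noise_s + truth$theta_trend * dy,
                           0.05), 1)
    psi <- soil_water_potential(theta_rel * tex$theta_sat, tex)
    par <- pmax(50, 900 - 6 * absla + noise_p)
    leaf_n <- pmax(0.5, 1.8 - 0.012 * absla + noise_n)
    co2 <- truth$co2_2001 + truth$co2_trend * dy
    mk <- function(v, nm) c4grid(matrix(v, length(lat)), lat, lon, nm)
    out[[i]] <- list(tair = mk(tair, "tair"), vpd = mk(vpd, "vpd"),
                     par = mk(par, "par"), co2 = mk(co2 + 0 * tair, "co2"),
                     psi_soil = mk(psi, "psi_soil"),
                     leaf_n = mk(leaf_n, "leaf_n"),
                     lai_overstory = mk(lai, "lai_overstory"),
                     canopy_closed = mk(closed, "canopy_closed"),
                     mask = mk(mask, "mask"))
  }
  list(years = years, climate = out)
}

#' Generate synthetic C4 observations from a ratio grid
#'
#' Derives the observation files from the synthetic truth: cell-level true
#' coverage is the true curve evaluated at the modeled ratio; true richness
#' is coverage divided by the true conversion slope. Produces (i) occurrence
#' records emulating a global trait database, with species lists matching
#' the cell's richness plus configurable woody and crop contamination;
#' (ii) plot-level paired richness/cover observations with within-group
#' noise; and (iii) a gridded coverage dataset ("DG-like") over a
#' mid-latitude window with observation noise.
#'
#' @param truth a [synth_truth()].
#' @param ratio a [c4grid()] of AC4/AC3 at the native resolution.
#' @param seed RNG seed.
#' @return list with data.frames `occurrences`, `plot_pairs`, `dg`.
#' @export
generate_observations <- function(truth, ratio, seed = 1) {
  stopifnot(inherits(truth, "synth_truth"), inherits(ratio, "c4grid"))
  set.seed(seed %% .Machine$integer.max)
  curve <- truth_curve(truth)
  res <- grid_resolution(ratio)

  # TRY-like occurrences over 10-degree cells
  r10 <- aggregate_ratio(ratio, 10)
  occ <- NULL
  for (i in seq_along(r10$lat)) for (j in seq_along(r10$lon)) {
    rr <- r10$values[i, j]
    if (is.na(rr) || abs(r10$lat[i]) > 55) next
    cov <- curve(rr)
    rich <- min(100, cov / truth$conversion_slope)
    n_sp <- 30 + stats::rpois(1, truth$try_mean_species - 30)
    n_c4 <- round(rich / 100 * n_sp)
    n_woody <- round(truth$woody_contamination * n_sp)
    cell <- sprintf("%d_%d", i, j)
    n_all <- n_sp + n_woody + 1
    occ <- rbind(occ, data.frame(
      species = c(sprintf("Herbus sp%s_%d", cell, seq_len(n_sp)),
                  sprintf("Woodus sp%s_%d", cell, seq_len(n_woody)),
                  "Zea mays"),
      latitude = r10$lat[i] + stats::runif(n_all, -4.9, 4.9),
      longitude = r10$lon[j] + stats::runif(n_all, -4.9, 4.9),
      pathway = c(rep("C4", n_c4), rep("C3", n_sp - n_c4),
                  rep("C3", n_woody), "C4"),
      woody = c(rep(FALSE, n_sp), rep(TRUE, n_woody), FALSE),
      crop = c(rep(FALSE, n_sp + n_woody), TRUE)))
  }

  # NutNet-like paired plot observations
  rich_groups <- seq(2, 44, by = 3)
  pp <- expand.grid(site = sprintf("site%02d", seq_along(rich_groups)),
                    plot = 1:4)
  pp <- pp[order(pp$site), ]
  pp$richness_pct <- rep(rich_groups, each = 4)
  pp$cover_pct <- pmin(100, pmax(0, truth$conversion_slope * pp$richness_pct +
    stats::rnorm(nrow(pp), 0, truth$conversion_group_sd)))
  rownames(pp) <- NULL

  # DG-like gridded coverage over a mid-latitude window
  sel <- which(!is.na(ratio$values) &
                 abs(matrix(ratio$lat, length(ratio$lat),
                            length(ratio$lon))) >= 25 &
                 abs(matrix(ratio$lat, length(ratio$lat),
                            length(ratio$lon))) <= 50)
  # observation error on the logit scale: bounded in (0, 100), median-
  # unbiased for the true curve, and shrinking near the bounds where cover
  # estimates are precise; dg_noise_sd is the mid-scale (50% cover) sd
  true_cov <- curve(ratio$values[sel])
  noisy <- 100 * stats::plogis(stats::qlogis(pmin(pmax(true_cov / 100, 1e-6),
                                                  1 - 1e-6)) +
                                 stats::rnorm(length(sel), 0,
                                              truth$dg_noise_sd / 25))
  dg <- data.frame(
    lat = matrix(ratio$lat, length(ratio$lat), length(ratio$lon))[sel],
    lon = matrix(ratio$lon, length(ratio$lat), length(ratio$lon),
                 byrow = TRUE)[sel],
    ratio = ratio$values[sel],
    coverage_pct = noisy,
    source = rep("DG", length(sel)),
    scale_deg = rep(res, length(sel)))

  list(occurrences = occ, plot_pairs = pp, dg = dg)
}

#' Generate synthetic land-cover fraction products
#'
#' Two grassland-fraction products straddling a latitudinally structured
#' truth by half the configured inter-product disagreement (plus clipped
#' Gaussian noise), and an annual C4 crop-fraction series concentrated in
#' temperate latitudes whose global mean expands linearly between the
#' configured 2001 and 2019 levels (emulating maize expansion).
#'
#' @param truth a [synth_truth()].
#' @param seed RNG seed.
#' @param years years of the crop series.
#' @param res_deg grid resolution (degrees).
#' @return list with `grass_truth`, `product_a`, `product_b` ([c4grid()]s)
#'   and `crop` (list of [c4grid()]s, one per year).
#' @export
generate_fraction_products <- function(truth = synth_truth(), seed = 1,
                                       years = 2001:2019, res_deg = 5) {
  g0 <- global_grid(res_deg)
  lat <- g0$lat; lon <- g0$lon
  absla <- matrix(abs(lat), length(lat), length(lon))
  land <- absla <= truth$mask_lat
  gtruth <- (0.55 * exp(-((absla - 30) / 18)^2) + 0.08) * land
  gtruth[!land] <- NA_real_
  na <- smooth_field(lat, lon, truth$grass_frac_noise, seed + 21)
  nb <- smooth_field(lat, lon, truth$grass_frac_noise, seed + 22)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  pa <- clip01(gtruth + truth$grass_frac_disagreement / 2 + na)
  pb <- clip01(gtruth - truth$grass_frac_disagreement / 2 + nb)

  # crop base pattern scaled so the masked area-weighted mean hits the
  # configured 2001 level, then expanded linearly to the 2019 level
  base <- exp(-((absla - 40) / 10)^2) * land
  base[!land] <- NA_real_
  w <- matrix(cos(lat * pi / 180), length(lat), length(lon))
  ok <- !is.na(base)
  base <- base * (truth$crop_pct_2001 / 100) /
    (sum(base[ok] * w[ok]) / sum(w[ok]))
  growth <- (truth$crop_pct_2019 / truth$crop_pct_2001 - 1) / 18
  crop <- lapply(years, function(y)
    c4grid(clip01(base * (1 + growth * (y - 2001))), lat, lon,
           sprintf("c4_crop_fraction_%d", y)))
  names(crop) <- as.character(years)
  list(grass_truth = c4grid(gtruth, lat, lon, "grass_fraction_truth"),
       product_a = c4grid(pa, lat, lon, "grass_fraction_a"),
       product_b = c4grid(pb, lat, lon, "grass_fraction_b"),
       crop = crop)
}

#' Generate a synthetic vegetation-model ensemble
#'
#' Ensemble members' C4 area shares are spread over the configured range
#' (emulating the wide inter-model disagreement that powers the emergent
#' constraint); their GPP shares lie on the true constraint line for that
#' year plus Gaussian scatter. The grass line's slope declines linearly from
#' its 2001 to its 2019 value, as does the crop line's.
#'
#' @param truth a [synth_truth()].
#' @param seed RNG seed.
#' @param years years to generate.
#' @param n_models number of members for the grass component (the crop
#'   component uses the configured, typically smaller, count).
#' @return data.frame with `model`, `year`, `component`, `area_pct`,
#'   `gpp_pct`.
#' @export
generate_dgvm_ensemble <- function(truth = synth_truth(), seed = 1,
                                   years = 2001:2019,
                                   n_models = truth$constraint$grass$n_models) {
  set.seed(seed %% .Machine$integer.max)
  out <- NULL
  for (cmp in c("grass", "crop")) {
    cc <- truth$constraint[[cmp]]
    nm <- if (cmp == "grass") n_models else min(n_models, cc$n_models)
    base_area <- seq(cc$area_range[1], cc$area_range[2], length.out = nm)
    for (y in years) {
      fr <- (y - 2001) / 18
      slope <- cc$slope_2001 + fr * (cc$slope_2019 - cc$slope_2001)
      area <- base_area + stats::rnorm(nm, 0, diff(cc$area_range) * 0.02)
      gpp <- pmax(0, cc$intercept + slope * area +
                    stats::rnorm(nm, 0, cc$scatter))
      out <- rbind(out, data.frame(model = sprintf("model%02d", seq_len(nm)),
                                   year = y, component = cmp,
                                   area_pct = area, gpp_pct = gpp))
    }
  }
  out
}
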
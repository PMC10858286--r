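# From coverage (% of grassland) to area abundance (% of land surface):
# grassland/crop fraction handling, global summaries, change synergies and
# scenario-replacement driver attribution.

#' Combine two grassland-fraction products with bootstrap uncertainty
#'
#' The grassland fraction is the mean of two remote-sensing products; its
#' per-cell uncertainty is one standard deviation of 1000 bootstrap draws,
#' each picking one of the two products at random (independently per cell),
#' so as the number of draws grows the sd approaches half the inter-product
#' disagreement.
#'
#' @param product_a,product_b [c4grid()]s of grassland fraction in `[0, 1]`
#'   on a shared grid.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return list of [c4grid()]s `fraction` and `sd`.
#' @export
combine_grassland_fraction <- function(product_a, product_b, n_boot = 1000,
                                       seed = 1) {
  stopifnot_same_grid(product_a, product_b, "grassland product")
  a <- as.vector(product_a$values)
  b <- as.vector(product_b$values)
  if (any(c(a, b) < 0 | c(a, b) > 1, na.rm = TRUE))
    stop("grassland fractions must be in [0, 1]")
  mean_v <- (a + b) / 2
  sd_v <- rep(NA_real_, length(a))
  ok <- which(!is.na(a) & !is.na(b))
  set.seed(seed)
  if (length(ok)) {
    pick <- matrix(stats::runif(length(ok) * n_boot) < 0.5, length(ok), n_boot)
    draws <- ifelse(pick, a[ok], b[ok])
    dim(draws) <- dim(pick)
    m <- rowMeans(draws)
    sd_v[ok] <- sqrt(rowSums((draws - m)^2) / (n_boot - 1))
  }
  nl <- length(product_a$lat)
  list(fraction = grid_like(product_a, matrix(mean_v, nl), "grassland_fraction"),
       sd = grid_like(product_a, matrix(sd_v, nl), "grassland_fraction_sd"))
}

# Quadrature of relative uncertainties for a product x = u * v.
quad_rel_sd <- function(x, u, su, v, sv) {
  rel2 <- ifelse(u > 0, (su / u)^2, 0) + ifelse(v > 0, (sv / v)^2, 0)
  ifelse(is.na(x), NA_real_, abs(x) * sqrt(rel2))
}

#' C4 natural grass area abundance
#'
#' Overlays predicted C4 coverage (% of grassland) on the grassland fraction
#' to obtain the share of the land surface occupied by C4 natural grasses.
#' Uncertainty combines the coverage-curve uncertainty and the
#' grassland-fraction uncertainty in quadrature on relative terms (the two
#' error sources are independent).
#'
#' @param coverage [c4grid()] of C4 coverage (% of grassland).
#' @param coverage_sd [c4grid()] of its uncertainty (same units).
#' @param fraction [c4grid()] of grassland fraction in `[0, 1]`.
#' @param fraction_sd [c4grid()] of its uncertainty.
#' @param year optional year tag.
#' @return an object of class `c4_abundance`: list with `abundance` and `sd`
#'   [c4grid()]s (% of land surface), `component = "grass"`, `year`.
#' @export
grass_abundance <- function(coverage, coverage_sd, fraction, fraction_sd,
                            year = NA) {
  stopifnot_same_grid(coverage, fraction, "grassland fraction")
  stopifnot_same_grid(coverage, coverage_sd, "coverage sd")
  stopifnot_same_grid(coverage, fraction_sd, "fraction sd")
  ab <- coverage$values * fraction$values
  sd <- quad_rel_sd(ab, coverage$values, coverage_sd$values,
                    fraction$values, fraction_sd$values)
  sd[!is.na(ab) & ab == 0] <- 0
  structure(list(abundance = grid_like(coverage, ab, "c4_grass_abundance_pct"),
                 sd = grid_like(coverage, sd, "c4_grass_abundance_sd"),
                 component = "grass", year = year),
            class = "c4_abundance")
}

#' C4 crop area abundance
#'
#' C4 crop abundance is the crop fraction itself expressed as % of the land
#' surface; its uncertainty is a flat 10% of the reported area (the
#' between-product spread of global cropland datasets).
#'
#' @param crop_fraction [c4grid()] of C4 crop fraction in `[0, 1]`.
#' @param rel_uncertainty relative uncertainty (default 0.10).
#' @param year optional year tag.
#' @return a `c4_abundance` with `component = "crop"`.
#' @export
crop_abundance <- function(crop_fraction, rel_uncertainty = 0.10, year = NA) {
  stopifnot(inherits(crop_fraction, "c4grid"))
  if (any(crop_fraction$values < 0 | crop_fraction$values > 1, na.rm = TRUE))
    stop("crop fractions must be in [0, 1]")
  ab <- 100 * crop_fraction$values
  structure(list(abundance = grid_like(crop_fraction, ab, "c4_crop_abundance_pct"),
                 sd = grid_like(crop_fraction, rel_uncertainty * ab,
                                "c4_crop_abundance_sd"),
                 component = "crop", year = year),
            class = "c4_abundance")
}

#' Total C4 abundance (grass + crop)
#'
#' @param grass,crop `c4_abundance` objects on a shared grid.
#' @return a `c4_abundance` with `component = "total"`; per-cell sum with
#'   uncertainties combined in quadrature. Cells missing in one component are
#'   treated as zero there if present in the other.
#' @export
total_abundance <- function(grass, crop) {
  stopifnot(inherits(grass, "c4_abundance"), inherits(crop, "c4_abundance"))
  stopifnot_same_grid(grass$abundance, crop$abundance, "crop abundance")
  g <- grass$abundance$values; cg <- crop$abundance$values
  gs <- grass$sd$values; cs <- crop$sd$values
  both_na <- is.na(g) & is.na(cg)
  z <- function(x) ifelse(is.na(x), 0, x)
  ab <- ifelse(both_na, NA_real_, z(g) + z(cg))
  sd <- ifelse(both_na, NA_real_, sqrt(z(gs)^2 + z(cs)^2))
  structure(list(abundance = grid_like(grass$abundance, ab, "c4_total_abundance_pct"),
                 sd = grid_like(grass$abundance, sd, "c4_total_abundance_sd"),
                 component = "total", year = grass$year),
            class = "c4_abundance")
}

#' @export
print.c4_abundance <- function(x, ...) {
  cat(sprintf("<c4_abundance> component '%s'%s\n", x$component,
              if (!is.na(x$year)) paste0(", year ", x$year) else ""))
  print(x$abundance)
  invisible(x)
}

#' Global summary of a C4 abundance grid
#'
#' Area-weighted global statistics: the % of (masked) land surface occupied,
#' its mean uncertainty, and the absolute area in million km2 using spherical
#' cell areas.
#'
#' @param abundance a `c4_abundance` (or a bare [c4grid()] of %).
#' @param land_mask optional 0/1 [c4grid()] of the non-frozen vegetated
#'   domain; defaults to all valid cells.
#' @return list with `pct`, `sd_pct` (area-weighted means) and `area_mkm2`.
#' @export
global_summary <- function(abundance, land_mask = NULL) {
  sd_grid <- NULL
  if (inherits(abundance, "c4_abundance")) {
    sd_grid <- abundance$sd
    abundance <- abundance$abundance
  }
  stopifnot(inherits(abundance, "c4grid"))
  pct <- grid_mean(abundance, land_mask)
  sd_pct <- if (!is.null(sd_grid)) grid_mean(sd_grid, land_mask) else NA_real_
  area <- cell_area_km2(abundance)
  keep <- !is.na(abundance$values)
  if (!is.null(land_mask)) {
    stopifnot_same_grid(abundance, land_mask, "mask")
    keep <- keep & !is.na(land_mask$values) & land_mask$values > 0
  }
  if (!any(keep)) stop("no valid cells under the mask")
  list(pct = pct, sd_pct = sd_pct,
       area_mkm2 = sum(abundance$values[keep] / 100 * area[keep]) / 1e6)
}

#' Period change and grass/crop synergy classes
#'
#' Compares early- and late-period mean abundances for the grass and crop
#' components, and classifies cells where both components are present into
#' the four synergy classes: `++` (both increased), `--` (both decreased),
#' `+-` (grass up, crop down) and `-+` (grass down, crop up). Class shares
#' are reported over the eligible (both-present, both-changed) cells and sum
#' to one.
#'
#' @param early_grass,early_crop,late_grass,late_crop `c4_abundance` objects
#'   (period means) on a shared grid.
#' @param land_mask optional 0/1 [c4grid()] for the global aggregates.
#' @return an object of class `c4_change`: per-component global means and
#'   deltas, `synergy_fractions`, and per-cell delta grids.
#' @export
change_and_synergy <- function(early_grass, early_crop, late_grass, late_crop,
                               land_mask = NULL) {
  for (x in list(early_crop, late_grass, late_crop))
    stopifnot_same_grid(early_grass$abundance, x$abundance, "abundance")
  dg <- late_grass$abundance$values - early_grass$abundance$values
  dc <- late_crop$abundance$values - early_crop$abundance$values
  present <- function(e, l) {
    (ifelse(is.na(e$abundance$values), 0, e$abundance$values) > 0) |
      (ifelse(is.na(l$abundance$values), 0, l$abundance$values) > 0)
  }
  eligible <- present(early_grass, late_grass) & present(early_crop, late_crop) &
    !is.na(dg) & !is.na(dc) & dg != 0 & dc != 0
  cls <- rep(NA_character_, length(dg))
  cls[eligible & dg > 0 & dc > 0] <- "++"
  cls[eligible & dg < 0 & dc < 0] <- "--"
  cls[eligible & dg > 0 & dc < 0] <- "+-"
  cls[eligible & dg < 0 & dc > 0] <- "-+"
  n <- sum(eligible)
  syn <- if (n) table(factor(cls[eligible], levels = c("++", "--", "+-", "-+"))) / n
         else  table(factor(character(), levels = c("++", "--", "+-", "-+")))
  summ <- function(e, l) {
    es <- global_summary(e, land_mask); ls <- global_summary(l, land_mask)
    c(early = es$pct, late = ls$pct, delta = ls$pct - es$pct)
  }
  structure(list(
    grass = summ(early_grass, late_grass),
    crop = summ(early_crop, late_crop),
    total = summ(total_abundance(early_grass, early_crop),
                 total_abundance(late_grass, late_crop)),
    synergy_fractions = as.numeric(syn),
    synergy_labels = names(syn), n_eligible = n,
    delta_grass = grid_like(early_grass$abundance, dg, "delta_grass"),
    delta_crop = grid_like(early_crop$abundance, dc, "delta_crop")),
    class = "c4_change")
}

#' @export
print.c4_change <- function(x, ...) {
  for (cmp in c("grass", "crop", "total"))
    cat(sprintf("  %-5s %.2f%% -> %.2f%% (delta %+0.2f%% of land surface)\n",
                cmp, x[[cmp]]["early"], x[[cmp]]["late"], x[[cmp]]["delta"]))
  cat(sprintf("  synergy over %d both-present cells: %s\n", x$n_eligible,
              paste(sprintf("%s %.0f%%", x$synergy_labels,
                            100 * x$synergy_fractions), collapse = ", ")))
  invisible(x)
}

#' Attribute C4 grass change to individual climate drivers
#'
#' Scenario-replacement attribution: the baseline C4 grass distribution is
#' computed from the baseline (e.g. 2001) climate; then, one driver at a
#' time, the baseline field is replaced by the target-period (e.g. 2019)
#' field and the distribution recomputed. Each driver's contribution is the
#' difference from the baseline distribution; the sum of single-driver
#' contributions is reported next to the full change, with their difference
#' as an interaction residual (not forced to match).
#'
#' @param climate_base,climate_target named driver-grid lists as for
#'   [ac_ratio_grid()].
#' @param curve a fitted [fit_coverage_curve()].
#' @param fraction,fraction_sd grassland fraction and uncertainty
#'   [c4grid()]s, held fixed across scenarios.
#' @param drivers driver fields to attribute (default CO2, temperature, VPD
#'   and soil moisture).
#' @param land_mask optional 0/1 [c4grid()].
#' @param p_c3,p_c4 pathway parameter sets.
#' @return an object of class `c4_attribution`: per-driver delta grids and
#'   global deltas (% of land surface), plus `full_delta` and
#'   `interaction_residual`.
#' @export
attribute_change <- function(climate_base, climate_target, curve,
                             fraction, fraction_sd,
                             drivers = c("co2", "tair", "vpd", "psi_soil"),
                             land_mask = NULL,
                             p_c3 = photo_params("C3"), p_c4 = photo_params("C4")) {
  miss <- setdiff(drivers, intersect(names(climate_base), names(climate_target)))
  if (length(miss))
    stop("drivers absent from both climates: ", paste(miss, collapse = ", "))
  for (nm in names(climate_target))
    stopifnot_same_grid(climate_base[[1]], climate_target[[nm]], nm)
  run <- function(clim) {
    r <- ac_ratio_grid(clim, p_c3, p_c4)
    pc <- predict_coverage(r, curve)
    grass_abundance(pc$coverage, pc$uncertainty, fraction, fraction_sd)
  }
  base <- run(climate_base)
  base_pct <- global_summary(base, land_mask)$pct
  res <- list()
  for (d in drivers) {
    clim <- climate_base
    clim[[d]] <- climate_target[[d]]
    ab <- run(clim)
    res[[d]] <- list(
      delta_grid = grid_like(ab$abundance,
                             ab$abundance$values - base$abundance$values,
                             paste0("delta_", d)),
      delta_pct = global_summary(ab, land_mask)$pct - base_pct)
  }
  full <- run(climate_target)
  full_delta <- global_summary(full, land_mask)$pct - base_pct
  sum_single <- sum(vapply(res, `[[`, numeric(1), "delta_pct"))
  structure(list(drivers = res, baseline_pct = base_pct,
                 full_delta = full_delta, sum_single = sum_single,
                 interaction_residual = full_delta - sum_single),
            class = "c4_attribution")
}

#' @export
print.c4_attribution <- function(x, ...) {
  cat("<c4_attribution> C4 grass abundance change by driver (% of land surface)\n")
  for (d in names(x$drivers))
    cat(sprintf("  %-9s %+0.3f\n", d, x$drivers[[d]]$delta_pct))
  cat(sprintf("  full change %+0.3f; sum of drivers %+0.3f; interaction %+0.3f\n",
              x$full_delta, x$sum_single, x$interaction_residual))
  invisible(x)
}
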
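# End-to-end orchestration: configuration, the synthetic closed-loop
# pipeline, output writing and the run manifest.

#' Pipeline run configuration
#'
#' Central configuration for [run_pipeline()]. Every stochastic stage draws
#' its seed deterministically from `seed`, so identical configurations give
#' bit-identical runs. Unknown keys are rejected.
#'
#' @param seed master RNG seed.
#' @param res_deg grid resolution in degrees (default 5; 0.5 supported but
#'   slow).
#' @param years simulation years.
#' @param n_boot bootstrap replicates for every bootstrap stage.
#' @param curve_form saturating curve family (`"logistic"` or `"gompertz"`).
#' @param slope_only if `TRUE`, apply the emergent constraint by slope-only
#'   scaling instead of the full fitted line.
#' @param run_attribution,run_constraint stage toggles.
#' @param out_dir optional output directory; when set, summaries, grids, the
#'   serialized curve and a manifest are written there.
#' @param truth a [synth_truth()] describing the synthetic world.
#' @return an object of class `c4_config`.
#' @export
c4_config <- function(seed = 42, res_deg = 5, years = 2001:2019,
                      n_boot = 1000, curve_form = "logistic",
                      slope_only = FALSE, run_attribution = TRUE,
                      run_constraint = TRUE, out_dir = NULL,
                      truth = synth_truth()) {
  stopifnot(inherits(truth, "synth_truth"))
  structure(list(seed = as.integer(seed), res_deg = res_deg, years = years,
                 n_boot = n_boot, curve_form = curve_form,
                 slope_only = slope_only, run_attribution = run_attribution,
                 run_constraint = run_constraint, out_dir = out_dir,
                 truth = truth), class = "c4_config")
}

# Deterministic per-stage seed below 2^31.
stage_seed <- function(seed, stage) {
  (seed + 1000003 * stage) %% 2147483647L
}

# Element-wise mean of abundance grids over a period.
period_mean_abundance <- function(lst) {
  ab <- Reduce(`+`, lapply(lst, function(x) x$abundance$values)) / length(lst)
  sd <- Reduce(`+`, lapply(lst, function(x) x$sd$values)) / length(lst)
  structure(list(abundance = grid_like(lst[[1]]$abundance, ab),
                 sd = grid_like(lst[[1]]$sd, sd),
                 component = lst[[1]]$component, year = NA),
            class = "c4_abundance")
}

#' Run the full synthetic closed-loop pipeline
#'
#' Chains every stage on the synthetic world: climate generation, the
#' optimality-model ratio grids for each year, observation generation,
#' the richness-to-cover conversion factor, ratio-coverage curve fitting,
#' annual coverage and abundance maps, global summaries, early/late change
#' and synergy classes, single-driver attribution, and the annual emergent
#' constraint. Since the synthetic truth is known, the returned object pairs
#' every recovered quantity with its true value.
#'
#' @param config a [c4_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `c4_run`; see `print()` for the highlights.
#'   When `config$out_dir` is set, also writes summary CSVs, first/last-year
#'   grids, the serialized curve and a JSON manifest with file hashes.
#' @export
run_pipeline <- function(config = c4_config(), quiet = FALSE) {
  stopifnot(inherits(config, "c4_config"))
  truth <- config$truth
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  say("generating climate drivers (", length(config$years), " years)")
  clim <- generate_climate_grid(truth, stage_seed(config$seed, 1),
                                config$years, config$res_deg)
  say("running the optimality model per year")
  ratios <- lapply(clim$climate, ac_ratio_grid)
  mean_ratio <- grid_like(ratios[[1]]$ratio,
                          apply(simplify2array(lapply(ratios,
                            function(r) r$ratio$values)), c(1, 2),
                            function(v) if (all(is.na(v))) NA_real_
                                        else mean(v, na.rm = TRUE)),
                          "ac4_ac3_mean")

  say("generating observations and fitting the conversion factor")
  obs <- generate_observations(truth, mean_ratio, stage_seed(config$seed, 2))
  conv <- fit_conversion_factor(obs$plot_pairs, config$n_boot,
                                stage_seed(config$seed, 3))

  filtered <- filter_records(obs$occurrences)
  rich <- grid_richness(filtered)
  r10 <- aggregate_ratio(mean_ratio, 10)
  ri <- match(rich$lat, r10$lat); ci <- match(rich$lon, r10$lon)
  try_pairs <- data.frame(
    ratio = r10$values[cbind(ri, ci)],
    coverage_pct = richness_to_coverage(rich$richness_pct, conv),
    source = "TRY", scale_deg = 10)
  dg_pairs <- obs$dg[, c("ratio", "coverage_pct", "source", "scale_deg")]
  pairs <- rbind(try_pairs, dg_pairs)
  pairs <- pairs[!is.na(pairs$ratio), ]

  say("fitting the ratio-coverage curve on ", nrow(pairs), " pairs")
  curve <- fit_coverage_curve(pairs, config$curve_form, config$n_boot,
                              stage_seed(config$seed, 4))

  say("combining fraction products and mapping abundance per year")
  fr <- generate_fraction_products(truth, stage_seed(config$seed, 5),
                                   config$years, config$res_deg)
  gfrac <- combine_grassland_fraction(fr$product_a, fr$product_b,
                                      config$n_boot, stage_seed(config$seed, 6))
  land_mask <- clim$climate[[1]]$mask

  grass_y <- vector("list", length(config$years))
  crop_y <- vector("list", length(config$years))
  summary_rows <- NULL
  for (i in seq_along(config$years)) {
    pc <- predict_coverage(ratios[[i]], curve)
    grass_y[[i]] <- grass_abundance(pc$coverage, pc$uncertainty,
                                    gfrac$fraction, gfrac$sd,
                                    year = config$years[i])
    crop_y[[i]] <- crop_abundance(fr$crop[[i]], year = config$years[i])
    tot <- total_abundance(grass_y[[i]], crop_y[[i]])
    for (x in list(grass_y[[i]], crop_y[[i]], tot)) {
      s <- global_summary(x, land_mask)
      summary_rows <- rbind(summary_rows,
        data.frame(year = config$years[i], component = x$component,
                   pct = s$pct, sd = s$sd_pct, area_mkm2 = s$area_mkm2))
    }
  }

  early <- which(config$years <= 2005)
  late <- which(config$years >= 2015)
  change <- change_and_synergy(period_mean_abundance(grass_y[early]),
                               period_mean_abundance(crop_y[early]),
                               period_mean_abundance(grass_y[late]),
                               period_mean_abundance(crop_y[late]),
                               land_mask)

  attribution <- NULL
  if (config$run_attribution) {
    say("attributing 2001->2019 change to drivers")
    attribution <- attribute_change(clim$climate[[1]],
                                    clim$climate[[length(config$years)]],
                                    curve, gfrac$fraction, gfrac$sd,
                                    land_mask = land_mask)
  }

  constraint <- NULL
  if (config$run_constraint) {
    say("fitting and applying the annual emergent constraint")
    ens <- generate_dgvm_ensemble(truth, stage_seed(config$seed, 7),
                                  config$years)
    areas <- summary_rows[summary_rows$component != "total",
                          c("year", "component", "pct", "sd")]
    names(areas) <- c("year", "component", "area_pct", "sd_pct")
    constraint <- annual_constraint_series(ens, areas, config$n_boot,
                                           stage_seed(config$seed, 8),
                                           config$slope_only)
    constraint$ensemble <- ens
  }

  run <- structure(list(
    config = config, truth = truth, conversion = conv, curve = curve,
    pairs = pairs, ratios = ratios, mean_ratio = mean_ratio,
    grassland = gfrac, grass = grass_y, crop = crop_y,
    summary = summary_rows, change = change, attribution = attribution,
    constraint = constraint, land_mask = land_mask,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "c4_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.c4_run <- function(x, ...) {
  yrs <- range(x$config$years)
  cat(sprintf("<c4_run> %g-degree synthetic world, %d-%d (%.1f s)\n",
              x$config$res_deg, yrs[1], yrs[2], x$elapsed_s))
  cat(sprintf("  conversion factor: %.2f +/- %.2f (truth %.2f)\n",
              x$conversion$slope, x$conversion$sd, x$truth$conversion_slope))
  cat(sprintf("  coverage curve (%s): a = %.2f, b = %.2f (truth %.2f, %.2f)\n",
              x$curve$form, x$curve$coef["a"], x$curve$coef["b"],
              x$truth$curve_a, x$truth$curve_b))
  mean_cmp <- function(cmp) mean(x$summary$pct[x$summary$component == cmp])
  cat(sprintf("  mean area abundance: grass %.1f%%, crop %.1f%%, total %.1f%% of land\n",
              mean_cmp("grass"), mean_cmp("crop"), mean_cmp("total")))
  print(x$change)
  if (!is.null(x$constraint)) {
    ap <- x$constraint$applied
    cat(sprintf("  C4 share of GPP: %.1f%% (first year) -> %.1f%% (last year)\n",
                ap$total_gpp_pct[1], ap$total_gpp_pct[nrow(ap)]))
  }
  invisible(x)
}

#' Serialize a fitted coverage curve to a text file
#' @param curve a [fit_coverage_curve()] result.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "c4_curve"))
  qs <- apply(curve$boot, 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975), names = TRUE)
  jsonlite::write_json(list(form = curve$form, coef = as.list(curve$coef),
                            n_boot = curve$n_boot, seed = curve$seed,
                            boot_quantiles = as.data.frame(qs)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Write run outputs and a manifest with md5 hashes.
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wcsv <- function(df, nm) {
    p <- file.path(out_dir, nm)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(run$summary, "global_summary.csv")
  wcsv(run$pairs, "ratio_coverage_pairs.csv")
  if (!is.null(run$constraint)) {
    wcsv(run$constraint$fits, "constraint_fits.csv")
    wcsv(run$constraint$applied, "c4_gpp_share.csv")
  }
  n <- length(run$ratios)
  for (spec in list(list(run$ratios[[1]]$ratio, "ratio_first_year.csv"),
                    list(run$ratios[[n]]$ratio, "ratio_last_year.csv"),
                    list(run$grass[[n]]$abundance, "grass_abundance_last_year.csv"),
                    list(run$grassland$fraction, "grassland_fraction.csv"))) {
    p <- file.path(out_dir, spec[[2]])
    write_grid(spec[[1]], p)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "coverage_curve.json")
  write_curve(run$curve, p)
  files <- c(files, p)
  manifest <- list(
    package_version = tryCatch(as.character(utils::packageVersion("c4veg")),
                               error = function(e) "dev"),
    seed = run$config$seed, res_deg = run$config$res_deg,
    years = range(run$config$years),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
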
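# Emergent-constraint regression across a vegetation-model ensemble:
# C4 GPP share regressed on C4 area share, applied to the
# observation-constrained areas.

#' Fit the emergent constraint across an ensemble
#'
#' Ordinary least-squares regression of the C4 contribution to global GPP (%)
#' on the C4 area share (%) across the members of a vegetation-model
#' ensemble. The wide inter-model spread in both quantities is what makes
#' the across-model relationship usable as a constraint. The slope's
#' standard error comes from bootstrapping models with replacement.
#'
#' @param points data.frame with columns `model`, `area_pct`, `gpp_pct`
#'   (optionally `year`, `component`), one row per model.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return an object of class `c4_constraint`: `slope`, `intercept`,
#'   `se_slope`, `r`, `p`, `boot` (replicate coefficients), `n_models`.
#' @export
fit_constraint <- function(points, n_boot = 1000, seed = 1) {
  if (!all(c("model", "area_pct", "gpp_pct") %in% names(points)))
    stop("'points' needs columns model, area_pct, gpp_pct")
  points <- points[stats::complete.cases(points[, c("area_pct", "gpp_pct")]), ]
  if (anyDuplicated(points$model))
    stop("one point per model expected; duplicated: ",
         paste(unique(points$model[duplicated(points$model)]), collapse = ", "))
  n <- nrow(points)
  if (n < 4) stop("need >= 4 ensemble members, got ", n)
  if (stats::var(points$area_pct) == 0)
    stop("degenerate ensemble: all members report the same area")
  fit <- stats::lm(gpp_pct ~ area_pct, data = points)
  ct <- stats::cor.test(points$area_pct, points$gpp_pct)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("intercept", "slope")))
  b <- 1
  while (b <= n_boot) {
    i <- sample.int(n, replace = TRUE)
    if (stats::var(points$area_pct[i]) == 0) next  # redraw degenerate resamples
    boot[b, ] <- stats::coef(stats::lm(points$gpp_pct[i] ~ points$area_pct[i]))
    b <- b + 1
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = stats::sd(boot[, "slope"]),
                 r = unname(ct$estimate), p = ct$p.value,
                 boot = boot, n_models = n, points = points,
                 n_boot = n_boot, seed = seed),
            class = "c4_constraint")
}

#' @export
print.c4_constraint <- function(x, ...) {
  cat(sprintf(paste0("<c4_constraint> GPP%% = %.3f + %.3f x area%% ",
                     "(slope se %.3f; r = %.2f, p = %.2g; %d models)\n"),
              x$intercept, x$slope, x$se_slope, x$r, x$p, x$n_models))
  invisible(x)
}

#' @export
coef.c4_constraint <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.c4_constraint <- function(object, newdata, ...) {
  area <- if (is.data.frame(newdata)) newdata$area_pct else as.numeric(newdata)
  object$intercept + object$slope * area
}

#' Apply an emergent constraint to an observed C4 area
#'
#' Evaluates the fitted across-model line at the observation-constrained C4
#' area. The standard error comes from jointly resampling the area (Normal
#' with its reported sd) and the regression coefficients (from the fit's
#' bootstrap replicates).
#'
#' @param area_pct observed C4 area (% of vegetated land surface).
#' @param area_sd its one-standard-deviation uncertainty.
#' @param fit a [fit_constraint()] result.
#' @param n_boot joint resampling draws (default 1000).
#' @param seed RNG seed.
#' @param slope_only if `TRUE`, scale by the slope alone instead of using the
#'   full fitted line.
#' @return list with `gpp_pct` (point prediction) and `se`.
#' @export
apply_constraint <- function(area_pct, area_sd, fit, n_boot = 1000, seed = 1,
                             slope_only = FALSE) {
  stopifnot(inherits(fit, "c4_constraint"), area_sd >= 0)
  line <- function(a, icpt, slp) if (slope_only) slp * a else icpt + slp * a
  point <- line(area_pct, fit$intercept, fit$slope)
  set.seed(seed)
  areas <- stats::rnorm(n_boot, area_pct, area_sd)
  rows <- sample.int(nrow(fit$boot), n_boot, replace = TRUE)
  draws <- line(areas, fit$boot[rows, "intercept"], fit$boot[rows, "slope"])
  list(gpp_pct = point, se = stats::sd(draws))
}

#' Annual emergent-constraint series
#'
#' Fits the constraint per year and component, applies it to the matching
#' observed areas, and combines grass and crop into a total C4 GPP share with
#' standard errors added in quadrature. Years missing from either input are
#' skipped with a warning.
#'
#' @param points data.frame of ensemble values with columns `model`, `year`,
#'   `component` (`"grass"`/`"crop"`), `area_pct`, `gpp_pct`.
#' @param areas data.frame of observed areas with columns `year`,
#'   `component`, `area_pct`, `sd_pct`.
#' @param n_boot bootstrap replicates per fit/application.
#' @param seed RNG seed (advanced deterministically per year/component).
#' @param slope_only passed to [apply_constraint()].
#' @return list with `fits` (data.frame of per-year slopes and se) and
#'   `applied` (data.frame of per-year GPP shares for grass, crop, total).
#' @export
annual_constraint_series <- function(points, areas, n_boot = 1000, seed = 1,
                                     slope_only = FALSE) {
  need <- c("model", "year", "component", "area_pct", "gpp_pct")
  if (!all(need %in% names(points)))
    stop("'points' needs columns ", paste(need, collapse = ", "))
  years <- sort(intersect(unique(points$year), unique(areas$year)))
  skipped <- setdiff(union(unique(points$year), unique(areas$year)), years)
  if (length(skipped))
    warning("skipping years missing from one input: ",
            paste(sort(skipped), collapse = ", "))
  fits <- NULL; applied <- NULL
  for (y in years) {
    row <- list(year = y)
    ses <- c(grass = NA_real_, crop = NA_real_)
    vals <- c(grass = NA_real_, crop = NA_real_)
    for (cmp in c("grass", "crop")) {
      pts <- points[points$year == y & points$component == cmp, ]
      ar <- areas[areas$year == y & areas$component == cmp, ]
      if (!nrow(pts) || !nrow(ar)) next
      sub_seed <- (seed + 7919 * (y %% 1000) + 101 * (cmp == "crop")) %% .Machine$integer.max
      fit <- fit_constraint(pts, n_boot = n_boot, seed = sub_seed)
      app <- apply_constraint(ar$area_pct[1], ar$sd_pct[1], fit,
                              n_boot = n_boot, seed = sub_seed,
                              slope_only = slope_only)
      fits <- rbind(fits, data.frame(year = y, component = cmp,
                                     slope = fit$slope, se_slope = fit$se_slope,
                                     intercept = fit$intercept, r = fit$r,
                                     p = fit$p))
      vals[cmp] <- app$gpp_pct
      ses[cmp] <- app$se
    }
    applied <- rbind(applied, data.frame(
      year = y, grass_gpp_pct = vals["grass"], grass_se = ses["grass"],
      crop_gpp_pct = vals["crop"], crop_se = ses["crop"],
      total_gpp_pct = sum(vals, na.rm = TRUE),
      total_se = sqrt(sum(ses^2, na.rm = TRUE)), row.names = NULL))
  }
  list(fits = fits, applied = applied)
}
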
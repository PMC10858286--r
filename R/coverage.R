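# The saturating map from the C4:C3 assimilation ratio to C4 grass coverage,
# and the crossover-temperature baseline it is compared against.

curve_forms <- list(
  logistic = list(
    fn = function(ratio, a, b) 100 / (1 + exp(-(a + b * ratio))),
    link = function(p) log(p / (1 - p))
  ),
  gompertz = list(
    fn = function(ratio, a, b) 100 * exp(-exp(-(a + b * ratio))),
    link = function(p) -log(-log(p))
  )
)

#' Fit the saturating ratio-to-coverage curve
#'
#' Fits a monotone saturating curve relating the modeled AC4/AC3 assimilation
#' ratio to observed C4 coverage (% of grassland): coverage rises with the
#' C4 advantage and plateaus near 100%. Default form is a scaled logistic
#' `100 / (1 + exp(-(a + b * ratio)))`, fitted by nonlinear least squares
#' with a linearized start plus multi-start fallback; the 95% confidence band
#' comes from a residual bootstrap (percentile method).
#'
#' @param pairs data.frame with `ratio` (> 0) and `coverage_pct` in
#'   `[0, 100]`; an optional `source` column (e.g. `"TRY"`, `"DG"`) enables
#'   per-source refits via `subset_source`.
#' @param form `"logistic"` or `"gompertz"`.
#' @param n_boot residual-bootstrap replicates for the band (default 1000).
#' @param seed RNG seed.
#' @param subset_source optional source label to fit on a subset.
#' @return an object of class `c4_curve`: list with `form`, `coef` (a, b),
#'   `boot` (replicate coefficients), `pairs`, `n_boot`, `seed`.
#' @export
fit_coverage_curve <- function(pairs, form = c("logistic", "gompertz"),
                               n_boot = 1000, seed = 1, subset_source = NULL) {
  form <- match.arg(form)
  if (!all(c("ratio", "coverage_pct") %in% names(pairs)))
    stop("'pairs' needs columns ratio and coverage_pct")
  if (!is.null(subset_source))
    pairs <- pairs[pairs$source == subset_source, , drop = FALSE]
  pairs <- pairs[!is.na(pairs$ratio) & !is.na(pairs$coverage_pct), , drop = FALSE]
  if (nrow(pairs) < 6) stop("need at least 6 ratio-coverage pairs")
  if (any(pairs$ratio <= 0)) stop("'ratio' must be > 0")
  if (any(pairs$coverage_pct < 0 | pairs$coverage_pct > 100))
    stop("'coverage_pct' must be in [0, 100]")
  ff <- curve_forms[[form]]

  fit_once <- function(ratio, cov) {
    p <- pmin(pmax(cov / 100, 1e-3), 1 - 1e-3)
    lin <- stats::lm(ff$link(p) ~ ratio)
    starts <- rbind(stats::coef(lin), c(-5, 5), c(-2, 2), c(-8, 4))
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::nls(cov ~ ff$fn(ratio, a, b),
                   start = list(a = starts[s, 1], b = starts[s, 2]),
                   control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit)) return(stats::coef(fit))
    }
    # nls cannot handle (near-)zero-residual data; direct least squares can
    ss <- function(th) sum((cov - ff$fn(ratio, th[1], th[2]))^2)
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[s, ], ss, control = list(maxit = 2000,
                                                                 reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (!is.null(best) && best$convergence == 0)
      return(c(a = unname(best$par[1]), b = unname(best$par[2])))
    NULL
  }

  cf <- fit_once(pairs$ratio, pairs$coverage_pct)
  if (is.null(cf))
    stop("curve fit did not converge after multi-start (", form, ", n = ",
         nrow(pairs), ", ratio range [", min(pairs$ratio), ", ",
         max(pairs$ratio), "])")
  fitted <- ff$fn(pairs$ratio, cf[["a"]], cf[["b"]])
  resid <- pairs$coverage_pct - fitted
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("a", "b")))
  for (b in seq_len(n_boot)) {
    cov_b <- pmin(pmax(fitted + sample(resid, replace = TRUE), 0), 100)
    cb <- fit_once(pairs$ratio, cov_b)
    if (!is.null(cb)) boot[b, ] <- cb
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  structure(list(form = form, coef = c(a = cf[["a"]], b = cf[["b"]]),
                 boot = boot, pairs = pairs, n_boot = n_boot, seed = seed),
            class = "c4_curve")
}

#' @export
print.c4_curve <- function(x, ...) {
  cat(sprintf("<c4_curve> %s: coverage = 100 x %s(a + b ratio), a = %.3f, b = %.3f\n",
              x$form, if (x$form == "logistic") "ilogit" else "gompertz",
              x$coef["a"], x$coef["b"]))
  at <- c(1, 1.5, 2, 2.5)
  pr <- predict(x, data.frame(ratio = at))
  cat("  predicted coverage (%):",
      paste(sprintf("%.1f @ ratio %.1f", pr$coverage, at), collapse = ", "), "\n")
  cat(sprintf("  fitted on %d pairs, %d bootstrap bands, seed %d\n",
              nrow(x$pairs), nrow(x$boot), x$seed))
  invisible(x)
}

#' @export
coef.c4_curve <- function(object, ...) object$coef

#' Predict C4 coverage from the assimilation ratio
#'
#' @param object a [fit_coverage_curve()] result.
#' @param newdata data.frame with a `ratio` column (or a numeric vector).
#' @param level confidence level of the bootstrap band (default 0.95).
#' @param ... unused.
#' @return data.frame with `ratio`, `coverage` and the percentile band `lo`,
#'   `hi`; coverage in `[0, 100]`.
#' @export
predict.c4_curve <- function(object, newdata, level = 0.95, ...) {
  ratio <- if (is.data.frame(newdata)) newdata$ratio else as.numeric(newdata)
  ff <- curve_forms[[object$form]]
  cov <- ff$fn(ratio, object$coef["a"], object$coef["b"])
  alpha <- (1 - level) / 2
  if (nrow(object$boot)) {
    bands <- vapply(ratio, function(r) {
      v <- ff$fn(r, object$boot[, "a"], object$boot[, "b"])
      stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    }, numeric(2))
    lo <- bands[1, ]; hi <- bands[2, ]
  } else lo <- hi <- cov
  data.frame(ratio = ratio, coverage = pmin(pmax(cov, 0), 100),
             lo = pmin(pmax(lo, 0), 100), hi = pmin(pmax(hi, 0), 100))
}

#' Apply a fitted coverage curve to a ratio grid
#'
#' Evaluates the fitted curve (and its 95% band) at every valid cell of a
#' native-resolution ratio grid. The per-cell uncertainty is the half-width
#' of the bootstrap 95% band at the cell's ratio. Ratios outside `[0, 10]`
#' are flagged suspect (warning) but still evaluated.
#'
#' @param ratio a [c4grid()] of AC4/AC3 (or a `c4_ratio` object).
#' @param curve a [fit_coverage_curve()] result.
#' @return list with [c4grid()]s `coverage` (% of grassland, in `[0, 100]`)
#'   and `uncertainty` (half-width of the 95% band, >= 0).
#' @export
predict_coverage <- function(ratio, curve) {
  stopifnot(inherits(curve, "c4_curve"))
  if (inherits(ratio, "c4_ratio")) ratio <- ratio$ratio
  stopifnot(inherits(ratio, "c4grid"))
  v <- as.vector(ratio$values)
  ok <- !is.na(v)
  if (any(v[ok] > 10))
    warning(sum(v[ok] > 10), " cells have suspect AC4/AC3 > 10")
  cov <- unc <- rep(NA_real_, length(v))
  if (any(ok)) {
    pr <- predict(curve, data.frame(ratio = v[ok]))
    cov[ok] <- pr$coverage
    unc[ok] <- (pr$hi - pr$lo) / 2
  }
  list(coverage = grid_like(ratio, matrix(cov, length(ratio$lat)), "c4_coverage_pct"),
       uncertainty = grid_like(ratio, matrix(unc, length(ratio$lat)), "c4_coverage_unc"))
}

#' Crossover-temperature baseline model
#'
#' The classic monthly climate rule used as a comparison baseline: a month
#' favors C4 over C3 grasses when mean daytime air temperature is strictly
#' above 22 C and that month's precipitation is at least 25 mm. Where the
#' criteria are met, this baseline assumes the entire grassland fraction of
#' the pixel is C4 (unlike the gradual optimality-based curve).
#'
#' @param monthly_tair list of 12 [c4grid()]s of monthly mean daytime air
#'   temperature (degrees C).
#' @param monthly_precip list of 12 [c4grid()]s of monthly precipitation (mm).
#' @param t_threshold temperature threshold (default 22, strict >).
#' @param p_threshold precipitation threshold (default 25, inclusive >=).
#' @return list with `monthly` (list of 12 0/1 [c4grid()]s) and `annual`
#'   (fraction of favorable months, a [c4grid()]).
#' @export
crossover_baseline <- function(monthly_tair, monthly_precip,
                               t_threshold = 22, p_threshold = 25) {
  if (length(monthly_tair) != 12 || length(monthly_precip) != 12)
    stop("need 12 monthly fields for both temperature and precipitation")
  ref <- monthly_tair[[1]]
  monthly <- vector("list", 12)
  acc <- matrix(0, length(ref$lat), length(ref$lon))
  nok <- acc
  for (m in 1:12) {
    stopifnot_same_grid(ref, monthly_tair[[m]], paste0("tair_m", m))
    stopifnot_same_grid(ref, monthly_precip[[m]], paste0("precip_m", m))
    fav <- (monthly_tair[[m]]$values > t_threshold) &
      (monthly_precip[[m]]$values >= p_threshold)
    monthly[[m]] <- grid_like(ref, fav * 1, sprintf("c4_favorable_m%02d", m))
    ok <- !is.na(fav)
    acc[ok] <- acc[ok] + fav[ok]
    nok <- nok + ok
  }
  annual <- ifelse(nok == 12, acc / 12, NA_real_)
  list(monthly = monthly,
       annual = grid_like(ref, annual, "c4_favorable_fraction"))
}
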
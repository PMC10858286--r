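# Occurrence-record processing: filtering, 10-degree richness gridding, and
# the plot-calibrated richness-to-cover conversion factor.

#' Filter occurrence records to herbaceous, non-crop species
#'
#' Removes woody species and the major C4 crops (maize, sugarcane, millet,
#' sorghum) from a table of georeferenced photosynthetic-pathway records,
#' since the target is natural C4 grass coverage. A record flagged both woody
#' and crop is removed once and counted under woody.
#'
#' @param records data.frame with columns `species`, `latitude`, `longitude`,
#'   `pathway` (`"C3"`/`"C4"`), `woody` (logical) and `crop` (logical).
#' @return the retained records, with attribute `removed` holding the counts
#'   `c(woody = , crop = )`.
#' @export
filter_records <- function(records) {
  need <- c("species", "latitude", "longitude", "pathway", "woody", "crop")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack required columns: ",
                         paste(miss, collapse = ", "))
  bad <- is.na(records$woody) | is.na(records$crop)
  if (any(bad))
    stop("records with unresolvable growth form/crop status: ",
         paste(unique(records$species[bad]), collapse = ", "))
  woody <- records$woody
  crop <- !woody & records$crop
  out <- records[!woody & !crop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(woody = sum(woody), crop = sum(crop))
  out
}

# Half-open cell index anchored at -90/-180; boundary records go to the
# lower cell. Returns the cell's lower edge.
cell_edge <- function(x, origin, size) origin + floor((x - origin) / size) * size

#' Grid C4 species richness into large cells
#'
#' Aggregates filtered occurrence records to coarse (default 10 x 10 degree)
#' cells, counting unique species (case-insensitive binomial match) per cell,
#' and keeps only cells with at least `min_species` species so each retained
#' cell supports a meaningful richness estimate.
#'
#' @param records filtered records (see [filter_records()]).
#' @param cell_size_deg cell size in degrees (default 10).
#' @param min_species minimum unique species per retained cell (default 50).
#' @return data.frame with `cell_id`, `lat`, `lon` (cell centers),
#'   `n_species`, `n_c4`, `richness_pct`.
#' @export
grid_richness <- function(records, cell_size_deg = 10, min_species = 50) {
  if (!nrow(records))
    return(data.frame(cell_id = character(), lat = numeric(), lon = numeric(),
                      n_species = integer(), n_c4 = integer(),
                      richness_pct = numeric()))
  lat0 <- cell_edge(records$latitude, -90, cell_size_deg)
  lon0 <- cell_edge(records$longitude, -180, cell_size_deg)
  key <- paste(lat0, lon0, sep = "_")
  sp <- tolower(trimws(records$species))
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(i) {
    u <- !duplicated(sp[i])
    n <- sum(u)
    n4 <- sum(records$pathway[i][u] == "C4")
    data.frame(lat = lat0[i][1] + cell_size_deg / 2,
               lon = lon0[i][1] + cell_size_deg / 2,
               n_species = n, n_c4 = n4, richness_pct = 100 * n4 / n)
  }))
  out <- out[out$n_species >= min_species, , drop = FALSE]
  out <- cbind(cell_id = sprintf("cell_%g_%g", out$lat, out$lon), out)
  rownames(out) <- NULL
  out
}

#' Fit the richness-to-cover conversion factor
#'
#' Calibrates the factor translating C4 species richness (% of species) into
#' C4 areal cover (% of plot) from paired plot observations. Pairs are
#' grouped by (rounded) richness; each of `n_boot` replicates draws one cover
#' value per group from Normal(group mean, group sd) and fits a
#' through-origin least-squares line (cover must be zero when richness is
#' zero). The factor is the mean of the replicate slopes, its uncertainty
#' their standard deviation.
#'
#' @param pairs data.frame with `richness_pct` and `cover_pct`, both in
#'   `[0, 100]` (control plots only).
#' @param n_boot number of bootstrap fittings (default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @return an object of class `c4_conversion`: list with `slope`, `sd`,
#'   `slopes`, `groups`, `n_boot`, `seed`.
#' @export
fit_conversion_factor <- function(pairs, n_boot = 1000, seed = 1) {
  if (!all(c("richness_pct", "cover_pct") %in% names(pairs)))
    stop("'pairs' needs columns richness_pct and cover_pct")
  if (any(pairs$richness_pct < 0 | pairs$richness_pct > 100, na.rm = TRUE) ||
      any(pairs$cover_pct < 0 | pairs$cover_pct > 100, na.rm = TRUE))
    stop("richness and cover must be percentages in [0, 100]")
  grp <- round(pairs$richness_pct)
  groups <- do.call(rbind, lapply(split(pairs$cover_pct, grp), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  }))
  groups$richness <- as.numeric(rownames(groups))
  rownames(groups) <- NULL
  if (sum(groups$richness > 0) < 1 || nrow(groups) < 2)
    stop("need >= 2 distinct richness groups (with at least one nonzero) ",
         "to identify a slope")
  r <- groups$richness
  set.seed(seed)
  slopes <- vapply(seq_len(n_boot), function(b) {
    cov <- stats::rnorm(nrow(groups), groups$mean, groups$sd)
    sum(r * cov) / sum(r^2)            # through-origin least squares
  }, numeric(1))
  structure(list(slope = mean(slopes), sd = stats::sd(slopes), slopes = slopes,
                 groups = groups, n_boot = n_boot, seed = seed),
            class = "c4_conversion")
}

#' @export
print.c4_conversion <- function(x, ...) {
  cat(sprintf(paste0("<c4_conversion> 1%% C4 species richness -> %.2f +/- %.2f %%",
                     " C4 cover\n  (%d through-origin bootstrap fittings over %d",
                     " richness groups, seed %d)\n"),
              x$slope, x$sd, x$n_boot, nrow(x$groups), x$seed))
  invisible(x)
}

#' @export
coef.c4_conversion <- function(object, ...) c(slope = object$slope)

#' Convert C4 species richness to C4 cover
#'
#' Applies a fitted conversion factor; cover is capped at 100%.
#'
#' @param richness_pct C4 species richness (% of species), in `[0, 100]`;
#'   vectorized.
#' @param factor a [fit_conversion_factor()] result.
#' @param band if `TRUE`, also return the +/- one-sd band.
#' @return coverage (% of grassland), or a data.frame with `coverage`, `lo`,
#'   `hi` when `band = TRUE`.
#' @export
richness_to_coverage <- function(richness_pct, factor, band = FALSE) {
  stopifnot(inherits(factor, "c4_conversion"))
  if (any(richness_pct < 0 | richness_pct > 100, na.rm = TRUE))
    stop("'richness_pct' must be in [0, 100]")
  cov <- pmin(100, factor$slope * richness_pct)
  if (!band) return(cov)
  data.frame(coverage = cov,
             lo = pmin(100, pmax(0, (factor$slope - factor$sd) * richness_pct)),
             hi = pmin(100, (factor$slope + factor$sd) * richness_pct))
}
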
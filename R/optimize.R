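# Coupled leaf gas exchange and the stomatal/root optimality solver.
#
# The diffusion constraint A = g * (Ca - Ci) is solved analytically per
# limitation branch (each branch gives a quadratic or linear equation in Ci);
# the coupled net assimilation is the minimum of the per-branch solutions,
# which equals the intersection of the supply line with the minimum demand
# curve because all branch demands are nondecreasing in Ci.

# Rescale the capacity-derived fields of a parameter set to a new vcmax25.
with_capacity <- function(p, vcmax25) {
  scale <- if (p$vcmax25 > 0) vcmax25 / p$vcmax25 else 0
  p$vcmax25 <- vcmax25
  p$jmax25 <- p$jmax_vcmax_ratio * vcmax25
  p$rd25 <- p$rd25 * scale
  if (p$pathway == "C4") p$kp25 <- p$kp25 * scale
  p
}

# Positive root of g*Ci^2 + b*Ci + c = 0 (a = g > 0, c < 0).
pos_root <- function(g, b, cc) {
  (-b + sqrt(pmax(b^2 - 4 * g * cc, 0))) / (2 * g)
}

# Net assimilation coupled to diffusion at conductance g (mol m-2 s-1).
# Returns A (umol m-2 s-1), Ci (ppm) and the binding limitation label.
coupled_assimilation <- function(g, env, p, kin = kinetics_at(env, p)) {
  ca <- env$co2
  if (g < 1e-10) return(list(a = 0, ci = ca, limit = "stomata_closed"))
  if (p$pathway == "C3") {
    km <- kin$kc * (1 + p$o2 / kin$ko)
    a_c <- g * (ca - pos_root(g, kin$vcmax - kin$rd + g * (km - ca),
                              -(kin$vcmax * kin$gamma_star + kin$rd * km + g * ca * km)))
    j4 <- electron_transport(env$par, kin$jmax, p$quantum_yield, p$theta_j) / 4
    gs2 <- 2 * kin$gamma_star
    a_j <- g * (ca - pos_root(g, j4 - kin$rd + g * (gs2 - ca),
                              -(j4 * kin$gamma_star + kin$rd * gs2 + g * ca * gs2)))
    rates <- c(rubisco = a_c, rubp_regeneration = a_j)
  } else {
    a_v <- kin$vcmax - kin$rd
    a_l <- p$quantum_yield * env$par - kin$rd
    a_p <- (kin$kp * g * ca - g * kin$rd) / (kin$kp + g)
    rates <- c(c4_enzyme = a_v, c4_light = a_l, c4_pep = a_p)
  }
  i <- which.min(rates)
  a <- rates[[i]]
  list(a = a, ci = max(ca - a / g, 1e-6), limit = names(rates)[i])
}

#' Net carbon gain of a (resistance, root fraction) strategy
#'
#' Objective of the leaf optimality model:
#' `A - water_cost * E - root_cost * f_root`, where transpiration
#' `E = 1.6 * g * VPD / Patm` (mol m-2 s-1) and assimilation is coupled to
#' stomatal conductance `g = 1/resistance` through the diffusion constraint.
#' A strategy is feasible only if root water supply
#' `k_plant * f_root * (psi_soil - psi_min)` meets transpiration demand;
#' infeasible strategies return `-Inf`.
#'
#' @param stomatal_resistance stomatal resistance to CO2 (m2 s mol-1), > 0.
#' @param root_fraction fine-root allocation fraction in `[0, 1]`.
#' @param env an [env_state()].
#' @param p a [photo_params()].
#' @return net gain (umol CO2 m-2 s-1), or `-Inf` if water demand exceeds
#'   supply.
#' @export
plant_net_gain <- function(stomatal_resistance, root_fraction, env, p) {
  stopifnot(stomatal_resistance > 0, root_fraction >= 0, root_fraction <= 1)
  g <- 1 / stomatal_resistance
  e <- 1.6 * g * env$vpd / 101.325
  supply <- p$k_plant * root_fraction * max(env$psi_soil - p$psi_min, 0)
  if (e > supply + 1e-15) return(-Inf)
  cp <- coupled_assimilation(g, env, p)
  cp$a - p$water_cost * e - p$root_cost * root_fraction
}

#' Optimal leaf strategy for one environment
#'
#' Jointly optimizes stomatal resistance and fine-root allocation to maximize
#' net carbon gain `A - water_cost * E - root_cost * f_root` subject to the
#' soil-plant-air water balance (supply `k_plant * f_root * (psi_soil -
#' psi_min)` must meet transpiration demand `1.6 * g * VPD / Patm`).
#'
#' For any conductance the optimal root fraction is the smallest feasible one
#' (the objective is strictly decreasing in excess allocation), reducing the
#' problem to a 1-D concave search over conductance, solved by a coarse-grid
#' multistart plus golden-section refinement. Environments with no usable
#' water supply (soil at the -3 MPa floor under nonzero VPD) return the
#' closed-stomata solution with zero assimilation, flagged `"water_supply"`.
#'
#' @param env an [env_state()].
#' @param p a [photo_params()]; if `env$leaf_n` is finite the capacity is
#'   first rescaled from leaf nitrogen via [nitrogen_to_capacity()].
#' @param g_cap upper bound on stomatal conductance (mol m-2 s-1).
#' @return an object of class `plant_optimum`: list with `assimilation`,
#'   `stomatal_resistance`, `root_fraction`, `transpiration`, `ci`,
#'   `net_gain`, `limiting_process`, `convergence`.
#' @export
optimize_plant <- function(env, p, g_cap = 2) {
  stopifnot(inherits(env, "env_state"), inherits(p, "photo_params"))
  if (is.finite(env$leaf_n))
    p <- with_capacity(p, nitrogen_to_capacity(env$leaf_n, p$pathway)$vcmax25)
  par_eff <- if (env$canopy_closed)
    understory_par(env$par, env$lai_overstory) else env$par
  env_loc <- env
  env_loc$par <- par_eff
  kin <- kinetics_at(env_loc, p)
  d <- env$vpd / 101.325                       # mol H2O per mol air
  dpsi <- max(env$psi_soil - p$psi_min, 0)     # MPa above the growth floor
  supply_max <- p$k_plant * dpsi               # at root_fraction = 1
  g_max <- if (d > 0) min(g_cap, supply_max / (1.6 * d)) else g_cap

  if (g_max <= 1e-8) {
    return(structure(list(assimilation = 0, stomatal_resistance = 1e8,
                          root_fraction = 0, transpiration = 0, ci = env$co2,
                          net_gain = 0, limiting_process = "water_supply",
                          convergence = TRUE), class = "plant_optimum"))
  }
  # marginal cost of conductance: water plus the root allocation that must
  # support its transpiration
  unit_cost <- 1.6 * d * (p$water_cost +
    if (dpsi > 0 && d > 0) p$root_cost / (p$k_plant * dpsi) else 0)
  net <- function(g) coupled_assimilation(g, env_loc, p, kin)$a - unit_cost * g

  gs <- exp(seq(log(1e-4), log(g_max), length.out = 16))
  vals <- vapply(gs, net, numeric(1))
  i <- which.max(vals)
  lo <- if (i > 1) gs[i - 1] else 1e-8
  hi <- if (i < length(gs)) gs[i + 1] else g_max
  opt <- stats::optimize(net, c(lo, hi), maximum = TRUE, tol = 1e-7)
  g_star <- opt$maximum
  if (net(g_max) > opt$objective) g_star <- g_max  # boundary optimum
  if (vals[i] > net(g_star)) g_star <- gs[i]       # deterministic fallback

  cp <- coupled_assimilation(g_star, env_loc, p, kin)
  e <- 1.6 * g_star * d
  f <- if (dpsi > 0) min(e / (p$k_plant * dpsi), 1) else 0
  gain <- cp$a - p$water_cost * e - p$root_cost * f
  # closing stomata entirely (gain 0) is always available
  if (gain < 0) {
    return(structure(list(assimilation = 0, stomatal_resistance = 1e8,
                          root_fraction = 0, transpiration = 0, ci = env$co2,
                          net_gain = 0, limiting_process = "unprofitable",
                          convergence = TRUE), class = "plant_optimum"))
  }
  structure(list(assimilation = cp$a, stomatal_resistance = 1 / g_star,
                 root_fraction = f, transpiration = e, ci = cp$ci,
                 net_gain = gain, limiting_process = cp$limit,
                 convergence = TRUE), class = "plant_optimum")
}

#' @export
print.plant_optimum <- function(x, ...) {
  cat(sprintf(paste0("<plant_optimum> A = %.3f umol m-2 s-1, rs = %.3g m2 s mol-1,\n",
                     "  root fraction = %.3f, net gain = %.3f, limited by %s\n"),
              x$assimilation, x$stomatal_resistance, x$root_fraction,
              x$net_gain, x$limiting_process))
  invisible(x)
}

#' C4:C3 assimilation ratio over a climate grid
#'
#' Runs the leaf optimality model for both pathways in every valid cell of a
#' driver grid stack and returns the ratio of optimal C4 to C3 assimilation
#' (AC4/AC3), the statistic that predicts C4 grass coverage. Cells outside
#' the growing-season mask, or where either pathway attains no positive
#' assimilation, are masked.
#'
#' @param climate named list of [c4grid()] driver fields: `tair`, `vpd`,
#'   `par`, `co2`, `psi_soil`, and optionally `leaf_n`, `lai_overstory`,
#'   `canopy_closed` (0/1) and `mask` (growing season, 0/1). All fields must
#'   share the same grid.
#' @param p_c3,p_c4 [photo_params()] templates for the two pathways.
#' @return an object of class `c4_ratio`: list of [c4grid()]s `ratio`, `ac3`,
#'   `ac4`.
#' @export
ac_ratio_grid <- function(climate, p_c3 = photo_params("C3"),
                          p_c4 = photo_params("C4")) {
  need <- c("tair", "vpd", "par", "co2", "psi_soil")
  miss <- setdiff(need, names(climate))
  if (length(miss)) stop("missing driver fields: ", paste(miss, collapse = ", "))
  ref <- climate$tair
  for (nm in setdiff(names(climate), "tair"))
    stopifnot_same_grid(ref, climate[[nm]], nm)
  fld <- function(nm, default) {
    if (!is.null(climate[[nm]])) climate[[nm]]$values
    else matrix(default, length(ref$lat), length(ref$lon))
  }
  tair <- fld("tair", NA); vpd <- fld("vpd", NA); par <- fld("par", NA)
  co2 <- fld("co2", NA); psi <- fld("psi_soil", NA)
  leaf_n <- fld("leaf_n", NA_real_)
  lai <- fld("lai_overstory", 0)
  closed <- fld("canopy_closed", 0)
  gs <- fld("mask", 1)

  ac3 <- ac4 <- matrix(NA_real_, length(ref$lat), length(ref$lon))
  valid <- !is.na(tair) & !is.na(vpd) & !is.na(par) & !is.na(co2) &
    !is.na(psi) & !is.na(gs) & gs > 0
  for (idx in which(valid)) {
    e <- env_state(tair = tair[idx], vpd = vpd[idx], par = par[idx],
                   co2 = co2[idx], psi_soil = max(psi[idx], -3),
                   leaf_n = leaf_n[idx],
                   lai_overstory = if (is.na(lai[idx])) 0 else lai[idx],
                   canopy_closed = !is.na(closed[idx]) && closed[idx] > 0)
    ac3[idx] <- optimize_plant(e, p_c3)$assimilation
    ac4[idx] <- optimize_plant(e, p_c4)$assimilation
  }
  ratio <- ifelse(!is.na(ac3) & !is.na(ac4) & ac3 > 0 & ac4 > 0, ac4 / ac3,
                  NA_real_)
  structure(list(ratio = c4grid(ratio, ref$lat, ref$lon, "ac4_ac3"),
                 ac3 = c4grid(ac3, ref$lat, ref$lon, "ac3"),
                 ac4 = c4grid(ac4, ref$lat, ref$lon, "ac4")),
            class = "c4_ratio")
}

#' @export
print.c4_ratio <- function(x, ...) {
  cat("<c4_ratio> AC4/AC3 assimilation-ratio grid\n")
  print(x$ratio)
  invisible(x)
}
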
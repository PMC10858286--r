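#' Environment state for the leaf optimality model
#'
#' One cell's (or site's) growing-season mean environment driving the leaf
#' model.
#'
#' @param tair air temperature (degrees C).
#' @param vpd vapor pressure deficit (kPa), >= 0.
#' @param par photosynthetically active radiation at the herbaceous layer
#'   (umol m-2 s-1), >= 0.
#' @param co2 atmospheric CO2 mole fraction (ppm), > 0.
#' @param psi_soil soil water potential (MPa), floored at -3; must be <= 0.
#' @param leaf_n leaf nitrogen content (g m-2), >= 0; `NA` means "use the
#'   parameter set's own capacities".
#' @param lai_overstory overstory leaf area index, >= 0.
#' @param canopy_closed logical; `TRUE` for tree/shrub-dominated cells, where
#'   the herbaceous layer sees understory light via Beer's law.
#' @return an object of class `env_state`.
#' @export
env_state <- function(tair, vpd, par, co2, psi_soil = 0, leaf_n = NA_real_,
                      lai_overstory = 0, canopy_closed = FALSE) {
  if (vpd < 0) stop("'vpd' must be >= 0")
  if (par < 0) stop("'par' must be >= 0")
  if (co2 <= 0) stop("'co2' must be > 0")
  if (psi_soil > 0) stop("'psi_soil' must be <= 0")
  if (lai_overstory < 0) stop("'lai_overstory' must be >= 0")
  psi_soil <- max(psi_soil, -3)  # growth floor
  structure(list(tair = tair, vpd = vpd, par = par, co2 = co2,
                 psi_soil = psi_soil, leaf_n = leaf_n,
                 lai_overstory = lai_overstory,
                 canopy_closed = isTRUE(canopy_closed)),
            class = "env_state")
}

#' Soil texture parameters for the water retention curve
#' @param theta_sat saturated volumetric water content (m3 m-3), in (0, 1].
#' @param psi_sat saturation water potential (MPa), < 0.
#' @param b_ch Clapp-Hornberger exponent, > 0.
#' @return an object of class `soil_texture`.
#' @export
soil_texture <- function(theta_sat = 0.45, psi_sat = -0.002, b_ch = 5) {
  if (theta_sat <= 0 || theta_sat > 1) stop("'theta_sat' must be in (0, 1]")
  if (psi_sat >= 0) stop("'psi_sat' must be < 0")
  if (b_ch <= 0) stop("'b_ch' must be > 0")
  structure(list(theta_sat = theta_sat, psi_sat = psi_sat, b_ch = b_ch),
            class = "soil_texture")
}

#' Soil water potential from volumetric water content
#'
#' Clapp-Hornberger power-law retention curve
#' psi = psi_sat * (theta / theta_sat)^(-b), floored at -3 MPa (the
#' minimum potential at which growth is allowed in the optimality model).
#' Water contents above saturation are clipped to saturation.
#'
#' @param theta volumetric water content (m3 m-3), > 0; vectorized.
#' @param tex a [soil_texture()].
#' @param floor_mpa lower bound on the returned potential (MPa).
#' @return soil water potential (MPa), in `[floor_mpa, 0)`.
#' @examples
#' soil_water_potential(0.225, soil_texture(0.45, -0.002, 4))  # -0.032 MPa
#' @export
soil_water_potential <- function(theta, tex = soil_texture(), floor_mpa = -3) {
  stopifnot(inherits(tex, "soil_texture"))
  if (any(theta <= 0)) stop("'theta' must be > 0")
  rel <- pmin(theta / tex$theta_sat, 1)
  pmax(tex$psi_sat * rel^(-tex$b_ch), floor_mpa)
}

#' Understory light through an overstory canopy
#'
#' Beer's-law attenuation of top-of-canopy PAR through the overstory leaf
#' area: `par_top * exp(-k_ext * lai)`. Applied to closed-canopy cells only,
#' since C4 grasses in forests and shrublands grow in the understory.
#'
#' @param par_top above-canopy PAR (umol m-2 s-1), >= 0; vectorized.
#' @param lai_overstory overstory leaf area index, >= 0.
#' @param k_ext extinction coefficient, > 0 (default 0.5).
#' @return PAR at the herbaceous layer, in `[0, par_top]`.
#' @export
understory_par <- function(par_top, lai_overstory, k_ext = 0.5) {
  if (any(par_top < 0)) stop("'par_top' must be >= 0")
  if (any(lai_overstory < 0)) stop("'lai_overstory' must be >= 0")
  if (k_ext <= 0) stop("'k_ext' must be > 0")
  par_top * exp(-k_ext * lai_overstory)
}

#' Photosynthetic capacity from leaf nitrogen
#'
#' Linear mapping from leaf nitrogen content to carboxylation capacity, with
#' a pathway-specific slope (C4 leaves achieve their lower Rubisco load at
#' higher nitrogen-use efficiency), and the optimal Jmax/Vcmax ratio: 2.1 for
#' C3 and 5.0 for C4.
#'
#' @param leaf_n leaf nitrogen content (g m-2), >= 0.
#' @param pathway `"C3"` or `"C4"`.
#' @param slope umol CO2 m-2 s-1 per g N m-2; defaults 25 (C3), 18 (C4).
#' @return list with `vcmax25` and `jmax25` (umol m-2 s-1).
#' @export
nitrogen_to_capacity <- function(leaf_n, pathway = c("C3", "C4"), slope = NULL) {
  pathway <- match.arg(pathway)
  if (any(leaf_n < 0)) stop("'leaf_n' must be >= 0")
  if (is.null(slope)) slope <- if (pathway == "C3") 25 else 10
  vcmax25 <- slope * leaf_n
  ratio <- if (pathway == "C3") 2.1 else 5.0
  list(vcmax25 = vcmax25, jmax25 = ratio * vcmax25)
}

#' Leaf photosynthesis parameter set
#'
#' Kinetic constants, costs and temperature responses for one pathway.
#' C3 Rubisco kinetics follow the standard in-vivo values (Kc, Ko, Gamma* at
#' 25 C with Arrhenius activation energies); Vcmax and Jmax use a peaked
#' Arrhenius response; the C4 cycle uses Q10 = 2 kinetics with low- and
#' high-temperature inhibition and a PEP-carboxylase initial slope `kp25`.
#' The exact parameterization is provisional (standard literature values);
#' costs of water and fine roots enter the optimization objective
#' `A - water_cost * E - root_cost * f_root`.
#'
#' @param pathway `"C3"` or `"C4"`.
#' @param vcmax25 carboxylation capacity at 25 C (umol m-2 s-1); if `leaf_n`
#'   is supplied it is derived via [nitrogen_to_capacity()] instead.
#' @param leaf_n optional leaf nitrogen (g m-2) from which to derive capacity.
#' @param water_cost marginal carbon cost of transpiration
#'   (umol CO2 per mol H2O).
#' @param root_cost carbon cost of fine-root allocation
#'   (umol CO2 m-2 s-1 per unit root fraction).
#' @param k_plant maximum soil-to-leaf water supply per unit root fraction and
#'   water-potential difference (mol H2O m-2 s-1 MPa-1).
#' @return an object of class `photo_params`.
#' @export
photo_params <- function(pathway = c("C3", "C4"), vcmax25 = NULL, leaf_n = NULL,
                         water_cost = 400, root_cost = 10, k_plant = 0.004) {
  pathway <- match.arg(pathway)
  if (!is.null(leaf_n)) {
    vcmax25 <- nitrogen_to_capacity(leaf_n, pathway)$vcmax25
  } else if (is.null(vcmax25)) {
    vcmax25 <- if (pathway == "C3") 50 else 20
  }
  if (vcmax25 < 0) stop("'vcmax25' must be >= 0")
  ratio <- if (pathway == "C3") 2.1 else 5.0
  p <- list(
    pathway = pathway,
    vcmax25 = vcmax25,
    jmax_vcmax_ratio = ratio,
    jmax25 = ratio * vcmax25,
    water_cost = water_cost,
    root_cost = root_cost,
    k_plant = k_plant,
    psi_min = -3          # leaf water potential floor (MPa)
  )
  if (pathway == "C3") {
    p <- c(p, list(
      rd25 = 0.015 * vcmax25,
      quantum_yield = 0.3,   # mol e- per mol photon (effective)
      theta_j = 0.7,
      kc25 = 404.9,          # umol mol-1
      ko25 = 278.4,          # mmol mol-1
      gamma_star25 = 42.75,  # umol mol-1
      o2 = 210,              # mmol mol-1
      ea_vcmax = 65330, ea_jmax = 43540, ea_rd = 46390,
      ea_kc = 79430, ea_ko = 36380, ea_gamma = 37830,
      hd = 200000, ds = 640
    ))
  } else {
    p <- c(p, list(
      rd25 = 0.02 * vcmax25,
      quantum_yield = 0.05,       # mol CO2 per mol photon
      kp25 = 0.02 * vcmax25,      # umol m-2 s-1 per ppm CO2
      q10 = 2,
      t_low = 13, t_high = 38, s_inhib = 0.3
    ))
  }
  structure(p, class = "photo_params")
}

# Arrhenius response normalized to 25 C; Ea in J mol-1, T in deg C.
arrhenius <- function(tc, ea) {
  exp(ea * (tc - 25) / (298.15 * 8.314 * (tc + 273.15)))
}

# Peaked Arrhenius (activation + high-temperature deactivation), = 1 at 25 C.
peaked_arrhenius <- function(tc, ea, hd, ds) {
  tk <- tc + 273.15
  num <- 1 + exp((298.15 * ds - hd) / (298.15 * 8.314))
  den <- 1 + exp((tk * ds - hd) / (tk * 8.314))
  arrhenius(tc, ea) * num / den
}

# Collatz-style Q10 response with logistic low/high temperature inhibition.
collatz_temp <- function(tc, q10, t_low, t_high, s) {
  q10^((tc - 25) / 10) / ((1 + exp(s * (t_low - tc))) * (1 + exp(s * (tc - t_high))))
}

# Temperature-adjusted kinetic quantities for a parameter set.
kinetics_at <- function(env, p) {
  tc <- env$tair
  if (p$pathway == "C3") {
    list(vcmax = p$vcmax25 * peaked_arrhenius(tc, p$ea_vcmax, p$hd, p$ds),
         jmax = p$jmax25 * peaked_arrhenius(tc, p$ea_jmax, p$hd, p$ds),
         rd = p$rd25 * arrhenius(tc, p$ea_rd),
         kc = p$kc25 * arrhenius(tc, p$ea_kc),
         ko = p$ko25 * arrhenius(tc, p$ea_ko),
         gamma_star = p$gamma_star25 * arrhenius(tc, p$ea_gamma))
  } else {
    vt <- collatz_temp(tc, p$q10, p$t_low, p$t_high, p$s_inhib)
    list(vcmax = p$vcmax25 * vt,
         kp = p$kp25 * p$q10^((tc - 25) / 10),
         rd = p$rd25 * p$q10^((tc - 25) / 10) / (1 + exp(1.3 * (tc - 55))))
  }
}

# Electron transport rate from the non-rectangular hyperbola.
electron_transport <- function(par, jmax, alpha, theta) {
  if (jmax <= 0) return(0)
  ipar <- alpha * par
  b <- ipar + jmax
  (b - sqrt(pmax(b^2 - 4 * theta * ipar * jmax, 0))) / (2 * theta)
}

#' C3 net assimilation at a given internal CO2
#'
#' Farquhar-von Caemmerer-Berry model: net assimilation is the minimum of the
#' Rubisco-limited and RuBP-regeneration-limited gross rates minus dark
#' respiration, with temperature-adjusted kinetics.
#'
#' @param ci internal CO2 mole fraction (ppm), > 0.
#' @param env an [env_state()].
#' @param p a C3 [photo_params()].
#' @return net assimilation A (umol m-2 s-1).
#' @export
c3_assimilation <- function(ci, env, p) {
  stopifnot(inherits(p, "photo_params"))
  if (p$pathway != "C3") stop("'p' must be a C3 parameter set")
  if (any(ci <= 0)) stop("'ci' must be > 0")
  k <- kinetics_at(env, p)
  # Ko and O2 both in mmol/mol, so O2/Ko is dimensionless
  wc <- k$vcmax * (ci - k$gamma_star) / (ci + k$kc * (1 + p$o2 / k$ko))
  j <- electron_transport(env$par, k$jmax, p$quantum_yield, p$theta_j)
  wj <- (j / 4) * (ci - k$gamma_star) / (ci + 2 * k$gamma_star)
  pmin(wc, wj) - k$rd
}

#' C4 net assimilation at a given internal CO2
#'
#' Collatz-type C4 model: net assimilation is the minimum of the
#' enzyme-limited (Rubisco), light-limited, and PEP-carboxylase CO2-limited
#' rates minus dark respiration. The CO2-concentrating mechanism makes the
#' rate nearly CO2-saturated at ambient internal CO2.
#'
#' @param ci internal CO2 mole fraction (ppm), > 0.
#' @param env an [env_state()].
#' @param p a C4 [photo_params()].
#' @return net assimilation A (umol m-2 s-1).
#' @export
c4_assimilation <- function(ci, env, p) {
  stopifnot(inherits(p, "photo_params"))
  if (p$pathway != "C4") stop("'p' must be a C4 parameter set")
  if (any(ci <= 0)) stop("'ci' must be > 0")
  k <- kinetics_at(env, p)
  pmin(k$vcmax, p$quantum_yield * env$par, k$kp * ci) - k$rd
}

#' @rdname c3_assimilation
#' @details `assimilation()` dispatches on the parameter set's pathway.
#' @export
assimilation <- function(ci, env, p) {
  if (p$pathway == "C3") c3_assimilation(ci, env, p) else c4_assimilation(ci, env, p)
}
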
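# Shared fixtures and the exhaustive grid-search oracle for the optimality
# solver.

make_env <- function(tair = 25, vpd = 1.5, par = 1500, co2 = 400,
                     psi_soil = -0.5, ...) {
  env_state(tair = tair, vpd = vpd, par = par, co2 = co2,
            psi_soil = psi_soil, ...)
}

random_envs <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    env_state(tair = runif(1, 10, 35), vpd = runif(1, 0.5, 3),
              par = runif(1, 200, 2000), co2 = runif(1, 300, 600),
              psi_soil = runif(1, -1.5, -0.05)))
}

# Exhaustive 200 x 200 grid search over (stomatal resistance, root fraction),
# iteratively refined around the best cell. Net gain for a whole resistance
# column is derived from a single evaluation of the package objective at
# f = 1 (assimilation does not depend on the root fraction; the objective is
# linear in it), so the full grid is still evaluated exhaustively.
grid_oracle <- function(env, p, n = 200, stages = 3) {
  lr_lim <- log(c(0.5, 1e4))   # resistance bounds (m2 s mol-1)
  f_lim <- c(0, 1)
  dpsi <- max(env$psi_soil - p$psi_min, 0)
  d <- env$vpd / 101.325
  best <- -Inf; best_ij <- c(1, 1)
  for (s in seq_len(stages)) {
    lr <- seq(lr_lim[1], lr_lim[2], length.out = n)
    f <- seq(f_lim[1], f_lim[2], length.out = n)
    best_s <- -Inf; ij <- c(1, 1)
    for (i in seq_len(n)) {
      r <- exp(lr[i])
      e <- 1.6 * d / r
      if (e > p$k_plant * dpsi * max(f) + 1e-15) next  # column infeasible
      base <- plant_net_gain(r, 1, env, p)             # objective at f = 1
      nets <- base + p$root_cost * (1 - f)
      nets[p$k_plant * f * dpsi + 1e-15 < e] <- -Inf
      j <- which.max(nets)
      if (nets[j] > best_s) { best_s <- nets[j]; ij <- c(i, j) }
    }
    if (best_s > best) best <- best_s
    dlr <- (lr_lim[2] - lr_lim[1]) / (n - 1)
    lr_lim <- c(max(log(0.5), lr[ij[1]] - 2 * dlr),
                min(log(1e4), lr[ij[1]] + 2 * dlr))
    # the refined f window must cover the feasibility boundary of the
    # refined resistance window, where the optimum sits
    f_need <- if (dpsi > 0) 1.6 * d / (exp(lr_lim) * p$k_plant * dpsi) else c(0, 0)
    df <- (f_lim[2] - f_lim[1]) / (n - 1)
    f_lim <- c(max(0, min(f_need) - df), min(1, max(f_need) + df))
    if (f_lim[1] >= f_lim[2]) f_lim <- c(max(0, f_lim[2] - df), f_lim[2])
  }
  best
}

# Pairs drawn from a known logistic ratio->coverage curve plus noise.
logistic_pairs <- function(n = 60, a = -7.9, b = 5, noise = 4, seed = 3) {
  set.seed(seed)
  ratio <- runif(n, 0.4, 2.8)
  cov <- 100 / (1 + exp(-(a + b * ratio))) + rnorm(n, 0, noise)
  data.frame(ratio = ratio, coverage_pct = pmin(100, pmax(0, cov)),
             source = rep(c("TRY", "DG"), length.out = n))
}

# Toy 4-cell abundance fixture covering all four synergy classes.
synergy_fixture <- function() {
  lat <- c(2.5, -2.5); lon <- c(2.5, 7.5)
  mk <- function(v, comp) {
    structure(list(abundance = c4grid(matrix(v, 2, 2), lat, lon),
                   sd = c4grid(matrix(0, 2, 2), lat, lon),
                   component = comp, year = NA), class = "c4_abundance")
  }
  list(early_grass = mk(c(10, 10, 10, 10), "grass"),
       late_grass = mk(c(12, 12, 8, 8), "grass"),    # + + - -
       early_crop = mk(c(5, 5, 5, 5), "crop"),
       late_crop = mk(c(6, 4, 6, 4), "crop"))        # + - + -
}
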
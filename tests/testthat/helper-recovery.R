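# Parameter-recovery harness used by the acceptance suite: simulate a
# scenario, run selection + variation partitioning (ENV_ONLY / SPACE_ONLY)
# or the gradient nestedness test (NESTED / TURNOVER), and return the
# quantities the scenario is supposed to recover.

recover_varpart <- function(scenario, seed, n_sites = 30, spatial_range = 20,
                            n_perm_sel = 99, n_perm_vp = 199) {
  cfg <- scenario_config(scenario, n_sites = n_sites,
                         spatial_range = spatial_range, seed = seed)
  sim <- simulate_metacommunity(cfg)
  pooled <- pool_periods(sim$fall, sim$spring)
  keep <- rowSums(pooled$counts) > 0
  Y <- hellinger(pooled$counts[keep, colSums(pooled$counts) > 0, drop = FALSE])
  env <- as.data.frame(sim$env)[keep, ]
  Xe <- as.matrix(env[, c("beach_index", "mean_diameter_phi",
                          "slope_ratio", "width_m")])
  Xe <- Xe[, apply(Xe, 2, stats::sd) > 1e-12, drop = FALSE]
  mem <- dbmem(distance_matrix(sim$sites[keep, , drop = FALSE]))
  sel_e <- if (ncol(Xe) > 0)
    forward_select(Y, Xe, n_perm = n_perm_sel, seed = seed + 1) else NULL
  sel_s <- forward_select(Y, mem$vectors, n_perm = n_perm_sel, seed = seed + 2)
  E <- if (!is.null(sel_e) && nrow(sel_e) > 0)
    Xe[, sel_e$variable, drop = FALSE] else NULL
  S <- if (nrow(sel_s) > 0) mem$vectors[, sel_s$variable, drop = FALSE] else NULL
  if (is.null(E) && is.null(S))
    return(list(a = 0, c = 0, p_a = NA_real_, p_c = NA_real_))
  vp <- variation_partition(Y, E, S, n_perm = n_perm_vp, seed = seed + 3)
  list(a = vp$a, c = vp$c,
       p_a = if (!is.null(vp$test_a)) vp$test_a$p else NA_real_,
       p_c = if (!is.null(vp$test_c)) vp$test_c$p else NA_real_)
}

recover_nestedness <- function(scenario, seed, n_rand = 499) {
  sim <- simulate_metacommunity(scenario_config(scenario, seed = seed))
  rk <- gradient_rankings(sim$env)$BI_desc
  pres <- suppressWarnings(to_presence(pool_periods(sim$fall, sim$spring)))
  rmx <- suppressMessages(ranked_matrix(pres, rk))
  nestedness_test(rmx, "NODF", n = n_rand, seed = seed)$z
}
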
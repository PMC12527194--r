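# Shared fixtures.  Expensive simulations are computed once per test run
# and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# reference periodic solution of the default tree (coarse preset)
ref_solution <- function() {
  memo("ref_sol", simulate_to_periodic(build_default_tree(175),
                                       cfg = sim_config("coarse")))
}

# reference forward observables at the default initial parameter values
ref_observables <- function() {
  memo("ref_obs", forward_observables(fit_init(), build_default_tree(175),
                                      HR = 75, cfg = sim_config("coarse")))
}

# build a minimal pwp_tree around a hand-made segment table
toy_tree <- function(segments) {
  tr <- build_default_tree(175)
  tr$segments <- segments
  tr$cuff_sites <- list()
  tr$pwv_path <- list(from = segments$full_name[1],
                      to = segments$full_name[nrow(segments)])
  tr
}

toy_segment <- function(id, name, parent, L, rp, rd,
                        R1 = NA, R2 = NA, C = NA) {
  data.frame(id = id, name = name, side = "", full_name = name,
             length_cm = L, radius_prox_cm = rp, radius_dist_cm = rd,
             parent = parent, R1 = R1, R2 = R2, C = C,
             R1_baseline = R1, R2_baseline = R2)
}

# single uniform frictionless vessel with matched (reflection-free)
# resistive termination, excited by a narrow inflow pulse
matched_vessel_solution <- function() {
  memo("matched_vessel", {
    r0 <- 0.5; L <- 100
    k <- read_tree()$stiffness
    f0 <- 4 / 3 * wall_stiffness(r0, k)
    c0 <- sqrt(f0 / (2 * 1.06))
    Z <- 1.06 * c0 / (pi * r0^2) / 1333.223874
    tr <- toy_tree(toy_segment(1, "v", 0, L, r0, r0, R1 = Z, R2 = 0, C = 0))
    T <- 0.5
    tt <- seq(0, T, length.out = 500)[-500]
    Q <- 5 * exp(-((tt - 0.05) / 0.012)^2)
    sol <- simulate_to_periodic(
      tr, lv = list(T = T),
      cfg = sim_config(dx_target = 0.5, mu = 0, p_init = 0, p_ven = 0,
                       tol = 1e-8, max_cycles = 10),
      inflow = Q, period = T)
    list(sol = sol, c0 = c0)
  })
}

# wrap a normalized 1000-point waveform as an averaged_waveform
as_awf <- function(samples, period_s, site = NA_character_) {
  structure(list(site = site, samples = samples, period_s = period_s,
                 n_beats_averaged = 5),
            class = "averaged_waveform")
}

# a noise-free measured case generated by the forward model itself; the
# config carries the same pinned grid reference that pwp_fit uses, so the
# fitted forward model matches the generating one exactly
synthetic_case <- function(truth, height = 175, HR = 75,
                           cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- sim_config("coarse", max_cycles = 6, tol = 0)
    cfg$k3_ref <- fit_bounds()$k3[2]
  }
  tree <- build_default_tree(height)
  obs <- forward_observables(truth, tree, HR, cfg)
  case <- pwp_case(lapply(obs$waveforms, as_awf, period_s = 60 / HR),
                   SP = obs$SP, DP = obs$DP, HR = HR, height = height)
  list(case = case, tree = tree, obs = obs, cfg = cfg)
}

# small cached synthetic cohort used by several prediction-layer tests
small_cohort <- function() {
  memo("small_cohort", generate_cohort(12, 5, seed = 71))
}

# plausible truth draws (the generator's own rejection rule), cached
truth_draws <- function(n, seed) {
  memo(paste0("truth", n, "_", seed), {
    coh <- generate_cohort(n, 1, seed = seed)
    lapply(coh$patients, function(p)
      list(params = p$days[[1]]$params, HR = p$days[[1]]$HR,
           height = p$demographics$height))
  })
}
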
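test_that("elastance rises from Emin to a plateau at Emax and is periodic", {
  p <- list(Emax = 2.5, Emin = 0.08, tm = 0.3, T = 0.8)
  expect_equal(elastance(0, p), 0.08)
  expect_equal(elastance(0.8, p), elastance(0, p))
  # plateau: from tm to tm + 0.1 T
  expect_equal(elastance(0.31, p), 2.5)
  expect_equal(elastance(0.37, p), 2.5)
  # ventricular pressure is linear in elastance at fixed volume, so
  # doubling Emax doubles the plateau value
  p2 <- within(p, Emax <- 5)
  expect_equal(elastance(0.33, p2), 2 * elastance(0.33, p))
  # wrapped outside [0, T]
  expect_equal(elastance(0.9, p), elastance(0.1, p))
})

test_that("converged run conserves mass within 1 percent", {
  sol <- ref_solution()
  expect_true(sol$converged)
  expect_lt(flow_imbalance(sol), 0.01)
})

test_that("pressure metrics recover closed forms from the area trace", {
  # fabricate a one-segment solution with a known midpoint pressure trace
  f0 <- 1.2e6; A0 <- 3
  T <- 1
  t <- seq(0, T, length.out = 200 + 1)[1:200]
  mk_sol <- function(p_mmHg) {
    A <- A0 / (1 - p_mmHg * 1333.223874 / f0)^2
    tr <- toy_tree(toy_segment(1, "v", 0, 10, sqrt(A0 / pi), sqrt(A0 / pi),
                               R1 = 1, R2 = 1, C = 1))
    structure(list(tree = tr, lv = list(T = T), t = t,
                   A = list(matrix(rep(A, 3), nrow = 3, byrow = TRUE)),
                   A0 = list(rep(A0, 3)), f0 = list(rep(f0, 3)),
                   x = list(c(1, 5, 9))),
              class = "pwp_solution")
  }
  flat <- mk_sol(rep(80, 200))
  pm <- pressure_metrics(flat, "v")
  expect_equal(pm$SP, 80, tolerance = 1e-10)
  expect_equal(pm$DP, 80, tolerance = 1e-10)
  expect_equal(pm$MAP, 80, tolerance = 1e-10)
  sine <- mk_sol(90 + 30 * sin(2 * pi * t / T))
  pm <- pressure_metrics(sine, "v")
  expect_equal(pm$SP, 120, tolerance = 1e-3)
  expect_equal(pm$DP, 60, tolerance = 1e-3)
  expect_equal(pm$MAP, 90, tolerance = 1e-3)
  # the 2/3 DP + 1/3 SP rule as a cross-check heuristic
  expect_equal(2 / 3 * 60 + 1 / 3 * 120, 80)
})

test_that("segment volume waveform integrates area and is linear", {
  sol <- ref_solution()
  i <- which(sol$tree$segments$full_name == "radial L")
  v <- segment_volume_waveform(sol, "radial L")
  # constant-area analogue: volume = A * L
  fake <- sol
  fake$A[[i]][] <- 0.2
  vf <- segment_volume_waveform(fake, "radial L")
  expect_equal(unname(vf[1]), 0.2 * sol$tree$segments$length_cm[i],
               tolerance = 1e-10)
  # linearity
  fake2 <- sol
  fake2$A[[i]] <- 2 * sol$A[[i]]
  expect_equal(segment_volume_waveform(fake2, "radial L"), 2 * v)
  # periodic trace with physiologic pulsation
  expect_gt(diff(range(v)) / mean(v), 0.005)
  expect_error(segment_volume_waveform(sol, "no such artery"), "unknown")
})

test_that("stroke volume matches the ventricular volume excursion", {
  sol <- ref_solution()
  sv <- stroke_volume(sol)
  expect_gt(sv, 40)
  expect_lt(sv, 110)
  excursion <- diff(range(sol$Vlv))
  expect_equal(sv, excursion, tolerance = 0.01)
  # rectangular inflow: SV = Q * tau
  fake <- sol
  fake$Qin <- ifelse(sol$t < 0.25, 200, 0)
  fake$lv$T <- 0.8
  expect_equal(stroke_volume(fake), 200 * 0.25, tolerance = 0.01)
})

test_that("foot-to-foot transit of a pulse matches the analytic tube-law speed", {
  mv <- matched_vessel_solution()
  sol <- mv$sol
  x <- sol$x[[1]]
  i1 <- 21; i2 <- 181
  f1 <- wave_foot(sol$t, pressure_waveform(sol, "v", node = i1))
  f2 <- wave_foot(sol$t, pressure_waveform(sol, "v", node = i2))
  v <- (x[i2] - x[i1]) / (f2 - f1)
  expect_lt(abs(v - mv$c0) / mv$c0, 0.02)
  # matched termination is reflection-free: negligible late signal
  p1 <- pressure_waveform(sol, "v", node = i1)
  expect_lt(max(abs(p1[sol$t > 0.35])), 0.02 * max(p1))
})

test_that("wave_foot recovers known delays and rejects degenerate input", {
  t <- seq(0, 0.8, length.out = 400 + 1)[1:400]
  beat <- function(t0) {
    u <- ((t - t0) %% 0.8) / 0.8
    ifelse(u < 0.3, sin(pi * u / 0.3)^2, 0)
  }
  d <- wave_foot(t, beat(0.15)) - wave_foot(t, beat(0.10))
  expect_equal(d, 0.05, tolerance = 1e-3)
  # identical waveforms shifted by 0.05 s over a 50 cm path -> 1000 cm/s
  expect_equal(50 / d, 1000, tolerance = 0.02)
  expect_error(wave_foot(t, rep(1, 400)), "peak|upstroke")
})

test_that("pwv on the default tree is physiological and increases with k3", {
  sol <- ref_solution()
  pwv0 <- compute_pwv(sol)
  expect_gt(pwv0, 400)
  expect_lt(pwv0, 2000)
  tr <- build_default_tree(175)
  tr$stiffness$k3 <- 1.6e6
  pwv_stiff <- compute_pwv(simulate_to_periodic(tr, cfg = sim_config("coarse")))
  expect_gt(pwv_stiff, pwv0)
})

test_that("mean root pressure rises with SR, consistent with a lumped model", {
  tr <- build_default_tree(175)
  sol1 <- ref_solution()
  sol2 <- simulate_to_periodic(scale_terminals(tr, 2), cfg = sim_config("coarse"))
  map1 <- pressure_metrics(sol1, "ascending aorta")$MAP
  map2 <- pressure_metrics(sol2, "ascending aorta")$MAP
  expect_gt(map2, map1)
  # two-element lumped check: MAP - p_ven = CO * R_total
  lump1 <- sol1$inflow_mean * total_terminal_resistance(tr) + 5
  lump2 <- sol2$inflow_mean * total_terminal_resistance(scale_terminals(tr, 2)) + 5
  expect_lt(abs(map1 - lump1) / lump1, 0.10)
  expect_lt(abs(map2 - lump2) / lump2, 0.10)
})

test_that("halving the spatial step changes radial SP/DP by < 1 mmHg", {
  tr <- build_default_tree(175)
  a <- pressure_metrics(simulate_to_periodic(tr, cfg = sim_config(dx_target = 2)),
                        "radial L")
  b <- pressure_metrics(simulate_to_periodic(tr, cfg = sim_config(dx_target = 1)),
                        "radial L")
  expect_lt(abs(a$SP - b$SP), 1)
  expect_lt(abs(a$DP - b$DP), 1)
})

test_that("solution export writes readable CSV plus a convergence report", {
  sol <- ref_solution()
  path <- tempfile(fileext = ".csv")
  export_solution_csv(sol, "radial L", path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "pressure_mmHg", "flow_ml_s", "area_cm2"))
  expect_equal(nrow(df), sol$steps)
  rep <- jsonlite::read_json(sub("\\.csv$", "_convergence.json", path))
  expect_true(rep$converged)
})
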
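# Haemodynamic simulation: R surface over the compiled network solver,
# plus derived quantities (volume waveforms, SP/DP/MAP, stroke volume, PWV).

#' Left-ventricular time-varying elastance
#'
#' Piecewise raised-cosine elastance: rises from `Emin` to `Emax` over
#' `[0, tm]`, holds `Emax` for a plateau, relaxes back to `Emin`, and is
#' periodic with period `T`.  Times outside `[0, T]` are wrapped.
#'
#' @param t Time(s) in seconds (vectorized).
#' @param params List with `Emax`, `Emin` (mmHg/ml), `tm` (s), `T` (s) and
#'   optionally `plat_frac`, `relax_frac` (fractions of `T`, defaults 0.1
#'   and 0.15).
#' @return Elastance in mmHg/ml.
#' @export
elastance <- function(t, params) {
  p <- lv_defaults(params)
  vapply(t, function(ti)
    elastance_cpp(ti, p$Emax, p$Emin, p$tm, p$T, p$plat_frac, p$relax_frac),
    numeric(1))
}

lv_defaults <- function(params = list()) {
  p <- list(Emax = 2.5, Emin = 0.08, tm = 0.30, pla = 9, T = 0.8,
            V0 = 10, plat_frac = 0.10, relax_frac = 0.15,
            Rmv = 0.006, Rav = 0.010)
  p[names(params)] <- params
  stopifnot(p$Emax > p$Emin, p$Emin > 0, p$tm > 0, p$tm < p$T, p$pla > 0)
  p
}

#' Simulation configuration
#'
#' @param preset One of `"coarse"`, `"default"`, `"fine"` controlling the
#'   target spatial step (3, 2 and 1 cm).
#' @param dx_target Spatial step target in cm (overrides `preset`).
#' @param cfl CFL number used to set the time step (< 1).
#' @param max_cycles Cap on cardiac cycles run towards periodicity.
#' @param tol Relative cycle-to-cycle L2 tolerance on root pressure.
#' @param rho Blood density, g/ml.
#' @param mu Blood viscosity, poise (g/(cm s)); 0.04 poise = 4 mPa s.
#' @param p_init Initial arterial pressure, mmHg.
#' @param p_ven Venous (outflow) pressure, mmHg.
#' @param visc Dimensionless upwind-dissipation blend of the face fluxes
#'   (suppresses odd-even decoupling; 0 disables).
#' @return A `pwp_config` list.
#' @export
sim_config <- function(preset = c("default", "coarse", "fine"),
                       dx_target = NULL, cfl = 0.9, max_cycles = 20,
                       tol = 1e-3, rho = 1.06, mu = 0.04,
                       p_init = 75, p_ven = 5, visc = 0.05) {
  preset <- match.arg(preset)
  if (is.null(dx_target))
    dx_target <- c(default = 2, coarse = 3, fine = 1)[[preset]]
  # tol <= 0 runs exactly max_cycles cycles (smooth objective for fitting)
  stopifnot(cfl > 0, cfl <= 1, is.finite(tol), max_cycles >= 2, visc >= 0)
  structure(list(dx_target = dx_target, cfl = cfl, max_cycles = max_cycles,
                 tol = tol, rho = rho, mu = mu, p_init = p_init,
                 p_ven = p_ven, visc = visc, preset = preset),
            class = "pwp_config")
}

#' Simulate the arterial network to a periodic state
#'
#' Runs the compiled 1D solver (MacCormack scheme, characteristic
#' boundaries, total-pressure junction coupling, RCR Windkessel terminals)
#' with either an elastance-ventricle inflow or a prescribed periodic
#' inflow, until the root pressure trace repeats cycle-to-cycle within
#' tolerance.
#'
#' @param tree A `pwp_tree` (see [build_default_tree()]).
#' @param lv Left-ventricle parameter list (see [elastance()]); ignored
#'   when `inflow` is given.
#' @param cfg A `pwp_config` from [sim_config()].
#' @param inflow Optional numeric vector sampling a prescribed root inflow
#'   (ml/s) uniformly over one period; replaces the ventricle model.
#' @param period Period in seconds of the prescribed inflow (defaults to
#'   `lv$T`).
#' @param store Optional character vector of segment names whose full
#'   area/flow fields are kept (default: all segments).  Restricting
#'   storage speeds up repeated simulations during fitting.
#' @return A `pwp_solution` with per-segment pressure/flow/area over the
#'   final cycle and a convergence report.
#' @export
simulate_to_periodic <- function(tree, lv = list(), cfg = sim_config(),
                                 inflow = NULL, period = NULL,
                                 store = NULL) {
  validate_tree(tree)
  p <- lv_defaults(lv)
  if (!is.null(period)) p$T <- period
  s <- tree$segments
  tree_cgs <- list(
    length = s$length_cm, r_prox = s$radius_prox_cm, r_dist = s$radius_dist_cm,
    parent = as.integer(s$parent) - 1L,
    term_R1 = s$R1 * MMHG, term_R2 = s$R2 * MMHG, term_C = s$C / MMHG,
    k1 = tree$stiffness$k1, k2 = tree$stiffness$k2, k3 = tree$stiffness$k3)
  lv_cgs <- list(Emax = p$Emax * MMHG, Emin = p$Emin * MMHG, tm = p$tm,
                 T = p$T, pla = p$pla * MMHG, V0 = p$V0,
                 plat_frac = p$plat_frac, relax_frac = p$relax_frac,
                 Rmv = p$Rmv * MMHG, Rav = p$Rav * MMHG)
  cfg_cgs <- list(rho = cfg$rho, mu = cfg$mu, dx_target = cfg$dx_target,
                  cfl = cfg$cfl, max_cycles = as.integer(cfg$max_cycles),
                  tol = cfg$tol, p_init = cfg$p_init * MMHG,
                  p_ven = cfg$p_ven * MMHG, visc = cfg$visc,
                  attempts = if (is.null(cfg$attempts)) 3L
                             else as.integer(cfg$attempts),
                  store_idx = if (is.null(store)) integer(0)
                              else vapply(store, function(nm)
                                seg_index(tree, nm), integer(1)) - 1L,
                  k3_ref = if (is.null(cfg$k3_ref)) tree$stiffness$k3
                           else cfg$k3_ref,
                  inflow = if (is.null(inflow)) numeric(0) else inflow)
  out <- solve_network_cpp(tree_cgs, lv_cgs, cfg_cgs)
  if (!out$converged)
    warning("periodic state not reached in ", out$cycles,
            " cycles (residual ", signif(out$residual, 3), ")")
  sol <- structure(list(
    tree = tree, lv = p, cfg = cfg,
    converged = out$converged, cycles = out$cycles,
    residual = out$residual, dt = out$dt, steps = out$steps,
    t = out$t, A = out$A, Q = out$Q, x = out$x,
    A0 = out$A0, f0 = out$f0,
    Qin = out$Qin, Vlv = out$Vlv,
    term_outflow_mean = out$term_outflow_mean,
    inflow_mean = out$inflow_mean, cfl_max = out$cfl_max),
    class = "pwp_solution")
  sol
}

#' @method print pwp_solution
#' @export
print.pwp_solution <- function(x, ...) {
  cat("Periodic haemodynamic solution (", length(x$A), " segments)\n",
      sep = "")
  cat("  converged:", x$converged, " cycles:", x$cycles,
      " residual:", signif(x$residual, 3), "\n")
  pm <- pressure_metrics(x, root_name(x$tree))
  cat("  root SP/DP/MAP:", paste(round(unlist(pm), 1), collapse = "/"),
      "mmHg;  SV:", round(stroke_volume(x), 1), "ml\n")
  invisible(x)
}

root_name <- function(tree)
  tree$segments$full_name[tree$segments$parent == 0]

#' Pressure trace at a segment's midpoint
#'
#' @param sol A `pwp_solution`.
#' @param segment Full segment name (e.g. `"radial L"`).
#' @param node Optional node index (default: midpoint node).
#' @return Numeric vector of pressure in mmHg over the stored cycle.
#' @export
pressure_waveform <- function(sol, segment, node = NULL) {
  i <- seg_index(sol$tree, segment)
  A <- sol$A[[i]]
  if (is.null(node)) node <- max(1L, ceiling(nrow(A) / 2))
  a0 <- sol$A0[[i]][node]; f0 <- sol$f0[[i]][node]
  f0 * (1 - sqrt(a0 / A[node, ])) / MMHG
}

#' Systolic, diastolic and mean pressure at a segment
#'
#' SP/DP/MAP are the maximum, minimum and time average of the midpoint
#' pressure trace over one period.
#'
#' @inheritParams pressure_waveform
#' @return List with `SP`, `DP`, `MAP` in mmHg.
#' @export
pressure_metrics <- function(sol, segment) {
  p <- pressure_waveform(sol, segment)
  list(SP = max(p), DP = min(p), MAP = mean(p))
}

#' Arterial volume waveform of a whole segment
#'
#' Integrates the cross-sectional area along the segment (trapezoidal rule
#' over the spatial nodes) at each stored time.
#'
#' @inheritParams pressure_waveform
#' @return Numeric vector of segment volume in ml over one cycle.
#' @export
segment_volume_waveform <- function(sol, segment) {
  i <- seg_index(sol$tree, segment)
  A <- sol$A[[i]]
  x <- sol$x[[i]]
  dx <- if (length(x) > 1) x[2] - x[1] else 2 * x[1]
  # midpoint rule over the finite-volume cells
  colSums(A) * dx
}

#' Stroke volume of the simulated heart beat
#'
#' Integral of root inflow over one period.
#'
#' @param sol A `pwp_solution`.
#' @return Stroke volume in ml.
#' @export
stroke_volume <- function(sol) {
  mean(sol$Qin) * sol$lv$T
}

#' Mass-conservation check
#'
#' Relative difference between cycle-average root inflow and the summed
#' cycle-average terminal outflows.
#'
#' @param sol A `pwp_solution`.
#' @return Relative imbalance (dimensionless).
#' @export
flow_imbalance <- function(sol) {
  out <- sum(sol$term_outflow_mean, na.rm = TRUE)
  abs(sol$inflow_mean - out) / sol$inflow_mean
}

#' Locate the foot of a pulse wave by intersecting tangents
#'
#' The foot is the intersection of the horizontal line through the cycle
#' minimum with the tangent at the point of maximum upstroke slope, the
#' convention used for foot-to-foot pulse wave velocity.
#'
#' @param t Time vector (one period, uniform).
#' @param y Waveform values.
#' @return Foot time in the units of `t`.
#' @export
wave_foot <- function(t, y) {
  n <- length(y)
  stopifnot(n == length(t), n > 4)
  imin <- which.min(y)
  # rotate so the minimum comes first
  idx <- c(imin:n, seq_len(imin - 1))
  yr <- y[idx]
  dtau <- t[2] - t[1]
  ipk <- which.max(yr)
  if (ipk < 3) stop("degenerate waveform: peak at cycle minimum")
  # centred slope estimate (smoother than one-sided differences, which
  # matters for waveforms reconstructed from coarser sampling grids)
  up <- yr[1:ipk]
  dy <- (c(up[-1], up[ipk]) - c(up[1], up[-ipk])) / (2 * dtau)
  dy[c(1, ipk)] <- 0
  islp <- which.max(dy)
  slope <- dy[islp]
  if (slope <= 0) stop("non-rising upstroke; foot undefined")
  t_slp <- (islp - 1) * dtau       # time since minimum
  y_slp <- up[islp]
  t_foot_rel <- t_slp - (y_slp - min(yr)) / slope
  tf <- t[1] + (imin - 1) * dtau + t_foot_rel
  # wrap into [t[1], t[1]+period)
  period <- n * dtau
  ((tf - t[1]) %% period) + t[1]
}

#' Model-derived pulse wave velocity (foot-to-foot)
#'
#' PWV between the ascending-aorta inlet and the femoral end: path length
#' along the tree divided by the difference in wave-foot times of the
#' pressure waveforms at the two sites.
#'
#' @param sol A `pwp_solution`.
#' @return PWV in cm/s.
#' @export
compute_pwv <- function(sol) {
  tree <- sol$tree
  from <- tree$pwv_path$from
  to <- tree$pwv_path$to
  i_from <- seg_index(tree, from)
  i_to <- seg_index(tree, to)
  p_from <- pressure_waveform(sol, from, node = 1L)
  p_to <- pressure_waveform(sol, to, node = nrow(sol$A[[i_to]]))
  t <- sol$t
  f_from <- wave_foot(t, p_from)
  f_to <- wave_foot(t, p_to)
  delay <- f_to - f_from
  if (delay <= 0) delay <- delay + sol$lv$T
  path <- tree_path(tree, to)
  # distance between the two measurement cells (cell centres)
  len <- sum(tree$segments$length_cm[path]) -
    sol$x[[i_from]][1] -
    (tree$segments$length_cm[i_to] - tail(sol$x[[i_to]], 1))
  if (delay <= 1e-6)
    stop("non-positive transit time; foot detection failed")
  len / delay
}

#' Export a solution segment to CSV
#'
#' Writes time, midpoint pressure, flow and area for one segment plus a
#' JSON convergence report alongside.
#'
#' @param sol A `pwp_solution`.
#' @param segment Full segment name.
#' @param path Output CSV path.
#' @export
export_solution_csv <- function(sol, segment, path) {
  i <- seg_index(sol$tree, segment)
  node <- max(1L, ceiling(nrow(sol$A[[i]]) / 2))
  df <- data.frame(time_s = sol$t,
                   pressure_mmHg = pressure_waveform(sol, segment),
                   flow_ml_s = sol$Q[[i]][node, ],
                   area_cm2 = sol$A[[i]][node, ])
  utils::write.csv(df, path, row.names = FALSE)
  rep <- list(converged = sol$converged, cycles = sol$cycles,
              residual = sol$residual, dt = sol$dt, steps = sol$steps)
  jsonlite::write_json(rep, sub("\\.csv$", "_convergence.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
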
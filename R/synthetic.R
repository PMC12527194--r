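# Synthetic cohort generator: virtual patients with ground-truth
# cardiovascular parameters, forward-simulated four-site waveforms passed
# through an oscillometric-style distortion chain, AngE-like scalar
# outputs, and norepinephrine dose trajectories with a planted logistic
# dependence on standardized features.

SYNTH_FEATURES <- c("tm", "Emax", "pla", "k3", "SR",
                    "age", "height", "weight",
                    "HR", "SP", "DP", "MAP",
                    "rise_time_lw", "rise_time_rw",
                    "rise_time_la", "rise_time_ra",
                    "rise_to_fall_lw", "rise_to_fall_rw",
                    "rise_to_fall_la", "rise_to_fall_ra",
                    "ne_dose", "PWV")

# fixed reference scales used to standardize features inside the planted
# logistic model (population-typical centres/SDs, not data-derived, so the
# generative model is defined before any cohort is drawn)
planted_reference_scales <- function() {
  data.frame(
    feature = SYNTH_FEATURES,
    center = c(0.30, 2.2, 9.5, 9e5, 1.05, 50, 175, 85, 80, 160, 75, 100,
               rep(0.12, 4), rep(0.35, 4), 0.15, 900),
    scale = c(0.08, 1.0, 3.5, 4.5e5, 0.45, 20, 9.7, 16, 11, 25, 12, 15,
              rep(0.05, 4), rep(0.15, 4), 0.12, 250))
}

#' Planted logistic ground-truth model for dose-increase events
#'
#' Defines the generative probability that a patient's next dose change is
#' an increase: `logit p = intercept + beta . z + b_i` with `z` the
#' features standardized by fixed reference scales and `b_i` a per-patient
#' normal random intercept.
#'
#' @param coefficients Named numeric vector (subset of the 22 features);
#'   unnamed features have coefficient 0.
#' @param intercept Intercept on the logit scale.
#' @param ranef_sd SD of the per-patient random intercept.
#' @return A `planted_model`.
#' @export
planted_model <- function(coefficients = c(ne_dose = -1.2, pla = -0.9,
                                           HR = 0.8, PWV = -0.6),
                          intercept = -1.2, ranef_sd = 0.5) {
  stopifnot(all(names(coefficients) %in% SYNTH_FEATURES))
  beta <- setNames(numeric(length(SYNTH_FEATURES)), SYNTH_FEATURES)
  beta[names(coefficients)] <- coefficients
  structure(list(beta = beta, intercept = intercept, ranef_sd = ranef_sd,
                 scales = planted_reference_scales()),
            class = "planted_model")
}

planted_linpred <- function(planted, features) {
  z <- (unlist(features[SYNTH_FEATURES]) - planted$scales$center) /
    planted$scales$scale
  planted$intercept + sum(planted$beta * z)
}

# ground-truth parameter ranges: fitting bounds shrunk by 10% per side
truth_ranges <- function() {
  lapply(fit_bounds(), function(b) b + c(0.1, -0.1) * diff(b))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Sample a virtual patient
#'
#' Demographics near the reference cohort distributions (age 50.7 +/- 20.1
#' years truncated to 18-90, height 175.0 +/- 9.7 cm, weight 85.7 +/- 16.4
#' kg), day-one ground-truth parameters uniform inside the shrunk fitting
#' bounds, and smooth day-to-day parameter/HR trajectories (relative step
#' within +/- 8%).
#'
#' @param id Patient identifier.
#' @param n_days Number of recording days.
#' @return List describing the patient (demographics, per-day truth
#'   parameters and HR).
#' @export
virtual_patient <- function(id, n_days) {
  rng <- truth_ranges()
  demo <- list(age = rtrunc_norm(1, 50.7, 20.1, 18, 90),
               height = rtrunc_norm(1, 175.0, 9.7, 150, 205),
               weight = rtrunc_norm(1, 85.7, 16.4, 45, 140))
  p <- vapply(FIT_PARS, function(nm) runif(1, rng[[nm]][1], rng[[nm]][2]),
              numeric(1))
  HR <- runif(1, 60, 100)
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    if (d > 1) {
      p <- vapply(FIT_PARS, function(nm) {
        v <- p[[nm]] * (1 + runif(1, -0.08, 0.08))
        min(max(v, rng[[nm]][1]), rng[[nm]][2])
      }, numeric(1))
      HR <- min(max(HR * (1 + runif(1, -0.05, 0.05)), 55), 110)
    }
    days[[d]] <- list(params = p, HR = HR)
  }
  list(id = id, demographics = demo, days = days)
}

# raised-cosine attenuation across the cuff ladder: peak at MAP, total
# width 60 mmHg, small floor elsewhere
cuff_attenuation <- function(level, MAP, width = 60, floor = 0.08) {
  d <- abs(level - MAP)
  ifelse(d <= width / 2,
         floor + (1 - floor) * 0.5 * (1 + cos(2 * pi * d / (2 * width))),
         floor)
}

#' Synthesize four oscillometric cuff recordings for one patient-day
#'
#' Tiles each site's normalized one-beat volume waveform over 5 s
#' fragments with beat-period jitter, applies a cuff-pressure-dependent
#' amplitude attenuation (raised-cosine bump centred at the simulated MAP),
#' first-order low-pass smoothing and additive Gaussian noise, and
#' assembles the 180 to 40 mmHg fragment ladder.
#'
#' @param waveforms Named list of four normalized 1000-point waveforms
#'   (names: cuff sites), each starting at its foot.
#' @param period_s Beat period in seconds.
#' @param MAP Simulated mean pressure (centres the attenuation bump).
#' @param sampling_rate Hz (default 200).
#' @param jitter_sd Relative SD of beat-period jitter (default 0.02).
#' @param noise_sd Additive noise SD as a fraction of fragment amplitude
#'   (default 0.02).
#' @param lowpass_hz First-order low-pass cutoff; `Inf` disables.
#' @param fragment_s Fragment duration (default 5 s).
#' @return Named list of four `cuff_recording`s.
#' @export
synthesize_recording <- function(waveforms, period_s, MAP,
                                 sampling_rate = 200, jitter_sd = 0.02,
                                 noise_sd = 0.02, lowpass_hz = 20,
                                 fragment_s = 5) {
  n_frag <- as.integer(fragment_s * sampling_rate)
  recs <- lapply(CUFF_SITES, function(s) {
    tmpl <- waveforms[[s]]
    frags <- lapply(CUFF_LADDER, function(lev) {
      att <- cuff_attenuation(lev, MAP)
      sig <- numeric(0)
      while (length(sig) < n_frag + sampling_rate) {
        Tb <- period_s * (1 + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0)
        nb <- max(4L, as.integer(round(Tb * sampling_rate)))
        beat <- approx(seq(0, 1, length.out = length(tmpl)), tmpl,
                       xout = seq(0, 1, length.out = nb + 1)[1:nb])$y
        sig <- c(sig, beat)
      }
      sig <- sig[seq_len(n_frag)] * att
      if (is.finite(lowpass_hz)) {
        a <- exp(-2 * pi * lowpass_hz / sampling_rate)
        sig <- as.numeric(stats::filter(sig * (1 - a), a, method = "recursive",
                                        init = sig[1]))
      }
      if (noise_sd > 0)
        sig <- sig + rnorm(n_frag, 0, noise_sd * att)
      sig
    })
    names(frags) <- CUFF_LADDER
    amp <- vapply(frags, function(y) diff(range(y)), numeric(1))
    cuff_recording(s, frags, sampling_rate,
                   device_selected_pressure = CUFF_LADDER[which.max(amp)])
  })
  names(recs) <- CUFF_SITES
  recs
}

#' Synthesize a norepinephrine dose-event series for one patient
#'
#' Each day the probability that the first dose change is an increase
#' follows the planted logistic model evaluated on that day's features;
#' otherwise a decrease occurs with fixed probability (when the dose floor
#' allows) or the dose is left unchanged.  Event times fall strictly inside
#' the day so that [assign_label()] applied to the events reproduces the
#' generated increase/no-increase outcome by construction.
#'
#' @param features_by_day List (one element per day) of named feature
#'   lists; the `ne_dose` entry is filled in by this function.
#' @param planted A `planted_model`.
#' @param b_i Patient random intercept (logit scale).
#' @param dose0 Starting dose, ug/kg/min.
#' @param p_decrease Probability of a dose decrease on non-increase days.
#' @return List with `events` (data frame `time`, `new_dose`),
#'   `dose_at_rec` and `features_by_day` (with `ne_dose` filled).
#' @export
synthesize_dose_trajectory <- function(features_by_day, planted, b_i = 0,
                                       dose0 = 0.10, p_decrease = 0.45) {
  dose <- dose0
  times <- doses <- numeric(0)
  dose_at_rec <- numeric(length(features_by_day))
  for (d in seq_along(features_by_day)) {
    features_by_day[[d]]$ne_dose <- dose
    dose_at_rec[d] <- dose
    eta <- planted_linpred(planted, features_by_day[[d]]) + b_i
    p_up <- plogis(eta)
    t0 <- (d - 1) * 24
    if (runif(1) < p_up) {
      step <- runif(1, 0.02, 0.10)
      dose <- dose + step
      times <- c(times, t0 + runif(1, 1, 23))
      doses <- c(doses, dose)
    } else if (runif(1) < p_decrease && dose >= 0.06) {
      step <- min(runif(1, 0.02, 0.10), dose - 0.02)
      dose <- dose - step
      times <- c(times, t0 + runif(1, 1, 23))
      doses <- c(doses, dose)
    }
  }
  list(events = data.frame(time = times, new_dose = doses),
       dose_at_rec = dose_at_rec,
       features_by_day = features_by_day)
}

#' Generate a fully synthetic cohort
#'
#' Produces, per patient-day: ground-truth parameters, forward-simulated
#' four-site waveforms (optionally distorted into full oscillometric cuff
#' recordings), AngE-like scalar outputs (SP, DP, MAP, HR, rise time and
#' rise-to-fall per site, PWV), norepinephrine dose events driven by the
#' planted logistic model, and labels obtained by applying
#' [assign_label()] to the generated events.  Patients are recorded on 4
#' or 5 consecutive days; a fraction of final-day observations gets
#' follow-up shorter than 24 h and is therefore unlabeled.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_days Maximum days per patient (1-5).
#' @param seed RNG seed; the bundle is deterministic given the seed.
#' @param planted A `planted_model`.
#' @param cfg Solver configuration (default coarse preset).
#' @param recordings Also synthesize the distorted cuff-recording ladders
#'   (slower, larger); features and labels do not require them.
#' @param distortion List of [synthesize_recording()] arguments
#'   (jitter_sd, noise_sd, lowpass_hz).
#' @param short_followup_prob Probability that a patient's final-day
#'   observation has < 24 h follow-up.
#' @return A `synthetic_cohort` bundle.
#' @export
generate_cohort <- function(n_patients, n_days = 5, seed = 1,
                            planted = planted_model(),
                            cfg = sim_config("coarse"),
                            recordings = FALSE,
                            distortion = list(),
                            short_followup_prob = 0.6) {
  stopifnot(n_patients >= 2, n_days >= 1, n_days <= 5)
  set.seed(seed)
  dist_args <- list(jitter_sd = 0.02, noise_sd = 0.02, lowpass_hz = 20)
  dist_args[names(distortion)] <- distortion

  # joint plausibility filter: marginally valid parameters can combine
  # into unphysiological states (e.g. high filling pressure with strong
  # vasoconstriction); only converged, haemodynamically sane draws enter
  # the cohort
  plausible <- function(obs) {
    !is.null(obs) && obs$sol$converged &&
      obs$SV >= 30 && obs$SV <= 130 &&
      obs$MAP >= 50 && obs$MAP <= 140 && obs$SP <= 220
  }
  # closed-form two-element surrogate (elastance ventricle against the
  # total peripheral resistance): cheap pre-screen so that clearly
  # unphysiological draws never reach the 1D solver, and a warm-start
  # estimate of the mean pressure so the Windkessel states begin close to
  # their periodic values
  surrogate_map <- function(p, HR) {
    Emin <- 0.08
    h <- HR / 60
    R <- 1.05 * p[["SR"]]
    map <- h * R * (p[["pla"]] / Emin) / (1 + h * R / p[["Emax"]])
    sv <- p[["pla"]] / Emin - map / p[["Emax"]]
    list(map = map, sv = sv,
         ok = map > 45 && map < 150 && sv > 25 && sv < 140)
  }
  # fail fast while screening draws: cap the cycle count and do not retry
  # unstable runs with refined time steps
  cfg_screen <- cfg
  cfg_screen$max_cycles <- min(cfg$max_cycles, 12)
  cfg_screen$attempts <- 1
  try_day <- function(params, tree, HR, map_est) {
    cfg_screen$p_init <- min(max(map_est, 50), 140)
    tryCatch(
      suppressWarnings(forward_observables(params, tree, HR, cfg_screen)),
      error = function(e) NULL)
  }
  rng <- truth_ranges()
  draw_params <- function()
    vapply(FIT_PARS, function(nm) runif(1, rng[[nm]][1], rng[[nm]][2]),
           numeric(1))
  walk_params <- function(p)
    vapply(FIT_PARS, function(nm) {
      v <- p[[nm]] * (1 + runif(1, -0.08, 0.08))
      min(max(v, rng[[nm]][1]), rng[[nm]][2])
    }, numeric(1))

  patients <- list()
  obs_rows <- list()
  rec_store <- list()
  event_rows <- list()
  for (pid in seq_len(n_patients)) {
    nd <- if (n_days >= 4) sample(4:n_days, 1) else n_days
    pat <- virtual_patient(pid, nd)
    tree <- build_default_tree(pat$demographics$height)
    b_i <- rnorm(1, 0, planted$ranef_sd)
    if (recordings) rec_store[[pid]] <- list()
    feats_days <- list()
    day_obs <- list()
    for (d in seq_len(nd)) {
      day <- pat$days[[d]]
      obs <- NULL
      for (try in 1:120) {
        cand <- if (d == 1) {
          if (try == 1) pat$days[[1]]$params else draw_params()
        } else {
          walk_params(pat$days[[d - 1]]$params)
        }
        HR_cand <- if (d == 1) day$HR else
          min(max(pat$days[[d - 1]]$HR * (1 + runif(1, -0.05, 0.05)), 55),
              110)
        sg <- surrogate_map(cand, HR_cand)
        if (!sg$ok) next
        o <- try_day(cand, tree, HR_cand, sg$map)
        if (plausible(o)) {
          pat$days[[d]]$params <- cand
          pat$days[[d]]$HR <- HR_cand
          obs <- o
          break
        }
      }
      if (is.null(obs))
        stop("could not draw a plausible parameter set for patient ", pid,
             " day ", d)
      day <- pat$days[[d]]
      wf_feats <- lapply(CUFF_SITES, function(s) {
        w <- structure(list(site = s, samples = obs$waveforms[[s]],
                            period_s = 60 / day$HR, n_beats_averaged = 1),
                       class = "averaged_waveform")
        waveform_features(w)
      })
      names(wf_feats) <- CUFF_SITES
      sk <- c(lw = "left wrist", rw = "right wrist",
              la = "left ankle", ra = "right ankle")
      f <- c(as.list(day$params),
             pat$demographics,
             list(HR = day$HR, SP = obs$SP, DP = obs$DP, MAP = obs$MAP,
                  PWV = obs$PWV, ne_dose = NA))
      for (ab in names(sk)) {
        f[[paste0("rise_time_", ab)]] <- wf_feats[[sk[[ab]]]]$rise_time_s
        f[[paste0("rise_to_fall_", ab)]] <- wf_feats[[sk[[ab]]]]$rise_to_fall
      }
      feats_days[[d]] <- f
      day_obs[[d]] <- obs
      if (recordings) {
        rec_store[[pid]][[d]] <- do.call(synthesize_recording, c(
          list(waveforms = obs$waveforms, period_s = 60 / day$HR,
               MAP = obs$MAP), dist_args))
      }
    }
    traj <- synthesize_dose_trajectory(feats_days, planted, b_i)
    event_rows[[pid]] <- if (nrow(traj$events) > 0)
      cbind(patient_id = pid, traj$events)
    else data.frame(patient_id = integer(0), time = numeric(0),
                    new_dose = numeric(0))
    for (d in seq_len(nd)) {
      t_rec <- (d - 1) * 24
      fu_end <- if (d == nd && runif(1) < short_followup_prob)
        t_rec + runif(1, 4, 23) else t_rec + 24
      lab <- assign_label(traj$events, t_rec, fu_end,
                          dose0 = traj$dose_at_rec[1])
      row <- c(list(patient_id = pid, day = d, t_rec = t_rec,
                    follow_up_end = fu_end),
               traj$features_by_day[[d]][SYNTH_FEATURES],
               list(label = lab))
      obs_rows[[length(obs_rows) + 1]] <- as.data.frame(row)
    }
    pat$truth <- do.call(rbind, lapply(seq_len(nd), function(d)
      as.data.frame(as.list(c(day = d, pat$days[[d]]$params,
                              HR = pat$days[[d]]$HR)))))
    pat$random_intercept <- b_i
    patients[[pid]] <- pat
  }
  structure(list(
    observations = do.call(rbind, obs_rows),
    dose_events = do.call(rbind, event_rows),
    patients = patients,
    recordings = if (recordings) rec_store else NULL,
    planted = planted, seed = seed,
    distortion = dist_args),
    class = "synthetic_cohort")
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  ob <- x$observations
  cat("Synthetic cohort:", length(x$patients), "patients,",
      nrow(ob), "observations (", sum(!is.na(ob$label)), "labeled,",
      sum(ob$label, na.rm = TRUE), "positive )\n")
  cat("  seed:", x$seed, " planted features:",
      paste(names(which(x$planted$beta != 0)), collapse = ", "), "\n")
  invisible(x)
}

#' Write the cohort's observation and dose-event tables as CSV
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$observations,
                   file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(cohort$dose_events,
                   file.path(dir, "dose_events.csv"), row.names = FALSE)
  invisible(dir)
}
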
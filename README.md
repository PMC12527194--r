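# pulsedose

Personalized arterial pulse-wave propagation modelling and norepinephrine
dose-change prediction.

## What this package is for

In intensive care, vasopressor (norepinephrine, NE) doses are titrated by
watching mean arterial pressure drift over hours — a reactive loop that
risks transient under- and over-dosing. `pulsedose` implements a
physiology-based alternative: non-invasive oscillometric pulse waveforms
recorded at the two wrists and two ankles are used to personalize a 0-1D
model of arterial pulse-wave propagation, and the estimated patient-specific
cardiovascular parameters feed a mixed-effects classifier that predicts
whether the NE dose will be *increased* within the next 24 hours.

The package contains every stage of that pipeline as tested, reusable code:

- a **71-segment arterial tree** (geometry, Olufsen-type wall stiffness
  `Eh/r0 = k1·e^{k2 r0} + k3`, RCR Windkessel terminals, height scaling);
- a compiled **1D haemodynamic solver** — finite-volume two-step
  Lax–Wendroff on the area–flow `(A, Q)` equations with tube law
  `p = (4/3)(Eh/r0)(1 − √(A0/A))`, an elastance-ventricle inflow, total
  pressure continuity at junctions and RCR outflow boundaries — run to a
  periodic state, with derived SP/DP/MAP, stroke volume, segment volume
  waveforms and foot-to-foot pulse wave velocity (PWV);
- **oscillometric preprocessing**: cuff-pressure-ladder fragment selection,
  beat detection (intersecting tangents), beat averaging, and 1000-point
  min–max normalization;
- **personalization**: Levenberg–Marquardt estimation of the five
  patient-specific parameters `tm, Emax, SR, pla, k3` minimizing

  ```
  err = Σ_sites Σ_{j=1..1000} ||V_norm,sim − V_norm,meas||²
      + ||DP_sim − DP_meas||²/20 + ||SP_sim − SP_meas||²/20
      + ((SV_sim − 70)/40)^6
  ```

- **sensitivity and identifiability** machinery: first-order Sobol indices
  (Saltelli estimator), relative local sensitivity matrices, inverse-Hessian
  pairwise parameter correlations, and greedy parameter-subset selection;
- the **prediction layer**: 24-hour dose-event labeling, a binomial mixed
  model with per-patient random intercept (lme4), bidirectional stepwise AIC
  feature selection, leave-one-out cross-validation, and classification
  metrics;
- a fully **synthetic cohort generator** (virtual patients, distorted cuff
  recordings, dose trajectories with a planted logistic dependence), so the
  entire pipeline is testable without any clinical data.

## Worked example

Simulate the default tree, then run the full measure-and-refit loop on a
synthetic patient (forward simulation → distorted cuff recordings →
preprocessing → personalization):

```r
library(pulsedose)

tree <- build_default_tree(height_cm = 178)
sol <- simulate_to_periodic(tree, lv = list(Emax = 2.2, pla = 10, tm = 0.32),
                            cfg = sim_config("coarse"))
sol
#> Periodic haemodynamic solution (71 segments)
#>   converged: TRUE  cycles: 8  residual: 0.00059
#>   root SP/DP/MAP: 152.9/78.7/103.9 mmHg;  SV: 73.8 ml
compute_pwv(sol)
#> [1] 772.6  # cm/s, ascending aorta -> femoral end, foot-to-foot

truth <- c(tm = 0.32, Emax = 2.2, SR = 1.2, pla = 10, k3 = 7.5e5)
obs <- forward_observables(truth, tree, HR = 72,
                           cfg = sim_config("coarse", max_cycles = 6, tol = 0))
set.seed(1)
recs <- synthesize_recording(obs$waveforms, period_s = 60/72, MAP = obs$MAP)
avg <- process_recordings(recs)       # beat detection + averaging per site
case <- pwp_case(avg, SP = obs$SP, DP = obs$DP, HR = 72, height = 178)
fit <- pwp_fit(case)
fit
#> Personalized pulse-wave model fit
#>   parameters:
#>        tm      Emax        SR       pla        k3
#> 3.285e-01 2.632e+00 1.227e+00 9.326e+00 7.498e+05
#>   objective: 2.388  iterations: 10  converged: TRUE
#>   per-site R2: 0.995 0.987 0.993 0.991
#>   simulated SP/DP/MAP: 172.2 / 87.6 / 109.1 mmHg;  SV: 70 ml;  PWV: 710 cm/s
```

The per-site coefficients of determination (≈ 0.99 here) quantify the
waveform fit; `tm`, `SR` and `k3` are recovered closely, while `Emax` and
`pla` trade off against each other under measurement distortion (2.63 vs
the generating 2.2, compensated by a lower `pla`) — the model's softest
direction, which the identifiability analysis
(`local_sensitivity_matrix()` + `identifiability_correlations()`) makes
explicit.

The prediction layer runs on a synthetic cohort:

```r
coh <- generate_cohort(n_patients = 20, n_days = 5, seed = 11)
ob  <- coh$observations
lab <- !is.na(ob$label)
std <- standardize(ob[lab, colnames(ob)[5:26]])
sel <- stepwise_aic(std$X, ob$label[lab], ob$patient_id[lab])
cv  <- loocv(ob[lab, colnames(ob)[5:26]], ob$label[lab],
             ob$patient_id[lab], sel$features)
cm  <- confusion_counts(cv$y, cv$class)
classification_metrics(cm$tn, cm$fp, cm$fn, cm$tp)$rounded
```

`run_pipeline(pipeline_config(...))` chains all stages end to end and
writes a JSON report plus prediction CSVs.

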
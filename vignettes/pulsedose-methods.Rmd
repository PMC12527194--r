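---
title: "Models and methods in pulsedose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pulsedose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pulsedose` couples a distributed model of arterial pulse-wave propagation
to a statistical layer that predicts the direction of norepinephrine (NE)
dose changes in intensive-care patients. This vignette explains the models,
the numerical choices, the tunable parameters, and what the synthetic-data
experiments do and do not demonstrate.

## 1. The pulse wave propagation model

### Governing equations

Each of the 71 arterial segments carries the cross-sectionally averaged 1D
blood-flow equations in area–flow form,

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -\,2\pi(\zeta + 2)\,\nu\,\frac{Q}{A},$$

with a flat-core velocity profile ($\zeta = 9$), blood density
$\rho = 1.06$ g/ml and viscosity $\mu = 4$ mPa·s. The wall is elastic with
the Olufsen-type tube law

$$p - p_\text{ext} = \tfrac{4}{3}\,\frac{Eh}{r_0}
   \left(1 - \sqrt{A_0/A}\right), \qquad
  \frac{Eh}{r_0} = k_1 e^{k_2 r_0} + k_3 ,$$

whose additive constant $k_3$ sets large-artery stiffness and is one of the
five personalized parameters. The implied wave speed is
$c^2 = \frac{f_0}{2\rho}\sqrt{A_0/A}$ with $f_0 = \tfrac{4}{3} Eh/r_0$; the
solver's agreement with this closed form on a uniform frictionless vessel
is one of the package's physics checks.

### Network, boundaries, heart

The default tree (`inst/extdata/arterial_tree_71.json`) is a
literature-style adult systemic network: the classic 55-artery topology
extended with distal head, forearm, pelvic and lower-leg branches to 71
segments. Segment lengths scale linearly with patient height (reference
175 cm); radii, stiffness and terminal values do not — lengths are the one
dimension for which a simple allometric rule is defensible, and the data
file records which fields scale so the choice can be revised without code
changes. Every leaf carries an RCR Windkessel whose proximal resistance is
the local characteristic impedance (capped at 20 % of the terminal total),
whose total resistances distribute a systemic resistance of
1.05 mmHg·s/ml by outlet radius$^{2.5}$, and whose compliances follow a
uniform RC time of 1.3 s. The dimensionless factor `SR` scales both
terminal resistances of every leaf from their baselines; compliances are
untouched.

Inflow comes from a time-varying elastance ventricle: a raised-cosine rise
from $E_\min$ to $E_\max$ over $[0, t_m]$, a plateau of $0.1\,T$, a
raised-cosine relaxation of $0.15\,T$, and diastole at
$E_\min = 0.08$ mmHg/ml. The ventricle fills from a constant left-atrial
pressure `pla` through a mitral valve resistance and ejects into the root
through an aortic valve resistance (both simple diodes). The exact
elastance shape is a modelling choice; it is localized in one function and
its two shape fractions are parameters of `elastance()`.

### Numerics

The solver (C++/Rcpp) uses a cell-centred finite-volume Richtmyer
(two-step Lax–Wendroff) scheme with the conservative momentum flux
$F_2 = Q^2/A + B$, $B = (f_0/\rho)(\sqrt{A_0 A} - A_0)$, and a geometric
source that vanishes identically at $A = A_0$ — tapered segments therefore
hold the rest state exactly (well-balancing), which a naive
pressure-gradient discretization does not. Boundary faces take their
fluxes from characteristic solves (Riemann invariants $u \mp 4c$ for this
tube law): prescribed flow at the root, Newton solves enforcing mass
conservation and total-pressure continuity at junctions, and scalar Newton
solves against the Windkessel at terminals. Mass is therefore conserved to
round-off inside the network; the reported cycle imbalance (inflow vs
summed terminal outflow, required < 1 %) measures only residual
non-periodicity. A small Rusanov-type blending (default 0.05) applied to
the deviation from equilibrium suppresses the odd–even null mode of
two-step Lax–Wendroff without disturbing the rest state; boundary-adjacent
cells remain first-order accurate, which shows up as small flow offsets in
the cells next to junctions but does not affect areas, pressures, or the
face fluxes used for all derived quantities.

Spatial resolution comes in three presets (target cell size 3, 2, 1 cm;
at least 2 cells, i.e. one interior face, per segment); halving the step
changes radial SP/DP by less than 1 mmHg, so the coarse preset is used
wherever many simulations are needed. The time step obeys a per-segment
CFL bound with headroom for pressurization and advection; if the CFL
monitor still trips, the run restarts with a halved step (at most twice).
Periodicity is declared when the cycle-to-cycle relative L2 difference of
root pressure drops below 1e-3 (cap 20 cycles). During parameter
estimation the solver instead runs a fixed number of cycles (`tol = 0`,
6 cycles) so the objective is a smooth deterministic function of the
parameters — variable stopping would inject step noise into
finite-difference Jacobians — and the CFL bound is evaluated at the upper
$k_3$ bound (`k3_ref`) so the step count cannot jump as the stiffness
parameter moves.

## 2. Oscillometric preprocessing

Recordings follow the cuff protocol: 5-s fragments at cuff pressures
descending from 180 to 40 mmHg in 10-mmHg steps, four sites. The analysis
selects, across sites, the fragments at the single ladder level nearest to
the mean of the per-site device-selected (highest-amplitude) levels, ties
towards the higher pressure. Beats are segmented at wave feet found by
intersecting tangents (horizontal line through the inter-beat minimum
against the tangent at the steepest upstroke, with a centred slope
estimate); inter-onset periods outside 0.3–2 s are discarded, and fewer
than two surviving beats raises a quality error. Beats are resampled to
1000 points with the periodic convention (a beat spans its onset up to,
excluding, the next onset), refined to their exact fractional foot,
averaged pointwise, and min–max normalized to $[0,1]$.

Two interpolation choices matter. First, the periodic convention: treating
an $L$-sample beat as covering the closed interval $[0,1]$ stretches it by
$L/(L-1)$ — 0.6 % at 200 Hz — which misaligns the 1000-point grids of
measured and simulated waveforms by several samples. Second, upsampling
from the device rate to the 1000-point grid uses a periodic spline rather
than linear interpolation: the underlying signal is smooth, and linear
upsampling flattens the upstroke tangent enough to move the detected foot
by a fraction of a sample, which is the accuracy limit of the whole chain.
With both choices the zero-distortion round-trip (synthesize → detect →
average → normalize) reproduces the source waveform to < 0.01 per point.

The scalar waveform features are `rise time` (foot to global peak, after
rotating the beat to start at its foot) and `rise to fall` (rise time over
the remaining period).

## 3. Personalization

Five parameters are estimated per recording: $t_m$ (s), $E_\max$
(mmHg/ml), `SR` (–), `pla` (mmHg) and $k_3$ (dyn/cm²). Defaults bounds are

| parameter | lower | upper | initial |
|---|---|---|---|
| $t_m$ | 0.15 | 0.45 | 0.30 |
| $E_\max$ | 0.8 | 5 | 2.0 |
| `SR` | 0.3 | 2.5 | 0.87 |
| `pla` | 4 | 16 | 8 |
| $k_3$ | 2e5 | 2.5e6 | 7.1e5 |

(initials are arithmetic/geometric midpoints). The upper bounds of
$E_\max$, `SR` and `pla` delimit the region where the tube law and the
filling model remain jointly physiological; outside it simulated pressures
run toward the tube-law saturation $p \to f_0$.

The objective is the published error function: the pointwise squared
differences of the four normalized 1000-point volume waveforms (both
rotated to start at their feet), the squared radial–cuff SP and DP
differences weighted 1/20, and the stroke-volume penalty
$((SV-70)/40)^6$. Levenberg–Marquardt (minpack.lm) operates on the
residual vector whose squared norm is exactly that objective — waveform
residuals, SP/DP residuals weighted $1/\sqrt{20}$, and the penalty carried
as the cubed residual $((SV-70)/40)^3$. Every parameter maps to its range
through a logistic reparameterization centred at the default start, for
two reasons: the unconstrained coordinates are all O(1), so the
finite-difference machinery (relative step `epsfcn = 4e-4`, about 2 %
parameter probes — large enough to rise above the sub-sample kinks of
foot alignment) treats them uniformly; and a smoothly saturating
transform, unlike a hard clamp, keeps the Jacobian nonzero near a bound,
so the optimizer can re-enter the interior instead of freezing on a
clamped plateau. Convergence uses `ftol = 1e-6`, `ptol = 1e-8`, 40
iterations by default; seeded multi-start is available through
`control$restarts`, and a fit whose best objective stays above
`rescue_threshold` (default 10) is retried from a fixed palette of
complementary starts that straddle the $t_m$–$E_\max$–$k_3$ compensation
axis, the model's main soft direction. Solver failures inside the
objective return a large finite residual so the optimizer survives
excursions.

On ten synthetic cases the fit recovers all five generating parameters
with median relative errors below 5 % from noise-free waveforms and below
15 % through the full default-distortion oscillometric chain (the
acceptance suite recomputes both). The soft direction is the
$E_\max$–`pla` pair: both scale ventricular pressures, and their local
sensitivity correlation on the fitted output set is ≈ −0.9, the largest in
the matrix — consistent with the subset-selection analysis that keeps all
five parameters below the 0.9 collinearity ceiling.

## 4. Sensitivity and identifiability

`sobol_first_order()` implements the Saltelli estimator
$S_{1,i} = \mathrm{mean}\{f(B)(f(A_B^{(i)}) - f(A))\}/\mathrm{Var}(f)$
over two Latin-hypercube base samples (the `lhs` package; a dedicated
Sobol'-sequence generator is not among the dependencies, and LHS gives the
same estimator with slightly larger Monte-Carlo error). Outputs with zero
variance are flagged undefined rather than reported as zero.
`local_sensitivity_matrix()` builds the relative sensitivity matrix by
central differences (relative step 1e-2 by default — above the solver's
discretization noise floor), `identifiability_correlations()` converts the
inverse Gauss–Newton Hessian $S^\top S$ into pairwise parameter
correlations (near-singular Hessians yield a ranked list of collinear
pairs instead), and `select_parameters()` applies the greedy rule: visit
parameters by descending peak $S_1$, keep those above the 0.05 floor whose
correlation with everything already kept stays below 0.9.

## 5. The prediction layer

Each recording is labeled by the first NE dose change in the half-open
24-hour window after it: 1 if it raises the dose in force at recording
time, 0 if it lowers it or if no change occurs and follow-up covers the
full window, unlabeled otherwise. A change at exactly +24 h does not
count; a change at exactly the recording time defines the dose in force.

The classifier is a binomial mixed model with a per-patient random
intercept — the minimal structure that respects repeated observations per
patient — fitted by Laplace-approximate maximum likelihood (lme4). On
failure it refits with the faster nAGQ = 0 approximation and, as a last
resort, falls back to plain logistic regression with the variance
component pinned at zero (flagged). Features are z-scored with training
statistics only. Feature selection is bidirectional stepwise AIC from the
intercept-only model; near-exact ties prefer the smaller model, then the
lexicographically earlier feature. Leave-one-out cross-validation refits
the model per fold with the feature set selected once on the full data —
the reading most consistent with reporting a single selected model — and a
strict 0.5 threshold; per-fold re-selection is available via
`reselect = TRUE` and reported separately. Predictions for a held-out
observation use the patient's estimated random intercept when the patient
still appears in training, and the population level otherwise. Metrics are
reported exactly and rounded half-up to two decimals.

## 6. The synthetic cohort

The generator emulates the study design: 20 patients, one recording per
day on 4–5 consecutive days, demographics drawn near the reported cohort
distributions (age 50.7 ± 20.1 y truncated to 18–90, height 175.0 ± 9.7
cm, weight 85.7 ± 16.4 kg). Ground-truth parameters are drawn uniformly
inside the fitting bounds shrunk by 10 % per side, walk day-to-day within
±8 %, and must pass a joint plausibility filter (converged simulation,
SV 30–130 ml, radial MAP 50–140 mmHg, SP ≤ 220 mmHg) — marginally valid
parameters can combine into unphysiological states, and a cohort is a
sample of patients, not of parameter boxes. A closed-form two-element
surrogate (elastance ventricle against the total peripheral resistance)
pre-screens draws cheaply and supplies the initial pressure for each
simulation.

Cuff recordings are synthesized by tiling each site's simulated one-beat
volume waveform over 5-s fragments with 2 % beat-period jitter, scaling by
a raised-cosine attenuation bump centred at the simulated MAP (total width
60 mmHg, floor 0.08) across the 180→40 mmHg ladder, first-order low-pass
smoothing at 20 Hz, and 2 % additive Gaussian noise; the device-selected
pressure is the level of maximal amplitude. The attenuation profile is a
declared phenomenological stand-in for the true cuff transfer
characteristics, which are unknown; the sampling rate (200 Hz) is likewise
declared, not inferred.

Dose trajectories follow a planted logistic model: each day the
probability that the first dose change is an increase is
$\mathrm{logit}^{-1}(\beta_0 + \beta^\top z + b_i)$ with $z$ the features
standardized by fixed reference scales (so the generative model exists
before any cohort is drawn) and $b_i$ a patient random intercept (SD 0.5).
Default nonzero coefficients sit on current NE dose, `pla`, HR and PWV
with intercept −1.2, giving roughly the positive rate of the study
(≈ 28 % of 80–90 labeled observations; about 60 % of final-day recordings
get < 24 h follow-up and stay unlabeled, mirroring the observed labeled
fraction). Labels are never stored independently — they are always derived
by applying the labeling rule to the generated event series, so no leakage
path exists. Dose step sizes (0.02–0.10 µg/kg/min) and event frequency are
plausibility choices.

What passing the synthetic tests shows: the estimation machinery inverts
its own forward model through the full measurement chain, the planted
statistical signal is recoverable at the study's sample size, and every
module's contract holds. What it does not show: that the 71-segment
geometry, the elastance shape, or the attenuation stand-in match any real
patient, or that real oscillometric artefacts (motion, arrhythmia,
cuff-tissue nonlinearity) are survivable — the generator deliberately
models none of these.

## 7. Pipeline and reproducibility

`run_pipeline()` chains synthesis → preprocessing → (optional)
per-observation personalization → feature assembly → selection →
LOOCV → metrics, and writes a JSON report plus CSVs. One global seed fans
out to per-stage seeds via a documented folding of the stage name, so
stages are independently reproducible; identical config and seed give an
identical report apart from timings. Problem sizes used by the test and
acceptance runs — coarse grid, 6 fixed cycles during fitting, cohorts of
10–20 patients, 50-replicate statistical simulations — were chosen to make
a full run a matter of minutes on one core while keeping every estimate's
Monte-Carlo error far from its acceptance margin.

## 8. Known limitations

- Boundary-adjacent finite-volume cells are first-order; cell flows next
  to junctions carry small steady offsets (areas and pressures do not).
- The elastance shape, valve model and friction coefficient are standard
  but not patient-specific; the baroreflex, cerebral autoregulation and
  venous return are not modelled.
- `SR` scales all terminal resistances uniformly; regional vasoactivity is
  out of scope.
- The Emax–pla direction is weakly identified from normalized waveforms
  plus SP/DP alone; estimates of either parameter in isolation should be
  interpreted with its partner in view.
- The oscillometric distortion model is a stand-in; transfer-function
  inversion of real cuff mechanics is out of scope.
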
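---
title: "Muscle-tendon mechanics and metabolic energetics of walking with gaitmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-tendon mechanics and metabolic energetics of walking with gaitmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitmet estimates what individual muscles do — and what they cost — during one
gait cycle. The inputs are the standard products of a gait analysis: joint
angles and velocities from inverse kinematics, net joint moments from inverse
dynamics, muscle-tendon lengths and moment arms from a scaled musculoskeletal
model, and optionally EMG envelopes and breath-by-breath gas exchange. From
these the package computes muscle excitations, activations, fiber and tendon
states (the muscle redundancy problem), evaluates six published metabolic
energy models on those states, and aggregates the result at the whole-body,
muscle-group and gait-phase levels. A synthetic virtual subject with fully
known ground truth exercises every stage.

## The muscle-tendon model

Each actuator is a Hill-type muscle in series with an elastic tendon.
Normalized force curves describe the contraction machinery:

* an active force-length curve (sum of three Gaussians) maximal at the optimal
  fiber length (the Gaussian centers carry a small common shift so the summed
  curve peaks exactly at unit normalized length);
* a force-velocity curve `fv(v) = d1 asinh(d2 v + d3) + d4` on fiber velocity
  normalized by the maximum shortening velocity `vmax` (default 10 optimal
  fiber lengths per second). The offset and scale coefficients are solved at
  construction so that `fv(0) = 1` exactly and `fv(-1) <= 1e-3`; the eccentric
  plateau is about 1.8;
* a passive force-length curve
  `fpas(l) = (exp(k_pe (l - s0) / s_m) - 1) / (exp(k_pe) - 1)`, clamped at zero
  below the onset length `s0` (the raw expression is negative there, which
  would mean a compressive fiber force). Generic defaults are `k_pe = 4`,
  `s0 = 1`, `s_m = 0.6`;
* an exponential tendon curve `ft(l) = c1 exp(k_t (l - c2)) - c3` with
  `c1 = 0.2`, `c3 = 0.25` and `c2 = 1 - log(c3/c1)/k_t`, so the tendon
  transmits exactly zero force at its slack length for any stiffness factor
  `k_t` (generic 35; personalization range 15-45, where lower is more
  compliant).

Pennation uses the fixed-height assumption: the fiber lifts off the tendon
line of action with constant width `l_opt sin(alpha_opt)`. Activation follows
first-order dynamics with `tau_act = 0.015` s and `tau_deact = 0.060` s and a
smooth blend between the branches; these constants are configurable because
different laboratories use slightly different values.

## The redundancy problem and its transcription

At every instant the net joint moments must equal the sum of tendon-force
moments plus small "reserve" torques added for feasibility:
`sum_i r_ij F_T,i + tau_res,j = tau_ID,j`. Among the infinitely many muscle
force combinations satisfying this, the solver picks the one minimizing the
integral of summed squared activations, plus a strong penalty on squared
normalized reserves (`w_res = 1000` on reserves normalized by 10% of each
degree of freedom's peak moment, so reserves at convergence are well below 1%
of the peak moment).

The transcription exploits the problem's algebraic structure. With prescribed
kinematics, the normalized tendon force of every muscle at N periodic mesh
nodes (default N = 50 per cycle; states wrap around, which enforces cyclic
boundary conditions by construction) determines everything else in closed
form: inverting the exponential tendon curve gives tendon length, geometry
gives fiber length and pennation, a periodic central difference gives tendon
and fiber velocities, the Hill equilibrium gives the activation required to
transmit that force, and inverting the activation dynamics gives the
excitation. Moment balance is *linear* in the tendon forces. The discretized
objective is a bounded nonlinear least-squares problem in the N x m node
values, solved by a Levenberg-Marquardt method with a Jacobian assembled from
sparse forward differences (node columns of one muscle spaced five nodes apart
influence disjoint residual bands, so the full Jacobian costs 5m residual
sweeps). Bound constraints on activations, excitations and fiber velocity are
enforced by smooth hinge penalties (width 1e-3), which keeps the residuals
differentiable at the constraint boundary. The solver warm-starts from a
rigid-tendon static optimization at each node and stops at an iteration cap
(default 80) chosen where progress per iteration becomes negligible; the
returned status records whether the cap was hit.

Four individualization workflows map onto the solver options: `GEN` resets
the passive curve parameters to their generic values; `PAS` uses calibrated
passive parameters; `TEN` additionally applies personalized tendon stiffness;
`EMG` additionally requires the excitations of measured muscles to stay within
a +/-0.01 corridor around the recorded envelopes, each scaled by a per-channel
gain in [0.05, 5] optimized jointly with the states (EMG amplitude is only
known up to an electrode-dependent gain). The corridor is enforced by the same
smooth hinge penalty with a large weight, mirroring a hard tracking bound;
EMG workflows warm-start from the minimal-effort solution.

## Passive calibration and tendon personalization

`calibrate_passive_params()` adjusts `k_pe` and `s0` (with `s_m` fixed) so
that simulated passive joint moment-angle curves — rigid-tendon, zero
activation, quasi-static — match target curves, minimizing the summed squared
moment error. Parameters are shared within calibration groups (default one
group; per-muscle calibration from a handful of joint curves would be
under-determined). Bounds are `k_pe` in [1, 10] and `s0` in [0.8, 1.4], with a
seeded 5-start multi-start.

`personalize_tendon_stiffness()` treats one `k_t` per tendon group (Achilles:
gastrocnemius + soleus; quadriceps: vasti + rectus femoris) as a design
variable shared across all supplied trials and minimizes the total redundancy
objective by coordinate descent with warm-started inner solves. The incumbent
generic value is always evaluated as a candidate, so freeing the stiffness can
never return a worse optimum than the frozen one. Identification is driven by
the EMG workflow: with excitations pinned to measured envelopes, a wrong
stiffness cannot reproduce the joint moments without reserves or corridor
violations. An equivalent linear stiffness (N/mm at one-third of maximum
isometric force) is reported for comparison with in-vivo tendon literature.

## Metabolic energy models

All six models decompose the muscle metabolic rate as
`Edot = Wdot_CE + Hdot_A + Hdot_M + Hdot_SL` — contractile element work rate
plus activation, maintenance and shortening/lengthening heat rates. The work
rate convention is `Wdot_CE = -F_CE v_M`: positive when the fiber shortens.
Heats depend on muscle mass (volume x density, 1059.7 kg/m^3) for every model
except LW07, which is formulated on `fmax` and `vmax` directly. The
distinguishing rules:

* **UM03 / UM10** share one combined activation+maintenance expression
  (`(1.28 %FT + 25) A^0.6`, W/kg, with the aerobic scaling factor 1.5
  appropriate for walking) and velocity-proportional shortening/lengthening
  heats with fiber-type-specific coefficients; the total heat rate has a
  1 W/kg floor. UM03 counts the full signed work; UM10 counts only concentric
  work.
* **UC16** modifies UM10 in two ways: the fiber-type composition entering the
  heats follows orderly recruitment (slow fibers recruited first, so the
  effective fast-twitch share grows with excitation), it keeps the signed
  work, and the total rate is clamped at zero — which is what removes the
  eccentric "energy gain".
* **BH04** uses separate activation and maintenance heats with sinusoidal
  slow/fast recruitment weighting (activation 40/133 W/kg, maintenance 74/111
  W/kg, and a piecewise-linear fiber-length scaling of maintenance), and a
  force-scaled shortening coefficient `0.16 F_iso + 0.18 F_CE`
  (`0.157 F_CE` during lengthening, which yields heat absorption).
* **HO06** is implemented as a Hill-heat reconstruction: no separate
  activation heat, a small force-scaled maintenance term, Hill's shortening
  heat coefficient, and zero eccentric heat. The original coefficient table
  was not available when this package was written; the constants were chosen
  to reproduce the documented qualitative behavior of the model family
  (lowest isometric rate, third-highest shortening rate, negative unmodified
  eccentric rate) and are isolated in `metabolic_model_constants("HO06")` for
  auditing and replacement.
* **LW07** is linear in activation in every term (maintenance
  `a f_l fmax vmax / G^2`, shortening heat `a f_l fmax |v| / G`, Hill
  curvature G = 4), which is why its efficiency is invariant across activation
  levels; during lengthening half of the (negative) work is dissipated as
  heat, so its total rate can remain negative.

For BH04, HO06 and UM03, wherever the unmodified total would be negative the
shortening/lengthening heat is replaced by `-Wdot_CE - Hdot_AM`, pinning the
rate at zero (`apply_negative_rate_modification()`); trajectories flag where
this fired.

## Aggregation

Whole-body average rate = twice the time integral of the summed one-leg muscle
rates over the cycle, divided by cycle duration and body mass, plus a basal
rate (default 1.2 W/kg). Gas exchange converts through the Brockway equation
(16.58 J/mL O2, 4.51 J/mL CO2; coefficients are configuration, not code), with
the representative value taken as the mean over the last 3 minutes of a
6-minute trial. Biarticular muscle energy is attributed to joints by the
instantaneous ratio of absolute moment arms, falling back to the cycle-average
ratio when all arms vanish at an instant (flagged); attribution is exactly
conservative. Stance/swing shares integrate the total rate between initial
contact, toe-off and the next contact (contact-start cycle convention;
configurable toe-off event). Time integration is trapezoidal on the native
grid throughout. Maximum isometric forces come from a linear total-volume
regression in body mass x height (47.0 cm^3 per kg*m + 1285 cm^3) distributed
by an editable per-muscle fraction table, with PCSA = volume / optimal fiber
length and specific tension 60 N/cm^2.

## Statistics

`rmcorr()` fits the ANCOVA `y ~ subject + x` (common slope, subject
intercepts) and reports the signed within-subject correlation with
`N - k - 1` degrees of freedom. `snpm_paired_1d()` computes pointwise paired
t curves on time-normalized data (101 points per cycle by linear resampling)
and controls family-wise error by sign-flip permutation of subject difference
curves: the threshold is the 95th percentile of the maximum-statistic
distribution, and cluster p-values come from the maximum cluster-extent
distribution; sign assignments are fully enumerated when `2^n <= 4096`,
otherwise 10,000 seeded Monte-Carlo flips are used. Both point-level
(threshold) and cluster-level outputs are reported since either inference
style is common. `wilcoxon_signed_rank()` uses the exact distribution for
`n <= 12` without ties and drops zero differences with a warning.
`agreement_metrics()` reports Pearson r and RMSE between computed and
reference curves.

## The synthetic virtual subject

`make_virtual_subject()` builds a nine-muscle, three-joint (sagittal hip,
knee, ankle) leg: anthropometric maximum isometric forces and masses from the
volume regression at 71.3 kg / 1.74 m, moment arms as linear polynomials in
the joint angle, and muscle-tendon lengths obtained by exact integration of
those polynomials — so the moment arm equals minus the length partial
derivative to machine precision. Reference lengths are chosen so fibers
operate near optimal length *under a nominal load* (tendon force 15% of
maximum) at the muscle's own tendon stiffness, as real architecture does;
this is also what makes tendon stiffness identifiable from the data the
generator produces. `make_gait_trial()` generates speed-scaled periodic
kinematics from truncated Fourier templates (cycle duration 1.4 - 0.25 speed
s, toe-off near 60% at 1.3 m/s, drifting with speed within [55, 68]%),
ground-truth excitations as smooth periodic bump trains, activations and
compliant-tendon fiber states by forward Runge-Kutta integration repeated to
periodicity, and joint moments computed forward from the ground-truth tendon
forces, so the redundancy truth has zero reserves. EMG envelopes are the true
excitations scaled by hidden log-uniform gains in [0.3, 3] plus additive
Gaussian noise (SD 0.01); gas exchange inverts the Brockway computation at a
fixed respiratory exchange ratio of 0.85 (typical for walking) with
multiplicative breath noise. All generators are deterministic under the
subject seed, with sub-seeds derived per trial and component.

For parameter-recovery experiments, `truth = "minimal_effort"` replaces the
bump truth by the minimal-effort solution of the trial itself and rebuilds the
moments from that solution's tendon forces: the stored truth is then an exact
zero-reserve optimum of the discretized problem, so recovery error measures
the solver, not discretization mismatch between the forward simulation and
the collocation grid.

What the generator does *not* emulate: soft-tissue artifact and marker noise,
trial-to-trial variability of real gait, co-contraction strategies beyond the
minimal-effort criterion, frontal/transverse-plane degrees of freedom, EMG
crosstalk, and the slow mitochondrial dynamics that separate muscle heat
production from measured gas exchange. Passing recovery tests therefore
demonstrates internal consistency of the pipeline, not validity of the
minimal-effort assumption on real data.

## Numerical choices and problem sizes

Defaults used by the test-suite and the acceptance analysis, chosen as the
smallest sizes at which results are stable: 50 mesh nodes per cycle
(refinement to 100 changes recovered activations by well under 0.02 RMS),
101-point storage grids, Levenberg-Marquardt iteration cap 80, fiber-tendon
equilibrium root-finds to 1e-9 relative tolerance, trapezoidal quadrature,
and full enumeration of sign-flip permutations up to 4096 assignments.
Tendon-stiffness searches run coordinate descent over groups with a
coarse-to-fine 1-D grid (seven coarse points over the bounds, a fine grid
around the best, then parabolic refinement); a grid is used rather than a
golden-section search because warm-started inner solves make the objective
mildly path-dependent.

## Known limitations

* The redundancy solver is a local method on a non-convex problem; the
  rigid-tendon warm start makes it reproducible, but pathological trials can
  converge to local optima (the reserve report flags any degree of freedom
  whose reserve exceeds 5% of its peak moment).
* EMG gains and tendon stiffness are jointly only weakly identifiable when
  the tracked muscles' operating range is insensitive to stiffness; multiple
  trials at different speeds sharpen the estimate.
* The HO06 constants are a documented reconstruction (see above).
* Heat-rate coefficients of the UM-family are referred to the muscle's own
  `vmax`; muscles with atypical fiber-type mixes and the published reference
  velocities will differ proportionally.
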
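---
title: "A subject-specific multiscale model of central aortic pressure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A subject-specific multiscale model of central aortic pressure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(centralbp)
```

Central (ascending-aortic) systolic and diastolic pressure predict
cardiovascular outcomes better than the cuff pressure measured at the arm,
but they cannot be measured directly outside the catheterisation lab.
`centralbp` estimates them by simulating the subject's own arterial system:
a one-dimensional (1D) model of pulse-wave propagation through the large
arteries, closed by a lumped (0D) left ventricle at the inlet and lumped
microcirculation loads at the outlets, with every model parameter set
automatically from routine noninvasive measurements. This vignette
documents the model, the setting procedure, the numerical scheme, the
synthetic-cohort machinery, and the design decisions taken where more than
one defensible choice existed.

## The multiscale model

### 1D large-artery haemodynamics

Each arterial segment is an axisymmetric compliant tube. Mass and momentum
conservation give, for cross-sectional area $A(x,t)$ and volumetric flow
$Q(x,t)$,

$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
 + \frac{A}{\rho}\,\partial_x p = -\,\frac{8\pi\mu}{\rho}\,\frac{Q}{A},$$

with blood density $\rho = 1060\ \mathrm{kg/m^3}$ and dynamic viscosity
$\mu = 4\ \mathrm{mPa\,s}$. The friction term corresponds to a Poiseuille
velocity profile; the steady limit of the solver therefore reproduces
Poiseuille's law, which is one of the physics oracles in the test suite.

The wall is described by a Laplace-law elastic tube law plus a
Kelvin--Voigt viscous term:

$$p = p_{ext} + \beta\,\frac{\sqrt{A}-\sqrt{A_0}}{A_0}
   + \frac{\gamma}{A_0\sqrt{A}}\,\partial_t A .$$

This form is standard in 1D haemodynamics because it yields a closed-form
wave speed, $c^2 = \beta\sqrt{A}/(2\rho A_0)$, and hence an exact algebraic
inverse from a measured pulse wave velocity (PWV) to the wall coefficient
$\beta$ (`stiffness_from_pwv()`). A useful exact identity of this law is

$$c^2(p) = \frac{\beta}{2\rho\sqrt{A_0}} + \frac{p}{2\rho},$$

i.e. the squared wave speed grows linearly with distension pressure. The
package uses this identity to reference stiffness at the working pressure
(below) and tests it directly against the simulated propagation speed of a
small pulse in a pressurised vessel.

The reference tree is a 56-segment averaged-adult topology (aorta with its
iliac extension, both arms, the cerebral vessels, the main visceral
branches and both legs), shipped as a versioned JSON data file
(`inst/extdata/adult_reference_network.json`); geometry lives in the file,
not in code. Every leaf carries a three-element Windkessel (RCR) load with
venous pressure 5 mmHg. Terminal resistances split the reference cardiac
output according to Murray's law (flow fraction proportional to the cube of
the terminal radius), with $R_1 = \min(Z_c, 0.2\,R_{tot})$ set to the
characteristic impedance to limit artificial reflections, and compliances
set by a uniform peripheral time constant $R_2 C = 1.3$ s. The reference
working point is a mean pressure of 93.3 mmHg (120/80 via the 2/3 rule) at
90 mL/s (5.4 L/min); their ratio is stored in the file and anchors the
subject-specific resistance coefficient.

Wall viscosity is set to $\gamma = 100\sqrt{A_0}$ Pa s cm per segment:
large-vessel values of a few hundred Pa s cm are physiological, the
$\sqrt{A_0}$ scaling keeps the associated diffusion time scale uniform
across calibres, and the resulting damping removes grid-scale ringing from
the sharp systolic front without visibly distorting the waveforms.

### 0D heart and valves

The left ventricle is a time-varying elastance:
$p_{lv}(t) = E(t)\,(V - V_0)$ with unstressed volume $V_0 = 10$ mL. $E(t)$
sweeps between $E_{min}$ and $E_{max}$ following a normalized double-Hill
activation shape (rise exponent 1.32 at 0.269 of the shape clock, decay
exponent 21.9 at 0.452), rescaled so the peak falls at the activation time
$t_{act} = 0.38\sqrt{T}$ — about 0.37 s at 62 bpm, in the physiological
range of time-to-peak elastance, with the square-root rule emulating the
shortening of systole at faster rates. The aortic and mitral valves are
pressure-gated diodes with linear resistances (5 mPa-equivalent,
0.005 mmHg s/mL each; aortic inertance supported but off by default: in
this configuration it produced unphysiological flow overshoot). Preload is
a constant-pressure atrial source at 8 mmHg; the atrium itself is not
modelled. The discrete volume update is exactly conservative, which the
tests verify as inflow = outflow per converged cycle within 2%.

## The automatic subject-specific setting

`tailor_subject()` maps one `subject_record` (age, height, weight, heart
rate, brachial SBP/DBP, ESV/EDV/SV, carotid-femoral / carotid-radial /
femoral-tibial PWV) onto a tailored network plus cardiac parameters, with
no interactive input and a provenance entry for every modified parameter.

1. **Body size.** Du Bois body surface area
   $BSA = 0.007184\,W^{0.425}H^{0.725}$. Segment lengths scale with
   height, radii with $\sqrt{BSA/BSA_{ref}}$ (area-preserving allometry).
   Age enters no rule: no defensible quantitative age law was available
   from the inputs alone, so age is carried for completeness only.
2. **Mean working point.** MAP from the 2/3 approximation
   $MAP = DBP + PP/3$; mean flow $\bar Q = SV \cdot HR/60$. When the
   Doppler SV column is absent, $SV = EDV - ESV$. The subject's
   $MAP/\bar Q$ over the reference ratio gives the dimensionless
   resistance coefficient $k$ multiplying every terminal's $R_1$ and $R_2$
   (preserving the split; terminal compliances are left unchanged so the
   peripheral time constant scales mildly with $k$).
3. **Regional stiffness.** Aortic-region segments (including the
   aorto-iliac path that a carotid-femoral measurement traverses) take
   their target from cfPWV, arm segments from crPWV, leg segments from
   ftPWV; cerebral and visceral segments, and any missing limb PWV, scale
   the reference regional values by the subject's aortic ratio. Two
   refinements matter here:
   - *Working-pressure referencing.* A PWV measured in vivo holds at the
     vessel's distended state, so $\beta$ is inverted such that the
     distended wave speed at the subject's MAP (not the speed at zero
     pressure) matches the target, using the exact identity above.
   - *Transit-time identification.* A foot-to-foot measurement is an
     apparent transit speed: the detected front rides the systolic
     upstroke (pressure-stiffened), is advected by blood velocity, and is
     sharpened by viscoelastic dispersion. The shipped network stores a
     single identification constant (1.18, determined once on the
     reference configuration) by which measured targets are divided, so
     that applying the clinical foot-to-foot algorithm to the *simulated*
     carotid and femoral waveforms returns the assigned value. Without it
     the in-silico measurement overshoots the assigned PWV by 15-20%,
     i.e. the model would be systematically stiffer than the subject it
     claims to represent.
4. **Ventricle.** $T = 60/HR$; $E_{min} = 8/(EDV - V_0)$ so diastatic
   filling settles at the measured EDV; $E_{max}$ is calibrated so that
   one beat ejects the measured stroke volume against a lumped surrogate
   of the tailored network's own afterload (its total resistance from the
   subject's working point, its compliance as the distributed 1D
   compliance at MAP plus the terminal compliances), starting from the
   noninvasive end-systolic proxy $0.9\,bSBP/(V_{es} - V_0)$ and
   secant-iterating a fast 0D loop. Two deliberate departures from the
   simplest textbook rule: the end-systolic target volume is $EDV - SV$
   when SV is measured (Doppler SV and Simpson volumes are not mutually
   consistent in real data, and the mean-flow rule is anchored to SV), and
   the calibration replaces the fixed proxy because the aortic valve
   closes below peak pressure, so the uncalibrated rule over-ejects by
   several percent — enough to push the simulated mean pressure outside
   a 10% recovery band for SV-inconsistent subjects.

The closed loop that this procedure is designed to achieve — and that the
acceptance tests measure — is: simulated aortic mean pressure within 10%
of the 2/3-rule target, and in-silico foot-to-foot cfPWV within 10% of the
prescribed value, across subjects spanning the cohort mean ±1 SD (observed:
within ~3.5% and ~3% respectively).

## Numerics

Interior scheme: explicit two-step Lax--Wendroff (Richtmyer) on the
conservative form, second order in space and time, with the geometric
source terms of the radius taper included in both half and full steps (the
scheme is well balanced at rest to discretisation error). Default grid
0.25 cm; every segment gets at least 4 nodes. The time step is set from
the CFL condition with a 35% headroom for systolic stiffening and
advection (Courant number monitored every step; violation aborts with a
diagnostic). Wall viscosity is applied by operator splitting as an
implicit tridiagonal diffusion solve on $Q$ per segment, so physiological
$\gamma$ values impose no time-step penalty.

Boundaries are coupled through the Riemann invariants of the elastic law,
$W_\pm = u \pm 4c$, extrapolated along their characteristics with the
friction and taper sources retained (dropping them leaves an $O(\Delta x)$
steady-state pressure bias at every junction interface, which is visible
as a spurious mean-pressure gradient down the tree). Bifurcations solve,
by Newton iteration, mass conservation plus continuity of total pressure
$p + \tfrac12\rho u^2$ (documented so it can be switched; static-pressure
continuity differs negligibly at these velocities). Terminals couple the
outgoing characteristic to the RCR load; the inlet couples the valve law
and the incoming characteristic implicitly, which is what keeps the
explicit heart--network coupling stable at small valve resistances.

Runs start from a uniform diastolic pressure with zero flow and repeat
cycles until the aortic-root pressure trace is periodic within 0.5 mmHg
(max pointwise cycle-to-cycle difference), typically 4–8 cycles; the
convergence criterion makes the initial condition immaterial. Simulated
pressures reported at sites include the viscous wall stress. Verified
properties include global mass conservation (inlet volume vs summed
terminal outflow within 2%), junction flow residuals below $10^{-6}$
relative, and grid-convergence of central pressures (halving the grid
moves cSBP/cDBP by < 1 mmHg).

## Synthetic cohort and device emulator

`generate_cohort()` draws subjects matching the marginal statistics of a
young healthy male population (see `?cohort_spec` for the full table:
e.g. brachial pressure 121 ± 12.1 / 67.4 ± 8.73 mmHg, cfPWV
5.86 ± 0.87 m/s, SV 82.02 ± 19.73 mL). Sampling is truncated-normal
(mean ± 3 SD with physiological floors) with correlation 0.5 between
height–weight, SBP–DBP and EDV–ESV — moderate positive values chosen as
synthetic-only assumptions where no empirical correlations were available.
Three constructions keep every record valid by design: SBP is assembled as
DBP + pulse pressure (with the covariance implied by the requested
marginals), ESV is capped below EDV, and SV is generated as a noisy
Doppler-style re-measurement of EDV − ESV (ratio 1.058 ± 0.08), which
reproduces the SV marginal while keeping the volume set consistent enough
for the ventricle fit. The limb PWVs are cfPWV plus configurable offsets
(defaults +2.64 and +3.14 m/s).

The reference device emulator adds to the true central pressures the
documented cuff-calibration bias pattern of tonometric devices —
−8.2 ± 10.3 mmHg systolic (underestimation), +7.6 ± 8.7 mmHg diastolic
(overestimation) — as independent Gaussian noise. It emulates only the
scalar estimates, not the device waveform or transfer function. What the
synthetic cohort does **not** emulate: measurement error correlated with
subject characteristics, intra-subject variability, arrhythmia, or any
pathology; passing tests on synthetic cohorts therefore demonstrate the
pipeline's internal consistency, not clinical accuracy on real patients.

## Statistics pipeline choices

- Normality gate: Kolmogorov–Smirnov on standardized differences at 0.05
  decides between the paired t test and the Wilcoxon signed-rank test;
  both p values are retained in the output. A two-group (unpaired) variant
  covers subgroup comparisons.
- Percent difference: per-pair $100(m-r)/r$, then averaged — this is the
  definition under which a percent column carries its own SD.
- Accuracy threshold: $|d| \le 10$ mmHg with a *closed* boundary (a
  difference of exactly 10 counts as satisfactory).
- Regressor selection: full multivariate OLS, two-sided t tests at
  $\alpha = 0.025$; rank-deficient designs are rejected naming the
  collinear columns. The type-I error of this procedure is itself tested
  by simulation (200 null cohorts; retention rate ≈ 0.025 ± 0.015).
- Commonality analysis: the all-subsets (Nimon-style) variant. The
  coefficients are obtained by solving the exact linear system
  $R^2(W) = \sum_{S \cap W \ne \emptyset} C(S)$ over all non-empty
  subsets, which is numerically robust and whose solution provably
  satisfies $U_i = R^2_{full} - R^2_{full \setminus i}$ and sums to the
  full $R^2$ (verified to $10^{-10}$). Capped at 6 covariates.
- Bias correction: `apply_calibration_bias()` implements the arithmetic
  of adjusting an observed model-device difference for a known
  device-calibration bias; with the documented device biases it turns a
  (+7.8, −3.2) mmHg comparison into (−0.4, +4.4) mmHg — a speculative
  adjustment, as the real covariance between model and device errors is
  unknown, and it is documented as such.

## Problem sizes used by tests and the acceptance script

Physics oracles run on single vessels (5–100 cm, 21–401 nodes); the
parameter-recovery sweep tailors and simulates 10 subjects spanning the
cohort mean ±1 SD; the planted-bias validation uses 5000 synthetic
subjects (no 1D simulation needed — the perfect-model construction);
cohort-pipeline integration tests use 2–3 subjects. These sizes give
sub-percent Monte-Carlo error on the planted biases and keep a full run
of the suite in single-digit minutes on one core.

## Known limitations

- The reference tree is an averaged adult; only global allometric scaling
  (height, BSA) personalises its geometry. No imaging-based geometry.
- The tube law's pressure-stiffening is the $\sqrt{A}$ law's; real walls
  stiffen faster near hypertensive pressures.
- The foot-to-foot identification constant is calibrated on the reference
  configuration; it drifts slightly (±few %) across extreme subjects.
- Constant-pressure preload and diode valves omit atrial contraction,
  valve dynamics and regurgitation.
- The device emulator is statistical; no waveform-level transfer function
  is modelled, so waveform-shape comparisons with tonometric devices are
  out of scope.
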
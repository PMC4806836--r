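# centralbp

Noninvasive appraisal of **central (ascending-aortic) blood pressure** with
a subject-specific multiscale cardiovascular model, plus the
method-comparison statistics used to validate such estimates against a
tonometric reference device.

Central systolic/diastolic pressure (cSBP/cDBP) is a better marker of
cardiac afterload and cardiovascular risk than cuff pressure measured at
the arm, but it cannot be measured directly in routine practice. This
package is for physiological modellers and method-comparison researchers
who want a fully automatic, reproducible pipeline from routine
measurements to central pressure estimates and agreement statistics.

## The model

- **1D large arteries.** Pulse-wave propagation through a 56-segment
  averaged-adult arterial tree (shipped as a structured data file),
  governed by the area–flow equations
  `A_t + Q_x = 0`, `Q_t + (Q²/A)_x + (A/ρ) p_x = −8πμQ/(ρA)`
  with the viscoelastic tube law
  `p = β(√A − √A0)/A0 + γ/(A0√A) · A_t`
  (closed-form wave speed `c² = β√A/(2ρA0)`), solved by a two-step
  Lax–Wendroff scheme with characteristic boundary coupling and
  Newton-solved bifurcations (mass + total-pressure continuity).
- **0D heart and microcirculation.** A time-varying elastance left
  ventricle `p_lv = E(t)(V − V0)` with pressure-gated valves drives the
  root; every leaf ends in a three-element Windkessel (RCR) load.
- **Automatic subject-specific setting.** From one record — age, height,
  weight, heart rate, brachial SBP/DBP, LV end-systolic/diastolic volumes,
  stroke volume and carotid-femoral (plus optional carotid-radial,
  femoral-tibial) pulse wave velocity — the procedure scales geometry by
  height and Du Bois BSA, sets regional wall stiffness from the measured
  PWVs at the subject's working pressure, multiplies the terminal
  resistances by the mean pressure–flow coefficient
  `k = (MAP/Q̄) / reference ratio` (MAP by the 2/3 rule, `Q̄ = SV·HR/60`),
  and calibrates peak elastance so one beat ejects the measured stroke
  volume. Deterministic, no interactive input, full provenance.
- **Waveform analysis.** Intersecting-tangent foot detection,
  foot-to-foot PWV, pulse-pressure amplification.
- **Validation statistics.** Paired comparisons with a
  Kolmogorov–Smirnov normality gate (t vs Wilcoxon), regression agreement,
  Bland–Altman limits of agreement with error trends, accuracy
  classification at a 10 mmHg threshold, multivariate error-regressor
  selection (α = 0.025) and all-subsets commonality analysis.
- **Synthetic cohorts.** A seeded generator matching a young healthy male
  population's marginals, and a statistical emulator of a cuff-calibrated
  tonometric device (−8.2 ± 10.3 mmHg systolic, +7.6 ± 8.7 mmHg diastolic
  calibration bias), so the whole pipeline is testable without patient
  data.

See the methods vignette (`vignettes/central-pressure-model.Rmd`) for the
full model description, parameter rationale and limitations.

## Worked example

```r
library(centralbp)

s <- subject_record("demo", age = 24, height = 178, weight = 75,
                    heart_rate = 62, brachial_sbp = 121, brachial_dbp = 67,
                    esv = 54, edv = 131, stroke_volume = 82, cf_pwv = 5.9)
model <- tailor_subject(s)
model
#> Tailored multiscale model for subject demo
#>   resistance coefficient k = 0.9673
#>   E_max 2.40, E_min 0.0661 mmHg/mL, T 0.968 s
#>   provenance entries: 11 rules

est <- predict(model)   # runs the 1D simulation to periodic steady state
est
#>     id     cSBP    cDBP      cPP      MAP source converged
#> 1 demo 105.8951 70.4295 35.46564 86.45579  model      TRUE

sim <- attr(est, "simulation")
sim
#> 1D haemodynamic simulation: 4 cycles, converged (cycle residual 0.353 mmHg, tol 0.5)
#>   LV: EDV 130.7 mL, ESV 48.3 mL, SV 82.4 mL
#>   aortic root: 105.9/70.4 mmHg (mean 86.4)

measure_cfpwv(sim, model$network)
#> [1] 5.84
```

Reading the numbers: the model places this subject's central pressure at
105.9/70.4 mmHg against a cuff reading of 121/67 — systolic pressure is
lower centrally than at the arm (pulse-pressure amplification), while
diastolic and mean pressure barely change. The simulated stroke volume
(82.4 mL) recovers the measured input (82 mL), the simulated mean aortic
pressure (86.4 mmHg) recovers the 2/3-rule target (85 mmHg), and applying
the clinical foot-to-foot algorithm to the simulated carotid and femoral
waveforms returns 5.84 m/s against the prescribed 5.9 — the three closed
loops the setting procedure is designed to close.

Cohort-level use goes through `run_estimate()` / `run_validate()` (or the
CLI script in `inst/cli/centralbp.R`), which write per-subject estimate
CSVs and Table-style agreement reports with Bland–Altman and regression
figures; `generate_cohort()` + `emulate_reference_device()` produce
synthetic cohorts in the same schema.

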
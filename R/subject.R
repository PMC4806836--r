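#' One subject's noninvasive measurements
#'
#' The complete per-subject information set consumed by the automatic
#' setting procedure: anthropometry, brachial cuff pressures, heart rate,
#' echocardiographic ventricular volumes and regional pulse wave velocities.
#'
#' @param id subject identifier.
#' @param age years.
#' @param height cm.
#' @param weight kg.
#' @param heart_rate bpm, in \[30, 120\].
#' @param brachial_sbp,brachial_dbp brachial cuff pressures (mmHg),
#'   `brachial_sbp > brachial_dbp > 0`.
#' @param esv,edv LV end-systolic and end-diastolic volume (mL),
#'   `edv > esv > 0`.
#' @param stroke_volume Doppler-derived stroke volume (mL); optional, falls
#'   back to `edv - esv` where needed.
#' @param cf_pwv carotid-femoral PWV (m/s), required.
#' @param cr_pwv,ft_pwv carotid-radial and femoral-tibial PWV (m/s),
#'   optional (regional fallbacks scale the reference values by the aortic
#'   ratio).
#' @return object of class `subject_record`.
#' @export
subject_record <- function(id, age, height, weight, heart_rate,
                           brachial_sbp, brachial_dbp, esv, edv,
                           stroke_volume = NA_real_, cf_pwv,
                           cr_pwv = NA_real_, ft_pwv = NA_real_) {
  rec <- structure(list(id = as.character(id), age = age, height = height,
                        weight = weight, heart_rate = heart_rate,
                        brachial_sbp = brachial_sbp,
                        brachial_dbp = brachial_dbp,
                        esv = esv, edv = edv, stroke_volume = stroke_volume,
                        cf_pwv = cf_pwv, cr_pwv = cr_pwv, ft_pwv = ft_pwv),
                   class = "subject_record")
  validate_subject(rec)
  rec
}

#' @noRd
validate_subject <- function(rec) {
  who <- paste0("subject '", rec$id, "': ")
  num <- c("age", "height", "weight", "heart_rate", "brachial_sbp",
           "brachial_dbp", "esv", "edv", "cf_pwv")
  for (f in num) {
    v <- rec[[f]]
    if (is.null(v) || is.na(v) || !is.finite(v) || v <= 0) {
      stop_invalid(who, f, " must be a positive number")
    }
  }
  for (f in c("stroke_volume", "cr_pwv", "ft_pwv")) {
    v <- rec[[f]]
    if (!is.na(v) && v <= 0) stop_invalid(who, f, " must be positive if present")
  }
  if (!(rec$brachial_sbp > rec$brachial_dbp)) {
    stop_invalid(who, "brachial_sbp must exceed brachial_dbp")
  }
  if (!(rec$edv > rec$esv)) stop_invalid(who, "edv must exceed esv")
  if (rec$heart_rate < 30 || rec$heart_rate > 120) {
    stop_invalid(who, "heart_rate outside [30, 120] bpm")
  }
  invisible(rec)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s: %g y, %g cm, %g kg | BP %g/%g mmHg, HR %g bpm\n",
              x$id, x$age, x$height, x$weight, x$brachial_sbp,
              x$brachial_dbp, x$heart_rate))
  cat(sprintf("  ESV %g, EDV %g, SV %s mL | PWV cf %g, cr %s, ft %s m/s\n",
              x$esv, x$edv,
              if (is.na(x$stroke_volume)) "(EDV-ESV)" else format(x$stroke_volume),
              x$cf_pwv,
              if (is.na(x$cr_pwv)) "-" else format(x$cr_pwv),
              if (is.na(x$ft_pwv)) "-" else format(x$ft_pwv)))
  invisible(x)
}

#' Body surface area (Du Bois)
#'
#' \eqn{BSA = 0.007184\,W^{0.425}\,H^{0.725}} with weight in kg and height
#' in cm; the clinical default formula, used for body-size characterisation
#' of the arterial geometry.
#'
#' @param height cm, > 0.
#' @param weight kg, > 0.
#' @return BSA in m^2.
#' @export
#' @examples
#' compute_bsa(178, 75) # about 1.93
compute_bsa <- function(height, weight) {
  if (any(height <= 0) || any(weight <= 0)) {
    stop_invalid("compute_bsa: height and weight must be positive")
  }
  0.007184 * weight^0.425 * height^0.725
}

#' Mean arterial pressure by the 2/3 approximation
#'
#' \eqn{MAP = DBP + (SBP - DBP)/3}: diastolic plus one third of pulse
#' pressure, the standard cuff-based estimate.
#'
#' @param sbp systolic pressure (mmHg).
#' @param dbp diastolic pressure (mmHg), < `sbp`.
#' @return MAP (mmHg).
#' @export
#' @examples
#' mean_pressure_23(120, 80) # 93.33
mean_pressure_23 <- function(sbp, dbp) {
  if (any(sbp <= dbp)) stop_invalid("mean_pressure_23: need sbp > dbp")
  dbp + (sbp - dbp) / 3
}

#' Mean aortic flow from stroke volume and heart rate
#'
#' \eqn{\bar Q = SV \cdot HR / 60} (mL/s): stroke volume times heart pacing.
#'
#' @param sv stroke volume (mL), > 0.
#' @param hr heart rate (bpm), > 0.
#' @return mean flow (mL/s).
#' @export
mean_flow <- function(sv, hr) {
  if (any(sv <= 0) || any(hr <= 0)) {
    stop_invalid("mean_flow: sv and hr must be positive")
  }
  sv * hr / 60
}

#' @noRd
subject_sv <- function(subject) {
  if (!is.na(subject$stroke_volume)) subject$stroke_volume
  else subject$edv - subject$esv
}

#' Distal-resistance scaling coefficient
#'
#' The subject's mean pressure-flow ratio (MAP by the 2/3 rule over mean
#' flow SV*HR/60) referred to the reference ratio shipped with the network,
#' giving the dimensionless coefficient that multiplies every terminal's
#' reference distal resistances (preserving each terminal's R1:R2 split).
#'
#' @param subject a [subject_record()].
#' @param reference_ratio reference MAP / reference mean flow (mmHg s/mL),
#'   stored in the network file (`net$reference$ratio`).
#' @return scaling coefficient k (dimensionless).
#' @export
resistance_coefficient <- function(subject, reference_ratio) {
  if (is.null(reference_ratio) || reference_ratio <= 0) {
    stop_invalid("resistance_coefficient: reference_ratio must be > 0")
  }
  map <- mean_pressure_23(subject$brachial_sbp, subject$brachial_dbp)
  q <- mean_flow(subject_sv(subject), subject$heart_rate)
  (map / q) / reference_ratio
}

#' Scale network geometry to a subject's body size
#'
#' Segment lengths scale with height, radii with the square root of body
#' surface area (area-preserving allometry), both relative to the reference
#' subject stored with the network. Age is accepted for interface
#' completeness but enters no geometric rule.
#'
#' @param network an [arterial_network()].
#' @param bsa subject body surface area (m^2).
#' @param height subject height (cm).
#' @param age subject age (years); unused.
#' @param reference_bsa,reference_height reference values (defaults: the
#'   network's stored reference subject).
#' @return the scaled network.
#' @export
scale_geometry <- function(network, bsa, height, age = NULL,
                           reference_bsa = network$reference$bsa,
                           reference_height = network$reference$height) {
  if (bsa <= 0 || height <= 0 || reference_bsa <= 0 || reference_height <= 0) {
    stop_invalid("scale_geometry: all sizes must be positive")
  }
  len_f <- height / reference_height
  rad_f <- sqrt(bsa / reference_bsa)
  network$segments$length <- network$segments$length * len_f
  network$segments$proximal_radius <- network$segments$proximal_radius * rad_f
  network$segments$distal_radius <- network$segments$distal_radius * rad_f
  attr(network, "geometry_scaling") <- c(length = len_f, radius = rad_f)
  network
}

#' Assign regional wall stiffness from measured pulse wave velocities
#'
#' Aortic-region segments (including the aorto-iliac path, the territory a
#' carotid-femoral measurement covers) take their wall coefficient from the
#' carotid-femoral PWV, upper-limb segments from the carotid-radial PWV and
#' lower-limb segments from the femoral-tibial PWV. Cerebral and visceral
#' segments - and any missing limb PWV - scale their reference regional
#' value by the subject's aortic ratio `cf_pwv / reference aortic PWV`.
#' Each segment's coefficient is inverted at its own mid-segment reference
#' area via [stiffness_from_pwv()]; with `at_pressure > 0` the inversion
#' targets the distended wave speed at that working pressure.
#'
#' A clinical foot-to-foot PWV is an apparent transit speed: the measured
#' front rides the systolic upstroke (pressure-stiffened), is advected by
#' blood velocity and is sharpened by viscoelastic dispersion, so it
#' exceeds the intrinsic distended wave speed. The network file therefore
#' carries a transit-time identification constant (`ftf_calibration`,
#' determined once on the reference configuration) by which measured
#' targets are divided, so that the in-silico foot-to-foot measurement of
#' a tailored model reproduces the assigned value.
#'
#' @param network an [arterial_network()] (carrying reference regional PWVs).
#' @param cf_pwv carotid-femoral PWV (m/s), required.
#' @param cr_pwv,ft_pwv carotid-radial and femoral-tibial PWV (m/s), or NA.
#' @param at_pressure working transmural pressure (mmHg) at which the
#'   assigned wave speeds should hold (0 = at reference area).
#' @param ftf_calibration transit-time identification constant; defaults to
#'   the value stored in the network file (1 if absent).
#' @return the network with updated `wall_stiffness`.
#' @export
assign_regional_stiffness <- function(network, cf_pwv, cr_pwv = NA,
                                      ft_pwv = NA, at_pressure = 0,
                                      ftf_calibration = NULL) {
  if (is.null(ftf_calibration)) {
    ftf_calibration <- network$reference$ftf_calibration
    if (is.null(ftf_calibration)) ftf_calibration <- 1
  }
  if (is.na(cf_pwv) || cf_pwv <= 0) {
    stop_invalid("assign_regional_stiffness: cf_pwv must be positive")
  }
  for (v in c(cr_pwv, ft_pwv)) {
    if (!is.na(v) && v <= 0) {
      stop_invalid("assign_regional_stiffness: PWVs must be positive")
    }
  }
  ref <- network$reference$regional_pwv
  if (is.null(ref)) stop_invalid("network carries no reference regional PWVs")
  ratio <- cf_pwv / ref[["aortic"]]
  target <- c(
    "aortic" = cf_pwv,
    "upper-limb" = if (is.na(cr_pwv)) ref[["upper-limb"]] * ratio else cr_pwv,
    "lower-limb" = if (is.na(ft_pwv)) ref[["lower-limb"]] * ratio else ft_pwv,
    "cerebral" = ref[["cerebral"]] * ratio,
    "visceral" = ref[["visceral"]] * ratio
  )
  s <- network$segments
  a0_mid <- pi * ((s$proximal_radius + s$distal_radius) / 2)^2
  s$wall_stiffness <- stiffness_from_pwv(target[s$region] / ftf_calibration,
                                         a0_mid,
                                         network$fluid$blood_density,
                                         at_pressure = at_pressure)
  network$segments <- s
  attr(network, "regional_pwv_target") <- target
  network
}

# Total arterial compliance of a network at a working pressure (mL/mmHg):
# distributed 1D compliance of every segment at its distended area plus the
# lumped Windkessel compliances. Used as the afterload surrogate when
# calibrating peak elastance.
#' @noRd
network_compliance <- function(network, map) {
  s <- network$segments
  rho <- rho_to_cgs(network$fluid$blood_density)
  p <- mmHg_to_cgs(map)
  a0 <- pi * ((s$proximal_radius + s$distal_radius) / 2)^2
  beta <- beta_to_cgs(s$wall_stiffness)
  sqA <- sqrt(a0) + p * a0 / beta
  A <- sqA^2
  c2 <- beta * sqA / (2 * rho * a0)
  c1d <- sum(s$length * A / (rho * c2)) * MMHG_TO_DYNCM2 # cm^3/mmHg
  c1d + sum(network$terminals$C)
}

# 0D surrogate of the tailored model: elastance ventricle ejecting into a
# two-element Windkessel matching the network's total resistance and
# compliance. Fast deterministic run used to calibrate E_max so the loop
# delivers the target stroke volume.
#' @noRd
sv_0d <- function(E_max, E_min, period, activation_time, shape, V0,
                  preload, R_av, R_mit, R_art, C_art, p_ven,
                  cycles = 8, dt = 5e-4) {
  pk <- hill_peak(shape)
  n_steps <- round(period / dt)
  V <- V0 + preload / E_min
  p_art <- 80
  vmax <- vmin <- NULL
  for (cyc in seq_len(cycles)) {
    vs <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      t <- (i - 1) * dt
      E <- E_min + (E_max - E_min) *
        hill_shape(t * pk$s / activation_time, shape) / pk$value
      p_lv <- E * (V - V0)
      q_av <- max(0, (p_lv - p_art) / R_av)
      q_mit <- max(0, (preload - p_lv) / R_mit)
      V <- V + dt * (q_mit - q_av)
      p_art <- p_art + dt * (q_av - (p_art - p_ven) / R_art) / C_art
      vs[i] <- V
    }
    vmax <- max(vs); vmin <- min(vs)
  }
  vmax - vmin
}

#' Fit the lumped ventricle to a subject
#'
#' Builds [cardiac_params()] from the subject record: period `T = 60/HR`;
#' baseline elastance from diastatic filling to the measured EDV
#' (`E_min = preload/(EDV - V0)`); activation time `0.38 sqrt(T)`; and peak
#' elastance calibrated so that one beat ejects the subject's stroke volume
#' against a lumped (resistance + compliance) surrogate of the tailored
#' network's own afterload. The calibration starts from the noninvasive
#' end-systolic proxy `E_max = 0.9 bSBP / (V_es - V0)` (with
#' `V_es = EDV - SV` when the stroke-volume measurement is present, else
#' the measured ESV) and secant-iterates the 0D loop to the target stroke
#' volume.
#'
#' @param subject a [subject_record()].
#' @param network the tailored [arterial_network()] providing the afterload
#'   surrogate; when NULL, a generic afterload (from MAP/flow with 1.8
#'   mL/mmHg compliance) is used.
#' @param V0 unstressed ventricular volume (mL).
#' @param preload_pressure atrial filling pressure (mmHg).
#' @return a [cardiac_params()] object; attribute `"provenance"` logs every
#'   rule applied.
#' @export
fit_ventricle <- function(subject, network = NULL, V0 = 10,
                          preload_pressure = 8) {
  validate_subject(subject)
  if (subject$esv <= V0) {
    stop_invalid("subject '", subject$id, "': ESV must exceed V0 = ", V0, " mL")
  }
  period <- 60 / subject$heart_rate
  tact <- 0.38 * sqrt(period)
  E_min <- preload_pressure / (subject$edv - V0)
  sv_target <- subject_sv(subject)
  v_es <- if (!is.na(subject$stroke_volume)) subject$edv - subject$stroke_volume
          else subject$esv
  v_es <- max(v_es, V0 + 5)
  E_start <- 0.9 * subject$brachial_sbp / (v_es - V0)
  map <- mean_pressure_23(subject$brachial_sbp, subject$brachial_dbp)
  q <- mean_flow(sv_target, subject$heart_rate)
  p_ven <- if (!is.null(network)) network$terminals$venous_pressure[1] else 5
  R_art <- (map - p_ven) / q
  C_art <- if (!is.null(network)) network_compliance(network, map) else 1.8
  R_av <- 0.005; R_mit <- 0.005
  shape <- HILL_SHAPE
  f <- function(em) sv_0d(em, E_min, period, tact, shape, V0,
                          preload_pressure, R_av, R_mit, R_art, C_art,
                          p_ven) - sv_target
  e0 <- E_start; f0 <- f(e0)
  e1 <- E_start * (if (f0 > 0) 0.8 else 1.25); f1 <- f(e1)
  for (i in 1:8) {
    if (abs(f1) < 0.2 || abs(e1 - e0) < 1e-4) break
    e2 <- e1 - f1 * (e1 - e0) / (f1 - f0)
    e2 <- min(max(e2, 0.3), 15)
    e0 <- e1; f0 <- f1
    e1 <- e2; f1 <- f(e1)
  }
  E_max <- e1
  params <- cardiac_params(E_max = E_max, E_min = E_min, period = period,
                           V0 = V0, activation_time = tact,
                           preload_pressure = preload_pressure,
                           valve_resistance = R_av,
                           mitral_resistance = R_mit, shape = shape)
  attr(params, "provenance") <- list(
    period = "T = 60/HR",
    E_min = "preload_pressure / (EDV - V0): diastatic filling to measured EDV",
    activation_time = "0.38 * sqrt(T)",
    E_max = sprintf(paste0("secant-calibrated on 0D Windkessel surrogate ",
                           "(R %.3f mmHg s/mL, C %.2f mL/mmHg) to SV %.1f mL; ",
                           "start 0.9 bSBP/(V_es - V0), V_es from %s"),
                    R_art, C_art, sv_target,
                    if (!is.na(subject$stroke_volume)) "EDV - SV" else "ESV"),
    sv_residual_0d = f1
  )
  params
}

#' Tailor the multiscale model to a subject
#'
#' The automatic subject-specific setting procedure. Starting from the
#' reference network it (1) scales geometry to the subject's height and Du
#' Bois body surface area, (2) assigns regional wall stiffness from the
#' measured pulse wave velocities at the subject's working pressure (2/3
#' rule MAP), (3) multiplies every terminal's distal resistances by the
#' mean pressure-flow coefficient referred to the reference ratio, and (4)
#' fits the lumped ventricle. The procedure is deterministic and fully
#' automatic; every modified parameter carries a provenance entry.
#'
#' @param subject a [subject_record()].
#' @param reference_network an [arterial_network()]; default the shipped
#'   averaged-adult tree.
#' @return object of class `centralbp_model` with elements `subject`,
#'   `network` (tailored), `cardiac`, `resistance_coefficient` and
#'   `provenance`.
#' @export
#' @examples
#' \donttest{
#' s <- subject_record("mean", age = 24.3, height = 178, weight = 75,
#'                     heart_rate = 62.1, brachial_sbp = 121,
#'                     brachial_dbp = 67.4, esv = 53.57, edv = 131.1,
#'                     stroke_volume = 82.02, cf_pwv = 5.86)
#' m <- tailor_subject(s)
#' }
tailor_subject <- function(subject, reference_network = default_network()) {
  validate_subject(subject)
  net <- reference_network
  bsa <- compute_bsa(subject$height, subject$weight)
  map <- mean_pressure_23(subject$brachial_sbp, subject$brachial_dbp)
  net <- scale_geometry(net, bsa, subject$height, subject$age)
  gs <- attr(net, "geometry_scaling")
  net <- assign_regional_stiffness(net, subject$cf_pwv, subject$cr_pwv,
                                   subject$ft_pwv, at_pressure = map)
  pwv_t <- attr(net, "regional_pwv_target")
  k <- resistance_coefficient(subject, reference_network$reference$ratio)
  net$terminals$R1 <- net$terminals$R1 * k
  net$terminals$R2 <- net$terminals$R2 * k
  validate_network(net)
  cardiac <- fit_ventricle(subject, net)
  provenance <- list(
    bsa = sprintf("Du Bois BSA = %.3f m^2", bsa),
    map = sprintf("2/3-rule MAP = %.2f mmHg", map),
    mean_flow = sprintf("SV x HR/60 = %.1f mL/s (SV from %s)",
                        mean_flow(subject_sv(subject), subject$heart_rate),
                        if (!is.na(subject$stroke_volume)) "SV column"
                        else "EDV - ESV"),
    geometry = sprintf("lengths x %.3f (height), radii x %.3f (sqrt BSA)",
                       gs[["length"]], gs[["radius"]]),
    stiffness = sprintf(
      "regional PWV targets (m/s) at MAP: %s",
      paste(sprintf("%s %.2f", names(pwv_t), pwv_t), collapse = ", ")),
    resistance_coefficient = sprintf(
      "k = (MAP/Q) / reference ratio = %.4f on every terminal R1 and R2", k),
    cardiac = attr(cardiac, "provenance")
  )
  structure(list(subject = subject, network = net, cardiac = cardiac,
                 resistance_coefficient = k, provenance = provenance),
            class = "centralbp_model")
}

#' @export
print.centralbp_model <- function(x, ...) {
  cat("Tailored multiscale model for subject", x$subject$id, "\n")
  cat(sprintf("  resistance coefficient k = %.4f\n", x$resistance_coefficient))
  cat(sprintf("  E_max %.2f, E_min %.4f mmHg/mL, T %.3f s\n",
              x$cardiac$E_max, x$cardiac$E_min, x$cardiac$period))
  cat("  provenance entries:", length(unlist(x$provenance)), "rules\n")
  invisible(x)
}

#' Simulate a tailored model to periodic steady state
#'
#' @param object a `centralbp_model` from [tailor_subject()].
#' @param nsim,seed unused (the model is deterministic); kept for the
#'   generic's signature.
#' @param config a [sim_config()].
#' @param ... ignored.
#' @return a `centralbp_sim` (see [simulate_network()]).
#' @export
simulate.centralbp_model <- function(object, nsim = 1, seed = NULL,
                                     config = NULL, ...) {
  if (is.null(config)) {
    config <- sim_config(init_pressure = object$subject$brachial_dbp)
  }
  simulate_network(object$network, object$cardiac, config)
}

#' Predict central pressures for a tailored model
#'
#' Runs the 1D simulation and reads central systolic/diastolic/pulse
#' pressure off the aortic-root waveform.
#'
#' @param object a `centralbp_model`.
#' @param config a [sim_config()].
#' @param ... passed nowhere; kept for the generic.
#' @return a `central_pressure_estimate` (see [extract_pressures()]) with
#'   the simulation attached as attribute `"simulation"`.
#' @export
predict.centralbp_model <- function(object, config = NULL, ...) {
  sim <- simulate.centralbp_model(object, config = config)
  est <- extract_pressures(sim$waveforms$aortic_root, id = object$subject$id,
                           source = "model")
  est$converged <- sim$converged
  attr(est, "simulation") <- sim
  est
}
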
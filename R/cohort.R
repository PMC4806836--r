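#' Specification of a synthetic study cohort
#'
#' Defaults emulate the marginal statistics of a young, healthy, male
#' study population (mean +/- SD): age 24.3 +/- 1.59 y, height 178 +/- 6.15
#' cm, weight 75 +/- 10.2 kg, HR 62.1 +/- 11.15 bpm, brachial pressure
#' 121 +/- 12.1 over 67.4 +/- 8.73 mmHg, ESV 53.57 +/- 8.97 mL, EDV
#' 131.1 +/- 21.3 mL, SV 82.02 +/- 19.73 mL, cfPWV 5.86 +/- 0.87 m/s.
#' Sampling is truncated-normal (mean +/- 3 SD and physiological floors)
#' with moderate positive correlations between paired size/pressure/volume
#' variables; brachial systolic pressure is built as diastolic + pulse
#' pressure so that SBP > DBP holds by construction, and stroke volume is
#' generated as a noisy Doppler-style re-measurement of EDV - ESV so the
#' volume set stays physiologically consistent while matching the SV
#' marginal.
#'
#' The pseudo reference device emulates a tonometric central-pressure
#' estimate calibrated to cuff pressure: true central value plus a
#' calibration bias (default -8.2 +/- 10.3 mmHg systolic, +7.6 +/- 8.7
#' diastolic, the documented cuff-calibration error pattern:
#' underestimation of systolic, overestimation of diastolic central
#' pressure) plus subject-level noise.
#'
#' @param n cohort size (>= 3).
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @param means,sds named numeric vectors overriding any of the defaults
#'   (names: age, height, weight, heart_rate, brachial_sbp, brachial_dbp,
#'   esv, edv, stroke_volume, cf_pwv).
#' @param correlations named vector with `height_weight`, `sbp_dbp`,
#'   `edv_esv` (defaults 0.5).
#' @param pwv_offsets named vector `cr`, `cr_sd`, `ft`, `ft_sd`: offsets of
#'   carotid-radial and femoral-tibial PWV above cfPWV (m/s).
#' @param device named vector `sbp_bias`, `sbp_sd`, `dbp_bias`, `dbp_sd`
#'   (mmHg) for the reference-device emulator.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed = 1L,
                        means = NULL, sds = NULL,
                        correlations = NULL, pwv_offsets = NULL,
                        device = NULL) {
  if (n < 3) stop_invalid("cohort_spec: n must be >= 3")
  mu <- c(age = 24.3, height = 178, weight = 75, heart_rate = 62.1,
          brachial_sbp = 121, brachial_dbp = 67.4, esv = 53.57,
          edv = 131.1, stroke_volume = 82.02, cf_pwv = 5.86)
  sg <- c(age = 1.59, height = 6.15, weight = 10.2, heart_rate = 11.15,
          brachial_sbp = 12.1, brachial_dbp = 8.73, esv = 8.97,
          edv = 21.3, stroke_volume = 19.73, cf_pwv = 0.87)
  co <- c(height_weight = 0.5, sbp_dbp = 0.5, edv_esv = 0.5)
  po <- c(cr = 2.64, cr_sd = 0.4, ft = 3.14, ft_sd = 0.5)
  dv <- c(sbp_bias = -8.2, sbp_sd = 10.3, dbp_bias = 7.6, dbp_sd = 8.7)
  if (!is.null(means)) mu[names(means)] <- means
  if (!is.null(sds)) sg[names(sds)] <- sds
  if (!is.null(correlations)) co[names(correlations)] <- correlations
  if (!is.null(pwv_offsets)) po[names(pwv_offsets)] <- pwv_offsets
  if (!is.null(device)) dv[names(device)] <- device
  if (any(sg < 0)) stop_invalid("cohort_spec: SDs must be >= 0")
  if (any(abs(co) > 0.99)) stop_invalid("cohort_spec: |correlations| must be < 1")
  structure(list(n = as.integer(n), seed = as.integer(seed), means = mu,
                 sds = sg, correlations = co, pwv_offsets = po,
                 device = dv),
            class = "cohort_spec")
}

# truncated-normal sampling by resampling out-of-bounds draws
#' @noRd
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  lo <- max(lower, mean - 3 * sd)
  hi <- min(upper, mean + 3 * sd)
  if (lo >= hi) stop_invalid("infeasible truncation bounds for mean ", mean)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1
    if (tries > 1000) stop_invalid("truncated sampling failed to converge")
  }
  x
}

# correlated bivariate normal via Cholesky, then truncation by resampling
# the second coordinate conditionally
#' @noRd
rbvn <- function(n, mu1, sd1, mu2, sd2, rho, lo1, hi1, lo2, hi2) {
  z1 <- rtnorm(n, 0, 1, (lo1 - mu1) / sd1, (hi1 - mu1) / sd1)
  x1 <- mu1 + sd1 * z1
  cond_mu <- mu2 + rho * sd2 * z1
  cond_sd <- sd2 * sqrt(1 - rho^2)
  x2 <- vapply(seq_len(n), function(i) {
    rtnorm(1, cond_mu[i], cond_sd, lo2, hi2)
  }, 0)
  cbind(x1, x2)
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` subjects matching the cohort specification (see
#' [cohort_spec()] for the sampling model). Every returned record satisfies
#' the [subject_record()] invariants by construction, and the draw is
#' deterministic under the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of `subject_record`s.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  mu <- spec$means
  sg <- spec$sds
  co <- spec$correlations
  hw <- rbvn(n, mu[["height"]], sg[["height"]], mu[["weight"]], sg[["weight"]],
             co[["height_weight"]], 150, 210, 40, 140)
  # brachial pressure: sample (DBP, PP) with the covariance implied by the
  # requested SBP/DBP marginals and their correlation, then SBP = DBP + PP
  var_s <- sg[["brachial_sbp"]]^2
  var_d <- sg[["brachial_dbp"]]^2
  cov_sd <- co[["sbp_dbp"]] * sg[["brachial_sbp"]] * sg[["brachial_dbp"]]
  var_pp <- var_s + var_d - 2 * cov_sd
  if (var_pp <= 0) stop_invalid("generate_cohort: infeasible pressure spec")
  mu_pp <- mu[["brachial_sbp"]] - mu[["brachial_dbp"]]
  rho_dpp <- (cov_sd - var_d) / (sg[["brachial_dbp"]] * sqrt(var_pp))
  rho_dpp <- max(-0.95, min(0.95, rho_dpp))
  dp <- rbvn(n, mu[["brachial_dbp"]], sg[["brachial_dbp"]],
             mu_pp, sqrt(var_pp), rho_dpp, 45, 95, 15, 90)
  bdbp <- dp[, 1]
  bsbp <- bdbp + dp[, 2]
  # ventricular volumes: correlated EDV/ESV with a floor on their distance,
  # then SV as a noisy re-measurement of EDV - ESV matching the SV marginal
  ve <- rbvn(n, mu[["edv"]], sg[["edv"]], mu[["esv"]], sg[["esv"]],
             co[["edv_esv"]], 75, 200, 25, 95)
  edv <- ve[, 1]
  esv <- pmin(ve[, 2], edv - 25)
  sv_ratio <- mu[["stroke_volume"]] / (mu[["edv"]] - mu[["esv"]])
  sv <- (edv - esv) * rtnorm(n, sv_ratio, 0.08, 0.75, 1.35)
  sv <- pmin(sv, edv - 18) # keep an end-systolic reserve above V0
  age <- rtnorm(n, mu[["age"]], sg[["age"]], 18, 40)
  hr <- rtnorm(n, mu[["heart_rate"]], sg[["heart_rate"]], 40, 110)
  cf <- rtnorm(n, mu[["cf_pwv"]], sg[["cf_pwv"]], 3.8, 10)
  cr <- cf + rtnorm(n, spec$pwv_offsets[["cr"]], spec$pwv_offsets[["cr_sd"]],
                    0.5, 6)
  ft <- cf + rtnorm(n, spec$pwv_offsets[["ft"]], spec$pwv_offsets[["ft_sd"]],
                    0.5, 7)
  lapply(seq_len(n), function(i) {
    subject_record(
      id = sprintf("S%04d", i), age = age[i], height = hw[i, 1],
      weight = hw[i, 2], heart_rate = hr[i], brachial_sbp = bsbp[i],
      brachial_dbp = bdbp[i], esv = esv[i], edv = edv[i],
      stroke_volume = sv[i], cf_pwv = cf[i], cr_pwv = cr[i], ft_pwv = ft[i]
    )
  })
}

#' Emulate a tonometric reference device
#'
#' Statistical emulator of a cuff-calibrated central-pressure device: the
#' returned estimates are the true central pressures plus the calibration
#' bias (negative for systolic: the device underestimates central systolic
#' pressure; positive for diastolic) plus independent subject-level noise.
#' Only the device's scalar estimates are emulated, not its waveform.
#'
#' @param truth data.frame with columns `cSBP` and `cDBP` (true/model
#'   central pressures, mmHg).
#' @param spec a [cohort_spec()] carrying the `device` bias model.
#' @param seed optional seed for the noise draw (NULL = continue the
#'   current RNG stream).
#' @return data.frame with `cSBP`, `cDBP`, `cPP` device estimates.
#' @export
emulate_reference_device <- function(truth, spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  dv <- spec$device
  n <- nrow(truth)
  csbp <- truth$cSBP + dv[["sbp_bias"]] + rnorm(n, 0, dv[["sbp_sd"]])
  cdbp <- truth$cDBP + dv[["dbp_bias"]] + rnorm(n, 0, dv[["dbp_sd"]])
  data.frame(cSBP = csbp, cDBP = cdbp, cPP = csbp - cdbp)
}

#' Convert a cohort to its tabular form
#'
#' @param subjects list of `subject_record`s.
#' @return data.frame, one row per subject, canonical column names.
#' @export
cohort_to_df <- function(subjects) {
  df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(id = s$id, age = s$age, height = s$height, weight = s$weight,
               heart_rate = s$heart_rate, brachial_sbp = s$brachial_sbp,
               brachial_dbp = s$brachial_dbp, esv = s$esv, edv = s$edv,
               stroke_volume = s$stroke_volume, cf_pwv = s$cf_pwv,
               cr_pwv = s$cr_pwv, ft_pwv = s$ft_pwv,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
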
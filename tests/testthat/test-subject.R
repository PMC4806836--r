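test_that("subject record invariants are enforced", {
  expect_invalid(subject_record("x", 24, 178, 75, 62, brachial_sbp = 80,
                                brachial_dbp = 90, esv = 50, edv = 130,
                                cf_pwv = 6))
  expect_invalid(subject_record("x", 24, 178, 75, 62, 121, 67, esv = 140,
                                edv = 130, cf_pwv = 6))
  expect_invalid(subject_record("x", 24, 178, 75, heart_rate = 20,
                                brachial_sbp = 121, brachial_dbp = 67,
                                esv = 50, edv = 130, cf_pwv = 6))
  expect_invalid(subject_record("x", 24, 178, 75, 62, 121, 67, esv = 50,
                                edv = 130, cf_pwv = -1))
  expect_s3_class(mean_subject(), "subject_record")
})

test_that("Du Bois body surface area", {
  expect_equal(compute_bsa(178, 75), 1.9267344, tolerance = 1e-6)
  expect_equal(compute_bsa(100, 20), 0.7232760, tolerance = 1e-6)
  # power-law scaling: weight x 2^(1/0.425) doubles BSA at fixed height
  expect_equal(compute_bsa(178, 75 * 2^(1 / 0.425)) / compute_bsa(178, 75),
               2, tolerance = 1e-12)
  expect_invalid(compute_bsa(-170, 70))
})

test_that("2/3-rule mean pressure", {
  expect_equal(mean_pressure_23(121, 67.4), 85.26667, tolerance = 1e-6)
  expect_equal(mean_pressure_23(120, 80), 93.33333, tolerance = 1e-6)
  # zero pulse pressure limit
  expect_equal(mean_pressure_23(100, 100 - 1e-9), 100, tolerance = 1e-8)
  expect_invalid(mean_pressure_23(80, 90))
})

test_that("mean flow is stroke volume times heart pacing", {
  expect_equal(mean_flow(82.02, 62.1), 84.8907, tolerance = 1e-6)
  expect_equal(mean_flow(70, 60), 70)
  expect_equal(mean_flow(1e-4, 60), 1e-4) # no underflow
  expect_invalid(mean_flow(0, 60))
})

test_that("resistance coefficient against the shipped reference ratio", {
  s <- mean_subject()
  ref_ratio <- default_network()$reference$ratio
  # frozen regression value for the cohort-mean subject
  expect_equal(resistance_coefficient(s, ref_ratio), 0.9685564,
               tolerance = 1e-6)
  # a subject whose MAP/Q equals the reference ratio gets k = 1
  s1 <- subject_record("unit", 24, 175, 70, heart_rate = 60,
                       brachial_sbp = 120, brachial_dbp = 80,
                       esv = 50, edv = 140, stroke_volume = 90, cf_pwv = 6)
  expect_equal(resistance_coefficient(s1, ref_ratio), 1, tolerance = 1e-12)
  # doubling MAP at the reference flow doubles k
  s2 <- subject_record("double", 24, 175, 70, heart_rate = 60,
                       brachial_sbp = 240, brachial_dbp = 160,
                       esv = 50, edv = 145, stroke_volume = 90, cf_pwv = 6)
  expect_equal(resistance_coefficient(s2, ref_ratio), 2, tolerance = 1e-12)
  expect_invalid(resistance_coefficient(s, -1))
})

test_that("geometry scaling laws", {
  net <- default_network()
  ref_b <- net$reference$bsa
  ref_h <- net$reference$height
  id <- scale_geometry(net, ref_b, ref_h)
  expect_equal(id$segments$length, net$segments$length)
  expect_equal(id$segments$proximal_radius, net$segments$proximal_radius)
  tall <- scale_geometry(net, ref_b, ref_h * 1.1)
  expect_equal(tall$segments$length, net$segments$length * 1.1)
  expect_equal(tall$segments$distal_radius, net$segments$distal_radius)
  big <- scale_geometry(net, ref_b * 1.21, ref_h)
  expect_equal(big$segments$proximal_radius,
               net$segments$proximal_radius * 1.1, tolerance = 1e-12)
  expect_invalid(scale_geometry(net, -1, 170))
})

test_that("regional stiffness assignment and its fallbacks", {
  net <- default_network()
  ref <- net$reference$regional_pwv
  # reference PWVs at the reference working pressure reproduce the network
  same <- assign_regional_stiffness(net, ref[["aortic"]],
                                    ref[["upper-limb"]], ref[["lower-limb"]],
                                    at_pressure = net$reference$map)
  expect_equal(same$segments$wall_stiffness, net$segments$wall_stiffness,
               tolerance = 1e-9)
  # the assigned coefficient is the exact inversion of the calibrated
  # regional target at each segment's mid area
  cf <- 7
  up <- assign_regional_stiffness(net, cf, at_pressure = 90)
  s <- up$segments
  kappa <- net$reference$ftf_calibration
  i <- which(s$id == "thor_a")
  a0 <- pi * ((s$proximal_radius[i] + s$distal_radius[i]) / 2)^2
  expect_equal(s$wall_stiffness[i],
               stiffness_from_pwv(cf / kappa, a0, at_pressure = 90),
               tolerance = 1e-12)
  # missing limb PWVs fall back to reference values scaled by the aortic
  # ratio
  j <- which(s$id == "l_subcl_b")
  a0j <- pi * ((s$proximal_radius[j] + s$distal_radius[j]) / 2)^2
  expect_equal(s$wall_stiffness[j],
               stiffness_from_pwv(ref[["upper-limb"]] * (cf / ref[["aortic"]]) /
                                    kappa, a0j, at_pressure = 90),
               tolerance = 1e-12)
  expect_invalid(assign_regional_stiffness(net, -2))
})

test_that("ventricle fit: frozen fixture for the cohort-mean subject", {
  s <- mean_subject()
  m <- cached_mean_model()
  cp <- m$cardiac
  expect_equal(cp$period, 60 / 62.1, tolerance = 1e-12)
  expect_equal(cp$E_min, 8 / (131.1 - 10), tolerance = 1e-12)
  expect_equal(cp$activation_time, 0.38 * sqrt(60 / 62.1), tolerance = 1e-12)
  # calibrated peak elastance, frozen after the design was fixed
  expect_equal(cp$E_max, 2.3972, tolerance = 1e-3)
  # deterministic: refitting gives the identical value
  cp2 <- fit_ventricle(s, m$network)
  expect_identical(cp2$E_max, cp$E_max)
  # provenance names every rule
  expect_setequal(names(attr(cp2, "provenance")),
                  c("period", "E_min", "activation_time", "E_max",
                    "sv_residual_0d"))
  expect_invalid(fit_ventricle(
    subject_record("tiny", 24, 178, 75, 62, 121, 67, esv = 9, edv = 130,
                   cf_pwv = 6)))
})

test_that("fit_ventricle with HR 60 gives a 1 s period", {
  s <- subject_record("hr60", 24, 178, 75, heart_rate = 60,
                      brachial_sbp = 120, brachial_dbp = 70, esv = 50,
                      edv = 130, stroke_volume = 80, cf_pwv = 6)
  expect_equal(fit_ventricle(s)$period, 1)
})

test_that("tailoring is deterministic and fully provenanced", {
  s <- mean_subject()
  m1 <- tailor_subject(s)
  m2 <- tailor_subject(s)
  expect_identical(m1$network$segments, m2$network$segments)
  expect_identical(m1$network$terminals, m2$network$terminals)
  expect_identical(m1$cardiac$E_max, m2$cardiac$E_max)
  expect_identical(m1$resistance_coefficient, m2$resistance_coefficient)
  # terminal totals are the reference values scaled by k exactly
  ref <- default_network()
  k <- m1$resistance_coefficient
  expect_equal(m1$network$terminals$R1 + m1$network$terminals$R2,
               (ref$terminals$R1 + ref$terminals$R2) * k, tolerance = 1e-12)
  # R1:R2 split preserved
  expect_equal(m1$network$terminals$R1 / m1$network$terminals$R2,
               ref$terminals$R1 / ref$terminals$R2, tolerance = 1e-12)
  expect_true(all(c("bsa", "map", "mean_flow", "geometry", "stiffness",
                    "resistance_coefficient", "cardiac") %in%
                    names(m1$provenance)))
})

test_that("tailored mean subject: simulated pressures are physiological", {
  s <- mean_subject()
  sim <- cached_mean_sim()
  est <- extract_pressures(sim$waveforms$aortic_root, "mean", "model")
  # stroke volume recovered within 20% of the measured input
  expect_lt(abs(sim$sv - 82.02) / 82.02, 0.2)
  # aortic mean pressure within 10% of the 2/3-rule target
  expect_lt(abs(est$MAP - 85.2667) / 85.2667, 0.10)
  # central pressures in the plausible band; amplification direction
  expect_gt(est$cSBP, 90)
  expect_lt(est$cSBP, 130)
  expect_lt(est$cSBP, s$brachial_sbp)
  expect_gte(est$cDBP, s$brachial_dbp - 5)
  # peak systolic LV pressure within 25% of brachial SBP
  cp <- cached_mean_model()$cardiac
  t_lv <- seq_along(sim$volume_trace) * sim$dt
  p_lv <- elastance(t_lv, cp) * (sim$volume_trace - cp$V0)
  expect_lt(abs(max(p_lv) - s$brachial_sbp) / s$brachial_sbp, 0.25)
})
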
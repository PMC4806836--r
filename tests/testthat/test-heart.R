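test_that("elastance waveform honors its normalization contract", {
  cp <- cardiac_params(E_max = 2.5, E_min = 0.07, period = 1)
  t <- seq(0, 1, by = 1e-4)
  E <- elastance(t, cp)
  expect_equal(min(E), 0.07, tolerance = 1e-3)
  expect_equal(max(E), 2.5, tolerance = 1e-3)
  # maximum attained at the activation time
  expect_equal(t[which.max(E)], cp$activation_time, tolerance = 0.01)
  # periodicity
  expect_equal(elastance(0.3, cp), elastance(1.3, cp), tolerance = 1e-12)
  expect_equal(elastance(0, cp), cp$E_min, tolerance = 1e-6)
  expect_invalid(elastance(-0.1, cp))
})

test_that("default double-Hill shape constants are frozen", {
  # peak location and integral of the raw normalized shape, computed by
  # dense numerical evaluation and frozen as a regression fixture
  s <- seq(0.02, 1.5, by = 1e-5)
  v <- centralbp:::hill_shape(s)
  expect_equal(s[which.max(v)], 0.38113, tolerance = 1e-3)
  expect_equal(max(v), 0.5987019, tolerance = 1e-5)
  expect_equal(sum(v) * 1e-5, 0.1823248, tolerance = 2e-3)
})

test_that("cardiac parameter invariants are enforced", {
  expect_invalid(cardiac_params(E_max = 1, E_min = 2, period = 1))
  expect_invalid(cardiac_params(E_max = 2, E_min = 0.1, period = -1))
  expect_invalid(cardiac_params(E_max = 2, E_min = 0.1, period = 1,
                                activation_time = 1.2))
})

test_that("ventricle pressure is the elastance pressure-volume relation", {
  cp <- cardiac_params(E_max = 2, E_min = 0.05, period = 1,
                       activation_time = 0.35)
  expect_equal(suppressWarnings(
    ventricle_pressure(list(volume = cp$V0, time_in_cycle = 0.1), cp)),
    0, tolerance = 1e-9)
  # at peak elastance E = 2: V0 + 50 mL -> 100 mmHg
  expect_equal(ventricle_pressure(list(volume = cp$V0 + 50,
                                       time_in_cycle = 0.35), cp),
               100, tolerance = 0.2)
  expect_warning(ventricle_pressure(list(volume = cp$V0 - 1,
                                         time_in_cycle = 0), cp),
                 "unstressed")
  expect_invalid(ventricle_pressure(list(volume = -5, time_in_cycle = 0), cp))
})

test_that("step_heart valve logic: isovolumic phase keeps volume constant", {
  cp <- cardiac_params(E_max = 2.5, E_min = 0.07, period = 1)
  # p_lv between preload (8) and root pressure (90): both valves shut
  V <- cp$V0 + 30 / elastance(0.2, cp) # p_lv = 30 mmHg
  st <- step_heart(list(volume = V, time_in_cycle = 0.2), 90, 1e-4, cp)
  expect_equal(st$Q, 0)
  expect_false(st$state$aortic_valve_open)
  expect_false(st$state$mitral_valve_open)
  expect_equal(st$state$volume, V)
})

test_that("0D loop conserves volume, keeps valves exclusive and pumps", {
  cp <- cardiac_params(E_max = 2.2, E_min = 0.066, period = 1)
  run <- centralbp:::simulate_heart_0d(cp, R_art = 1.0, C_art = 1.5,
                                       cycles = 8)
  expect_false(any(run$both_valves_open))
  inflow <- sum(pmax(run$q_mitral, 0)) * run$dt
  outflow <- sum(run$q_aortic) * run$dt
  expect_lt(abs(inflow - outflow) / outflow, 0.02)
  sv <- max(run$volume) - min(run$volume)
  expect_gt(sv, 20)
})

test_that("stroke volume grows monotonically with peak elastance", {
  svs <- vapply(c(0.7, 1, 1.3), function(f) {
    cp <- cardiac_params(E_max = 2.2 * f, E_min = 0.066, period = 1)
    run <- centralbp:::simulate_heart_0d(cp, R_art = 1.0, C_art = 1.5,
                                         cycles = 8)
    max(run$volume) - min(run$volume)
  }, 0)
  expect_true(all(diff(svs) > 0))
})

test_that("zero elastance modulation pumps nothing", {
  cp <- cardiac_params(E_max = 2.2, E_min = 0.066, period = 1)
  cp$E_max <- cp$E_min * 1.0000001 # constructor forbids equality; bypass
  # arterial pressure held above the preload so no passive trickle occurs
  run <- centralbp:::simulate_heart_0d(cp, R_art = 1.0, C_art = 1.5,
                                       cycles = 6, p_art0 = 80, p_ven = 60)
  outflow <- sum(run$q_aortic) * run$dt
  expect_lt(outflow, 1) # mL per cycle, essentially no pump
})
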
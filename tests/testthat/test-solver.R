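test_that("steady pressure drop matches the Poiseuille oracle within 5%", {
  r <- 0.2; L <- 5; Q <- 2; mu <- 0.004
  beta <- stiffness_from_pwv(20, pi * r^2) # stiff vessel: area ~ constant
  net <- single_vessel(L, r, beta = beta)
  fl <- list(flow = rep(Q, 3001), dt = 1e-3, duration = 3)
  sim <- simulate_network(net, config = sim_config(init_pressure = 10),
                          inflow = fl)
  p <- vapply(sim$waveforms, function(w) tail(w$pressure, 1), 0)
  dp_sim <- p[["aortic_root"]] - p[["tibial"]]
  dp_poiseuille <- 8 * mu * (L / 100) * (Q * 1e-6) /
    (pi * (r / 100)^4) / 133.322387415
  expect_equal(dp_sim, dp_poiseuille, tolerance = 0.05)
  # interior gradient is uniform: per-length drops between the interior
  # sites (at fractions 0.25/0.4/0.5/0.75) agree within 2%
  grads <- -diff(p[2:5]) / diff(c(0.25, 0.4, 0.5, 0.75))
  expect_lt(max(grads) / min(grads) - 1, 0.02)
})

test_that("small pulses travel at the closed-form wave speed within 2%", {
  r <- 1; A0 <- pi * r^2
  beta <- stiffness_from_pwv(5, A0)
  zc <- 1.06 * 500 / A0 / 1333.22387415
  net <- single_vessel(100, r, beta = beta, R1 = zc, R2 = 100, C = 0.01)
  sim <- simulate_network(net,
                          config = sim_config(init_pressure = 0.01,
                                              output_sampling = 5000),
                          inflow = gaussian_inflow())
  peak_t <- function(site) {
    w <- sim$waveforms[[site]]
    keep <- w$time < 0.3
    w$time[keep][which.max(w$pressure[keep])]
  }
  measured <- 0.5 / (peak_t("femoral") - peak_t("carotid")) # x = 25 -> 75 cm
  expect_equal(measured, 5, tolerance = 0.02)
})

test_that("pressurization speeds the pulse as c^2 = c0^2 + p/(2 rho)", {
  r <- 1; A0 <- pi * r^2
  beta <- stiffness_from_pwv(5, A0)
  zc <- 1.06 * 500 / A0 / 1333.22387415
  net <- single_vessel(100, r, beta = beta, R1 = zc, R2 = 100, C = 0.01)
  p0 <- 67
  sim <- simulate_network(net,
                          config = sim_config(init_pressure = p0,
                                              output_sampling = 5000),
                          inflow = gaussian_inflow())
  peak_t <- function(site) {
    w <- sim$waveforms[[site]]
    keep <- w$time < 0.3
    w$time[keep][which.max(w$pressure[keep])]
  }
  measured <- 0.5 / (peak_t("femoral") - peak_t("carotid"))
  expected <- sqrt(5^2 + p0 * 133.322387415 / (2 * 1060)) # exact closed form
  expect_equal(measured, expected, tolerance = 0.02)
})

test_that("a closed end doubles the incident pressure wave within 5%", {
  r <- 1; A0 <- pi * r^2
  beta <- stiffness_from_pwv(5, A0)
  # closed end: R1 huge, negligible compliance drain
  net <- single_vessel(100, r, beta = beta, R1 = 1e5, R2 = 1e5, C = 1e-4)
  sim <- simulate_network(net,
                          config = sim_config(init_pressure = 0.01,
                                              output_sampling = 5000),
                          inflow = gaussian_inflow())
  w_mid <- sim$waveforms$radial # x = 50, incident before any reflection
  keep <- w_mid$time < 0.17
  incident <- max(w_mid$pressure[keep]) - 0.01
  w_end <- sim$waveforms$tibial
  reflected <- max(w_end$pressure) - 0.01
  expect_equal(reflected / incident, 2, tolerance = 0.05)
})

test_that("symmetric bifurcations split flow symmetrically and conserve mass", {
  net <- symmetric_bifurcation()
  sim <- simulate_network(net,
                          config = sim_config(init_pressure = 0.01,
                                              output_sampling = 5000),
                          inflow = gaussian_inflow())
  q1 <- sim$waveforms$femoral$flow  # child 1 at 0.9
  q2 <- sim$waveforms$tibial$flow   # child 2 at 0.9
  expect_equal(q1, q2, tolerance = 1e-10)
  expect_lt(sim$junction_residual, 1e-6)
})

test_that("an area-matched junction reflects less than 1% of the pulse", {
  # two identical daughters with half the parent area each: the combined
  # characteristic admittance matches the parent, so the linear reflection
  # coefficient is zero
  net <- symmetric_bifurcation()
  sim <- simulate_network(net,
                          config = sim_config(init_pressure = 0.01,
                                              output_sampling = 5000),
                          inflow = gaussian_inflow())
  w <- sim$waveforms$carotid # parent mid-point
  t_inc <- w$time < 0.12     # incident passage at x = 20 cm (c = 5 m/s)
  t_ref <- w$time > 0.14 & w$time < 0.26 # window for a junction echo
  incident <- max(w$pressure[t_inc]) - 0.01
  reflected <- max(abs(w$pressure[t_ref] - 0.01))
  expect_lt(reflected / incident, 0.01)
})

test_that("check_convergence measures the cycle-to-cycle residual", {
  a <- sin(seq(0, 2 * pi, length.out = 100))
  expect_invalid(check_convergence(rbind(a), 0.5))
  r <- check_convergence(rbind(a, a), 0.5)
  expect_true(r$converged)
  expect_equal(r$residual, 0)
  r <- check_convergence(list(a, a + 1), 0.5)
  expect_false(r$converged)
  expect_equal(r$residual, 1)
})

test_that("full-network run converges with global mass balance within 2%", {
  sim <- cached_mean_sim()
  expect_true(sim$converged)
  expect_lte(sim$cycle_residual, sim$config$convergence_tol)
  expect_lt(sim$junction_residual, 1e-6)
  expect_lt(abs(sim$inlet_volume - sum(sim$terminal_volumes)) /
              sim$inlet_volume, 0.02)
  # discrete LV mass balance: cycle-integrated outflow = EDV - ESV
  expect_equal(sim$inlet_volume, sim$edv - sim$esv, tolerance = 0.02)
  # waveform container invariants
  for (w in sim$waveforms) {
    expect_gte(nrow(w), 50)
    expect_true(all(diff(w$time) > 0))
    expect_equal(max(w$time), sim$period, tolerance = 1e-9)
  }
})

test_that("halving the grid changes central pressures by less than 1 mmHg", {
  m <- cached_mean_model()
  fine <- cached_mean_sim() # dx = 0.25 cm
  coarse <- simulate(m, config = sim_config(init_pressure = 67.4,
                                            spatial_resolution = 0.5))
  pf <- fine$waveforms$aortic_root$pressure
  pc <- coarse$waveforms$aortic_root$pressure
  expect_lt(abs(max(pf) - max(pc)), 1)
  expect_lt(abs(min(pf) - min(pc)), 1)
})

test_that("solver aborts with a diagnostic on a CFL violation", {
  r <- 0.5; A0 <- pi * r^2
  net <- single_vessel(20, r, beta = stiffness_from_pwv(5, A0))
  # a huge inflow step forces velocities past the initial CFL margin
  fl <- list(flow = c(0, rep(4000, 2000)), dt = 1e-3, duration = 1)
  expect_error(
    simulate_network(net, config = sim_config(init_pressure = 1),
                     inflow = fl),
    "CFL|blow-up")
})
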
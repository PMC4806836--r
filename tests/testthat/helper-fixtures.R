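# Shared fixtures. Expensive full-network simulations are memoized so the
# suite runs each of them once.

.fixture_cache <- new.env(parent = emptyenv())

# The cohort-mean subject of the emulated study population
mean_subject <- function() {
  subject_record("mean", age = 24.3, height = 178, weight = 75,
                 heart_rate = 62.1, brachial_sbp = 121, brachial_dbp = 67.4,
                 esv = 53.57, edv = 131.1, stroke_volume = 82.02,
                 cf_pwv = 5.86, cr_pwv = 8.5, ft_pwv = 9.0)
}

cached_mean_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- tailor_subject(mean_subject())
  }
  .fixture_cache$model
}

cached_mean_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    m <- cached_mean_model()
    .fixture_cache$sim <- simulate(
      m, config = sim_config(init_pressure = 67.4, output_sampling = 2000))
  }
  .fixture_cache$sim
}

# Single straight vessel with an RCR outlet and the six named sites spread
# along it; used by the physics-oracle tests.
single_vessel <- function(L, r_prox, r_dist = r_prox, beta, gamma = 0,
                          R1 = 0.5, R2 = 10, C = 0.05, p_ven = 0) {
  seg <- data.frame(id = "v", name = "vessel", length = L,
                    proximal_radius = r_prox, distal_radius = r_dist,
                    wall_stiffness = beta, viscoelastic_coeff = gamma,
                    region = "aortic", parent = NA_character_)
  term <- data.frame(segment = "v", R1 = R1, R2 = R2, C = C,
                     venous_pressure = p_ven)
  sites <- data.frame(
    site = c("aortic_root", "carotid", "brachial", "radial", "femoral",
             "tibial"),
    segment = "v", position = c(0, 0.25, 0.4, 0.5, 0.75, 1.0))
  arterial_network(seg, term, sites)
}

# Symmetric bifurcation: one parent feeding two identical daughters.
symmetric_bifurcation <- function(r_parent = 1, r_child = r_parent / sqrt(2),
                                  c_ms = 5, L = 40) {
  a0p <- pi * r_parent^2
  a0c <- pi * r_child^2
  seg <- data.frame(
    id = c("p", "c1", "c2"), name = c("parent", "child 1", "child 2"),
    length = c(L, L, L),
    proximal_radius = c(r_parent, r_child, r_child),
    distal_radius = c(r_parent, r_child, r_child),
    wall_stiffness = stiffness_from_pwv(c_ms, c(a0p, a0c, a0c)),
    viscoelastic_coeff = 0, region = "aortic",
    parent = c(NA_character_, "p", "p"))
  zc <- 1.06 * (c_ms * 100) / a0c / 1333.22387415
  term <- data.frame(segment = c("c1", "c2"), R1 = zc, R2 = 100, C = 0.01,
                     venous_pressure = 0)
  sites <- data.frame(
    site = c("aortic_root", "carotid", "brachial", "radial", "femoral",
             "tibial"),
    segment = c("p", "p", "p", "c1", "c1", "c2"),
    position = c(0, 0.5, 0.9, 0.25, 0.9, 0.9))
  arterial_network(seg, term, sites)
}

# Short Gaussian inflow pulse (mL/s) sampled at 0.1 ms
gaussian_inflow <- function(amplitude = 5, center = 0.05, width = 0.01,
                            duration = 0.45) {
  tt <- seq(0, duration, by = 1e-4)
  list(flow = amplitude * exp(-((tt - center) / width)^2), dt = 1e-4,
       duration = duration)
}

expect_invalid <- function(expr) {
  expect_error(expr, class = "centralbp_invalid_input")
}
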
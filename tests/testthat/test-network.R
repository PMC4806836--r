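test_that("tube law: zero distension, elastic branch and viscous sign", {
  expect_equal(tube_law(3, 3, beta = 100), 0)
  expect_equal(tube_law(3, 3, beta = 100, p_ext = 12), 12)
  # elastic branch: direct evaluation of the Laplace-law form
  A0 <- 3; A <- 1.1 * A0; beta <- 150
  expected <- 150 * 10 * (sqrt(A) - sqrt(A0)) / A0 / 1333.22387415
  expect_equal(tube_law(A, A0, beta), expected, tolerance = 1e-12)
  # pure viscous stress at A = A0 is positive for expanding area
  expect_gt(tube_law(3, 3, beta = 100, gamma = 5, dA_dt = 2), 0)
  expect_lt(tube_law(3, 3, beta = 100, gamma = 5, dA_dt = -2), 0)
  expect_invalid(tube_law(-1, 3, 100))
  expect_invalid(tube_law(3, 3, beta = -5))
})

test_that("tube law is strictly increasing in area and consistent with wave speed", {
  A0 <- 2.5; beta <- 120; rho <- 1060
  A <- seq(0.7, 1.3, by = 0.01) * A0
  p <- tube_law(A, A0, beta)
  expect_true(all(diff(p) > 0))
  # c^2 = (A/rho) dp/dA: compare finite differences of the tube law with
  # the closed form in wave_speed, within 0.1%
  h <- 1e-6
  dpdA <- (tube_law(A + h, A0, beta) - tube_law(A - h, A0, beta)) / (2 * h)
  c_fd <- sqrt((A / (rho / 1000)) * dpdA * 1333.22387415) / 100
  expect_equal(c_fd, wave_speed(A, A0, beta, rho), tolerance = 1e-3)
})

test_that("wave speed scaling laws and limits", {
  A0 <- 3; beta <- 100
  expect_equal(wave_speed(A0, A0, 2 * beta) / wave_speed(A0, A0, beta),
               sqrt(2), tolerance = 1e-12)
  # c -> 0 as A -> 0 for this elastic law (c ~ A^(1/4))
  expect_lt(wave_speed(1e-8, A0, beta), 1e-2)
  expect_lt(wave_speed(1e-12, A0, beta), 1e-3)
  expect_invalid(wave_speed(-1, A0, beta))
})

test_that("stiffness_from_pwv is the exact inverse of wave_speed", {
  A0 <- 6.68
  for (v in c(4, 5.86, 10)) {
    b <- stiffness_from_pwv(v, A0)
    expect_equal(wave_speed(A0, A0, b), v, tolerance = 1e-12)
    expect_gt(b, 0)
  }
  # doubling rho doubles beta (Moens-Korteweg-type scaling)
  expect_equal(stiffness_from_pwv(5, A0, rho = 2120) /
                 stiffness_from_pwv(5, A0, rho = 1060), 2, tolerance = 1e-12)
  expect_invalid(stiffness_from_pwv(-2, A0))
})

test_that("stiffness_from_pwv at a working pressure targets the distended speed", {
  A0 <- 3; rho <- 1060; v <- 5.86; p <- 85.3
  b <- stiffness_from_pwv(v, A0, rho, at_pressure = p)
  # distended area at that pressure, from the tube law inverse
  sqA <- sqrt(A0) + p * 1333.22387415 * A0 / (b * 10)
  expect_equal(wave_speed(sqA^2, A0, b, rho), v, tolerance = 1e-10)
  # a target below the pressure floor is rejected
  expect_invalid(stiffness_from_pwv(0.5, A0, rho, at_pressure = 85))
})

test_that("network validation names the offending element", {
  net <- default_network()
  bad <- net
  bad$segments$parent[bad$segments$id == "asc_ao"] <- "asc_ao"
  expect_invalid(arterial_network(bad$segments, bad$terminals,
                                  bad$named_sites, bad$fluid, bad$reference))
  bad <- net
  bad$segments$parent[bad$segments$id == "l_radial"] <- "nowhere"
  expect_error(arterial_network(bad$segments, bad$terminals, bad$named_sites),
               "nowhere")
  bad <- net
  bad$terminals <- bad$terminals[bad$terminals$segment != "l_radial", ]
  expect_error(validate_network(bad), "l_radial")
  bad <- net
  bad$named_sites$segment[bad$named_sites$site == "carotid"] <- "ghost"
  expect_error(validate_network(bad), "carotid")
  bad <- net
  bad$segments$length[3] <- -1
  expect_invalid(validate_network(bad))
})

test_that("network file round trip is lossless", {
  net <- default_network()
  tmp <- tempfile(fileext = ".json")
  save_network(net, tmp)
  net2 <- load_network(tmp)
  expect_equal(net2$segments, net$segments, tolerance = 1e-12)
  expect_equal(net2$terminals, net$terminals, tolerance = 1e-12)
  expect_equal(net2$named_sites, net$named_sites)
  expect_equal(net2$fluid, net$fluid)
  expect_equal(net2$reference$ratio, net$reference$ratio)
  # a second round trip is byte-stable
  tmp2 <- tempfile(fileext = ".json")
  save_network(net2, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
  expect_invalid(load_network(tempfile()))
})

test_that("shipped reference network is physiologically plausible", {
  net <- default_network()
  s <- net$segments
  expect_gte(nrow(s), 50)
  expect_setequal(net$named_sites$site,
                  c("aortic_root", "carotid", "brachial", "radial",
                    "femoral", "tibial"))
  # at least 5 segments along each limb path (root to radial / tibial)
  lineage_len <- function(id) {
    n <- 0
    while (!is.na(id)) {
      n <- n + 1
      id <- s$parent[s$id == id]
    }
    n
  }
  expect_gte(lineage_len("l_radial"), 5)
  expect_gte(lineage_len("l_post_tibial"), 5)
  # every segment's wave speed at reference area within [3, 12] m/s
  a0 <- pi * ((s$proximal_radius + s$distal_radius) / 2)^2
  c0 <- wave_speed(a0, a0, s$wall_stiffness, net$fluid$blood_density)
  expect_true(all(c0 >= 3 & c0 <= 12))
  # regions partition the tree
  expect_true(all(s$region %in% c("aortic", "upper-limb", "lower-limb",
                                  "cerebral", "visceral")))
})

test_that("site path distances follow the tree", {
  net <- default_network()
  s <- net$segments
  # root to carotid site: ascending aorta + arch A + fraction of l_carotid
  d <- site_path_distance(net, "aortic_root", "carotid")
  expect_equal(d, 4 + 2 + 0.02 * 20.8, tolerance = 1e-9)
  expect_equal(site_path_distance(net, "carotid", "aortic_root"), d)
  # carotid-femoral crosses the arch: both branches plus the aortic trunk
  d_cf <- site_path_distance(net, "carotid", "femoral")
  trunk <- sum(s$length[s$id %in% c("arch_b", "thor_a", "thor_b", "abd_a",
                                    "abd_b", "abd_c", "abd_d", "abd_e",
                                    "abd_f", "l_com_iliac", "l_ext_iliac")])
  expect_equal(d_cf, 0.02 * 20.8 + trunk + 0.02 * 44.3, tolerance = 1e-9)
  expect_invalid(site_path_distance(net, "carotid", "nowhere"))
})
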
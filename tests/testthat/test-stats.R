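# Printed toy comparison set; expected values frozen from independent
# spreadsheet-style arithmetic (mean/SD/quantiles/Pearson/OLS by their
# textbook formulas).
toy_m <- c(110, 105, 98, 120)
toy_r <- c(100, 102, 101, 108)

test_that("paired comparison: degenerate branches", {
  x <- c(100, 105, 98, 112)
  same <- paired_compare(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
  off <- paired_compare(x + 5, x)
  expect_equal(off$mean_diff, 5)
  expect_equal(off$sd_diff, 0)
  expect_true(off$degenerate)
  expect_invalid(paired_compare(x, x[-1]))
  expect_invalid(paired_compare(1:2, 2:3))
})

test_that("paired comparison reproduces the toy-set oracle", {
  pc <- paired_compare(toy_m, toy_r)
  expect_equal(pc$mean_diff, 5.5, tolerance = 1e-12)
  expect_equal(pc$sd_diff, 6.8556546, tolerance = 1e-6)
  expect_equal(pc$median_diff, 6.5, tolerance = 1e-12)
  expect_equal(pc$q1, 1.5, tolerance = 1e-12)
  expect_equal(pc$q3, 10.5, tolerance = 1e-12)
  expect_equal(pc$percent_diff, 5.2704976, tolerance = 1e-6)
  expect_equal(pc$percent_sd, 6.5781809, tolerance = 1e-6)
  expect_equal(pc$p_t, 0.2069410, tolerance = 1e-6)
})

test_that("paired comparison is antisymmetric in its arguments", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(30, 100, 10)
    b <- a + rnorm(30, 2, 4)
    f <- paired_compare(a, b)
    g <- paired_compare(b, a)
    expect_equal(f$mean_diff, -g$mean_diff, tolerance = 1e-12)
    expect_equal(f$median_diff, -g$median_diff, tolerance = 1e-12)
    expect_equal(f$p, g$p, tolerance = 1e-12)
  }
})

test_that("regression agreement: identities and the toy oracle", {
  x <- c(90, 100, 105, 111, 120)
  id <- regression_agreement(x, x)
  expect_equal(id$r, 1, tolerance = 1e-12)
  expect_equal(id$slope, 1, tolerance = 1e-12)
  expect_equal(id$intercept, 0, tolerance = 1e-9)
  neg <- regression_agreement(-x, x)
  expect_equal(neg$r, -1, tolerance = 1e-12)
  toy <- regression_agreement(toy_m, toy_r)
  expect_equal(toy$r, 0.7744750, tolerance = 1e-6)
  expect_equal(toy$slope, 1.9935484, tolerance = 1e-6)
  expect_equal(toy$intercept, -96.5870968, tolerance = 1e-6)
  expect_invalid(regression_agreement(rep(5, 5), x))
})

test_that("Bland-Altman: identities and the toy oracle", {
  x <- c(90, 100, 105, 111, 120)
  z <- bland_altman(x, x)
  expect_equal(z$mean_diff, 0)
  expect_equal(z$loa_low, 0)
  expect_equal(z$loa_high, 0)
  off <- bland_altman(x + 5, x)
  expect_equal(off$mean_diff, 5)
  expect_equal(off$loa_low, 5)
  expect_equal(off$trend_slope, 0)
  toy <- bland_altman(toy_m, toy_r)
  expect_equal(toy$mean_diff, 5.5, tolerance = 1e-12)
  expect_equal(toy$loa_low, -7.9370830, tolerance = 1e-6)
  expect_equal(toy$loa_high, 18.9370830, tolerance = 1e-6)
  expect_equal(toy$trend_slope, 0.9688889, tolerance = 1e-6)
})

test_that("accuracy classification with a closed threshold boundary", {
  r <- accuracy_classification(c(3, -12, 9))
  expect_equal(r$proportion, 2 / 3, tolerance = 1e-12)
  expect_equal(accuracy_classification(rep(0, 4))$proportion, 1)
  # a difference of exactly the threshold counts as satisfactory
  expect_true(accuracy_classification(10.0)$satisfactory)
  expect_false(accuracy_classification(10.0000001)$satisfactory)
})

test_that("regressor selection finds planted signal and rejects rank deficiency", {
  set.seed(21)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  err <- 2 * x1 + rnorm(n)
  sel <- select_error_regressors(err, data.frame(x1, x2, x3))
  expect_true(sel$retained[sel$covariate == "x1"])
  expect_gt(abs(sel$t[sel$covariate == "x1"]), 5)
  expect_error(
    select_error_regressors(err, data.frame(x1, const = rep(1, n))),
    "collinear")
  expect_invalid(select_error_regressors(rnorm(4),
                                         data.frame(x1 = 1:4, x2 = 4:1,
                                                    x3 = c(2, 1, 4, 3))))
})

test_that("commonality analysis: closed-form special cases", {
  set.seed(31)
  n <- 300
  # single covariate: U equals the full R^2
  x <- rnorm(n)
  y <- x + rnorm(n)
  cm1 <- communality_analysis(y, data.frame(x))
  expect_equal(unname(cm1$unique["x"]), cm1$total_r2, tolerance = 1e-12)
  expect_equal(cm1$total_r2, cor(y, x)^2, tolerance = 1e-12)
  # exactly orthogonal pair: uniques are the squared simple correlations
  # and the common component vanishes
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  y2 <- 2 * x1 + x2 + rnorm(n)
  cm2 <- communality_analysis(y2, data.frame(x1, x2))
  expect_equal(unname(cm2$unique["x1"]), cor(y2, x1)^2, tolerance = 1e-10)
  expect_equal(unname(cm2$unique["x2"]), cor(y2, x2)^2, tolerance = 1e-10)
  common <- cm2$components$coefficient[cm2$components$size == 2]
  expect_equal(common, 0, tolerance = 1e-10)
})

test_that("commonality of a correlated pair equals the two-variable closed form", {
  set.seed(32)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + 0.8 * rnorm(n)
  y <- x1 + 0.5 * x2 + rnorm(n)
  cm <- communality_analysis(y, data.frame(x1, x2))
  # independent enumeration oracle: R^2 of each subset by direct fits
  r2_1 <- summary(lm(y ~ x1))$r.squared
  r2_2 <- summary(lm(y ~ x2))$r.squared
  r2_12 <- summary(lm(y ~ x1 + x2))$r.squared
  expect_equal(unname(cm$unique["x1"]), r2_12 - r2_2, tolerance = 1e-10)
  expect_equal(unname(cm$unique["x2"]), r2_12 - r2_1, tolerance = 1e-10)
  expect_equal(cm$components$coefficient[cm$components$size == 2],
               r2_1 + r2_2 - r2_12, tolerance = 1e-10)
})

test_that("commonality components always sum to the total R^2", {
  set.seed(33)
  for (k in c(3, 5)) {
    n <- 120
    X <- matrix(rnorm(n * k), n)
    X[, 2] <- X[, 1] * 0.5 + X[, 2] # induce correlation
    y <- X %*% runif(k, -1, 1) + rnorm(n)
    cm <- communality_analysis(as.numeric(y), as.data.frame(X))
    expect_equal(sum(cm$components$coefficient), cm$total_r2,
                 tolerance = 1e-10)
    # U_i = R^2(full) - R^2(full minus i), from direct fits
    for (i in seq_len(k)) {
      r2_wo <- summary(lm(y ~ X[, -i]))$r.squared
      expect_equal(unname(cm$unique[i]), cm$total_r2 - r2_wo,
                   tolerance = 1e-10)
    }
  }
  expect_invalid(communality_analysis(rnorm(30),
                                      as.data.frame(matrix(rnorm(30 * 7),
                                                           30))))
})

test_that("device-calibration bias correction arithmetic", {
  expect_equal(apply_calibration_bias(7.8, -8.2), -0.4, tolerance = 1e-12)
  expect_equal(apply_calibration_bias(-3.2, 7.6), 4.4, tolerance = 1e-12)
})

test_that("agreement report runs the full pipeline and keeps its contracts", {
  set.seed(41)
  n <- 60
  truth_s <- rnorm(n, 105, 9)
  truth_d <- rnorm(n, 68, 6)
  df <- data.frame(
    id = sprintf("s%02d", 1:n),
    model_cSBP = truth_s + rnorm(n, 2, 3),
    model_cDBP = truth_d + rnorm(n, -1, 2),
    ref_cSBP = truth_s, ref_cDBP = truth_d,
    brachial_sbp = truth_s + rnorm(n, 14, 4),
    brachial_dbp = truth_d + rnorm(n, 1, 3),
    cf_pwv = rnorm(n, 5.9, 0.8), heart_rate = rnorm(n, 62, 10),
    height = rnorm(n, 178, 6), weight = rnorm(n, 75, 10))
  rep <- agreement_report(df)
  # both systolic and diastolic sections always present
  expect_setequal(names(rep$quantities), c("cSBP", "cDBP", "cPP"))
  expect_setequal(names(rep$errors), c("systolic", "diastolic"))
  ba <- rep$quantities$cSBP$bland_altman
  expect_equal(ba$loa_high - ba$mean_diff, 1.96 * ba$sd_diff,
               tolerance = 1e-12)
  expect_true(all(vapply(rep$quantities,
                         function(e) e$accuracy$proportion, 0) >= 0))
  # model column equal to reference column: all differences zero
  df2 <- df
  df2$model_cSBP <- df2$ref_cSBP
  df2$model_cDBP <- df2$ref_cDBP
  rep2 <- agreement_report(df2)
  expect_equal(rep2$quantities$cSBP$paired$mean_diff, 0)
  expect_equal(rep2$quantities$cSBP$accuracy$proportion, 1)
  expect_invalid(agreement_report(df[1:2, ]))
})
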
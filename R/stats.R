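#' Paired comparison of two methods
#'
#' Per-quantity agreement statistics between paired measurements: mean
#' difference with SD, median and interquartile range of the differences,
#' mean per-pair percent difference, and a paired significance test. The
#' test branch follows a normality gate: differences passing a
#' Kolmogorov--Smirnov test (at 0.05) get a paired t test, otherwise a
#' Wilcoxon signed-rank test; both p values are retained.
#'
#' @param model,reference equal-length numeric vectors (n >= 3), or two
#'   independent groups when `paired = FALSE`.
#' @param paired paired comparison (default) or two-group comparison.
#' @return list of class `paired_comparison`: `mean_diff`, `sd_diff`,
#'   `median_diff`, `q1`, `q3`, `iqr`, `percent_diff`, `percent_sd`, `p`,
#'   `test` ("t" or "wilcoxon"), `normal`, `p_t`, `p_wilcoxon`,
#'   `degenerate` flag, `n`.
#' @export
paired_compare <- function(model, reference, paired = TRUE) {
  if (length(model) != length(reference) && paired) {
    stop_invalid("paired_compare: length mismatch between model and reference")
  }
  if (length(model) < 3 || length(reference) < 3) {
    stop_invalid("paired_compare: need n >= 3")
  }
  if (paired) {
    d <- model - reference
    pct <- 100 * (model - reference) / reference
  } else {
    d <- NULL
    pct <- NULL
  }
  stat_vec <- if (paired) d else model
  degenerate <- FALSE
  if (paired) {
    m <- mean(d)
    s <- sd(d)
    if (s < 1e-12) {
      degenerate <- TRUE
      p_t <- p_w <- if (abs(m) < 1e-12) 1 else NA_real_
      normal <- TRUE
    } else {
      z <- (d - m) / s
      normal <- stats::ks.test(z, "pnorm")$p.value >= 0.05
      p_t <- stats::t.test(model, reference, paired = TRUE)$p.value
      p_w <- suppressWarnings(
        stats::wilcox.test(model, reference, paired = TRUE)$p.value)
    }
    out <- list(
      n = length(d), mean_diff = m, sd_diff = s,
      median_diff = median(d),
      q1 = unname(quantile(d, 0.25)), q3 = unname(quantile(d, 0.75)),
      iqr = unname(diff(quantile(d, c(0.25, 0.75)))),
      percent_diff = mean(pct), percent_sd = sd(pct),
      normal = normal, p_t = p_t, p_wilcoxon = p_w,
      test = if (normal) "t" else "wilcoxon",
      p = if (normal) p_t else p_w,
      degenerate = degenerate, paired = TRUE
    )
  } else {
    if (sd(model) < 1e-12 && sd(reference) < 1e-12) {
      degenerate <- TRUE
      normal <- TRUE
      p_t <- p_w <- if (abs(mean(model) - mean(reference)) < 1e-12) 1
                    else NA_real_
    } else {
      z1 <- scale(model)
      z2 <- scale(reference)
      normal <- stats::ks.test(as.numeric(z1), "pnorm")$p.value >= 0.05 &&
        stats::ks.test(as.numeric(z2), "pnorm")$p.value >= 0.05
      p_t <- stats::t.test(model, reference)$p.value
      p_w <- suppressWarnings(stats::wilcox.test(model, reference)$p.value)
    }
    out <- list(
      n = length(model), mean_diff = mean(model) - mean(reference),
      sd_diff = NA_real_, median_diff = median(model) - median(reference),
      q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
      percent_diff = NA_real_, percent_sd = NA_real_,
      normal = normal, p_t = p_t, p_wilcoxon = p_w,
      test = if (normal) "t" else "wilcoxon",
      p = if (normal) p_t else p_w,
      degenerate = degenerate, paired = FALSE
    )
  }
  class(out) <- "paired_comparison"
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s comparison (n = %d): mean diff %.2f +/- %.2f, median %.2f (%.2f; %.2f)\n",
              if (x$paired) "Paired" else "Two-group", x$n, x$mean_diff,
              x$sd_diff, x$median_diff, x$q1, x$q3))
  if (x$paired) {
    cat(sprintf("  percent difference %.2f +/- %.2f %%\n",
                x$percent_diff, x$percent_sd))
  }
  cat(sprintf("  %s test p = %.4g%s\n", x$test, x$p,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Regression agreement between two methods
#'
#' Ordinary least squares of the model estimate on the reference estimate,
#' with the Pearson correlation and its p value.
#'
#' @param model,reference equal-length numeric vectors (n >= 3).
#' @return list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
regression_agreement <- function(model, reference) {
  if (length(model) != length(reference)) {
    stop_invalid("regression_agreement: length mismatch")
  }
  if (length(model) < 3) stop_invalid("regression_agreement: need n >= 3")
  if (sd(model) < 1e-12 || sd(reference) < 1e-12) {
    stop_invalid("regression_agreement: zero variance input")
  }
  fit <- lm(model ~ reference)
  ct <- stats::cor.test(model, reference)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(model))
}

#' Bland-Altman agreement analysis
#'
#' Differences against pair means, limits of agreement at mean +/- 1.96 SD,
#' and the error trend (OLS slope of the difference on the pair mean with
#' its p value), which reveals whether disagreement grows with pressure.
#'
#' @param model,reference equal-length numeric vectors (n >= 3).
#' @return list of class `bland_altman`: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, `trend_slope`, `trend_p`, plus the per-pair `means` and
#'   `differences`.
#' @export
bland_altman <- function(model, reference) {
  if (length(model) != length(reference)) {
    stop_invalid("bland_altman: length mismatch")
  }
  n <- length(model)
  if (n < 3) stop_invalid("bland_altman: need n >= 3")
  d <- model - reference
  m <- (model + reference) / 2
  md <- mean(d)
  s <- sd(d)
  if (s < 1e-12 || sd(m) < 1e-12) {
    trend_slope <- 0
    trend_p <- NA_real_
  } else {
    fit <- summary(lm(d ~ m))
    trend_slope <- fit$coefficients[2, 1]
    trend_p <- fit$coefficients[2, 4]
  }
  structure(list(mean_diff = md, sd_diff = s,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 trend_slope = trend_slope, trend_p = trend_p,
                 means = m, differences = d, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  cat(sprintf("  trend of difference on mean: slope %.3f (p = %.3g)\n",
              x$trend_slope, x$trend_p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods (mmHg)",
                              ylab = "difference (mmHg)", ...) {
  graphics::plot(x$means, x$differences, pch = 19, col = "grey30",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "firebrick")
  invisible(x)
}

#' Accuracy classification at a fixed threshold
#'
#' A per-subject estimate is "satisfactory" when its absolute difference
#' from the reference is within the threshold (boundary inclusive:
#' a difference of exactly the threshold counts as satisfactory).
#'
#' @param differences numeric vector of model - reference differences
#'   (mmHg).
#' @param threshold accuracy threshold (mmHg), default 10.
#' @return list with `proportion` (in \[0, 1\]), `satisfactory` logical
#'   flags and `n`.
#' @export
accuracy_classification <- function(differences, threshold = 10) {
  if (length(differences) < 1) {
    stop_invalid("accuracy_classification: empty input")
  }
  ok <- abs(differences) <= threshold
  list(proportion = mean(ok), satisfactory = ok, n = length(differences))
}

#' Select significant error regressors
#'
#' Multivariate OLS of the estimation errors on the subject covariates;
#' covariates are retained when their two-sided t-test p value falls below
#' `alpha` (default 0.025). Rank-deficient designs are rejected with the
#' offending columns named.
#'
#' @param errors numeric response vector.
#' @param covariates data.frame of candidate regressors.
#' @param alpha retention level for the two-sided t test.
#' @return data.frame with one row per covariate: `estimate`, `t`, `p`,
#'   `retained`.
#' @export
select_error_regressors <- function(errors, covariates, alpha = 0.025) {
  covariates <- as.data.frame(covariates)
  n <- length(errors)
  p <- ncol(covariates)
  if (n <= p + 1) {
    stop_invalid("select_error_regressors: need n > number of covariates + 1")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_invalid("select_error_regressors: rank-deficient design; ",
                 "collinear columns: ", paste(bad, collapse = ", "))
  }
  fit <- summary(lm(errors ~ ., data = covariates))
  tab <- fit$coefficients[-1, , drop = FALSE]
  data.frame(covariate = rownames(tab), estimate = tab[, 1],
             t = tab[, 3], p = tab[, 4],
             retained = tab[, 4] < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @noRd
subset_r2 <- function(y, X, members) {
  if (!length(members)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, members, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Commonality (communality) analysis
#'
#' All-subsets decomposition of the regression R^2 into the unique
#' contribution of each covariate and the common (shared) contributions of
#' every covariate subset. The commonality coefficients C(S) are defined by
#' the exact linear system \eqn{R^2(W) = \sum_{S \cap W \neq \emptyset} C(S)}
#' over all non-empty subsets W, whose solution satisfies
#' \eqn{U_i = C(\{i\}) = R^2(full) - R^2(full \setminus i)} and sums to the
#' full-model R^2.
#'
#' @param response numeric response vector.
#' @param covariates data.frame with at most 6 columns (the enumeration is
#'   exponential in the number of covariates).
#' @return list of class `commonality`: `unique` (named vector U_i),
#'   `components` (data.frame of all subset coefficients), `total_r2`,
#'   `r2_subsets` (all-subsets R^2 values).
#' @export
communality_analysis <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  k <- ncol(covariates)
  if (k > 6) {
    stop_invalid("communality_analysis: more than 6 covariates; the ",
                 "all-subsets decomposition is exponential - reduce the ",
                 "candidate set (e.g. to the regressors retained by ",
                 "select_error_regressors)")
  }
  if (k < 1) stop_invalid("communality_analysis: no covariates")
  X <- as.matrix(covariates)
  y <- response
  nsub <- 2^k - 1
  masks <- seq_len(nsub)
  members <- lapply(masks, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  r2 <- vapply(members, function(mm) subset_r2(y, X, mm), 0)
  # M[w, s] = 1 iff subsets w and s intersect
  M <- outer(masks, masks, function(a, b) as.numeric(bitwAnd(a, b) > 0))
  coefs <- solve(M, r2)
  labels <- vapply(members, function(mm) {
    paste(colnames(covariates)[mm], collapse = " & ")
  }, "")
  sizes <- lengths(members)
  uniq <- setNames(coefs[sizes == 1][order(unlist(members[sizes == 1]))],
                   colnames(covariates))
  structure(list(
    unique = uniq,
    components = data.frame(subset = labels, size = sizes,
                            coefficient = coefs, stringsAsFactors = FALSE),
    total_r2 = r2[nsub],
    r2_subsets = setNames(r2, labels)
  ), class = "commonality")
}

#' @export
print.commonality <- function(x, ...) {
  cat(sprintf("Commonality analysis: total R^2 = %.4f\n", x$total_r2))
  u <- sort(x$unique, decreasing = TRUE)
  for (nm in names(u)) cat(sprintf("  unique %-12s %.4f\n", nm, u[nm]))
  commons <- sum(x$components$coefficient[x$components$size > 1])
  cat(sprintf("  common contributions (all subsets): %.4f\n", commons))
  invisible(x)
}

#' Correct a method-comparison bias for a known device calibration bias
#'
#' When the reference device itself carries a known calibration bias b
#' (device minus truth), the model-minus-truth difference is the observed
#' model-minus-device difference plus b. Used to ask what the comparison
#' would look like against an unbiased reference.
#'
#' @param mean_diff observed mean model - device difference (mmHg).
#' @param device_bias known device - truth calibration bias (mmHg).
#' @return corrected mean model - truth difference (mmHg).
#' @export
#' @examples
#' apply_calibration_bias(7.8, -8.2)  # -0.4: systolic overestimation gone
apply_calibration_bias <- function(mean_diff, device_bias) {
  mean_diff + device_bias
}

#' Full method-comparison report between model and reference estimates
#'
#' Runs the whole statistics pipeline on a paired cohort: per-quantity
#' (systolic, diastolic, pulse pressure) paired comparison, regression,
#' Bland-Altman and accuracy classification, then error-regressor selection
#' and commonality ranking against the subject covariates.
#'
#' @param cohort data.frame with columns `id`, `model_cSBP`, `model_cDBP`,
#'   `ref_cSBP`, `ref_cDBP` (pulse pressures are derived), plus any subject
#'   covariate columns.
#' @param covariates character vector of covariate column names for the
#'   error analysis (at most 6 are passed to the commonality step; when
#'   more are given, commonality uses the 6 with the largest absolute
#'   t values).
#' @param threshold accuracy threshold (mmHg).
#' @param alpha regressor-retention level.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(cohort,
                             covariates = intersect(
                               c("brachial_sbp", "brachial_dbp", "cf_pwv",
                                 "heart_rate", "height", "weight"),
                               names(cohort)),
                             threshold = 10, alpha = 0.025) {
  need <- c("model_cSBP", "model_cDBP", "ref_cSBP", "ref_cDBP")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop_invalid("agreement_report: missing columns: ",
                 paste(miss, collapse = ", "))
  }
  cohort <- cohort[complete.cases(cohort[, need]), , drop = FALSE]
  if (nrow(cohort) < 3) stop_invalid("agreement_report: need n >= 3 pairs")
  cohort$model_cPP <- cohort$model_cSBP - cohort$model_cDBP
  cohort$ref_cPP <- cohort$ref_cSBP - cohort$ref_cDBP
  quantities <- list(cSBP = c("model_cSBP", "ref_cSBP"),
                     cDBP = c("model_cDBP", "ref_cDBP"),
                     cPP = c("model_cPP", "ref_cPP"))
  per_q <- lapply(quantities, function(cols) {
    m <- cohort[[cols[1]]]
    r <- cohort[[cols[2]]]
    list(paired = paired_compare(m, r),
         regression = regression_agreement(m, r),
         bland_altman = bland_altman(m, r),
         accuracy = accuracy_classification(m - r, threshold))
  })
  err_an <- function(err) {
    if (sd(err) < 1e-12) return(list(selection = NULL, commonality = NULL))
    cov_df <- cohort[, covariates, drop = FALSE]
    sel <- tryCatch(select_error_regressors(err, cov_df, alpha),
                    error = function(e) NULL)
    comm <- NULL
    if (!is.null(sel) && length(covariates)) {
      use <- covariates
      if (length(use) > 6) use <- sel$covariate[order(-abs(sel$t))][1:6]
      comm <- tryCatch(communality_analysis(err, cohort[, use, drop = FALSE]),
                       error = function(e) NULL)
    }
    list(selection = sel, commonality = comm)
  }
  errors <- list(
    systolic = err_an(cohort$model_cSBP - cohort$ref_cSBP),
    diastolic = err_an(cohort$model_cDBP - cohort$ref_cDBP)
  )
  structure(list(quantities = per_q, errors = errors, n = nrow(cohort),
                 threshold = threshold, alpha = alpha,
                 covariates = covariates, cohort = cohort),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Method-comparison report, n = %d subjects\n", x$n))
  cat(sprintf("%-6s %9s %9s %9s %9s %8s %7s %9s\n", "", "mean diff", "SD",
              "pct diff", "p", "r", "slope", "within"))
  for (q in names(x$quantities)) {
    e <- x$quantities[[q]]
    cat(sprintf("%-6s %9.2f %9.2f %8.1f%% %9.3g %8.2f %7.2f %8.0f%%\n", q,
                e$paired$mean_diff, e$paired$sd_diff, e$paired$percent_diff,
                e$paired$p, e$regression$r, e$regression$slope,
                100 * e$accuracy$proportion))
  }
  cat(sprintf("accuracy threshold %g mmHg; regressor alpha %g\n",
              x$threshold, x$alpha))
  for (side in names(x$errors)) {
    sel <- x$errors[[side]]$selection
    if (!is.null(sel) && any(sel$retained %in% TRUE)) {
      kept <- sel[which(sel$retained), ]
      cat(sprintf("%s error regressors retained: %s\n", side,
                  paste(sprintf("%s (t = %.1f)", kept$covariate, kept$t),
                        collapse = ", ")))
    }
    comm <- x$errors[[side]]$commonality
    if (!is.null(comm)) {
      top <- names(which.max(comm$unique))
      cat(sprintf("%s commonality: dominant unique contribution %s (U = %.2f of R^2 = %.2f)\n",
                  side, top, max(comm$unique), comm$total_r2))
    }
  }
  invisible(x)
}

#' @export
plot.agreement_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (q in c("cSBP", "cDBP")) {
    e <- x$quantities[[q]]
    cols <- if (q == "cSBP") c("model_cSBP", "ref_cSBP") else
      c("model_cDBP", "ref_cDBP")
    m <- x$cohort[[cols[1]]]
    r <- x$cohort[[cols[2]]]
    graphics::plot(r, m, pch = 19, col = "grey30",
                   xlab = sprintf("reference %s (mmHg)", q),
                   ylab = sprintf("model %s (mmHg)", q),
                   main = sprintf("%s: r = %.2f", q, e$regression$r))
    graphics::abline(0, 1, lty = 3)
    graphics::abline(e$regression$intercept, e$regression$slope,
                     col = "firebrick")
    plot(e$bland_altman, main = sprintf("%s Bland-Altman", q))
  }
  invisible(x)
}
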
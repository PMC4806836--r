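COHORT_COLUMNS <- c("id", "age", "height", "weight", "heart_rate",
                    "brachial_sbp", "brachial_dbp", "esv", "edv",
                    "stroke_volume", "cf_pwv", "cr_pwv", "ft_pwv")
REFERENCE_COLUMNS <- c("ref_csbp", "ref_cdbp")

#' Read a cohort file
#'
#' Reads a per-subject cohort table (CSV, or TSV by extension) into
#' validated [subject_record()]s. The canonical column names are `id, age,
#' height, weight, heart_rate, brachial_sbp, brachial_dbp, esv, edv,
#' stroke_volume, cf_pwv, cr_pwv, ft_pwv` (plus optional reference-device
#' columns `ref_csbp`, `ref_cdbp`); files with other headers are adapted
#' through `column_map`. Rows that violate the record invariants are either
#' collected and skipped (with their row numbers reported) or fatal,
#' depending on `strict`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(brachial_sbp = "SBP")`.
#' @param strict if TRUE an invalid row aborts the read; if FALSE invalid
#'   rows are skipped and reported.
#' @return list with `subjects` (list of `subject_record`), `reference`
#'   (data.frame of device pressures or NULL) and `skipped` (data.frame of
#'   row numbers and reasons).
#' @export
read_cohort <- function(path, column_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop_invalid("cohort file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        comment.char = "#", check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      have <- tolower(column_map[[canon]])
      if (have %in% names(df)) names(df)[names(df) == have] <- canon
    }
  }
  mandatory <- setdiff(COHORT_COLUMNS, c("stroke_volume", "cr_pwv", "ft_pwv"))
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop_invalid("cohort file missing mandatory columns: ",
                 paste(miss, collapse = ", "))
  }
  for (opt in c("stroke_volume", "cr_pwv", "ft_pwv")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  subjects <- list()
  skipped <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      subject_record(
        id = df$id[i], age = df$age[i], height = df$height[i],
        weight = df$weight[i], heart_rate = df$heart_rate[i],
        brachial_sbp = df$brachial_sbp[i], brachial_dbp = df$brachial_dbp[i],
        esv = df$esv[i], edv = df$edv[i],
        stroke_volume = df$stroke_volume[i],
        cf_pwv = df$cf_pwv[i], cr_pwv = df$cr_pwv[i], ft_pwv = df$ft_pwv[i]
      ),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (strict) {
        stop_invalid("cohort row ", i, ": ", conditionMessage(rec))
      }
      skipped <- rbind(skipped,
                       data.frame(row = i, reason = conditionMessage(rec),
                                  stringsAsFactors = FALSE))
    } else {
      subjects[[length(subjects) + 1L]] <- rec
    }
  }
  reference <- NULL
  if (all(REFERENCE_COLUMNS %in% names(df))) {
    keep <- setdiff(seq_len(nrow(df)), skipped$row)
    reference <- data.frame(id = as.character(df$id[keep]),
                            ref_cSBP = df$ref_csbp[keep],
                            ref_cDBP = df$ref_cdbp[keep],
                            stringsAsFactors = FALSE)
  }
  list(subjects = subjects, reference = reference, skipped = skipped)
}

#' Write a cohort file
#'
#' Writes subjects (and optional reference-device pressures) in the
#' canonical CSV schema that [read_cohort()] consumes, so synthetic and
#' measured cohorts are interchangeable.
#'
#' @param subjects list of `subject_record`s.
#' @param path output file.
#' @param reference optional data.frame with `id`, `ref_cSBP`, `ref_cDBP`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path, reference = NULL) {
  df <- cohort_to_df(subjects)
  if (!is.null(reference)) {
    names(reference) <- sub("^ref_cSBP$", "ref_csbp",
                            sub("^ref_cDBP$", "ref_cdbp", names(reference)))
    df <- merge(df, reference, by = "id", sort = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the cohort pipeline
#'
#' @param cohort_file cohort CSV path.
#' @param output_dir directory for outputs (created if needed).
#' @param network_file network description path (default: the shipped
#'   reference network).
#' @param threshold accuracy threshold (mmHg).
#' @param alpha regressor-retention level, in (0, 1).
#' @param seed integer seed (recorded in provenance; the estimation itself
#'   is deterministic).
#' @param strict fatal (TRUE) or skip-and-report (FALSE) row validation.
#' @param sim a [sim_config()] for the per-subject simulations.
#' @param column_map forwarded to [read_cohort()].
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort_file, output_dir,
                       network_file = NULL, threshold = 10, alpha = 0.025,
                       seed = 1L, strict = FALSE, sim = sim_config(),
                       column_map = NULL) {
  if (threshold <= 0) stop_invalid("run_config: threshold must be > 0")
  if (alpha <= 0 || alpha >= 1) stop_invalid("run_config: alpha in (0, 1)")
  structure(list(cohort_file = cohort_file, output_dir = output_dir,
                 network_file = network_file, threshold = threshold,
                 alpha = alpha, seed = as.integer(seed), strict = strict,
                 sim = sim, column_map = column_map),
            class = "run_config")
}

#' @noRd
provenance_header <- function(config) {
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = " ")
  hash <- sprintf("%08x",
                  sum(utf8ToInt(cfg_txt) * seq_along(utf8ToInt(cfg_txt))) %%
                    .Machine$integer.max)
  c(sprintf("# centralbp %s",
            as.character(utils::packageVersion("centralbp"))),
    sprintf("# config hash: %s", hash),
    sprintf("# seed: %d", config$seed),
    sprintf("# generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Estimate central pressures for a whole cohort
#'
#' Reads the cohort, tailors and simulates every subject, extracts central
#' pressures, and writes `estimates.csv` (one row per subject, with inputs,
#' cSBP/cDBP/cPP/MAP, convergence flag, cycles run and the resistance
#' coefficient) plus a provenance log to the output directory. Per-subject
#' solver failures are isolated: the cohort run continues and failed
#' subjects appear flagged in the output, never silently dropped.
#'
#' @param config a [run_config()].
#' @return the estimates data.frame, invisibly.
#' @export
run_estimate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  net <- if (is.null(config$network_file)) default_network()
         else load_network(config$network_file)
  set.seed(config$seed)
  ch <- read_cohort(config$cohort_file, config$column_map,
                    strict = config$strict)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(ch$subjects, function(s) {
    base <- cohort_to_df(list(s))
    out <- tryCatch({
      model <- tailor_subject(s, net)
      cfg <- config$sim
      cfg$init_pressure <- s$brachial_dbp
      sim <- simulate_network(model$network, model$cardiac, cfg)
      est <- extract_pressures(sim$waveforms$aortic_root, s$id, "model")
      cbind(base,
            data.frame(model_cSBP = est$cSBP, model_cDBP = est$cDBP,
                       model_cPP = est$cPP, model_MAP = est$MAP,
                       converged = sim$converged, cycles = sim$cycles_run,
                       resistance_coefficient = model$resistance_coefficient,
                       error = "", stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base,
            data.frame(model_cSBP = NA_real_, model_cDBP = NA_real_,
                       model_cPP = NA_real_, model_MAP = NA_real_,
                       converged = FALSE, cycles = NA_integer_,
                       resistance_coefficient = NA_real_,
                       error = conditionMessage(e), stringsAsFactors = FALSE))
    })
    out
  })
  est <- do.call(rbind, rows)
  if (!is.null(ch$reference)) {
    est <- merge(est, ch$reference, by = "id", sort = FALSE)
  }
  out_file <- file.path(config$output_dir, "estimates.csv")
  con <- file(out_file, "w")
  writeLines(provenance_header(config), con)
  utils::write.csv(est, con, row.names = FALSE)
  close(con)
  if (nrow(ch$skipped)) {
    utils::write.csv(ch$skipped,
                     file.path(config$output_dir, "skipped_rows.csv"),
                     row.names = FALSE)
  }
  n_fail <- sum(est$error != "")
  message(sprintf("estimated %d subjects (%d failed, %d input rows skipped)",
                  nrow(est), n_fail, nrow(ch$skipped)))
  invisible(est)
}

#' Validate model estimates against a reference device
#'
#' Consumes the output of [run_estimate()] (or any results CSV with
#' `model_cSBP`/`model_cDBP` and `ref_csbp`/`ref_cdbp` columns, so measured
#' device data can be injected between the two steps), runs the full
#' method-comparison pipeline, and writes a human-readable report, the
#' per-quantity summary CSV and regression/Bland-Altman figures.
#' Non-converged subjects are excluded from the statistics, with the
#' exclusion count reported.
#'
#' @param results_file path to the estimates CSV.
#' @param output_dir output directory.
#' @param threshold accuracy threshold (mmHg).
#' @param alpha regressor-retention level.
#' @param figures write PNG figures (default TRUE).
#' @return the `agreement_report`, invisibly.
#' @export
run_validate <- function(results_file, output_dir, threshold = 10,
                         alpha = 0.025, figures = TRUE) {
  df <- utils::read.csv(results_file, stringsAsFactors = FALSE,
                        comment.char = "#")
  names(df) <- sub("^ref_csbp$", "ref_cSBP",
                   sub("^ref_cdbp$", "ref_cDBP", names(df)))
  need <- c("model_cSBP", "model_cDBP", "ref_cSBP", "ref_cDBP")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_invalid("run_validate: results lack columns: ",
                 paste(miss, collapse = ", "))
  }
  n_all <- nrow(df)
  if ("converged" %in% names(df)) df <- df[df$converged %in% TRUE, ]
  excluded <- n_all - nrow(df)
  if (nrow(df) < 3) stop_invalid("run_validate: fewer than 3 usable pairs")
  rep <- agreement_report(df, threshold = threshold, alpha = alpha)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(output_dir, "agreement_report.txt")
  con <- file(txt, "w")
  writeLines(sprintf("# excluded (non-converged or failed): %d", excluded),
             con)
  utils::capture.output(print(rep), file = con)
  close(con)
  summ <- do.call(rbind, lapply(names(rep$quantities), function(q) {
    e <- rep$quantities[[q]]
    data.frame(quantity = q, n = e$paired$n,
               mean_diff = e$paired$mean_diff, sd_diff = e$paired$sd_diff,
               median_diff = e$paired$median_diff,
               q1 = e$paired$q1, q3 = e$paired$q3,
               percent_diff = e$paired$percent_diff,
               p = e$paired$p, test = e$paired$test,
               r = e$regression$r, r_p = e$regression$p,
               slope = e$regression$slope,
               ba_loa_low = e$bland_altman$loa_low,
               ba_loa_high = e$bland_altman$loa_high,
               ba_trend_slope = e$bland_altman$trend_slope,
               ba_trend_p = e$bland_altman$trend_p,
               prop_within_threshold = e$accuracy$proportion,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(summ, file.path(output_dir, "agreement_summary.csv"),
                   row.names = FALSE)
  if (figures) {
    grDevices::png(file.path(output_dir, "agreement_plots.png"),
                   width = 1200, height = 1000, res = 130)
    plot(rep)
    grDevices::dev.off()
  }
  invisible(rep)
}
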
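#' Season of accelerometer wear
#'
#' Meteorological quarters: Dec-Feb winter, Mar-May spring, Jun-Aug summer,
#' Sep-Nov autumn. Used as a covariate for accelerometer-derived exposures.
#'
#' @param date A Date (or coercible) vector.
#' @return Factor with levels winter/spring/summer/autumn.
#' @examples
#' season_of_wear(as.Date(c("2015-01-15", "2015-06-01", "2015-11-30")))
#' @export
season_of_wear <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  s <- ifelse(m %in% c(12L, 1L, 2L), "winter",
              ifelse(m %in% 3:5, "spring",
                     ifelse(m %in% 6:8, "summer", "autumn")))
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

#' Derive per-participant objective metrics for a cohort
#'
#' Computes rhythm and sleep metrics for every accelerometer participant of
#' a generated cohort.
#'
#' @param cohort A cohort from [generate_cohort()] (phenotyped or not).
#' @param ids Optional subset of participant ids.
#' @return Data.frame with one row per accelerometer participant: `id`,
#'   `AA`, `M10`, `L5`, `RA`, `IS`, `IV`, `n_valid_days`,
#'   `sleep_duration_h`, `sleep_efficiency`, `sleep_duration_cat`,
#'   `n_valid_nights`.
#' @export
cohort_metrics <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  sel <- cohort$id[cohort$has_accel]
  if (!is.null(ids)) sel <- intersect(sel, ids)
  rows <- lapply(sel, function(pid) {
    es <- cohort_actigraphy(cohort, pid)
    cbind(data.frame(id = pid, stringsAsFactors = FALSE),
          rhythm_metrics(es), sleep_metrics(es))
  })
  if (!length(rows)) {
    stop("no accelerometer participants selected", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Analysis-ready table: phenotyped cohort merged with metrics and all
# derived exposure codings.
prepare_analysis_table <- function(cohort, metrics = NULL) {
  d <- as.data.frame(cohort)
  if (!is.null(metrics)) {
    d <- merge(d, metrics, by = "id", all.x = TRUE, sort = FALSE)
  }
  d <- d[d$group %in% c("BD", "UM", "CONTROL"), , drop = FALSE]
  d$season <- season_of_wear(d$wear_start_date)
  d$neuroticism <- neuroticism_score(d[paste0("neuro_", 1:12)])
  d$chronotype <- condense_categories(d$chronotype_raw, "chronotype")
  d$happiness <- condense_categories(d$happiness_raw, "happiness")
  d$happiness_health <- condense_categories(d$happiness_health_raw, "happiness")
  d$getting_up <- condense_categories(d$getting_up_raw, "getting_up")
  d$subjective_sleep_cat <- factor(
    categorize_sleep_duration(d$subjective_sleep_hours),
    levels = c("regular", "short", "long"))
  # quintiles on the pooled analysed sample; high quintile = worse outcome
  if (!is.null(metrics)) {
    d$aa_q <- make_quintiles(d$AA, invert = TRUE)
    d$ra_q <- make_quintiles(d$RA, invert = TRUE)
    d$is_q <- make_quintiles(d$IS, invert = TRUE)
    d$iv_q <- make_quintiles(d$IV, invert = FALSE)
    d$sleep_eff_q <- make_quintiles(d$sleep_efficiency, invert = TRUE)
    d$objective_sleep_cat <- factor(d$sleep_duration_cat,
                                    levels = c("regular", "short", "long"))
    disc <- sleep_discrepancy(d$subjective_sleep_hours, d$sleep_duration_h,
                              d$napping)
    d$discrepancy <- ifelse(disc$category == "excluded", NA, disc$category)
    d$discrepancy_minutes <- disc$diff_minutes
  }
  d$neuroticism_q <- make_quintiles(d$neuroticism)
  d
}

# Default exposure set for compare_groups(): name, reference level,
# whether accelerometer-derived.
default_exposures <- function(with_objective = TRUE) {
  subj <- list(
    list(name = "anxiety", ref = "no", objective = FALSE),
    list(name = "self_harm", ref = "no", objective = FALSE),
    list(name = "risk_taker", ref = "no", objective = FALSE),
    list(name = "happiness", ref = "happy", objective = FALSE),
    list(name = "happiness_health", ref = "happy", objective = FALSE),
    list(name = "neuroticism_q", ref = "1", objective = FALSE),
    list(name = "chronotype", ref = "intermediate", objective = FALSE),
    list(name = "sleeplessness_raw", ref = "1", objective = FALSE),
    list(name = "getting_up", ref = "not_difficult", objective = FALSE),
    list(name = "subjective_sleep_cat", ref = "regular", objective = FALSE))
  obj <- list(
    list(name = "aa_q", ref = "1", objective = TRUE),
    list(name = "ra_q", ref = "1", objective = TRUE),
    list(name = "is_q", ref = "1", objective = TRUE),
    list(name = "iv_q", ref = "1", objective = TRUE),
    list(name = "sleep_eff_q", ref = "1", objective = TRUE),
    list(name = "objective_sleep_cat", ref = "regular", objective = TRUE))
  if (with_objective) c(subj, obj) else subj
}

#' Run all pairwise group comparisons
#'
#' For every exposure, fits the three pairwise models (BD vs UM, UM vs
#' control, BD vs control) under both covariate sets, then applies one
#' pooled Benjamini-Hochberg correction to the fully adjusted p-values.
#'
#' @param analysis Analysis table from `prepare_analysis_table()` (or any
#'   data.frame with `group`, covariates and the exposures).
#' @param exposures List of exposure descriptors (`name`, `ref`,
#'   `objective`); defaults to the package's standard set.
#' @param adjustments Character subset of `c("partly", "fully")`.
#' @return Tidy data.frame of [fit_group_logistic()] rows with a `p_fdr`
#'   column on the fully adjusted rows.
#' @export
compare_groups <- function(analysis,
                           exposures = NULL,
                           adjustments = c("partly", "fully")) {
  if (is.null(exposures)) {
    exposures <- default_exposures(with_objective = "AA" %in% names(analysis))
  }
  rows <- list()
  for (exp in exposures) {
    if (!exp$name %in% names(analysis)) next
    for (cmp in c("BD_vs_UM", "UM_vs_control", "BD_vs_control")) {
      for (adj in adjustments) {
        res <- tryCatch(
          fit_group_logistic(analysis, cmp, exp$name, adjustment = adj,
                             exposure_ref = exp$ref, objective = exp$objective),
          error = function(e) NULL)
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  fully <- out$adjustment == "fully"
  out$p_fdr[fully] <- bh_fdr(out$p[fully])
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates generate -> phenotype -> objective metrics -> group
#' comparisons as one reproducible run, writing the cohort table, the
#' per-participant metrics, the tidy results, a human-readable report and a
#' machine-readable manifest (configuration digest, filtering ledger, FDR
#' summary) into `outdir`.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @param fdr_alpha Discovery threshold on BH-adjusted p-values (default
#'   0.05).
#' @return Invisibly, a list with `cohort`, `metrics`, `results`, `manifest`
#'   and the output paths.
#' @export
run_pipeline <- function(config, outdir, fdr_alpha = 0.05) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cohort <- phenotype_cohort(generate_cohort(config))
  ledger <- attr(cohort, "ledger")
  metrics <- if (any(cohort$has_accel & cohort$group %in%
                       c("BD", "UM", "CONTROL"))) {
    cohort_metrics(cohort,
                   ids = cohort$id[cohort$group %in% c("BD", "UM", "CONTROL")])
  } else {
    NULL
  }
  analysis <- prepare_analysis_table(cohort, metrics)
  results <- compare_groups(analysis)

  cohort_path <- file.path(outdir, "cohort.csv")
  metrics_path <- file.path(outdir, "metrics.csv")
  results_path <- file.path(outdir, "results.csv")
  report_path <- file.path(outdir, "report.md")
  manifest_path <- file.path(outdir, "manifest.json")

  write_cohort(cohort, cohort_path)
  if (!is.null(metrics)) {
    utils::write.csv(metrics, metrics_path, row.names = FALSE)
  }
  utils::write.csv(results, results_path, row.names = FALSE)

  manifest <- list(
    config_digest = config_digest(config),
    seed = config$seed,
    n_participants = config$n_participants,
    ledger = as.list(ledger),
    n_results = nrow(results),
    n_fdr_significant = sum(results$p_fdr < fdr_alpha, na.rm = TRUE),
    fdr_alpha = fdr_alpha,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  writeLines(render_report(cohort, metrics, results, ledger, fdr_alpha),
             report_path)

  invisible(list(cohort = cohort, metrics = metrics, results = results,
                 manifest = manifest,
                 paths = c(cohort = cohort_path, metrics = metrics_path,
                           results = results_path, report = report_path,
                           manifest = manifest_path)))
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

render_report <- function(cohort, metrics, results, ledger, fdr_alpha) {
  lines <- c("# Synthetic cohort analysis report", "",
             "## Filtering ledger", "")
  lines <- c(lines, sprintf("- %s: %d", names(ledger), ledger), "")
  groups <- c("BD", "UM", "CONTROL")
  lines <- c(lines, "## Descriptives", "")
  d <- as.data.frame(cohort)
  d <- d[d$group %in% groups, ]
  age <- tapply(d$age, d$group, mean)
  lines <- c(lines, sprintf("- mean age: %s",
                            paste(sprintf("%s %.1f", groups, age[groups]),
                                  collapse = ", ")))
  if (!is.null(metrics)) {
    dm <- merge(d["id"], cbind(metrics, group = d$group[match(metrics$id, d$id)]),
                by = "id")
    aa <- tapply(dm$AA, dm$group, mean, na.rm = TRUE)
    sl <- tapply(dm$sleep_duration_h, dm$group, mean, na.rm = TRUE)
    lines <- c(lines,
               sprintf("- mean AA (milli-g): %s",
                       paste(sprintf("%s %.1f", groups, aa[groups]), collapse = ", ")),
               sprintf("- mean objective sleep duration (h): %s",
                       paste(sprintf("%s %.2f", groups, sl[groups]), collapse = ", ")))
  }
  lines <- c(lines, "", "## Comparisons", "",
             sprintf("- models fitted: %d", nrow(results)),
             sprintf("- FDR-significant fully adjusted results (alpha %.2f): %d",
                     fdr_alpha, sum(results$p_fdr < fdr_alpha, na.rm = TRUE)))
  sig <- results[!is.na(results$p_fdr) & results$p_fdr < fdr_alpha, ]
  if (nrow(sig)) {
    lines <- c(lines, "",
               sprintf("- %s / %s [%s]: OR %.2f (%.2f-%.2f), p_fdr %.2g",
                       sig$exposure, sig$level, sig$comparison, sig$or,
                       sig$ci_low, sig$ci_high, sig$p_fdr))
  }
  lines
}
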
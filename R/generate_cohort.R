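#' Generate a synthetic three-group cohort
#'
#' Draws a participant table with group-conditional demographics, touchscreen
#' and online mental-health questionnaire responses, subjective sleep items,
#' exclusion-condition flags and (for a configurable subset) a seed from
#' which each participant's accelerometer series can be reproduced with
#' [cohort_actigraphy()]. The questionnaire items are generated so that the
#' phenotyping rules ([assign_group()]) recover the generating stratum with
#' very high probability, which makes the full pipeline testable end to end.
#'
#' Instrument gating is respected: mania symptom counts are only present when
#' the participant answered yes to the hyper/irritable gate, and the
#' health-professional consultation item only when the depression gate was
#' passed, as in the modelled questionnaires.
#'
#' @param config A [cohort_config()].
#' @return A data.frame of class `cohort` (one row per participant) with the
#'   generator configuration in `attr(, "config")`. Columns include
#'   demographics/covariates, `ts_*` (touchscreen) and `onl_*` (online)
#'   questionnaire items, `neuro_1` ... `neuro_12` neuroticism items,
#'   subjective sleep items, `excl_*` exclusion flags, `group_truth`,
#'   `has_accel`, `accel_seed` and `wear_start_date`, plus one column per
#'   injected effect.
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 50, seed = 1))
#' table(coh$group_truth)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_participants
  grp_names <- c("BD", "UM", "CONTROL")

  dep_only <- stats::runif(n) < config$p_depression_only
  group <- ifelse(dep_only, "DEPRESSION_ONLY",
                  sample(grp_names, n, replace = TRUE,
                         prob = config$group_proportions[grp_names]))

  gp <- function(block, field) {
    vapply(config$groups, function(g) g[[block]][[field]], numeric(1))[group]
  }
  draw_cat <- function(block, field, levels) {
    out <- character(n)
    for (g in names(config$groups)) {
      idx <- which(group == g)
      if (length(idx)) {
        out[idx] <- sample(levels, length(idx), replace = TRUE,
                           prob = config$groups[[g]][[block]][[field]])
      }
    }
    out
  }
  yn <- function(p) ifelse(stats::runif(n) < p, "yes", "no")

  df <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    group_truth = group,
    stringsAsFactors = FALSE
  )

  ## demographics / covariates
  df$age <- round(stats::rnorm(n, gp("demographics", "age_mean"),
                               gp("demographics", "age_sd")), 1)
  df$sex <- ifelse(stats::runif(n) < gp("demographics", "p_male"), "Male", "Female")
  df$townsend <- round(stats::rnorm(n, gp("demographics", "townsend_mean"),
                                    gp("demographics", "townsend_sd")), 3)
  df$education <- draw_cat("demographics", "education_probs",
                           c("Incomplete", "Compulsory", "Continued", "College",
                             "University"))
  df$ethnicity <- draw_cat("demographics", "ethnicity_probs",
                           c("White", "Mixed", "Asian", "Black", "Chinese", "Other"))
  df$bmi <- round(pmax(15, stats::rnorm(n, gp("demographics", "bmi_mean"),
                                        gp("demographics", "bmi_sd"))), 1)
  df$smoking <- draw_cat("demographics", "smoking_probs",
                         c("Never", "Previous", "Current"))
  df$alcohol <- draw_cat("demographics", "alcohol_probs",
                         c("Never", "Previous", "Current"))
  df$psychotropic <- stats::runif(n) < gp("demographics", "p_psychotropic")

  ## self-reported exclusion conditions
  for (flag in exclusion_flag_names()) {
    df[[paste0("excl_", flag)]] <- stats::runif(n) < config$p_exclusion_flag
  }

  ## touchscreen mania + depression sections (gated)
  df$ts_hyper <- yn(gp("questionnaire", "p_hyper"))
  df$ts_irritable <- yn(gp("questionnaire", "p_irritable"))
  gate <- df$ts_hyper == "yes" | df$ts_irritable == "yes"
  high <- stats::runif(n) < gp("questionnaire", "p_mania_sympt_high")
  df$ts_mania_symptoms <- ifelse(gate,
                                 ifelse(high, sample(3:4, n, TRUE),
                                        sample(0:2, n, TRUE)),
                                 NA_integer_)
  df$ts_mania_duration <- ifelse(gate,
                                 sample(c("less than a week",
                                          "less than a week but more than two days",
                                          "a week or more"), n, TRUE),
                                 NA_character_)
  df$ts_mania_problematic <- ifelse(gate, yn(0.4), NA_character_)
  df$ts_depressed <- yn(gp("questionnaire", "p_depressed"))
  df$ts_anhedonia <- yn(gp("questionnaire", "p_anhedonia"))
  dgate <- df$ts_depressed == "yes" | df$ts_anhedonia == "yes"
  dhigh <- stats::runif(n) < gp("questionnaire", "p_dep_sympt_high")
  df$ts_dep_symptoms <- ifelse(dgate,
                               ifelse(dhigh, sample(5:8, n, TRUE),
                                      sample(0:4, n, TRUE)),
                               NA_integer_)
  df$ts_consulted <- ifelse(dgate, yn(gp("questionnaire", "p_consulted")),
                            NA_character_)

  ## online follow-up instrument (same criteria, 0-8 symptom scale)
  df$has_online <- stats::runif(n) < config$p_online
  df$onl_hyper <- yn(gp("questionnaire", "p_hyper"))
  df$onl_irritable <- yn(gp("questionnaire", "p_irritable"))
  ogate <- df$onl_hyper == "yes" | df$onl_irritable == "yes"
  ohigh <- stats::runif(n) < gp("questionnaire", "p_mania_sympt_high")
  df$onl_mania_symptoms <- ifelse(ogate,
                                  ifelse(ohigh, sample(3:8, n, TRUE),
                                         sample(0:2, n, TRUE)),
                                  NA_integer_)
  df$onl_mania_duration <- ifelse(ogate,
                                  sample(c("less than 24 h",
                                           "more than one day but less than a week",
                                           "a week or more"), n, TRUE),
                                  NA_character_)
  df$onl_depressed <- yn(gp("questionnaire", "p_depressed"))
  df$onl_anhedonia <- yn(gp("questionnaire", "p_anhedonia"))
  odgate <- df$onl_depressed == "yes" | df$onl_anhedonia == "yes"
  odhigh <- stats::runif(n) < gp("questionnaire", "p_dep_sympt_high")
  df$onl_dep_symptoms <- ifelse(odgate,
                                ifelse(odhigh, sample(5:8, n, TRUE),
                                       sample(0:4, n, TRUE)),
                                NA_integer_)
  df$onl_consulted <- ifelse(odgate, yn(gp("questionnaire", "p_consulted")),
                             NA_character_)
  onl_cols <- grep("^onl_", names(df), value = TRUE)
  df[!df$has_online, onl_cols] <- NA

  ## mental health / wellbeing (online instrument) and touchscreen items
  df$anxiety <- ifelse(df$has_online, yn(gp("questionnaire", "p_anxiety")), NA)
  df$self_harm <- ifelse(df$has_online, yn(gp("questionnaire", "p_self_harm")), NA)
  happy_levels <- c("extremely happy", "very happy", "moderately happy",
                    "moderately unhappy", "very unhappy", "extremely unhappy")
  df$happiness_raw <- ifelse(df$has_online,
                             draw_cat("questionnaire", "happiness_probs",
                                      happy_levels), NA)
  df$happiness_health_raw <- ifelse(df$has_online,
                                    draw_cat("questionnaire",
                                             "happiness_health_probs",
                                             happy_levels), NA)
  df$risk_taker <- yn(gp("questionnaire", "p_risk_taker"))
  p_neuro <- gp("questionnaire", "p_neuroticism_item")
  for (k in 1:12) {
    df[[paste0("neuro_", k)]] <- as.integer(stats::runif(n) < p_neuro)
  }

  ## subjective sleep items
  df$napping <- draw_cat("questionnaire", "napping_probs",
                         c("never", "sometimes", "regular"))
  chron <- draw_cat("questionnaire", "chronotype_probs",
                    c("definitely a morning person", "more morning than evening",
                      "more evening than morning", "definitely an evening person"))
  nonresp <- stats::runif(n) < gp("questionnaire", "p_chronotype_nonresponse")
  chron[nonresp] <- sample(c("do not know", "prefer not to answer"),
                           sum(nonresp), TRUE)
  df$chronotype_raw <- chron
  df$sleeplessness_raw <- as.integer(draw_cat("questionnaire",
                                              "sleeplessness_probs",
                                              c("1", "2", "3")))
  df$getting_up_raw <- draw_cat("questionnaire", "getting_up_probs",
                                c("not at all easy", "not very easy",
                                  "fairly easy", "very easy"))
  df$subjective_sleep_hours <- pmax(
    2L, pmin(14L, as.integer(round(stats::rnorm(
      n, gp("questionnaire", "sleep_mean"), gp("questionnaire", "sleep_sd"))))))

  ## injected exposures for parameter-recovery experiments
  for (eff in config$effects) {
    p <- rep(eff$base_p, n)
    p[group == eff$pair[1]] <- stats::plogis(stats::qlogis(eff$base_p) + eff$log_or)
    df[[eff$name]] <- as.integer(stats::runif(n) < p)
  }

  ## accelerometer sub-study membership
  df$has_accel <- stats::runif(n) < config$accel_proportion
  df$accel_seed <- sample.int(.Machine$integer.max - 1L, n)
  df$wear_start_date <- as.Date("2013-06-01") +
    sample.int(920L, n, replace = TRUE) - 1L

  attr(df, "config") <- config
  class(df) <- c("cohort", "data.frame")
  df
}

exclusion_flag_names <- function() {
  c("neurological", "brain_cancer_injury", "personality_disorder",
    "psychosis", "schizophrenia", "sleep_apnoea_insomnia", "shift_work")
}

#' Reproduce one participant's accelerometer series
#'
#' Regenerates the epoch series for a participant of a generated cohort from
#' the stored per-participant seed and that participant's group actigraphy
#' parameters. Deterministic: the same cohort always yields the same series.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param id Participant id (or row index).
#' @return An [epoch_series()], or `NULL` if the participant is not in the
#'   accelerometer sub-study.
#' @export
cohort_actigraphy <- function(cohort, id) {
  stopifnot(inherits(cohort, "cohort"))
  config <- attr(cohort, "config")
  i <- if (is.numeric(id)) id else match(id, cohort$id)
  if (is.na(i) || i < 1 || i > nrow(cohort)) {
    stop("unknown participant id: ", id, call. = FALSE)
  }
  if (!cohort$has_accel[i]) {
    return(NULL)
  }
  start <- as.POSIXct(paste(cohort$wear_start_date[i], "12:00:00"), tz = "UTC")
  generate_actigraphy(
    params = config$groups[[cohort$group_truth[i]]]$actigraphy,
    seed = cohort$accel_seed[i],
    n_days = config$n_days,
    epoch_s = config$epoch_s,
    start = start,
    p_nonwear = config$p_nonwear
  )
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
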
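#' Configuration for the synthetic three-group cohort
#'
#' Builds and validates the full parameter set of the synthetic-cohort
#' generator. The cohort emulates a population study comparing probable
#' bipolar disorder (BD), probable unipolar mania (UM) and a no-mood-disorder
#' control group, with a depression-only stratum (generated so the exclusion
#' path of the phenotyping rules is exercised) and self-reported exclusion
#' conditions. Defaults reproduce the published group structure of the UK
#' Biobank mood-disorder comparison this package models: group proportions
#' and demographic distributions follow the published descriptive table, and
#' questionnaire response probabilities are chosen so that the phenotyping
#' rules recover the generating group with probability well above 0.99.
#'
#' @param n_participants Number of participants to simulate.
#' @param group_proportions Named numeric of length 3 (`BD`, `UM`, `CONTROL`)
#'   summing to 1: group mix among participants who are neither excluded nor
#'   depression-only.
#' @param p_depression_only Proportion of the cohort meeting depression but
#'   not mania criteria (analysed in no group; kept to test the exclusion
#'   path).
#' @param p_exclusion_flag Per-flag probability for each of the seven
#'   self-report exclusion conditions (neurological, brain cancer/injury,
#'   personality disorder, psychosis, schizophrenia, sleep apnoea/insomnia,
#'   shift work).
#' @param p_online Probability that a participant completed the online
#'   follow-up mental-health questionnaire (in addition to the touchscreen
#'   instrument, which everyone completes).
#' @param accel_proportion Probability that a participant has accelerometer
#'   data.
#' @param n_days Days of accelerometer wear per participant.
#' @param epoch_s Accelerometer epoch length in seconds (divisor of 3600).
#' @param p_nonwear Fraction of epochs flagged non-wear.
#' @param effects Optional list of injected exposure effects created with
#'   [cohort_effect()], used for parameter-recovery testing.
#' @param groups Optional per-group parameter overrides; a named list whose
#'   entries (named `BD`, `UM`, `CONTROL`, `DEPRESSION_ONLY`) are lists with
#'   any of the elements `demographics`, `questionnaire`, `actigraphy`
#'   (themselves named lists of the fields shown in
#'   [default_group_params()]). Only supplied fields are replaced.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A validated object of class `cohort_config`.
#' @seealso [generate_cohort()], [default_group_params()]
#' @export
cohort_config <- function(n_participants = 2000,
                          group_proportions = c(BD = 0.075, UM = 0.019, CONTROL = 0.906),
                          p_depression_only = 0.12,
                          p_exclusion_flag = 0.0085,
                          p_online = 0.35,
                          accel_proportion = 0.4,
                          n_days = 7,
                          epoch_s = 60,
                          p_nonwear = 0,
                          effects = list(),
                          groups = NULL,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    group_proportions = group_proportions,
    p_depression_only = p_depression_only,
    p_exclusion_flag = p_exclusion_flag,
    p_online = p_online,
    accel_proportion = accel_proportion,
    n_days = as.integer(n_days),
    epoch_s = as.integer(epoch_s),
    p_nonwear = p_nonwear,
    effects = effects,
    groups = default_group_params(),
    seed = as.integer(seed)
  )
  if (!is.null(groups)) {
    for (g in names(groups)) {
      if (!g %in% names(cfg$groups)) {
        stop("unknown group in `groups`: ", g, call. = FALSE)
      }
      for (block in names(groups[[g]])) {
        if (!block %in% names(cfg$groups[[g]])) {
          stop("unknown parameter block `", block, "` for group ", g, call. = FALSE)
        }
        for (fld in names(groups[[g]][[block]])) {
          if (!fld %in% names(cfg$groups[[g]][[block]])) {
            stop("unknown field `", fld, "` in ", g, "$", block, call. = FALSE)
          }
          cfg$groups[[g]][[block]][[fld]] <- groups[[g]][[block]][[fld]]
        }
      }
    }
  }
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Injected exposure effect for parameter-recovery experiments
#'
#' Describes a binary exposure generated with a specified log odds ratio
#' between the two named groups: participants in the reference (second) group
#' carry the exposure with probability `base_p`; participants in the first
#' group with probability `plogis(qlogis(base_p) + log_or)`; everyone else
#' with `base_p`.
#'
#' @param name Column name for the generated exposure.
#' @param pair Character vector of length 2, e.g. `c("BD", "CONTROL")`.
#' @param log_or Injected log odds ratio (first group vs second).
#' @param base_p Exposure probability in the reference group.
#' @return A list describing the effect, for the `effects` argument of
#'   [cohort_config()].
#' @export
cohort_effect <- function(name, pair, log_or, base_p = 0.3) {
  stopifnot(is.character(name), length(pair) == 2L,
            is.numeric(log_or), base_p > 0, base_p < 1)
  list(name = name, pair = pair, log_or = log_or, base_p = base_p)
}

#' Default per-group generator parameters
#'
#' One list per generated stratum (`BD`, `UM`, `CONTROL`, `DEPRESSION_ONLY`),
#' each holding `demographics`, `questionnaire` and `actigraphy` blocks.
#' Demographic distributions follow the published descriptive statistics of
#' the modelled study groups (age, sex, Townsend deprivation, education,
#' ethnicity, BMI, smoking, alcohol, psychotropic medication). Actigraphy
#' parameters are in milli-g / hours and are set so the generated groups show
#' the published qualitative ordering: UM the highest average acceleration
#' and shortest sleep, BD the lowest activity, longest and most fragmented
#' sleep.
#'
#' @return Named list of per-group parameter lists.
#' @export
default_group_params <- function() {
  demog <- function(age_mean, age_sd, p_male, townsend_mean, townsend_sd,
                    education_probs, ethnicity_probs, bmi_mean, bmi_sd,
                    smoking_probs, alcohol_probs, p_psychotropic) {
    list(age_mean = age_mean, age_sd = age_sd, p_male = p_male,
         townsend_mean = townsend_mean, townsend_sd = townsend_sd,
         education_probs = education_probs, ethnicity_probs = ethnicity_probs,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd, smoking_probs = smoking_probs,
         alcohol_probs = alcohol_probs, p_psychotropic = p_psychotropic)
  }
  quest <- function(p_hyper, p_irritable, p_mania_sympt_high,
                    p_depressed, p_anhedonia, p_dep_sympt_high, p_consulted,
                    p_anxiety, p_self_harm, p_risk_taker, p_neuroticism_item,
                    napping_probs, chronotype_probs, p_chronotype_nonresponse,
                    sleeplessness_probs, getting_up_probs,
                    happiness_probs, happiness_health_probs,
                    sleep_mean, sleep_sd) {
    list(p_hyper = p_hyper, p_irritable = p_irritable,
         p_mania_sympt_high = p_mania_sympt_high,
         p_depressed = p_depressed, p_anhedonia = p_anhedonia,
         p_dep_sympt_high = p_dep_sympt_high, p_consulted = p_consulted,
         p_anxiety = p_anxiety, p_self_harm = p_self_harm,
         p_risk_taker = p_risk_taker, p_neuroticism_item = p_neuroticism_item,
         napping_probs = napping_probs, chronotype_probs = chronotype_probs,
         p_chronotype_nonresponse = p_chronotype_nonresponse,
         sleeplessness_probs = sleeplessness_probs,
         getting_up_probs = getting_up_probs,
         happiness_probs = happiness_probs,
         happiness_health_probs = happiness_health_probs,
         sleep_mean = sleep_mean, sleep_sd = sleep_sd)
  }
  actig <- function(mesor, amplitude, noise_sd, peak_hour,
                    onset_mean, onset_sd, window_mean, window_sd,
                    window_night_sd, jitter_sd, frag_rate, frag_bout_min,
                    p_wake_epoch) {
    list(mesor = mesor, amplitude = amplitude, noise_sd = noise_sd,
         peak_hour = peak_hour, onset_mean = onset_mean, onset_sd = onset_sd,
         window_mean = window_mean, window_sd = window_sd,
         window_night_sd = window_night_sd, jitter_sd = jitter_sd,
         frag_rate = frag_rate, frag_bout_min = frag_bout_min,
         p_wake_epoch = p_wake_epoch)
  }
  list(
    BD = list(
      demographics = demog(52.11, 7.31, 0.3834, -1.02, 3.16,
                           c(0.0615, 0.1505, 0.0736, 0.2914, 0.4230),
                           c(0.9630, 0.0114, 0.0098, 0.0085, 0.0017, 0.0056),
                           27.81, 5.19,
                           c(0.4818, 0.3716, 0.1466), c(0.0245, 0.0559, 0.9196),
                           0.0377),
      questionnaire = quest(0.99, 0.95, 0.999, 0.995, 0.90, 0.999, 0.9995,
                            0.742, 0.179, 0.393, 0.58,
                            c(never = 0.45, sometimes = 0.40, regular = 0.15),
                            c(0.2443, 0.33, 0.2814, 0.1443), 0.05,
                            c(0.15, 0.50, 0.35),
                            c(0.08, 0.2154, 0.50, 0.2046),
                            c(0.10, 0.40, 0.30, 0.12, 0.06, 0.02),
                            c(0.08, 0.35, 0.2733, 0.18, 0.09, 0.0267),
                            7.1, 1.15),
      actigraphy = actig(38, 18, 6, 14, 23.6, 1.0, 10.3, 0.8, 0.4,
                         0.9, 0.5, 20, 0.26)
    ),
    UM = list(
      demographics = demog(54.05, 7.76, 0.6083, -1.71, 2.82,
                           c(0.0360, 0.1213, 0.0695, 0.2828, 0.4904),
                           c(0.9581, 0.0059, 0.0142, 0.0092, 0.0017, 0.0109),
                           27.25, 4.36,
                           c(0.5563, 0.3703, 0.0734), c(0.0208, 0.0258, 0.9533),
                           0.0033),
      questionnaire = quest(0.99, 0.95, 0.999, 0.03, 0.02, 0.15, 0.25,
                            0.154, 0.038, 0.435, 0.36,
                            c(never = 0.55, sometimes = 0.35, regular = 0.10),
                            c(0.2986, 0.32, 0.2746, 0.1068), 0.05,
                            c(0.25, 0.48, 0.27),
                            c(0.03, 0.1245, 0.55, 0.2955),
                            c(0.18, 0.55, 0.235, 0.025, 0.007, 0.003),
                            c(0.12, 0.50, 0.2522, 0.09, 0.028, 0.0098),
                            7.2, 1.03),
      actigraphy = actig(42, 18, 6, 14, 22.9, 0.8, 9.0, 0.8, 0.4,
                         0.5, 0.3, 20, 0.25)
    ),
    CONTROL = list(
      demographics = demog(57.06, 7.56, 0.5335, -2.00, 2.67,
                           c(0.0816, 0.1445, 0.0607, 0.2707, 0.4425),
                           c(0.9706, 0.0037, 0.0098, 0.0084, 0.0027, 0.0048),
                           26.53, 4.14,
                           c(0.6146, 0.3305, 0.0550), c(0.0301, 0.0191, 0.9507),
                           0.0033),
      questionnaire = quest(0.01, 0.02, 0.03, 0.03, 0.02, 0.10, 0.30,
                            0.057, 0.008, 0.247, 0.21,
                            c(never = 0.55, sometimes = 0.35, regular = 0.10),
                            c(0.2691, 0.34, 0.3176, 0.0733), 0.05,
                            c(0.31, 0.49, 0.20),
                            c(0.02, 0.0884, 0.55, 0.3416),
                            c(0.20, 0.60, 0.1895, 0.007, 0.0025, 0.001),
                            c(0.15, 0.55, 0.2397, 0.04, 0.015, 0.0053),
                            7.3, 0.95),
      actigraphy = actig(40, 18, 6, 14, 23.2, 0.9, 9.5, 0.8, 0.4,
                         0.7, 0.35, 20, 0.24)
    ),
    DEPRESSION_ONLY = list(
      demographics = demog(55.0, 7.6, 0.42, -1.6, 2.9,
                           c(0.07, 0.15, 0.065, 0.28, 0.435),
                           c(0.968, 0.006, 0.010, 0.009, 0.002, 0.005),
                           27.2, 4.7,
                           c(0.55, 0.35, 0.10), c(0.028, 0.032, 0.94),
                           0.015),
      questionnaire = quest(0.01, 0.02, 0.03, 0.995, 0.90, 0.999, 0.9995,
                            0.35, 0.10, 0.25, 0.45,
                            c(never = 0.50, sometimes = 0.37, regular = 0.13),
                            c(0.25, 0.33, 0.30, 0.12), 0.05,
                            c(0.20, 0.50, 0.30),
                            c(0.05, 0.17, 0.52, 0.26),
                            c(0.12, 0.45, 0.28, 0.09, 0.04, 0.02),
                            c(0.10, 0.42, 0.28, 0.12, 0.05, 0.03),
                            7.1, 1.2),
      actigraphy = actig(39, 18, 6, 14, 23.4, 0.95, 9.6, 0.8, 0.4,
                         0.8, 0.4, 20, 0.25)
    )
  )
}

check_probs <- function(x, nm, len = NULL) {
  if (!is.null(len) && length(x) != len) {
    stop("configuration error in `", nm, "`: expected length ", len, call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("configuration error in `", nm, "`: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  # allow printed-percentage rounding in category distributions
  if (!is.null(len) && len > 1 && abs(sum(x) - 1) > 1e-3) {
    stop("configuration error in `", nm, "`: probabilities must sum to 1",
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) {
    stop("configuration error in `n_participants`: must be >= 1", call. = FALSE)
  }
  if (length(cfg$group_proportions) != 3L ||
      !setequal(names(cfg$group_proportions), c("BD", "UM", "CONTROL"))) {
    stop("configuration error in `group_proportions`: need named BD/UM/CONTROL",
         call. = FALSE)
  }
  check_probs(cfg$group_proportions, "group_proportions", 3L)
  check_probs(cfg$p_depression_only, "p_depression_only")
  check_probs(cfg$p_exclusion_flag, "p_exclusion_flag")
  check_probs(cfg$p_online, "p_online")
  check_probs(cfg$accel_proportion, "accel_proportion")
  check_probs(cfg$p_nonwear, "p_nonwear")
  if (cfg$n_days < 1) {
    stop("configuration error in `n_days`: must be >= 1", call. = FALSE)
  }
  if (cfg$epoch_s <= 0 || 3600 %% cfg$epoch_s != 0) {
    stop("configuration error in `epoch_s`: must divide 3600", call. = FALSE)
  }
  for (g in names(cfg$groups)) {
    d <- cfg$groups[[g]]$demographics
    q <- cfg$groups[[g]]$questionnaire
    a <- cfg$groups[[g]]$actigraphy
    for (fld in c("age_sd", "townsend_sd", "bmi_sd")) {
      if (d[[fld]] < 0) {
        stop("configuration error in `", g, "$demographics$", fld,
             "`: sd must be >= 0", call. = FALSE)
      }
    }
    check_probs(d$p_male, paste0(g, "$demographics$p_male"))
    check_probs(d$education_probs, paste0(g, "$demographics$education_probs"), 5L)
    check_probs(d$ethnicity_probs, paste0(g, "$demographics$ethnicity_probs"), 6L)
    check_probs(d$smoking_probs, paste0(g, "$demographics$smoking_probs"), 3L)
    check_probs(d$alcohol_probs, paste0(g, "$demographics$alcohol_probs"), 3L)
    check_probs(d$p_psychotropic, paste0(g, "$demographics$p_psychotropic"))
    for (fld in c("p_hyper", "p_irritable", "p_mania_sympt_high", "p_depressed",
                  "p_anhedonia", "p_dep_sympt_high", "p_consulted", "p_anxiety",
                  "p_self_harm", "p_risk_taker", "p_neuroticism_item",
                  "p_chronotype_nonresponse")) {
      check_probs(q[[fld]], paste0(g, "$questionnaire$", fld))
    }
    check_probs(q$napping_probs, paste0(g, "$questionnaire$napping_probs"), 3L)
    check_probs(q$chronotype_probs, paste0(g, "$questionnaire$chronotype_probs"), 4L)
    check_probs(q$sleeplessness_probs, paste0(g, "$questionnaire$sleeplessness_probs"), 3L)
    check_probs(q$getting_up_probs, paste0(g, "$questionnaire$getting_up_probs"), 4L)
    check_probs(q$happiness_probs, paste0(g, "$questionnaire$happiness_probs"), 6L)
    check_probs(q$happiness_health_probs,
                paste0(g, "$questionnaire$happiness_health_probs"), 6L)
    if (q$sleep_sd < 0) {
      stop("configuration error in `", g, "$questionnaire$sleep_sd`", call. = FALSE)
    }
    for (fld in c("mesor", "amplitude", "noise_sd", "onset_sd", "window_mean",
                  "window_sd", "window_night_sd", "jitter_sd", "frag_rate",
                  "frag_bout_min")) {
      if (a[[fld]] < 0) {
        stop("configuration error in `", g, "$actigraphy$", fld,
             "`: must be >= 0", call. = FALSE)
      }
    }
    check_probs(a$p_wake_epoch, paste0(g, "$actigraphy$p_wake_epoch"))
  }
  for (eff in cfg$effects) {
    if (!all(c("name", "pair", "log_or", "base_p") %in% names(eff))) {
      stop("configuration error in `effects`: use cohort_effect()", call. = FALSE)
    }
    if (!all(eff$pair %in% c("BD", "UM", "CONTROL"))) {
      stop("configuration error in `effects$", eff$name,
           "$pair`: groups must be BD/UM/CONTROL", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n=%d, seed=%d, groups BD/UM/CONTROL = %.3f/%.3f/%.3f,\n",
    x$n_participants, x$seed, x$group_proportions[["BD"]],
    x$group_proportions[["UM"]], x$group_proportions[["CONTROL"]]))
  cat(sprintf(
    "  depression-only %.2f, accelerometer %.2f of cohort, %d x %d-s epochs/day x %d days\n",
    x$p_depression_only, x$accel_proportion, 86400 %/% x$epoch_s, x$epoch_s, x$n_days))
  if (length(x$effects)) {
    cat("  injected effects:",
        paste(vapply(x$effects, function(e)
          sprintf("%s (%s vs %s, logOR %.3f)", e$name, e$pair[1], e$pair[2],
                  e$log_or), ""), collapse = "; "), "\n")
  }
  invisible(x)
}
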
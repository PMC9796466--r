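#' Questionnaire-based mood-disorder phenotyping
#'
#' Implements the probable-mood-disorder assignment rules used throughout the
#' package. A participant meets the mania core when they report having been
#' "hyper" or irritable for two days or more AND at least 3 manic symptoms;
#' they meet the depression criteria when they report 2+ weeks of depressed
#' mood or anhedonia AND at least 5 depressive symptoms AND having consulted
#' a health professional about them. Probable bipolar disorder (BD) is mania
#' core plus depression; probable unipolar mania (UM) is mania core without
#' depression; controls meet neither; depression without mania is kept as a
#' separate `DEPRESSION_ONLY` stratum (analysed in no group rather than
#' contaminating controls). When a participant completed the more detailed
#' online instrument, its answers take precedence over the touchscreen ones.
#'
#' @name phenotyping
NULL

# Vectorised three-valued rule cores. Each returns "meets"/"fails"/NA
# (NA = criteria cannot be evaluated from the available answers).
.mania_core <- function(hyper, irritable, symptoms, threshold = 3L) {
  gate_yes <- (!is.na(hyper) & hyper == "yes") |
    (!is.na(irritable) & irritable == "yes")
  gate_no <- !is.na(hyper) & hyper == "no" & !is.na(irritable) & irritable == "no"
  out <- rep(NA_character_, length(gate_yes))
  out[gate_no] <- "fails"
  ok <- gate_yes & !is.na(symptoms)
  out[ok & symptoms >= threshold] <- "meets"
  out[ok & symptoms < threshold] <- "fails"
  out
}

.depression_core <- function(depressed, anhedonia, symptoms, consulted,
                             threshold = 5L) {
  gate_yes <- (!is.na(depressed) & depressed == "yes") |
    (!is.na(anhedonia) & anhedonia == "yes")
  gate_no <- !is.na(depressed) & depressed == "no" &
    !is.na(anhedonia) & anhedonia == "no"
  out <- rep(NA_character_, length(gate_yes))
  out[gate_no] <- "fails"
  known <- gate_yes & !is.na(symptoms) & !is.na(consulted)
  out[known & symptoms >= threshold & consulted == "yes"] <- "meets"
  out[known & (symptoms < threshold | consulted == "no")] <- "fails"
  # a definite "no" on consultation settles the rule even if symptoms are missing
  out[gate_yes & is.na(out) & !is.na(consulted) & consulted == "no"] <- "fails"
  out
}

#' Exclusion screen
#'
#' A participant is excluded from all analyses when any self-reported
#' exclusion condition is present: severe neurological diagnosis, brain
#' cancer/injury, personality disorder, psychosis, schizophrenia, sleep
#' apnoea/insomnia, or a main job involving shift work.
#'
#' @param record A named list (or one-row data.frame) with logical
#'   `excl_neurological`, `excl_brain_cancer_injury`,
#'   `excl_personality_disorder`, `excl_psychosis`, `excl_schizophrenia`,
#'   `excl_sleep_apnoea_insomnia`, `excl_shift_work` entries (missing entries
#'   count as not reported).
#' @return `TRUE` if the participant must be excluded.
#' @examples
#' apply_exclusions(list(excl_schizophrenia = TRUE))
#' apply_exclusions(list())
#' @export
apply_exclusions <- function(record) {
  flags <- paste0("excl_", exclusion_flag_names())
  any(vapply(flags, function(f) isTRUE(as.logical(record[[f]])), logical(1)))
}

#' Mania core criterion
#'
#' Met when the participant answered yes to being "hyper" or irritable for
#' two days or more and reported at least 3 manic symptoms. The same absolute
#' symptom threshold applies to both instruments (touchscreen scale 0-4,
#' online scale 0-8).
#'
#' @param record Named list with `hyper`, `irritable` ("yes"/"no"/NA) and
#'   `mania_symptoms` (integer, NA when not asked).
#' @return `"meets"`, `"fails"`, or `NA` when the answers available cannot
#'   decide the rule (the participant is then unclassifiable, never silently
#'   a control).
#' @examples
#' classify_mania(list(hyper = "yes", irritable = "no", mania_symptoms = 3))
#' @export
classify_mania <- function(record) {
  .mania_core(record$hyper, record$irritable, record$mania_symptoms)
}

#' Probable major-depression criterion
#'
#' Met when the participant reported 2+ weeks of depressed feelings or
#' anhedonia, at least 5 depressive symptoms, and that a health professional
#' was consulted about these symptoms.
#'
#' @param record Named list with `depressed`, `anhedonia`, `consulted`
#'   ("yes"/"no"/NA) and `dep_symptoms` (integer, NA when not asked).
#' @return `"meets"`, `"fails"`, or `NA` when undecidable.
#' @examples
#' classify_depression(list(depressed = "yes", anhedonia = "no",
#'                          dep_symptoms = 5, consulted = "yes"))
#' @export
classify_depression <- function(record) {
  .depression_core(record$depressed, record$anhedonia, record$dep_symptoms,
                   record$consulted)
}

#' Assign the analysis group from questionnaire records
#'
#' Applies the mania and depression criteria with online-instrument
#' precedence and returns the analysis label. The rule trace records, in
#' order, which instrument decided and how each criterion evaluated.
#'
#' @param touchscreen Touchscreen record (named list with `hyper`,
#'   `irritable`, `mania_symptoms`, `depressed`, `anhedonia`, `dep_symptoms`,
#'   `consulted`), or `NULL`.
#' @param online Online record in the same shape, or `NULL`.
#' @return A list with `label` (one of `"BD"`, `"UM"`, `"CONTROL"`,
#'   `"DEPRESSION_ONLY"`, `"UNCLASSIFIABLE"`), `source` (`"online"`,
#'   `"touchscreen"` or `NA`) and `trace` (character).
#' @examples
#' ts <- list(hyper = "yes", irritable = "no", mania_symptoms = 3,
#'            depressed = "no", anhedonia = "no", dep_symptoms = NA,
#'            consulted = NA)
#' assign_group(ts)$label
#' @export
assign_group <- function(touchscreen = NULL, online = NULL) {
  if (is.null(touchscreen) && is.null(online)) {
    return(list(label = "UNCLASSIFIABLE", source = NA_character_,
                trace = "no questionnaire record"))
  }
  rec <- if (!is.null(online)) online else touchscreen
  src <- if (!is.null(online)) "online" else "touchscreen"
  mania <- classify_mania(rec)
  dep <- classify_depression(rec)
  label <- .combine_criteria(mania, dep)
  trace <- sprintf("source=%s; mania_core=%s; depression=%s; label=%s",
                   src, ifelse(is.na(mania), "undecidable", mania),
                   ifelse(is.na(dep), "undecidable", dep), label)
  list(label = label, source = src, trace = trace)
}

.combine_criteria <- function(mania, dep) {
  out <- rep("UNCLASSIFIABLE", length(mania))
  m <- !is.na(mania)
  d <- !is.na(dep)
  out[m & d & mania == "meets" & dep == "meets"] <- "BD"
  out[m & d & mania == "meets" & dep == "fails"] <- "UM"
  out[m & d & mania == "fails" & dep == "fails"] <- "CONTROL"
  out[m & d & mania == "fails" & dep == "meets"] <- "DEPRESSION_ONLY"
  out
}

#' Phenotype a whole cohort table
#'
#' Vectorised application of the exclusion screen and group-assignment rules
#' to a cohort data.frame (as produced by [generate_cohort()], or any table
#' with the same `ts_*`/`onl_*`/`excl_*` columns). Adds `group`,
#' `group_source` and `rule_trace` columns; excluded participants get
#' `group = "EXCLUDED"` before any criteria are evaluated.
#'
#' @param cohort Cohort data.frame.
#' @return The cohort with `group`, `group_source`, `rule_trace` columns, and
#'   a filtering ledger in `attr(, "ledger")` with counts per label.
#' @export
phenotype_cohort <- function(cohort) {
  n <- nrow(cohort)
  excl_cols <- paste0("excl_", exclusion_flag_names())
  present <- intersect(excl_cols, names(cohort))
  excluded <- if (length(present)) {
    rowSums(as.matrix(cohort[present]), na.rm = TRUE) > 0
  } else {
    rep(FALSE, n)
  }

  ts_m <- .mania_core(cohort$ts_hyper, cohort$ts_irritable,
                      cohort$ts_mania_symptoms)
  ts_d <- .depression_core(cohort$ts_depressed, cohort$ts_anhedonia,
                           cohort$ts_dep_symptoms, cohort$ts_consulted)
  has_onl <- if ("has_online" %in% names(cohort)) {
    cohort$has_online %in% TRUE
  } else {
    rep(FALSE, n)
  }
  if (any(has_onl)) {
    onl_m <- .mania_core(cohort$onl_hyper, cohort$onl_irritable,
                         cohort$onl_mania_symptoms)
    onl_d <- .depression_core(cohort$onl_depressed, cohort$onl_anhedonia,
                              cohort$onl_dep_symptoms, cohort$onl_consulted)
  } else {
    onl_m <- onl_d <- rep(NA_character_, n)
  }

  mania <- ifelse(has_onl, onl_m, ts_m)
  dep <- ifelse(has_onl, onl_d, ts_d)
  src <- ifelse(has_onl, "online", "touchscreen")

  label <- .combine_criteria(mania, dep)
  label[excluded] <- "EXCLUDED"

  cohort$group <- label
  cohort$group_source <- ifelse(excluded, NA_character_, src)
  cohort$rule_trace <- ifelse(
    excluded, "excluded before criteria",
    sprintf("source=%s; mania_core=%s; depression=%s; label=%s", src,
            ifelse(is.na(mania), "undecidable", mania),
            ifelse(is.na(dep), "undecidable", dep), label))

  ledger <- c(
    n_input = n,
    n_excluded = sum(label == "EXCLUDED"),
    n_unclassifiable = sum(label == "UNCLASSIFIABLE"),
    n_depression_only = sum(label == "DEPRESSION_ONLY"),
    n_BD = sum(label == "BD"),
    n_UM = sum(label == "UM"),
    n_control = sum(label == "CONTROL")
  )
  attr(cohort, "ledger") <- ledger
  cohort
}
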
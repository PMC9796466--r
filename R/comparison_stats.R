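#' Group-comparison statistics
#'
#' Variable preparation (quintiles with inversion, category condensation),
#' pairwise case-control logistic models with two covariate sets and a
#' Fisher's-exact fallback for sparse tables, the objective-vs-subjective
#' sleep-discrepancy procedure with its multinomial model, Benjamini-
#' Hochberg FDR control, and descriptive chi-squared / one-way ANOVA tests
#' with effect sizes.
#'
#' @name comparison_stats
NULL

#' Quintile coding of a continuous exposure
#'
#' Sample quintiles (type-7 quantiles) computed on the pooled analysed
#' sample. With `invert = TRUE` the value sign is reversed before binning,
#' so the highest raw values land in quintile 1 — used for measures where a
#' high raw value is a good outcome (relative amplitude, interdaily
#' stability, average acceleration, sleep efficiency) so that a higher
#' quintile always reflects a more negative outcome. Boundary ties share the
#' lower bin.
#'
#' @param values Numeric vector (NA allowed; at least 5 distinct values).
#' @param invert Reverse sign before binning.
#' @return Integer labels 1-5 (NA preserved).
#' @examples
#' make_quintiles(1:10)
#' @export
make_quintiles <- function(values, invert = FALSE) {
  x <- as.numeric(values)
  if (length(unique(x[!is.na(x)])) < 5L) {
    stop("need at least 5 distinct values to form quintiles", call. = FALSE)
  }
  if (invert) x <- -x
  br <- stats::quantile(x, probs = 0:5 / 5, na.rm = TRUE, type = 7, names = FALSE)
  if (anyDuplicated(br[2:5])) {
    warning("tied quintile boundaries collapsed; fewer than 5 bins")
    br <- unique(br)
  }
  cut(x, breaks = br, include.lowest = TRUE, right = TRUE, labels = FALSE)
}

#' Condense raw questionnaire categories for analysis
#'
#' Implements the exact condensation rules used in the analysis:
#' * chronotype: "definitely a morning person" -> `early`; "more morning
#'   than evening" and "more evening than morning" -> `intermediate`
#'   (reference); "definitely an evening person" -> `late`;
#' * happiness (both general and with health): the three happy levels ->
#'   `happy` (reference), the three unhappy levels -> `unhappy`;
#' * getting up in the morning: "fairly easy"/"very easy" -> `not_difficult`
#'   (reference), "not at all easy"/"not very easy" -> `difficult`.
#'
#' "Do not know" and "prefer not to answer" become missing (excluded); any
#' other unknown code is an error naming the code.
#'
#' @param raw Character vector of raw codes.
#' @param item One of `"chronotype"`, `"happiness"`, `"getting_up"`.
#' @return Factor with the reference category as first level.
#' @examples
#' condense_categories("definitely a morning person", "chronotype")
#' @export
condense_categories <- function(raw, item = c("chronotype", "happiness",
                                              "getting_up")) {
  item <- match.arg(item)
  maps <- list(
    chronotype = c("definitely a morning person" = "early",
                   "more morning than evening" = "intermediate",
                   "more evening than morning" = "intermediate",
                   "definitely an evening person" = "late"),
    happiness = c("extremely happy" = "happy", "very happy" = "happy",
                  "moderately happy" = "happy",
                  "moderately unhappy" = "unhappy", "very unhappy" = "unhappy",
                  "extremely unhappy" = "unhappy"),
    getting_up = c("fairly easy" = "not_difficult", "very easy" = "not_difficult",
                   "not very easy" = "difficult", "not at all easy" = "difficult")
  )
  refs <- c(chronotype = "intermediate", happiness = "happy",
            getting_up = "not_difficult")
  lvls <- list(chronotype = c("intermediate", "early", "late"),
               happiness = c("happy", "unhappy"),
               getting_up = c("not_difficult", "difficult"))
  map <- maps[[item]]
  nonresp <- c("do not know", "prefer not to answer")
  x <- tolower(trimws(as.character(raw)))
  unknown <- !is.na(x) & !(x %in% c(names(map), nonresp))
  if (any(unknown)) {
    stop("unknown ", item, " code: ",
         paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(x))
  hit <- x %in% names(map)
  out[hit] <- unname(map[x[hit]])
  factor(out, levels = lvls[[item]])
}

# Wald OR row from a fitted glm for one coefficient name.
.or_row <- function(fit, term) {
  cf <- stats::coef(summary(fit))
  if (!term %in% rownames(cf)) {
    return(NULL)
  }
  b <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  data.frame(or = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se), p = cf[term, "Pr(>|z|)"],
             stringsAsFactors = FALSE)
}

partly_covariates <- function(objective = FALSE) {
  c("age", "sex", "townsend", "education", "ethnicity",
    if (objective) "season")
}

fully_covariates <- function(objective = FALSE) {
  c(partly_covariates(objective), "bmi", "smoking", "alcohol", "psychotropic")
}

#' Pairwise group logistic model for one exposure
#'
#' Fits `outcome ~ exposure + covariates` by binomial logistic regression,
#' where the outcome is membership of the first-named group of the pair (so
#' OR > 1 means the exposure is more likely in that group). Categorical
#' exposures are dummy-coded against `exposure_ref` and yield one result row
#' per non-reference level. For a binary (2-level) contrast whose 2x2 table
#' against the outcome has any expected cell below `fisher_threshold`, the
#' covariate-adjusted model is replaced by Fisher's exact test on that
#' contrast (method `"fisher"`), mirroring standard sparse-cell practice.
#' Multi-level exposures check each level-vs-reference subtable the same
#' way. Non-convergence or separation is flagged, never an error.
#'
#' @param data Data.frame with a `group` column and the exposure/covariates.
#' @param comparison `"BD_vs_UM"`, `"UM_vs_control"` or `"BD_vs_control"`.
#' @param exposure Name of the exposure column.
#' @param adjustment `"unadjusted"`, `"partly"` (age, sex, Townsend,
#'   education, ethnicity, + season for objective exposures) or `"fully"`
#'   (partly + BMI, smoking, alcohol, psychotropic medication).
#' @param exposure_ref Reference level for a categorical exposure (default:
#'   first factor level).
#' @param objective Is the exposure accelerometer-derived? Adds the season
#'   covariate to the adjusted models.
#' @param fisher_threshold Minimum expected cell count below which the
#'   Fisher fallback triggers (default 5).
#' @return Data.frame, one row per exposure level: `comparison`, `exposure`,
#'   `level`, `adjustment`, `or`, `ci_low`, `ci_high`, `p`, `n_cases`,
#'   `n_controls`, `method`, `flag`.
#' @export
fit_group_logistic <- function(data, comparison = c("BD_vs_UM", "UM_vs_control",
                                                    "BD_vs_control"),
                               exposure, adjustment = c("unadjusted", "partly",
                                                        "fully"),
                               exposure_ref = NULL, objective = FALSE,
                               fisher_threshold = 5) {
  comparison <- match.arg(comparison)
  adjustment <- match.arg(adjustment)
  pair <- switch(comparison,
                 BD_vs_UM = c("BD", "UM"),
                 UM_vs_control = c("UM", "CONTROL"),
                 BD_vs_control = c("BD", "CONTROL"))
  d <- data[data$group %in% pair, , drop = FALSE]
  covs <- switch(adjustment,
                 unadjusted = character(0),
                 partly = partly_covariates(objective),
                 fully = fully_covariates(objective))
  keep <- c("group", exposure, covs)
  missing_cols <- setdiff(keep, names(d))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- d[stats::complete.cases(d[keep]), keep, drop = FALSE]
  if (!nrow(d) || length(unique(d$group)) < 2L) {
    stop("both groups must be non-empty after removing missing data",
         call. = FALSE)
  }
  x <- d[[exposure]]
  if (!is.numeric(x) || length(unique(x[!is.na(x)])) <= 5L) {
    x <- factor(x)
    if (!is.null(exposure_ref)) {
      x <- stats::relevel(x, ref = as.character(exposure_ref))
    }
  }
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("exposure `", exposure, "` has no variation", call. = FALSE)
  }
  d$.exposure <- x
  d$.y <- as.integer(d$group == pair[1])
  n_cases <- sum(d$.y == 1L)
  n_controls <- sum(d$.y == 0L)

  fml <- stats::as.formula(paste(".y ~ .exposure",
                                 if (length(covs)) paste("+", paste(covs, collapse = " + "))
                                 else ""))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })

  base <- function(level) {
    data.frame(comparison = comparison, exposure = exposure, level = level,
               adjustment = adjustment, stringsAsFactors = FALSE)
  }
  rows <- list()
  if (is.factor(d$.exposure)) {
    ref <- levels(d$.exposure)[1]
    for (lv in levels(d$.exposure)[-1]) {
      sub <- d[d$.exposure %in% c(ref, lv), ]
      tab <- table(factor(sub$.exposure == lv, c(FALSE, TRUE)),
                   factor(sub$.y, c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < fisher_threshold)) {
        ft <- fisher_exact_2x2(matrix(c(tab[2, 2], tab[2, 1],
                                        tab[1, 2], tab[1, 1]), 2, byrow = TRUE))
        rows[[lv]] <- cbind(base(lv),
                            data.frame(or = ft$or, ci_low = ft$ci_low,
                                       ci_high = ft$ci_high, p = ft$p),
                            method = "fisher",
                            flag = "sparse cells: Fisher's exact used")
      } else {
        rr <- .or_row(fit, paste0(".exposure", lv))
        if (is.null(rr)) next
        flag <- if (warned || !fit$converged || rr$or > 1e3 || rr$or < 1e-3) {
          "possible separation or non-convergence"
        } else if (any(tab < 10)) {
          "cell count below 10"
        } else {
          NA_character_
        }
        rows[[lv]] <- cbind(base(lv), rr, method = "logistic", flag = flag)
      }
    }
  } else {
    rr <- .or_row(fit, ".exposure")
    flag <- if (warned || !fit$converged) "possible separation or non-convergence"
            else NA_character_
    rows[["linear"]] <- cbind(base("per unit"), rr, method = "logistic",
                              flag = flag)
  }
  out <- do.call(rbind, rows)
  out$n_cases <- n_cases
  out$n_controls <- n_controls
  rownames(out) <- NULL
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test and conditional maximum-likelihood odds ratio, used
#' as the automatic fallback for sparse contingency tables.
#'
#' @param table 2x2 matrix of nonnegative integers, exposed/unexposed rows by
#'   case/control columns.
#' @return List with `or`, `ci_low`, `ci_high`, `p`; the OR is `NA` with a
#'   `flag` when a margin is empty.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0) || any(m != round(m))) {
    stop("need a 2x2 table of nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = 1, flag = "empty margin: OR undefined"))
  }
  ft <- stats::fisher.test(m)
  list(or = unname(ft$estimate), ci_low = ft$conf.int[1],
       ci_high = ft$conf.int[2], p = ft$p.value, flag = NA_character_)
}

#' Objective-vs-subjective sleep-duration discrepancy
#'
#' Classifies each participant's self-reported sleep duration against the
#' accelerometer-derived duration. Regular nappers are excluded because the
#' self-report includes napping while the objective estimate does not. The
#' objective duration is rounded to the nearest hour and the signed
#' difference `subjective - round(objective)` determines the class: 0 is
#' accurate, positive is overestimation, negative is underestimation.
#' `diff_minutes` reports the unrounded `(subjective - objective) * 60`.
#'
#' @param subjective_h Self-reported sleep duration (whole hours).
#' @param objective_h Accelerometer-derived mean sleep duration (hours).
#' @param napping Self-reported napping frequency: `"never"`, `"sometimes"`,
#'   `"regular"`.
#' @return Data.frame with `category` (`accurate` / `overestimation` /
#'   `underestimation` / `excluded`) and `diff_minutes` (NA when excluded).
#' @examples
#' sleep_discrepancy(8, 7.4, "never")
#' @export
sleep_discrepancy <- function(subjective_h, objective_h, napping) {
  n <- max(length(subjective_h), length(objective_h), length(napping))
  subjective_h <- rep_len(subjective_h, n)
  objective_h <- rep_len(objective_h, n)
  napping <- rep_len(as.character(napping), n)
  excluded <- (!is.na(napping) & napping == "regular") |
    is.na(subjective_h) | is.na(objective_h)
  diff_h <- subjective_h - round(objective_h)
  category <- ifelse(excluded, "excluded",
                     ifelse(diff_h == 0, "accurate",
                            ifelse(diff_h > 0, "overestimation",
                                   "underestimation")))
  data.frame(
    category = category,
    diff_minutes = ifelse(excluded, NA_real_,
                          (subjective_h - objective_h) * 60)
  )
}

#' Multinomial model of sleep-estimation accuracy
#'
#' Regresses the three-level discrepancy outcome (accurate as reference,
#' underestimation, overestimation) on group membership plus the requested
#' covariate set, and reports per-contrast odds ratios with Wald intervals.
#'
#' @param data Data.frame with a factor/character `discrepancy` column
#'   (levels among accurate/underestimation/overestimation), a `group`
#'   column, and the covariates.
#' @param adjustment `"unadjusted"`, `"partly"` or `"fully"` (season is
#'   included in adjusted sets: the outcome is accelerometer-derived).
#' @param group_ref Reference group (default `"CONTROL"`).
#' @return Data.frame with one row per outcome level x non-reference group:
#'   `outcome`, `term`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
multinomial_discrepancy <- function(data, adjustment = c("unadjusted", "partly",
                                                         "fully"),
                                    group_ref = "CONTROL") {
  adjustment <- match.arg(adjustment)
  y <- as.character(data$discrepancy)
  keep_lv <- c("accurate", "underestimation", "overestimation")
  data <- data[!is.na(y) & y %in% keep_lv, , drop = FALSE]
  y <- factor(as.character(data$discrepancy), levels = keep_lv)
  if (nlevels(droplevels(y)) < 3L) {
    stop("outcome has fewer than 3 observed categories; ",
         "use a binary logistic model instead", call. = FALSE)
  }
  covs <- switch(adjustment,
                 unadjusted = character(0),
                 partly = partly_covariates(objective = TRUE),
                 fully = fully_covariates(objective = TRUE))
  covs <- intersect(covs, names(data))
  d <- data.frame(.y = y, group = stats::relevel(factor(data$group),
                                                 ref = group_ref),
                  data[covs], check.names = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~ group",
                                 if (length(covs)) paste("+", paste(covs, collapse = " + "))
                                 else ""))
  fit <- nnet::multinom(fml, data = d, trace = FALSE, maxit = 200)
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  rows <- list()
  for (lv in rownames(cf)) {
    for (term in grep("^group", colnames(cf), value = TRUE)) {
      b <- cf[lv, term]
      se <- sqrt(vc[paste(lv, term, sep = ":"), paste(lv, term, sep = ":")])
      rows[[paste(lv, term)]] <- data.frame(
        outcome = lv, term = sub("^group", "", term),
        or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
        p = 2 * stats::pnorm(-abs(b / se)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; the
#' analysis declares discoveries at adjusted p < 0.05.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04))
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-squared test with Cramer's V
#'
#' @param counts Matrix of nonnegative integer counts, at least 2x2, rows =
#'   groups, columns = categories.
#' @return List with `statistic`, `df`, `p`, `cramers_v`, `n`.
#' @examples
#' chi_squared_table(rbind(c(20, 30), c(25, 25)))
#' @export
chi_squared_table <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m)) || anyNA(m)) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin: chi-squared undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  n <- sum(m)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       cramers_v = sqrt(unname(ct$statistic) / (n * min(dim(m) - 1L))),
       n = n)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the classic one-way ANOVA from group means, standard
#' deviations and sizes: between-group sum of squares
#' `SSB = sum n_g (m_g - grand)^2`, within `SSW = sum (n_g - 1) s_g^2`,
#' `F = (SSB/(k-1)) / (SSW/(N-k))`, `eta^2 = SSB / (SSB + SSW)`. Identical
#' to the raw-data ANOVA when the summaries are exact.
#'
#' @param means,sds,ns Numeric vectors, one entry per group (>= 2 groups,
#'   all `ns >= 2`).
#' @return List with `F`, `df1`, `df2`, `p`, `eta_sq`; `F` is `NA` with a
#'   `reason` when the within-group variance is zero.
#' @examples
#' oneway_anova_summary(c(1, 2), c(1, 1), c(10, 10))
#' @export
oneway_anova_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k) {
    stop("need >= 2 groups with matching means/sds/ns", call. = FALSE)
  }
  if (any(ns < 2)) {
    stop("all group sizes must be >= 2", call. = FALSE)
  }
  if (any(sds < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw <= 0) {
    return(list(F = NA_real_, df1 = k - 1L, df2 = N - k, p = NA_real_,
                eta_sq = NA_real_, reason = "zero within-group variance"))
  }
  Fval <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fval, df1 = k - 1L, df2 = N - k,
       p = stats::pf(Fval, k - 1, N - k, lower.tail = FALSE),
       eta_sq = ssb / (ssb + ssw))
}

#' One-way ANOVA from raw data
#'
#' Computes the exact group summaries and delegates to
#' [oneway_anova_summary()]; gives results identical to `anova(lm(...))`.
#'
#' @param values Numeric response.
#' @param groups Grouping vector.
#' @return As [oneway_anova_summary()].
#' @export
oneway_anova_raw <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ns <- tapply(values, groups, length)
  oneway_anova_summary(as.numeric(means), as.numeric(sds), as.numeric(ns))
}

#' Neuroticism sum score
#'
#' Sum of 12 binary neuroticism items; the score is missing whenever any
#' item is missing (an incomplete item set cannot support the 0-12 scale).
#'
#' @param items Numeric/logical vector of exactly 12 items (0/1), or a
#'   matrix/data.frame with 12 columns (one row per participant).
#' @return Integer score(s) 0-12, NA when any item is missing.
#' @examples
#' neuroticism_score(rep(1, 12))
#' @export
neuroticism_score <- function(items) {
  score1 <- function(v) {
    if (length(v) != 12L) {
      stop("neuroticism requires exactly 12 items, got ", length(v),
           call. = FALSE)
    }
    v <- as.numeric(v)
    if (any(!is.na(v) & !v %in% c(0, 1))) {
      stop("neuroticism items must be binary (0/1)", call. = FALSE)
    }
    if (anyNA(v)) NA_integer_ else as.integer(sum(v))
  }
  if (is.matrix(items) || is.data.frame(items)) {
    m <- as.matrix(items)
    if (ncol(m) != 12L) {
      stop("neuroticism requires exactly 12 items, got ", ncol(m),
           call. = FALSE)
    }
    apply(m, 1L, score1)
  } else {
    score1(items)
  }
}
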
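#' Published reference summaries of the modelled study groups
#'
#' Loads the descriptive summary statistics of the published UK Biobank
#' probable-BD / probable-UM / control comparison that this package models:
#' per-group category counts (sex, education, ethnicity, smoking, alcohol,
#' psychotropic medication, reported anxiety, objective sleep-duration
#' categories) and per-group means/SDs with group sizes for age, Townsend
#' deprivation and BMI. These printed summaries are the inputs from which
#' the package's descriptive tests can be recomputed without any
#' access-restricted participant-level data.
#'
#' @return A list with `counts` (named list of group-by-category integer
#'   matrices, rows BD/UM/CONTROL) and `continuous` (data.frame with
#'   `variable`, `group`, `mean`, `sd`, `n`).
#' @examples
#' ref <- reference_summaries()
#' chi_squared_table(ref$counts$sex)$statistic
#' @export
reference_summaries <- function() {
  cdir <- system.file("extdata", package = "actimood")
  counts_df <- utils::read.csv(file.path(cdir, "reference_group_counts.csv"),
                               stringsAsFactors = FALSE)
  counts <- lapply(split(counts_df, counts_df$variable), function(d) {
    m <- t(as.matrix(d[, c("BD", "UM", "CONTROL")]))
    colnames(m) <- d$category
    m
  })
  continuous <- utils::read.csv(file.path(cdir, "reference_group_continuous.csv"),
                                stringsAsFactors = FALSE)
  list(counts = counts, continuous = continuous)
}

#' Recompute descriptive test statistics from the reference summaries
#'
#' Chi-squared statistics (with Cramer's V) for each categorical variable
#' and summary-statistic one-way ANOVA F for each continuous variable of
#' [reference_summaries()], plus the unadjusted BD-vs-control odds ratio for
#' reported anxiety from its 2x2 counts.
#'
#' @return Data.frame with `quantity`, `value`, `n`.
#' @export
reference_statistics <- function() {
  ref <- reference_summaries()
  rows <- list()
  for (v in c("sex", "education", "ethnicity", "smoking", "alcohol",
              "psychotropic")) {
    ct <- chi_squared_table(ref$counts[[v]])
    rows[[paste0("chisq_", v)]] <- data.frame(
      quantity = paste0("chisq_", v), value = ct$statistic, n = ct$n)
    rows[[paste0("cramers_v_", v)]] <- data.frame(
      quantity = paste0("cramers_v_", v), value = ct$cramers_v, n = ct$n)
  }
  for (v in unique(ref$continuous$variable)) {
    d <- ref$continuous[ref$continuous$variable == v, ]
    a <- oneway_anova_summary(d$mean, d$sd, d$n)
    rows[[paste0("anova_f_", v)]] <- data.frame(
      quantity = paste0("anova_f_", v), value = a$F, n = sum(d$n))
    rows[[paste0("anova_eta2_", v)]] <- data.frame(
      quantity = paste0("anova_eta2_", v), value = a$eta_sq, n = sum(d$n))
  }
  anx <- ref$counts$anxiety[c("BD", "CONTROL"), ]
  rows[["or_anxiety"]] <- data.frame(
    quantity = "or_anxiety_bd_vs_control_unadjusted",
    value = (anx["BD", "Yes"] * anx["CONTROL", "No"]) /
      (anx["BD", "No"] * anx["CONTROL", "Yes"]),
    n = sum(anx))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
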
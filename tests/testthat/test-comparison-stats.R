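test_that("quintile coding matches sample quantiles and honours inversion", {
  expect_equal(make_quintiles(1:10), rep(1:5, each = 2))
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4, 0.3, 0.6, 0.8, 0.7, 0.95)
  q <- make_quintiles(x, invert = TRUE)
  expect_equal(q[which.max(x)], 1L)  # best raw value -> lowest quintile
  expect_equal(q[which.min(x)], 5L)
  expect_error(make_quintiles(rep(1:2, 10)), "distinct")
  # balanced bins when n divisible by 5 and values continuous
  set.seed(17)
  for (i in 1:10) {
    v <- runif(5 * sample(10:40, 1))
    sizes <- as.numeric(table(make_quintiles(v)))
    expect_true(max(sizes) - min(sizes) <= 1)
  }
})

test_that("category condensation follows the analysis mappings exactly", {
  expect_equal(as.character(condense_categories("definitely a morning person",
                                                "chronotype")), "early")
  expect_equal(as.character(condense_categories("more evening than morning",
                                                "chronotype")), "intermediate")
  expect_equal(as.character(condense_categories("definitely an evening person",
                                                "chronotype")), "late")
  expect_true(is.na(condense_categories("do not know", "chronotype")))
  expect_error(condense_categories("night owl", "chronotype"), "night owl")
  expect_equal(levels(condense_categories("very happy", "happiness")),
               c("happy", "unhappy"))
  expect_equal(as.character(condense_categories("extremely unhappy", "happiness")),
               "unhappy")
  expect_equal(as.character(condense_categories("not very easy", "getting_up")),
               "difficult")
  expect_equal(as.character(condense_categories("fairly easy", "getting_up")),
               "not_difficult")
})

test_that("unadjusted logistic OR on a 2x2 equals the cross-product ratio", {
  # counts expanded to rows: exposed/unexposed x case/control
  counts <- c(a = 40, b = 25, c = 15, d = 60)  # case-exp, ctl-exp, case-unexp, ctl-unexp
  d <- data.frame(
    group = rep(c("BD", "CONTROL", "BD", "CONTROL"), counts),
    expo = rep(c("yes", "yes", "no", "no"), counts))
  r <- fit_group_logistic(d, "BD_vs_control", "expo", "unadjusted",
                          exposure_ref = "no")
  expect_equal(r$or, (40 * 60) / (25 * 15), tolerance = 1e-6)
  expect_equal(r$method, "logistic")
  expect_equal(r$n_cases, 55)
  expect_equal(r$n_controls, 85)
})

test_that("a null exposure fits near OR 1 with a covering interval", {
  set.seed(18)
  d <- data.frame(group = rep(c("UM", "CONTROL"), each = 1500),
                  expo = rbinom(3000, 1, 0.3))
  r <- fit_group_logistic(d, "UM_vs_control", "expo", "unadjusted",
                          exposure_ref = "0")
  expect_gt(r$or, 0.8)
  expect_lt(r$or, 1.25)
  expect_true(r$ci_low < 1 && r$ci_high > 1)
})

test_that("sparse cells trigger the Fisher fallback automatically", {
  # rare exposure in a small case group: expected long-sleep cell < 5
  d <- data.frame(
    group = c(rep("UM", 100), rep("CONTROL", 5000)),
    cat = c(rep("long", 2), rep("regular", 98),
            rep("long", 40), rep("regular", 4960)))
  r <- fit_group_logistic(d, "UM_vs_control", "cat", "unadjusted",
                          exposure_ref = "regular")
  expect_equal(r$method, "fisher")
  expect_true(r$p > 0 && r$p <= 1)
  # a well-filled table keeps the logistic route
  d2 <- data.frame(group = rep(c("UM", "CONTROL"), each = 200),
                   cat = rep(c("long", "regular"), 200))
  expect_equal(fit_group_logistic(d2, "UM_vs_control", "cat", "unadjusted",
                                  exposure_ref = "regular")$method, "logistic")
  # the published sparse long-sleep table: exact test applies, odds below 1
  ft <- fisher_exact_2x2(matrix(c(2, 283, 345, 14964), 2, byrow = TRUE))
  expect_lt(ft$or, 1)
  expect_true(ft$p > 0 && ft$p <= 1)
})

test_that("Fisher's exact matches hypergeometric enumeration", {
  flat <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$or, 1, tolerance = 1e-6)
  expect_equal(flat$p, 1)
  empty <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_true(is.na(empty$or))
  set.seed(19)
  for (i in 1:40) {
    m <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p, oracle_fisher_p(m), tolerance = 1e-9)
  }
})

test_that("sleep discrepancy classifies against the rounded objective duration", {
  d <- sleep_discrepancy(8, 7.4, "never")
  expect_equal(d$category, "overestimation")
  expect_equal(d$diff_minutes, (8 - 7.4) * 60)
  expect_equal(sleep_discrepancy(7, 7.2, "sometimes")$category, "accurate")
  expect_equal(sleep_discrepancy(6, 7.6, "never")$category, "underestimation")
  expect_equal(sleep_discrepancy(8, 7.4, "regular")$category, "excluded")
  expect_equal(sleep_discrepancy(NA, 7.4, "never")$category, "excluded")
  expect_true(is.na(sleep_discrepancy(8, 7.4, "regular")$diff_minutes))
})

test_that("multinomial discrepancy model recovers injected contrast effects", {
  set.seed(20)
  n <- 6000
  group <- sample(c("BD", "CONTROL"), n, TRUE, prob = c(0.3, 0.7))
  base <- c(accurate = 1, underestimation = 0.8, overestimation = 0.6)
  w <- sapply(names(base), function(k) rep(base[[k]], n))
  w[group == "BD", "overestimation"] <- base[["overestimation"]] * 1.5
  y <- apply(w, 1, function(p) sample(names(base), 1, prob = p))
  d <- data.frame(group = group, discrepancy = y)
  r <- multinomial_discrepancy(d, "unadjusted")
  over <- r[r$outcome == "overestimation", ]
  se <- (log(over$ci_high) - log(over$or)) / 1.96
  expect_lt(abs(log(over$or) - log(1.5)), 2 * se)
  under <- r[r$outcome == "underestimation", ]
  expect_true(under$ci_low < 1 && under$ci_high > 1)
  # degenerate two-category outcome is rejected with advice
  d2 <- d[d$discrepancy != "underestimation", ]
  expect_error(multinomial_discrepancy(d2, "unadjusted"), "binary")
})

test_that("BH adjustment equals the step-up oracle and is order invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.03, 6)), rep(0.03, 6))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(21)
  p <- runif(7)
  base <- bh_fdr(p)
  for (i in 1:25) {
    o <- sample(7)
    expect_equal(bh_fdr(p[o]), base[o], tolerance = 1e-12)
    expect_equal(bh_fdr(p[o]), oracle_bh(p[o]), tolerance = 1e-12)
  }
})

test_that("chi-squared matches the direct Pearson computation", {
  m <- rbind(c(20, 30, 10), c(25, 25, 12))
  got <- chi_squared_table(m)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(got$statistic, sum((m - expected)^2 / expected), tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$cramers_v,
               sqrt(got$statistic / (sum(m) * 1)), tolerance = 1e-12)
  prop <- rbind(c(10, 20), c(30, 60))
  expect_equal(chi_squared_table(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_squared_table(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_squared_table(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("summary-statistic ANOVA is identical to the raw-data fit", {
  set.seed(22)
  for (i in 1:20) {
    g <- factor(sample(letters[1:3], 120, TRUE))
    y <- rnorm(120, as.integer(g))
    a_sum <- oneway_anova_raw(y, g)
    fit <- anova(lm(y ~ g))
    expect_equal(a_sum$F, fit$`F value`[1], tolerance = 1e-9)
    expect_equal(a_sum$p, fit$`Pr(>F)`[1], tolerance = 1e-9)
    expect_equal(a_sum$eta_sq,
                 fit$`Sum Sq`[1] / sum(fit$`Sum Sq`), tolerance = 1e-9)
  }
  expect_equal(oneway_anova_summary(c(5, 5), c(1, 1), c(10, 10))$F, 0)
  zero <- oneway_anova_summary(c(1, 2), c(0, 0), c(5, 5))
  expect_true(is.na(zero$F))
  expect_match(zero$reason, "variance")
})

test_that("neuroticism score sums complete 12-item sets only", {
  expect_equal(neuroticism_score(rep(1, 12)), 12L)
  expect_equal(neuroticism_score(rep(0, 12)), 0L)
  expect_true(is.na(neuroticism_score(c(rep(1, 11), NA))))
  expect_error(neuroticism_score(rep(1, 13)), "12")
  m <- rbind(rep(1, 12), rep(0, 12), c(rep(1, 6), rep(0, 6)))
  expect_equal(neuroticism_score(m), c(12L, 0L, 6L))
})
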
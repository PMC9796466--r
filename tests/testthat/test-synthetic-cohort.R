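test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_participants = 200, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  # per-participant actigraphy is reproducible too
  pid <- c1$id[c1$has_accel][1]
  expect_identical(cohort_actigraphy(c1, pid), cohort_actigraphy(c2, pid))
  # a different seed changes the draw
  c3 <- generate_cohort(cohort_config(n_participants = 200, seed = 8))
  expect_false(identical(c1$age, c3$age))
})

test_that("degenerate group mix yields an all-control cohort", {
  cfg <- cohort_config(n_participants = 300, seed = 3,
                       group_proportions = c(BD = 0, UM = 0, CONTROL = 1),
                       p_depression_only = 0, p_exclusion_flag = 0)
  ph <- phenotype_cohort(generate_cohort(cfg))
  expect_true(all(ph$group_truth == "CONTROL"))
  expect_true(mean(ph$group == "CONTROL") > 0.98)
  expect_identical(sum(ph$group == "EXCLUDED"), 0L)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(group_proportions = c(BD = 0.5, UM = 0.6, CONTROL = -0.1)),
               "group_proportions")
  expect_error(cohort_config(epoch_s = 7), "epoch_s")
  expect_error(cohort_config(n_days = 0), "n_days")
  expect_error(cohort_config(groups = list(BD = list(actigraphy = list(mesor = -1)))),
               "mesor")
  expect_error(cohort_config(groups = list(BD = list(actigraphy = list(bogus = 1)))),
               "bogus")
})

test_that("phenotyping recovers generator labels at default probabilities", {
  cfg <- cohort_config(n_participants = 3000, seed = 21, accel_proportion = 0)
  ph <- phenotype_cohort(generate_cohort(cfg))
  keep <- ph$group %in% c("BD", "UM", "CONTROL", "DEPRESSION_ONLY")
  acc <- mean(ph$group[keep] == ph$group_truth[keep])
  expect_gte(acc, 0.99)
})

test_that("raising a group's mesor strictly raises its mean activity", {
  aa <- vapply(c(30, 36, 42, 48), function(m) {
    p <- perfect_params("CONTROL", mesor = m, noise_sd = 4)
    average_acceleration(generate_actigraphy(p, seed = 5, n_days = 3))
  }, numeric(1))
  expect_true(all(diff(aa) > 0))
})

test_that("wake-bout probability sets the expected sleep efficiency", {
  # p = 0.0625 wake probability per sleep epoch -> efficiency 1 - p
  effs <- vapply(1:100, function(s) {
    p <- perfect_params("CONTROL", p_wake_epoch = 0.0625,
                        onset_mean = 23, window_mean = 8)
    sleep_metrics(generate_actigraphy(p, seed = s, n_days = 1))$sleep_efficiency
  }, numeric(1))
  expect_equal(mean(effs), 0.9375, tolerance = 0.005)
})

test_that("perfectly periodic generator signal gives IS = 1 and efficiency = 1", {
  es <- generate_actigraphy(perfect_params("CONTROL"), seed = 2)
  m <- rhythm_metrics(es)
  expect_equal(m$IS, 1, tolerance = 1e-9)
  expect_equal(sleep_metrics(es)$sleep_efficiency, 1, tolerance = 1e-9)
})

test_that("flat generator signal (no amplitude, no sleep) gives RA = 0", {
  p <- perfect_params("CONTROL", amplitude = 0, window_mean = 0)
  es <- generate_actigraphy(p, seed = 2, n_days = 2)
  expect_equal(relative_amplitude(es)$RA, 0, tolerance = 1e-12)
})

test_that("an injected null-free exposure is recovered near its true odds ratio", {
  # ln 2 injected BD vs control; the mean over seeds must sit close to 2
  ors <- vapply(1:5, function(s) {
    cfg <- cohort_config(n_participants = 20000, seed = s, accel_proportion = 0,
                         effects = list(cohort_effect("expo", c("BD", "CONTROL"),
                                                      log(2))))
    coh <- phenotype_cohort(generate_cohort(cfg))
    fit_group_logistic(coh, "BD_vs_control", "expo", "unadjusted",
                       exposure_ref = "0")$or
  }, numeric(1))
  expect_gt(mean(ors), 1.8)
  expect_lt(mean(ors), 2.2)
})

test_that("epoch series round-trip through CSV", {
  es <- generate_actigraphy(perfect_params("UM", noise_sd = 3), seed = 9,
                            n_days = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_series(es, path)
  back <- read_epoch_series(path)
  expect_equal(back$values, es$values)
  expect_identical(back$wear, es$wear)
  expect_equal(back$start, es$start)
  expect_identical(back$epoch_s, es$epoch_s)
})

test_that("epoch series constructor enforces its invariants", {
  expect_error(epoch_series(c(-1, 2), noon()), "nonnegative")
  expect_error(epoch_series(1:10, noon(), epoch_s = 7), "3600")
  expect_error(epoch_series(1:10, noon(), wear = c(TRUE, FALSE)), "length")
})
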
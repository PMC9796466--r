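test_that("hourly binning averages worn epochs and tracks completeness", {
  es <- epoch_series(rep(5, 60), noon(), epoch_s = 60)
  h <- bin_hourly(es)
  expect_equal(h$mean, 5)
  expect_equal(h$completeness, 1)

  wear <- rep(c(TRUE, FALSE), 30)
  es2 <- epoch_series(ifelse(wear, 10, 99), noon(), epoch_s = 60, wear = wear)
  h2 <- bin_hourly(es2)
  expect_equal(h2$mean, 10)
  expect_equal(h2$completeness, 0.5)

  # brute-force oracle on a random day with scattered non-wear
  set.seed(4)
  v <- runif(1440, 0, 80)
  w <- runif(1440) > 0.2
  es3 <- epoch_series(v, noon(), epoch_s = 60, wear = w)
  h3 <- bin_hourly(es3, min_frac = 0)
  oracle <- vapply(1:24, function(k) {
    idx <- ((k - 1) * 60 + 1):(k * 60)
    mean(v[idx][w[idx]])
  }, numeric(1))
  expect_equal(h3$mean, oracle, tolerance = 1e-12)
})

test_that("average acceleration is the worn-epoch mean", {
  expect_equal(average_acceleration(epoch_series(rep(30, 100), noon())), 30)
  expect_equal(average_acceleration(epoch_series(rep(c(0, 60), 50), noon())), 30)
  set.seed(8)
  v <- rexp(500, 1 / 20)
  w <- runif(500) > 0.3
  es <- epoch_series(v, noon(), wear = w)
  expect_equal(average_acceleration(es), mean(v[w]))
  expect_error(average_acceleration(
    epoch_series(1:5, noon(), wear = rep(FALSE, 5))), "worn")
})

test_that("interdaily stability hits its closed forms and null expectation", {
  set.seed(11)
  pattern <- runif(24, 0, 50)
  expect_equal(as.numeric(interdaily_stability(make_hourly(rep(pattern, 7)))),
               1, tolerance = 1e-12)
  const <- interdaily_stability(make_hourly(rep(7, 168)))
  expect_true(is.na(const))
  expect_match(attr(const, "reason"), "variance")
  expect_true(is.na(interdaily_stability(make_hourly(runif(24)))))  # 1 day

  # i.i.d. noise over d days: IS concentrates near 1/d. First-order oracle
  # for the ratio of expectations: E[between-hour var] = 23 sigma^2 / (24 d),
  # E[total var] = (N - 1) sigma^2 / N, so IS ~ 23 N / (24 d (N - 1)).
  d <- 7; N <- 24 * d
  oracle <- 23 * N / (24 * d * (N - 1))
  expect_equal(oracle, 1 / 7, tolerance = 0.05)  # the 1/d rule of thumb
  set.seed(12)
  iss <- replicate(250, as.numeric(interdaily_stability(
    make_hourly(abs(rnorm(N, 10, 2))))))
  expect_lt(abs(mean(iss) - oracle), 0.005)
})

test_that("intradaily variability matches alternation, sinusoid and noise forms", {
  # strict hourly alternation: squared step 4, unit variance -> IV = 4
  expect_equal(as.numeric(intradaily_variability(make_hourly(rep(c(2, 0), 84)))),
               4, tolerance = 1e-9)
  # 24-h cosine sampled hourly: IV = 2 * (1 - cos(pi / 12))
  x <- 10 + 4 * cos(2 * pi * (0:(24 * 50 - 1)) / 24)
  expect_equal(as.numeric(intradaily_variability(make_hourly(x))),
               2 * (1 - cos(pi / 12)), tolerance = 1e-3)
  # white noise: IV -> 2
  set.seed(13)
  ivs <- replicate(10, as.numeric(intradaily_variability(
    make_hourly(abs(rnorm(168 * 20, 10, 2))))))
  expect_equal(mean(ivs), 2, tolerance = 0.1)
  expect_true(is.na(intradaily_variability(make_hourly(rep(3, 168)))))
})

test_that("M10/L5 sliding windows agree with the exhaustive oracle", {
  sq <- square_day_series(high = 100, low = 0, high_hours = 10)
  ra <- relative_amplitude(sq)
  expect_equal(ra$M10, 100)
  expect_equal(ra$L5, 0)
  expect_equal(ra$RA, 1)

  const <- relative_amplitude(square_day_series(high = 42, low = 42))
  expect_equal(const$RA, 0)

  set.seed(14)
  for (i in 1:20) {
    v <- runif(288, 0, 60)  # one day at 5-min epochs
    es <- epoch_series(v, noon(), epoch_s = 300)
    got <- relative_amplitude(es)
    want <- oracle_m10_l5(v, epoch_s = 300)
    expect_equal(got$M10, want$M10, tolerance = 1e-10)
    expect_equal(got$L5, want$L5, tolerance = 1e-10)
  }
})

test_that("metric ranges and scale behaviour hold on fuzzed inputs", {
  set.seed(15)
  for (i in 1:15) {
    v <- rexp(1440 * 3, 1 / 30) * rbinom(1440 * 3, 1, 0.8)
    es <- epoch_series(v, noon(), epoch_s = 60)
    m <- rhythm_metrics(es)
    expect_true(m$RA >= 0 && m$RA <= 1)
    expect_true(m$IS >= 0 && m$IS <= 1)
    expect_true(m$IV >= 0)
    # positive rescaling leaves RA (and IS, IV) unchanged; AA scales linearly
    es2 <- epoch_series(v * 3.7, noon(), epoch_s = 60)
    m2 <- rhythm_metrics(es2)
    expect_equal(m2$RA, m$RA, tolerance = 1e-12)
    expect_equal(m2$IS, m$IS, tolerance = 1e-12)
    expect_equal(m2$AA, 3.7 * m$AA, tolerance = 1e-12)
  }
})

test_that("phase jitter lowers IS and fragmentation raises IV in expectation", {
  mean_metric <- function(field, ...) {
    mean(vapply(1:6, function(s) {
      rhythm_metrics(generate_actigraphy(perfect_params("CONTROL", noise_sd = 4,
                                                        ...),
                                         seed = s, n_days = 4))[[field]]
    }, numeric(1)))
  }
  is_by_jitter <- vapply(c(0, 1, 2.5), function(j)
    mean_metric("IS", jitter_sd = j), numeric(1))
  expect_true(all(diff(is_by_jitter) < 0))
  iv_by_frag <- vapply(c(0, 0.8, 2), function(f)
    mean_metric("IV", frag_rate = f), numeric(1))
  expect_true(all(diff(iv_by_frag) > 0))
})
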
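# Shared fixture builders. Everything is generated in code; no stored data.

noon <- function(date = "2015-06-01") {
  as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
}

# hourly_series built directly from a vector of hourly means
make_hourly <- function(values, start_clock = 12) {
  n <- length(values)
  structure(
    data.frame(hour = seq_len(n) - 1L,
               clock_hour = (start_clock + seq_len(n) - 1L) %% 24,
               day = ((seq_len(n) - 1L) %/% 24L) + 1L,
               mean = values, completeness = 1),
    class = c("hourly_series", "data.frame"))
}

# square-wave day(s): `high_hours` at `high` then the rest of the day at `low`
square_day_series <- function(high = 100, low = 0, high_hours = 10, days = 1,
                              epoch_s = 60) {
  per_hour <- 3600 %/% epoch_s
  day <- c(rep(high, high_hours * per_hour),
           rep(low, (24 - high_hours) * per_hour))
  epoch_series(rep(day, days), start = noon(), epoch_s = epoch_s)
}

# day with a sleep block: `high` when awake, `low` from sleep_start_h to
# sleep_start_h + sleep_len_h (hours after noon)
sleep_day_values <- function(high = 50, low = 0, sleep_start_h = 11,
                             sleep_len_h = 8, epoch_s = 60) {
  per_hour <- 3600 %/% epoch_s
  v <- rep(high, 24 * per_hour)
  idx <- (sleep_start_h * per_hour + 1):((sleep_start_h + sleep_len_h) * per_hour)
  v[idx] <- low
  v
}

# questionnaire record with sensible defaults, overridable per field
make_record <- function(hyper = "no", irritable = "no", mania_symptoms = NA,
                        depressed = "no", anhedonia = "no", dep_symptoms = NA,
                        consulted = NA) {
  list(hyper = hyper, irritable = irritable, mania_symptoms = mania_symptoms,
       depressed = depressed, anhedonia = anhedonia,
       dep_symptoms = dep_symptoms, consulted = consulted)
}

# deterministic actigraphy parameters (no noise, no jitter, no wake bouts)
perfect_params <- function(group = "CONTROL", ...) {
  p <- default_group_params()[[group]]$actigraphy
  p$jitter_sd <- 0
  p$noise_sd <- 0
  p$frag_rate <- 0
  p$p_wake_epoch <- 0
  p$onset_sd <- 0
  p$window_sd <- 0
  p$window_night_sd <- 0
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# exhaustive sliding-window oracle for M10/L5 on one day of epoch values
oracle_m10_l5 <- function(values, epoch_s = 60) {
  w10 <- 10 * 3600 %/% epoch_s
  w5 <- 5 * 3600 %/% epoch_s
  n <- length(values)
  m10 <- max(vapply(1:(n - w10 + 1), function(i) mean(values[i:(i + w10 - 1)]),
                    numeric(1)))
  l5 <- min(vapply(1:(n - w5 + 1), function(i) mean(values[i:(i + w5 - 1)]),
                   numeric(1)))
  list(M10 = m10, L5 = l5)
}

# hand-written BH step-up oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided Fisher p by hypergeometric enumeration using choose()
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  prob <- function(a) choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  p_obs <- prob(m[1, 1])
  sum(vapply(a_min:a_max, prob, numeric(1))[
    vapply(a_min:a_max, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}
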
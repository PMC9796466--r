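#' Nonparametric circadian rest-activity metrics
#'
#' Classic nonparametric characterisation of a rest-activity rhythm from an
#' epoch series: average acceleration (AA), the most-active 10-hour (M10) and
#' least-active 5-hour (L5) windows, relative amplitude
#' RA = (M10 - L5) / (M10 + L5), interdaily stability (IS) and intradaily
#' variability (IV). IS and IV are computed on hourly means; M10/L5 slide at
#' epoch resolution within each noon-to-noon day.
#'
#' @name actigraphy_metrics
NULL

#' Hourly binning of an epoch series
#'
#' Means of worn epochs per clock hour, with a per-hour completeness
#' fraction. Hours whose worn fraction falls below `min_frac` are set
#' missing.
#'
#' @param series An [epoch_series()].
#' @param min_frac Minimum worn fraction for an hour to count (default 0.5).
#' @param strict If `TRUE`, error (naming the hours) instead of returning
#'   missing hours.
#' @return A data.frame of class `hourly_series` with columns `hour`
#'   (0-based index from series start), `clock_hour`, `day` (1-based,
#'   noon-to-noon), `mean` and `completeness`.
#' @export
bin_hourly <- function(series, min_frac = 0.5, strict = FALSE) {
  stopifnot(inherits(series, "epoch_series"))
  if (!length(series$values)) {
    stop("empty series", call. = FALSE)
  }
  per_hour <- 3600L %/% series$epoch_s
  n_hours <- length(series$values) %/% per_hour
  idx <- rep(seq_len(n_hours), each = per_hour)
  vals <- series$values[seq_len(n_hours * per_hour)]
  worn <- series$wear[seq_len(n_hours * per_hour)]
  v <- vals
  v[!worn] <- NA_real_
  sums <- tapply(v, idx, sum, na.rm = TRUE)
  cnts <- tapply(worn, idx, sum)
  m <- as.numeric(sums) / as.numeric(cnts)
  completeness <- as.numeric(cnts) / per_hour
  m[completeness < min_frac] <- NA_real_
  if (strict && anyNA(m)) {
    stop("hours below completeness threshold: ",
         paste(which(is.na(m)) - 1L, collapse = ", "), call. = FALSE)
  }
  start_clock <- as.numeric(format(series$start, "%H")) +
    as.numeric(format(series$start, "%M")) / 60
  out <- data.frame(
    hour = seq_len(n_hours) - 1L,
    clock_hour = (floor(start_clock) + seq_len(n_hours) - 1L) %% 24,
    day = ((seq_len(n_hours) - 1L) %/% 24L) + 1L,
    mean = m,
    completeness = completeness
  )
  class(out) <- c("hourly_series", "data.frame")
  out
}

#' Average acceleration
#'
#' Mean magnitude over all worn epochs of the full measurement period
#' (milli-g).
#'
#' @param series An [epoch_series()].
#' @return Mean worn-epoch magnitude.
#' @export
average_acceleration <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  v <- series$values[series$wear]
  if (!length(v)) {
    stop("no worn epochs: average acceleration undefined", call. = FALSE)
  }
  mean(v)
}

# Keep only days with at least `min_hours` non-missing hourly values.
complete_days <- function(hourly, min_hours = 20L) {
  ok <- tapply(!is.na(hourly$mean), hourly$day, sum) >= min_hours
  keep <- hourly$day %in% as.integer(names(ok)[ok])
  hourly[keep, , drop = FALSE]
}

#' Interdaily stability
#'
#' The proportion of total hourly variance explained by the average 24-hour
#' profile:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (24 * sum_i (x_i - xbar)^2)`
#' over N hourly values with clock-hour means `xbar_h`. 1 means every day
#' repeats the same profile; i.i.d. noise over d days gives about 1/d in
#' expectation. With missing hours the equivalent ratio of the between-hour
#' to total variance is used over available values.
#'
#' @param hourly An `hourly_series` from [bin_hourly()].
#' @param min_hours Minimum complete hours for a day to be used (default 20).
#' @return IS in `[0, 1]`, or `NA` with attribute `reason` when fewer than 2
#'   complete days are available or the signal is constant (zero variance).
#' @export
interdaily_stability <- function(hourly, min_hours = 20L) {
  h <- complete_days(hourly, min_hours)
  if (!nrow(h) || length(unique(h$day)) < 2L) {
    return(structure(NA_real_, reason = "fewer than 2 complete days"))
  }
  x <- h$mean[!is.na(h$mean)]
  ch <- h$clock_hour[!is.na(h$mean)]
  xbar <- mean(x)
  tot <- mean((x - xbar)^2)
  if (tot <= 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  hr_means <- tapply(x, ch, mean)
  between <- mean((hr_means - xbar)^2)
  min(1, between / tot)
}

#' Intradaily variability
#'
#' Fragmentation of the rhythm via the normalised mean squared successive
#' difference of the hourly series:
#' `IV = (N * sum_{i>=2} (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i - xbar)^2)`.
#' Around 2 for white noise, small for smooth sinusoidal profiles, up to 4
#' for strict hourly alternation. Pairs spanning a missing hour are skipped.
#'
#' @param hourly An `hourly_series` from [bin_hourly()].
#' @param min_hours Minimum complete hours for a day to be used (default 20).
#' @return IV >= 0, or `NA` with attribute `reason` for constant or too-short
#'   series.
#' @export
intradaily_variability <- function(hourly, min_hours = 20L) {
  h <- complete_days(hourly, min_hours)
  if (nrow(h) < 24L) {
    return(structure(NA_real_, reason = "fewer than 24 hourly values"))
  }
  x <- h$mean
  ok <- !is.na(x)
  xs <- x[ok]
  xbar <- mean(xs)
  tot <- mean((xs - xbar)^2)
  if (tot <= 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  d <- diff(x)
  adjacent <- diff(h$hour) == 1L
  d <- d[adjacent & !is.na(d)]
  if (!length(d)) {
    return(structure(NA_real_, reason = "no adjacent hour pairs"))
  }
  mean(d^2) / tot
}

#' M10, L5 and relative amplitude
#'
#' Per noon-to-noon day, the maximum mean over contiguous 10-hour windows
#' (M10) and minimum mean over contiguous 5-hour windows (L5), sliding at
#' epoch resolution with windows fully inside the day (no wrap-around). The
#' default aggregation averages the daily RA values
#' (`RA_day = (M10 - L5)/(M10 + L5)`) across days; `method = "average_profile"`
#' instead averages daily M10 and L5 first and forms RA from those means.
#' Days with under `min_hours` worn hours, and days where M10 + L5 = 0, are
#' dropped (counted in the `n_dropped_days` attribute).
#'
#' @param series An [epoch_series()].
#' @param method `"daily"` (default) or `"average_profile"`.
#' @param min_hours Minimum worn hours for a day to be used (default 20).
#' @return List with `M10`, `L5`, `RA`, `n_valid_days`; `NA` values (with
#'   attribute `n_dropped_days`) when no day qualifies.
#' @export
relative_amplitude <- function(series, method = c("daily", "average_profile"),
                               min_hours = 20L) {
  stopifnot(inherits(series, "epoch_series"))
  method <- match.arg(method)
  per_day <- epochs_per_day(series)
  nd <- length(series$values) %/% per_day
  w10 <- 10L * 3600L %/% series$epoch_s
  w5 <- 5L * 3600L %/% series$epoch_s
  per_hour <- 3600L %/% series$epoch_s

  m10 <- l5 <- ra <- numeric(0)
  dropped <- 0L
  for (d in seq_len(nd)) {
    sl <- ((d - 1L) * per_day + 1L):(d * per_day)
    v <- series$values[sl]
    worn <- series$wear[sl]
    if (sum(worn) < min_hours * per_hour) {
      dropped <- dropped + 1L
      next
    }
    # worn-hour requirement met; window means treat non-worn epochs as the
    # day's worn mean so sparse non-wear does not bias window extremes
    if (any(!worn)) {
      v[!worn] <- mean(v[worn])
    }
    cs <- c(0, cumsum(v))
    win_mean <- function(w) (cs[(w + 1L):(per_day + 1L)] - cs[1L:(per_day - w + 1L)]) / w
    M <- max(win_mean(w10))
    L <- min(win_mean(w5))
    if (M + L <= 0) {
      dropped <- dropped + 1L
      next
    }
    m10 <- c(m10, M)
    l5 <- c(l5, L)
    ra <- c(ra, (M - L) / (M + L))
  }
  if (!length(m10)) {
    return(structure(list(M10 = NA_real_, L5 = NA_real_, RA = NA_real_,
                          n_valid_days = 0L), n_dropped_days = dropped))
  }
  RA <- if (method == "daily") {
    mean(ra)
  } else {
    (mean(m10) - mean(l5)) / (mean(m10) + mean(l5))
  }
  structure(list(M10 = mean(m10), L5 = mean(l5), RA = RA,
                 n_valid_days = length(m10)),
            n_dropped_days = dropped)
}

#' All rhythm metrics for one participant
#'
#' Convenience wrapper computing AA, M10, L5, RA, IS and IV from one epoch
#' series.
#'
#' @param series An [epoch_series()].
#' @param bin_min Bin width in minutes for the IS/IV substrate (default 60).
#' @param ra_method Passed to [relative_amplitude()].
#' @param min_hours Day-completeness threshold in hours (default 20).
#' @return One-row data.frame with columns `AA`, `M10`, `L5`, `RA`, `IS`,
#'   `IV`, `n_valid_days`.
#' @export
rhythm_metrics <- function(series, bin_min = 60, ra_method = "daily",
                           min_hours = 20L) {
  stopifnot(bin_min == 60)  # hourly bins; other widths not supported yet
  hourly <- bin_hourly(series)
  ra <- relative_amplitude(series, method = ra_method, min_hours = min_hours)
  data.frame(
    AA = average_acceleration(series),
    M10 = ra$M10, L5 = ra$L5, RA = ra$RA,
    IS = as.numeric(interdaily_stability(hourly, min_hours)),
    IV = as.numeric(intradaily_variability(hourly, min_hours)),
    n_valid_days = ra$n_valid_days
  )
}
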
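#' Sleep-window detection and summary metrics
#'
#' Detects one main sleep period per noon-to-noon day as the longest
#' contiguous block of smoothed low activity, then summarises mean sleep
#' duration (hours asleep within the window), mean sleep efficiency (slept
#' time as a proportion of the in-bed window) and the standard short /
#' regular / long duration categories. The detector is a documented
#' threshold heuristic on magnitude epochs: activity is smoothed with a
#' rolling median, an epoch is "low" when the smoothed value falls below a
#' fraction of the participant's median daytime activity, and the sleep
#' window is the longest low block of at least `min_block_h` hours. Naps are
#' deliberately not scored: only the single main window per day counts.
#'
#' @name sleep_metrics
NULL

# Median worn activity between 09:00 and 21:00 over the whole record.
daytime_median <- function(series) {
  t_h <- (seq_along(series$values) - 1L) * series$epoch_s / 3600
  clock <- (as.numeric(format(series$start, "%H")) +
              as.numeric(format(series$start, "%M")) / 60 + t_h) %% 24
  day_idx <- clock >= 9 & clock < 21 & series$wear
  if (!any(day_idx)) {
    return(NA_real_)
  }
  stats::median(series$values[day_idx])
}

#' Detect the sleep window of one day
#'
#' @param series An [epoch_series()] starting at noon.
#' @param day 1-based noon-to-noon day index.
#' @param theta_frac Threshold as a fraction of the participant's median
#'   daytime (09:00-21:00) activity (default 0.1).
#' @param min_block_h Minimum window length in hours (default 3).
#' @param median_min Rolling-median smoothing width in minutes (default 30).
#' @param min_wear_h Minimum worn hours for the day to be scored (default 20).
#' @return A list (`sleep_window`) with `day`, `valid`, `onset`, `offset`
#'   (POSIXct), `window_hours`, `slept_hours`, and `reason` when invalid.
#' @export
detect_sleep_window <- function(series, day, theta_frac = 0.1, min_block_h = 3,
                                median_min = 30, min_wear_h = 20) {
  stopifnot(inherits(series, "epoch_series"))
  per_day <- epochs_per_day(series)
  nd <- length(series$values) %/% per_day
  if (day < 1 || day > nd) {
    stop("day out of range: ", day, call. = FALSE)
  }
  invalid <- function(reason) {
    list(day = day, valid = FALSE, onset = NA, offset = NA,
         window_hours = NA_real_, slept_hours = NA_real_, reason = reason)
  }
  sl <- ((day - 1L) * per_day + 1L):(day * per_day)
  v <- series$values[sl]
  worn <- series$wear[sl]
  per_hour <- 3600L %/% series$epoch_s
  if (sum(worn) < min_wear_h * per_hour) {
    return(invalid("insufficient wear"))
  }
  theta <- theta_frac * daytime_median(series)
  if (is.na(theta)) {
    return(invalid("no daytime activity to set threshold"))
  }
  k <- max(3L, round(median_min * 60 / series$epoch_s))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
  smoothed <- stats::runmed(v, k, endrule = "median")
  low <- smoothed < theta
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_block_h * per_hour)
  if (!length(cand)) {
    return(invalid("no low-activity block of minimum length"))
  }
  best <- cand[which.max(r$lengths[cand])]
  i0 <- starts[best]
  i1 <- ends[best]
  window_ep <- i1 - i0 + 1L
  slept_ep <- sum(v[i0:i1] < theta)
  day_start <- series$start + (day - 1L) * 86400
  list(
    day = day, valid = TRUE,
    onset = day_start + (i0 - 1L) * series$epoch_s,
    offset = day_start + i1 * series$epoch_s,
    window_hours = window_ep * series$epoch_s / 3600,
    slept_hours = slept_ep * series$epoch_s / 3600,
    reason = NA_character_
  )
}

#' Summarise nightly sleep windows
#'
#' @param windows List of sleep windows from [detect_sleep_window()].
#' @return A list (`sleep_metrics`) with `mean_sleep_duration` (hours),
#'   `mean_sleep_efficiency` (mean over nights of slept/window),
#'   `duration_category` and `n_valid_nights`. With zero valid nights the
#'   metrics are `NA` and `reason` says so.
#' @export
summarise_sleep <- function(windows) {
  valid <- Filter(function(w) isTRUE(w$valid), windows)
  if (!length(valid)) {
    return(list(mean_sleep_duration = NA_real_,
                mean_sleep_efficiency = NA_real_,
                duration_category = NA_character_,
                n_valid_nights = 0L, reason = "no valid nights"))
  }
  dur <- vapply(valid, function(w) w$slept_hours, numeric(1))
  eff <- vapply(valid, function(w) w$slept_hours / w$window_hours, numeric(1))
  list(
    mean_sleep_duration = mean(dur),
    mean_sleep_efficiency = mean(eff),
    duration_category = categorize_sleep_duration(mean(dur)),
    n_valid_nights = length(valid),
    reason = NA_character_
  )
}

#' Sleep metrics for one participant
#'
#' Runs the window detector on every day of a series and summarises.
#'
#' @param series An [epoch_series()].
#' @inheritParams detect_sleep_window
#' @return One-row data.frame with `sleep_duration_h`, `sleep_efficiency`,
#'   `sleep_duration_cat`, `n_valid_nights`.
#' @export
sleep_metrics <- function(series, theta_frac = 0.1, min_block_h = 3,
                          median_min = 30, min_wear_h = 20) {
  nd <- floor(n_days(series))
  windows <- lapply(seq_len(nd), function(d)
    detect_sleep_window(series, d, theta_frac, min_block_h, median_min,
                        min_wear_h))
  s <- summarise_sleep(windows)
  data.frame(
    sleep_duration_h = s$mean_sleep_duration,
    sleep_efficiency = s$mean_sleep_efficiency,
    sleep_duration_cat = s$duration_category,
    n_valid_nights = s$n_valid_nights,
    stringsAsFactors = FALSE
  )
}

#' Categorise a sleep duration
#'
#' Short is under 7 h, long is over 9 h, regular is between 7 and 9 h with
#' both endpoints regular.
#'
#' @param hours Nonnegative sleep duration(s) in hours; `NA` allowed.
#' @return Character vector in `{"short", "regular", "long"}`.
#' @examples
#' categorize_sleep_duration(c(6.9, 7, 9, 9.5))
#' @export
categorize_sleep_duration <- function(hours) {
  if (any(!is.na(hours) & hours < 0)) {
    stop("sleep duration must be nonnegative", call. = FALSE)
  }
  ifelse(is.na(hours), NA_character_,
         ifelse(hours < 7, "short", ifelse(hours > 9, "long", "regular")))
}
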
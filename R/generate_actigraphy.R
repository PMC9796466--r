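#' Simulate a wrist-accelerometer epoch series
#'
#' Signal model: days run noon-to-noon. While awake, expected activity is
#' `mesor + amplitude * max(0, cos(2*pi*(clock - peak)/24))` milli-g, with
#' nonnegative (truncated-at-zero) Gaussian noise added per epoch. One main
#' sleep window is drawn per day: onset clock time and in-bed length come
#' from the participant-level parameters, both perturbed per night; within
#' the window activity is zero except for isolated wake bouts (probability
#' `p_wake_epoch` per epoch), which revert to waking-level activity. The
#' day-to-day phase jitter shifts both the diurnal peak and the sleep onset
#' of the whole day, and daytime fragmentation inserts low-activity bouts at
#' rate `frag_rate` per waking hour. Setting `window_mean = 0` disables the
#' sleep window entirely (a purely diurnal signal).
#'
#' @param params Actigraphy parameter list, as one `$actigraphy` block of
#'   [default_group_params()]: `mesor`, `amplitude`, `noise_sd` (milli-g),
#'   `peak_hour`, `onset_mean`, `onset_sd`, `window_mean`, `window_sd`,
#'   `window_night_sd`, `jitter_sd` (hours), `frag_rate` (bouts per waking
#'   hour), `frag_bout_min` (minutes), `p_wake_epoch`.
#' @param seed Integer seed; output is deterministic given it.
#' @param n_days Number of whole recording days.
#' @param epoch_s Epoch length in seconds (divisor of 3600).
#' @param start Start timestamp (noon); defaults to 2015-06-01 12:00 UTC.
#' @param p_nonwear Fraction of epochs flagged non-wear (at random).
#'
#' @return An [epoch_series()] of `n_days * 86400 / epoch_s` epochs, with
#'   attribute `truth`: a data.frame of the per-day generated sleep onset and
#'   offset (hours from the day's noon) for validation against detectors.
#' @examples
#' p <- default_group_params()$CONTROL$actigraphy
#' es <- generate_actigraphy(p, seed = 1, n_days = 2)
#' average_acceleration(es)
#' @export
generate_actigraphy <- function(params, seed, n_days = 7, epoch_s = 60,
                                start = as.POSIXct("2015-06-01 12:00:00", tz = "UTC"),
                                p_nonwear = 0) {
  stopifnot(3600 %% epoch_s == 0, n_days >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  per_day <- 86400L %/% as.integer(epoch_s)
  n_ep <- per_day * n_days
  epoch_h <- epoch_s / 3600
  # day/time-of-day from integer epoch indices so that parameter-identical
  # days are bit-identical (exact periodicity at zero jitter)
  ep <- seq_len(n_ep) - 1L
  day <- ep %/% per_day                      # 0-based day index
  within_day_h <- (ep %% per_day) * epoch_h  # hours since the day's noon
  clock <- (12 + within_day_h) %% 24

  jitter <- stats::rnorm(n_days, 0, params$jitter_sd)

  # participant-level sleep anchors, perturbed per night
  has_sleep <- params$window_mean > 0
  if (has_sleep) {
    onset0 <- stats::rnorm(1, params$onset_mean, params$onset_sd)
    win0 <- max(3, stats::rnorm(1, params$window_mean, params$window_sd))
    onset_d <- ((onset0 - 12) %% 24) + jitter            # hours from noon
    win_d <- pmax(3, win0 + stats::rnorm(n_days, 0, params$window_night_sd))
    offset_d <- pmin(onset_d + win_d, 24 - epoch_h)      # keep inside the day
    onset_d <- pmax(pmin(onset_d, 24 - 3), 0)
  } else {
    onset_d <- rep(NA_real_, n_days)
    offset_d <- rep(NA_real_, n_days)
  }

  asleep <- if (has_sleep) {
    within_day_h >= onset_d[day + 1L] & within_day_h < offset_d[day + 1L]
  } else {
    rep(FALSE, n_ep)
  }

  peak_d <- params$peak_hour + jitter
  diurnal <- params$amplitude * pmax(0, cos(2 * pi * (clock - peak_d[day + 1L]) / 24))
  noise <- if (params$noise_sd > 0) {
    pmax(0, stats::rnorm(n_ep, 0, params$noise_sd))
  } else {
    numeric(n_ep)
  }
  wake_val <- params$mesor + diurnal + noise

  values <- ifelse(asleep, 0, wake_val)

  # wake bouts inside the sleep window revert to waking-level activity
  if (has_sleep && params$p_wake_epoch > 0) {
    wake_bout <- asleep & stats::runif(n_ep) < params$p_wake_epoch
    values[wake_bout] <- wake_val[wake_bout]
  }

  # daytime fragmentation: low-activity bouts at frag_rate per waking hour
  if (params$frag_rate > 0) {
    starts <- which(!asleep & stats::runif(n_ep) < params$frag_rate * epoch_h)
    if (length(starts)) {
      bout_ep <- max(1L, round(params$frag_bout_min * 60 / epoch_s))
      idx <- unique(unlist(lapply(starts, function(s) s:min(s + bout_ep - 1L, n_ep))))
      idx <- idx[!asleep[idx]]
      values[idx] <- 0
    }
  }

  wear <- rep(TRUE, n_ep)
  if (p_nonwear > 0) {
    wear[stats::runif(n_ep) < p_nonwear] <- FALSE
  }

  es <- epoch_series(values, start = start, epoch_s = epoch_s, wear = wear)
  attr(es, "truth") <- data.frame(day = seq_len(n_days),
                                  onset_h = onset_d, offset_h = offset_d)
  es
}

# Save/restore the global RNG state so generators can be called inside
# other seeded code without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
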
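#' Clean a CGM stream
#'
#' Drops the warm-up period of each sensor (the first `warmup_hours` of
#' readings from every device, counted from that device's first reading) and
#' flags the person ineligible when the remaining coverage does not exceed
#' `min_hours`. Coverage is reading count times the nominal inter-reading
#' interval.
#'
#' @param series Data frame with `timestamp`, `glucose`, `device_id` (and
#'   usually `person_id`).
#' @param warmup_hours Hours discarded at the start of each device.
#' @param min_hours Minimum remaining coverage (strictly greater than) for
#'   eligibility.
#' @param interval_min Nominal reading interval in minutes, used to convert
#'   reading counts to hours.
#' @return List with `series` (the cleaned stream), `eligible` (logical),
#'   `hours` (remaining coverage) and `n_dropped`.
#' @export
#' @examples
#' s <- simulate_glucose_series(list(glu_mean = 180, glu_sd = 50,
#'                                   ar1_phi = 0.9), 5, seed = 1)
#' clean_glucose(s)$hours
clean_glucose <- function(series, warmup_hours = 24, min_hours = 72,
                          interval_min = 5) {
  if (is.null(series) || nrow(series) == 0) {
    return(list(series = series, eligible = FALSE, hours = 0, n_dropped = 0L))
  }
  keep <- rep(TRUE, nrow(series))
  for (dev in unique(series$device_id)) {
    i <- series$device_id == dev
    t0 <- min(series$timestamp[i])
    keep[i] <- as.numeric(series$timestamp[i] - t0, units = "hours") >=
      warmup_hours
  }
  cleaned <- series[keep, , drop = FALSE]
  hours <- nrow(cleaned) * interval_min / 60
  list(series = cleaned, eligible = hours > min_hours, hours = hours,
       n_dropped = sum(!keep))
}

#' Person-level glycemic summary metrics
#'
#' Computes the standard CGM summary metrics over a cleaned stream: mean and
#' SD (n-1 denominator) of glucose, coefficient of variation
#' (100 * SD / mean), and percent of readings in the consensus bands.
#' Band conventions: in-range is inclusive 70-180 mg/dL; below-70 and
#' below-54 are strict `<`; above-180 and above-250 are strict `>`. "Percent
#' time" is the fraction of readings, which at a fixed reading cadence equals
#' time weighting.
#'
#' @param series Cleaned CGM data frame with a `glucose` column.
#' @param interval_min Nominal reading interval (minutes), for the coverage
#'   field.
#' @return One-row data frame: `gluMean`, `gluSD`, `gluCV`,
#'   `gluInRange70_180`, `gluBelow70`, `gluBelow54`, `gluAbove180`,
#'   `gluAbove250` (percent), `nReadings`, `gluHours`.
#' @export
#' @examples
#' glycemic_profile(data.frame(glucose = c(60, 80, 100, 200, 260)))
glycemic_profile <- function(series, interval_min = 5) {
  g <- series$glucose
  if (length(g) < 2) {
    stop("glycemic_profile needs at least 2 readings", call. = FALSE)
  }
  pct <- function(x) 100 * mean(x)
  data.frame(
    gluMean = mean(g),
    gluSD = sd(g),
    gluCV = 100 * sd(g) / mean(g),
    gluInRange70_180 = pct(g >= 70 & g <= 180),
    gluBelow70 = pct(g < 70),
    gluBelow54 = pct(g < 54),
    gluAbove180 = pct(g > 180),
    gluAbove250 = pct(g > 250),
    nReadings = length(g),
    gluHours = length(g) * interval_min / 60)
}

#' Align CGM readings to EMA sessions
#'
#' For every session with a start time, selects the most recent reading in the
#' half-open window `[start - window_min, start)`; a reading exactly at the
#' session start is outside the window. Sessions with no reading in the
#' window contribute no observation.
#'
#' @param series Cleaned CGM data frame (`timestamp`, `glucose`).
#' @param sessions Data frame with `person_id`, `session_index`, `start_time`.
#' @param window_min Look-back window, minutes.
#' @return Data frame of aligned observations: `person_id`, `session_index`,
#'   `start_time`, `glucose_raw`.
#' @export
align_glucose_to_ema <- function(series, sessions, window_min = 5) {
  present <- sessions[!is.na(sessions$start_time), , drop = FALSE]
  if (nrow(present) == 0) {
    return(data.frame(person_id = character(), session_index = integer(),
                      glucose_raw = numeric()))
  }
  ts <- as.numeric(series$timestamp)
  rows <- lapply(seq_len(nrow(present)), function(i) {
    t1 <- as.numeric(present$start_time[i])
    in_win <- ts >= t1 - window_min * 60 & ts < t1
    if (!any(in_win)) return(NULL)
    k <- which(in_win)[which.max(ts[in_win])]
    data.frame(person_id = present$person_id[i],
               session_index = present$session_index[i],
               start_time = present$start_time[i],
               glucose_raw = series$glucose[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(person_id = character(), session_index = integer(),
                      glucose_raw = numeric())
  }
  out
}

#' Within-person centering and scaling of aligned glucose
#'
#' Centers each person's aligned glucose at that person's mean and, when
#' `scale = TRUE`, divides by that person's SD (n-1 denominator), so the
#' model's exposure is in person-SD units. The person mean and SD are
#' computed from the aligned values entering the model, not the full CGM
#' stream.
#'
#' @param observations Aligned observations (one row per person-session) with
#'   `person_id` and `glucose_raw`.
#' @param scale Scale by the person SD? When `FALSE`, `glucose_scaled` equals
#'   `glucose_centered` (centering-only robustness variant).
#' @return The input with `glucose_centered`, `glucose_scaled`,
#'   `person_glu_mean`, `person_glu_sd` columns added.
#' @export
#' @examples
#' obs <- data.frame(person_id = "a", glucose_raw = c(100, 150, 200))
#' center_scale_within_person(obs)$glucose_scaled
center_scale_within_person <- function(observations, scale = TRUE) {
  split_idx <- split(seq_len(nrow(observations)), observations$person_id)
  observations$glucose_centered <- NA_real_
  observations$glucose_scaled <- NA_real_
  observations$person_glu_mean <- NA_real_
  observations$person_glu_sd <- NA_real_
  for (idx in split_idx) {
    g <- observations$glucose_raw[idx]
    if (length(g) < 2) {
      stop("person ", observations$person_id[idx[1]],
           " has fewer than 2 aligned observations", call. = FALSE)
    }
    m <- mean(g)
    s <- sd(g)
    if (scale && s == 0) {
      stop("person ", observations$person_id[idx[1]],
           " has zero glucose SD; cannot scale", call. = FALSE)
    }
    observations$glucose_centered[idx] <- g - m
    observations$glucose_scaled[idx] <-
      if (scale) (g - m) / s else g - m
    observations$person_glu_mean[idx] <- m
    observations$person_glu_sd[idx] <- s
  }
  observations
}
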
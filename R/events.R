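# Detection of pivoting motions (large crossing-angle excursions with
# return) and handedness interconversions (sign changes of the crossing
# angle), and attribution of helix rotations to detected events.

# Turning points of a series after hysteresis pruning: alternating local
# extrema such that every swing between consecutive extrema is >= min_swing.
# Endpoints are always included. Returns indices into x.
turning_points <- function(x, min_swing) {
  n <- length(x)
  if (n < 2L) return(seq_len(n))
  idx <- 1L
  dir <- 0L               # +1 rising, -1 falling, 0 undecided
  imin <- 1L; imax <- 1L  # running extremes while undecided
  ext <- 1L               # running extreme while decided
  for (i in 2:n) {
    if (dir == 0L) {
      if (x[i] <= x[imin]) imin <- i
      if (x[i] >= x[imax]) imax <- i
      if (x[imax] - x[imin] >= min_swing) {
        if (imax > imin) { dir <- 1L; ext <- imax }
        else { dir <- -1L; ext <- imin }
      }
    } else if (dir == 1L) {
      if (x[i] >= x[ext]) ext <- i
      else if (x[ext] - x[i] >= min_swing) {
        idx <- c(idx, ext); dir <- -1L; ext <- i
      }
    } else {
      if (x[i] <= x[ext]) ext <- i
      else if (x[i] - x[ext] >= min_swing) {
        idx <- c(idx, ext); dir <- 1L; ext <- i
      }
    }
  }
  if (dir != 0L && ext != n && !ext %in% idx) idx <- c(idx, ext)
  if (idx[length(idx)] != n) idx <- c(idx, n)
  idx
}

#' Detect pivoting motions in a crossing-angle series
#'
#' A pivot is a transient excursion of the (smoothed) crossing angle away
#' from its pre-excursion baseline and back: the series leaves the baseline
#' hysteresis band, and the total crossing-angle change spanned by the
#' excursion — the range max - min of the smoothed series over the
#' excursion window, from the last in-band turning point through the first
#' turning point after the return — is at least `threshold`. This captures
#' excursions whose outbound and return swings together exceed the
#' threshold (e.g. a swing -6.4 to -51 returning past baseline to +4.6
#' spans 55.6 degrees). Chatter below the hysteresis band (default 25% of
#' the threshold) is absorbed before windows are formed, which merges
#' overlapping sub-excursions.
#'
#' @param omega crossing-angle series in degrees (length >= 3).
#' @param time optional time stamps (default frame indices starting at 0).
#' @param threshold minimum excursion magnitude in degrees, > 0. Default 45
#'   (the crossing-angle change needed to enable helix rotation); 40 is a
#'   noted alternative preset.
#' @param smoothing_window centered moving-average window (frames) used for
#'   detection only; reported angles are raw values.
#' @param hysteresis baseline band half-width in degrees (default
#'   0.25 * threshold).
#' @return data.frame of class `event_table` with one row per pivot:
#'   kind, start_time, peak_time, end_time, omega_start, omega_peak,
#'   omega_end, excursion_deg.
#' @export
detect_pivots <- function(omega, time = NULL, threshold = 45,
                          smoothing_window = 5L,
                          hysteresis = 0.25 * threshold) {
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  if (length(omega) < 3L)
    stop("need at least 3 frames to detect pivots", call. = FALSE)
  if (is.null(time)) time <- seq_along(omega) - 1
  sm <- moving_average(omega, smoothing_window)
  tp <- turning_points(sm, hysteresis)
  events <- empty_events()
  if (length(tp) < 2L) return(events)
  base <- sm[tp[1L]]
  anchor <- tp[1L]          # last in-band turning point
  k <- 2L
  while (k <= length(tp)) {
    v <- sm[tp[k]]
    if (abs(v - base) <= hysteresis) {
      base <- v; anchor <- tp[k]; k <- k + 1L; next
    }
    # excursion begins at tp[k]; find the return turning point
    r <- k + 1L
    ret <- NA_integer_
    while (r <= length(tp)) {
      vr <- sm[tp[r]]
      if (abs(vr - base) <= hysteresis ||
          sign(vr - base) != sign(v - base)) { ret <- r; break }
      r <- r + 1L
    }
    if (is.na(ret)) break   # excursion never returns: not a pivot
    win <- anchor:tp[ret]
    rng <- max(sm[win]) - min(sm[win])
    if (rng >= threshold) {
      dev <- abs(sm[win] - base)
      peak <- win[which.max(dev)]
      events <- rbind(events, data.frame(
        kind = "pivot",
        start_time = time[anchor], peak_time = time[peak],
        end_time = time[tp[ret]],
        omega_start = omega[anchor], omega_peak = omega[peak],
        omega_end = omega[tp[ret]],
        excursion_deg = rng, stringsAsFactors = FALSE))
    }
    base <- sm[tp[ret]]
    anchor <- tp[ret]
    k <- ret + 1L
  }
  class(events) <- c("event_table", "data.frame")
  events
}

empty_events <- function() {
  structure(data.frame(kind = character(), start_time = numeric(),
                       peak_time = numeric(), end_time = numeric(),
                       omega_start = numeric(), omega_peak = numeric(),
                       omega_end = numeric(), excursion_deg = numeric(),
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

#' Detect handedness interconversions (sign changes of the crossing angle)
#'
#' One event per sign change of the smoothed crossing angle that exits the
#' dead band on both sides: the series must have been beyond `dead_band` on
#' one side and subsequently reach beyond it on the other. The event time
#' is the linearly interpolated zero crossing.
#'
#' @param omega crossing-angle series in degrees.
#' @param time optional time stamps (default frame indices starting at 0).
#' @param dead_band half-width in degrees of the band around zero that must
#'   be exited on both sides (default 5).
#' @param smoothing_window centered moving-average window for detection.
#' @return data.frame of class `event_table` with one row per flip: kind,
#'   start_time, peak_time, end_time (all the crossing time), omega_start /
#'   omega_end (signed armed values before/after), excursion_deg (their
#'   absolute difference).
#' @export
detect_handedness_flips <- function(omega, time = NULL, dead_band = 5,
                                    smoothing_window = 5L) {
  stopifnot_scalar(dead_band, "dead_band", nonneg = TRUE)
  if (is.null(time)) time <- seq_along(omega) - 1
  sm <- moving_average(omega, smoothing_window)
  events <- empty_events()
  armed <- 0L        # sign last armed beyond the dead band
  armed_i <- NA_integer_
  for (i in seq_along(sm)) {
    s <- if (sm[i] > dead_band) 1L else if (sm[i] < -dead_band) -1L else 0L
    if (s == 0L) next
    if (armed != 0L && s != armed) {
      # last sign change between the armed index and here
      seg <- armed_i:i
      ch <- which(sm[seg[-length(seg)]] * sm[seg[-1L]] <= 0)
      j <- seg[ch[length(ch)]]
      # linear interpolation between j and j+1
      x0 <- sm[j]; x1 <- sm[j + 1L]
      tc <- if (x1 == x0) time[j] else
        time[j] + (0 - x0) / (x1 - x0) * (time[j + 1L] - time[j])
      events <- rbind(events, data.frame(
        kind = "handedness_flip",
        start_time = tc, peak_time = tc, end_time = tc,
        omega_start = omega[armed_i], omega_peak = 0,
        omega_end = omega[i],
        excursion_deg = abs(omega[i] - omega[armed_i]),
        stringsAsFactors = FALSE))
    }
    armed <- s
    armed_i <- i
  }
  class(events) <- c("event_table", "data.frame")
  events
}

#' Attribute helix rotations to detected events
#'
#' For each event, the rotation change of each helix over the padded event
#' window, dtheta(end + pad) - dtheta(start - pad), is computed from a
#' rotation series on the same time base. Events are labeled "A-rotating",
#' "B-rotating", "both" or "neither" depending on which helices rotated by
#' at least `attribution_threshold` (default 50 degrees) in magnitude.
#' Events whose padded window falls outside the series are dropped with a
#' warning.
#'
#' @param events an `event_table` (pivots and/or flips).
#' @param series a `rotation_series` (see [rotation_timeseries()]).
#' @param pad window padding in time units (default 0).
#' @param attribution_threshold rotation magnitude in degrees that counts a
#'   helix as rotating.
#' @return the event table with added columns dtheta_A_deg, dtheta_B_deg,
#'   label.
#' @export
associate_rotations <- function(events, series, pad = 0,
                                attribution_threshold = 50) {
  if (!inherits(series, "rotation_series"))
    stop("'series' must be a rotation_series", call. = FALSE)
  if (!nrow(events)) {
    events$dtheta_A_deg <- numeric(0)
    events$dtheta_B_deg <- numeric(0)
    events$label <- character(0)
    return(events)
  }
  at <- function(v, t) stats::approx(series$time, v, xout = t, rule = 1)$y
  t0 <- events$start_time - pad
  t1 <- events$end_time + pad
  dA <- at(series$dtheta_A, t1) - at(series$dtheta_A, t0)
  dB <- at(series$dtheta_B, t1) - at(series$dtheta_B, t0)
  drop <- is.na(dA) | is.na(dB)
  if (any(drop)) {
    warning(sprintf("%d event(s) dropped: padded window outside the rotation series",
                    sum(drop)), call. = FALSE)
    events <- events[!drop, , drop = FALSE]
    dA <- dA[!drop]; dB <- dB[!drop]
  }
  rotA <- abs(dA) >= attribution_threshold
  rotB <- abs(dB) >= attribution_threshold
  events$dtheta_A_deg <- dA
  events$dtheta_B_deg <- dB
  events$label <- ifelse(rotA & rotB, "both",
                         ifelse(rotA, "A-rotating",
                                ifelse(rotB, "B-rotating", "neither")))
  events
}

#' Write events as JSON and/or CSV
#'
#' @param events an `event_table`.
#' @param json_path,csv_path output paths (NULL to skip either).
#' @return invisibly, the event table.
#' @export
write_events <- function(events, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(events, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(events, csv_path, row.names = FALSE, quote = FALSE)
  invisible(events)
}
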
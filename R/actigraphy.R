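# Heuristic sleep-period-time (SPT) window detection from wrist z-angle
# traces, and the sleep/circadian metrics derived from it. The detector
# works on sustained postural inactivity: a rolling median of the absolute
# epoch-to-epoch z-angle change is thresholded at a (scaled) low percentile
# of its own distribution, runs of sub-threshold epochs become inactivity
# bouts, nearby bouts merge into blocks, and the longest block in each
# noon-to-noon day is the SPT window.
#
# Epoch intervals are 1-based and half-open: [start, end) covers epochs
# start .. end-1, so duration in epochs is end - start.

#' Rolling median of the absolute z-angle change
#'
#' The absolute first difference of the z-angle (with the leading value
#' repeated so the series keeps its length) is smoothed with a centered
#' rolling median. The window spans `window_min` minutes rounded to an odd
#' number of epochs; edge windows are truncated.
#'
#' @param z_angle numeric vector of tilt angles in degrees.
#' @param window_min window length in minutes (default 5).
#' @param epoch_seconds epoch length in seconds (default 5).
#' @return numeric vector, same length as `z_angle`.
#' @export
rolling_median_abs_change <- function(z_angle, window_min = 5,
                                      epoch_seconds = 5) {
  n <- length(z_angle)
  if (n < 2L) stop("need at least two epochs")
  w <- round(window_min * 60 / epoch_seconds)
  if (w < 1L) stop("window must span at least one epoch")
  d <- abs(diff(z_angle))
  d <- c(d[1L], d)
  h <- floor(w / 2)                        # half-width; window = 2h+1 epochs
  if (h == 0L) return(d)
  out <- stats::runmed(d, 2L * h + 1L, endrule = "keep")
  edge <- seq_len(min(h, n))
  for (i in edge) out[i] <- stats::median(d[1L:min(n, i + h)])
  for (i in (n - edge + 1L)) out[i] <- stats::median(d[max(1L, i - h):n])
  as.numeric(out)
}

#' Movement threshold from the rolled angle-change series
#'
#' The threshold separating movement from non-movement epochs is a low
#' percentile of the rolled absolute-change series for one analysis day,
#' optionally scaled by a multiplier. The percentile is computed with the
#' linear-interpolation quantile definition (configurable via `type`, see
#' [stats::quantile]).
#'
#' @param rolled output of [rolling_median_abs_change].
#' @param percentile quantile level in (0, 1) (default 0.1).
#' @param multiplier scale factor applied to the percentile (default 1; the
#'   full detector uses 15, see [run_actigraphy]).
#' @param type quantile algorithm (default 7, linear interpolation).
#' @return single threshold in degrees.
#' @export
movement_threshold <- function(rolled, percentile = 0.1, multiplier = 1,
                               type = 7) {
  if (length(rolled) == 0L || anyNA(rolled)) {
    stop("rolled series must be nonempty and finite")
  }
  multiplier * stats::quantile(rolled, percentile, type = type,
                               names = FALSE)
}

#' Detect inactivity bouts from a non-movement mask
#'
#' Maximal runs of non-movement epochs lasting at least `min_duration_min`
#' minutes, returned as half-open 1-based epoch intervals in increasing
#' order. Shorter runs are discarded (strict minimum).
#'
#' @param nonmovement logical vector, `TRUE` where the rolled angle change
#'   is at or below the movement threshold.
#' @param min_duration_min minimum bout duration in minutes (default 30).
#' @param epoch_seconds epoch length in seconds (default 5).
#' @return data frame with columns `start`, `end`.
#' @export
detect_inactivity_bouts <- function(nonmovement, min_duration_min = 30,
                                    epoch_seconds = 5) {
  stopifnot(is.logical(nonmovement), !anyNA(nonmovement))
  r <- rle(nonmovement)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_ep <- min_duration_min * 60 / epoch_seconds
  keep <- r$values & r$lengths >= min_ep
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Merge inactivity bouts separated by short gaps into blocks
#'
#' Consecutive bouts whose gap is strictly shorter than `max_gap_min`
#' minutes are combined, transitively, into blocks spanning the first onset
#' to the last end.
#'
#' @param bouts data frame from [detect_inactivity_bouts]; must be sorted
#'   and disjoint.
#' @param max_gap_min maximum bridgeable gap in minutes, exclusive
#'   (default 60).
#' @param epoch_seconds epoch length in seconds (default 5).
#' @return data frame with columns `start`, `end`.
#' @export
merge_bouts_to_blocks <- function(bouts, max_gap_min = 60,
                                  epoch_seconds = 5) {
  if (nrow(bouts) == 0L) return(bouts)
  if (is.unsorted(bouts$start, strictly = TRUE) ||
      any(bouts$start[-1L] < bouts$end[-nrow(bouts)])) {
    stop("bouts must be sorted and disjoint")
  }
  gap_ep <- max_gap_min * 60 / epoch_seconds
  start <- bouts$start[1L]; end <- bouts$end[1L]
  out_start <- out_end <- integer(0)
  for (i in seq_len(nrow(bouts))[-1L]) {
    if (bouts$start[i] - end < gap_ep) {
      end <- bouts$end[i]
    } else {
      out_start <- c(out_start, start); out_end <- c(out_end, end)
      start <- bouts$start[i]; end <- bouts$end[i]
    }
  }
  data.frame(start = c(out_start, start), end = c(out_end, end))
}

#' Pick the sleep-period-time window from a day's inactivity blocks
#'
#' The SPT window is the longest inactivity block of the analysis day, with
#' sleep onset at the block start and waking time at its end; ties go to
#' the earliest block.
#'
#' @param blocks data frame from [merge_bouts_to_blocks].
#' @return one-row data frame with columns `onset`, `wake` (epochs), or
#'   `NULL` if the day has no blocks (SPT flagged missing).
#' @export
detect_spt_window <- function(blocks) {
  if (nrow(blocks) == 0L) return(NULL)
  len <- blocks$end - blocks$start
  i <- which(len == max(len))[1L]          # earliest of the longest
  data.frame(onset = blocks$start[i], wake = blocks$end[i])
}

#' Detect sleep episodes within an SPT window
#'
#' Epochs inside the SPT window are posture-stable when the rolling
#' absolute z-angle change is strictly below `angle_change_deg`; maximal
#' stable runs of at least `min_duration_min` minutes are the sleep
#' episodes. Episodes are separated by at least one non-stable epoch
#' (at 5-s epochs, the "at least 5 s of wakefulness" rule).
#'
#' @param z_angle the day's z-angle series in degrees.
#' @param spt one-row data frame from [detect_spt_window].
#' @param angle_change_deg stability threshold in degrees (default 5).
#' @param min_duration_min minimum episode duration in minutes (default 5).
#' @param window_min rolling-median window in minutes (default 5).
#' @param epoch_seconds epoch length in seconds (default 5).
#' @return data frame with columns `start`, `end` (half-open epoch
#'   intervals, disjoint, contained in the SPT window).
#' @export
detect_sleep_episodes <- function(z_angle, spt, angle_change_deg = 5,
                                  min_duration_min = 5, window_min = 5,
                                  epoch_seconds = 5) {
  if (is.null(spt) || spt$onset >= spt$wake) stop("invalid SPT window")
  if (spt$onset < 1L || spt$wake > length(z_angle) + 1L) {
    stop("SPT window lies outside the trace")
  }
  rolled <- rolling_median_abs_change(z_angle, window_min, epoch_seconds)
  stable <- rolled < angle_change_deg
  stable[seq_along(stable) < spt$onset | seq_along(stable) >= spt$wake] <-
    FALSE
  detect_inactivity_bouts(stable, min_duration_min, epoch_seconds)
}

# Sum of interval durations (epochs) falling outside [from, to)
.duration_outside <- function(intervals, from, to) {
  if (nrow(intervals) == 0L) return(0L)
  inside <- pmax(0L, pmin(intervals$end, to) - pmax(intervals$start, from))
  sum(intervals$end - intervals$start - inside)
}

# Midpoint (hours from day start) of the extreme moving-average window
.extreme_window_mid <- function(activity, window_h, epoch_seconds,
                                which = c("min", "max")) {
  which <- match.arg(which)
  w <- round(window_h * 3600 / epoch_seconds)
  n <- length(activity)
  if (w > n) return(NA_real_)
  cs <- c(0, cumsum(activity))
  means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
  i <- if (which == "min") which.min(means) else which.max(means)
  ((i - 1L) + w / 2) * epoch_seconds / 3600
}

#' Sleep and circadian metrics for one analysis day
#'
#' @param activity the day's activity series.
#' @param spt one-row data frame from [detect_spt_window].
#' @param episodes data frame from [detect_sleep_episodes].
#' @param bouts the day's inactivity bouts (pre-merge), used for diurnal
#'   inactivity.
#' @param epoch_seconds epoch length in seconds (default 5).
#' @return One-row data frame: `spt_duration_min`, `sleep_duration_min`,
#'   `sleep_efficiency` (sleep duration / SPT duration), `n_sleep_bouts`,
#'   `sleep_midpoint_min` (minutes from the noon day start),
#'   `l5_timing_h` (midpoint of the least-active 5-h window, hours since
#'   the previous midnight), `m10_timing_h` (most-active 10-h window,
#'   hours since the previous midday), `diurnal_inactivity_min` (inactivity
#'   bouts outside the SPT window).
#' @export
compute_day_metrics <- function(activity, spt, episodes, bouts,
                                epoch_seconds = 5) {
  if (is.null(spt) || spt$wake <= spt$onset) {
    stop("SPT window must have positive duration")
  }
  epm <- epoch_seconds / 60
  spt_min <- (spt$wake - spt$onset) * epm
  sleep_min <- sum(episodes$end - episodes$start) * epm
  mid_min <- ((spt$onset - 1L) + (spt$wake - 1L)) / 2 * epm
  l5_mid <- .extreme_window_mid(activity, 5, epoch_seconds, "min")
  m10_mid <- .extreme_window_mid(activity, 10, epoch_seconds, "max")
  data.frame(
    spt_duration_min = spt_min,
    sleep_duration_min = sleep_min,
    sleep_efficiency = sleep_min / spt_min,
    n_sleep_bouts = nrow(episodes),
    sleep_midpoint_min = mid_min,
    l5_timing_h = if (is.na(l5_mid)) NA_real_ else (l5_mid - 12) %% 24,
    m10_timing_h = m10_mid %% 24,
    diurnal_inactivity_min = .duration_outside(bouts, spt$onset,
                                               spt$wake) * epm
  )
}

#' Per-person summary across analysis days
#'
#' Sample mean and SD (n - 1 denominator) of sleep duration across days
#' with a detected SPT window, and means of the remaining metrics. Days
#' without an SPT window (all-`NA` rows) are excluded; with a single valid
#' day the SD is reported missing.
#'
#' @param days data frame of per-day rows from [compute_day_metrics].
#' @return one-row data frame of summaries plus `n_days`.
#' @export
summarize_person <- function(days) {
  valid <- days[!is.na(days$spt_duration_min), , drop = FALSE]
  if (nrow(valid) == 0L) stop("no days with a detected SPT window")
  data.frame(
    n_days = nrow(valid),
    sleep_duration_mean_min = mean(valid$sleep_duration_min),
    sleep_duration_sd_min = if (nrow(valid) > 1L) {
      stats::sd(valid$sleep_duration_min)
    } else NA_real_,
    spt_duration_mean_min = mean(valid$spt_duration_min),
    sleep_efficiency_mean = mean(valid$sleep_efficiency),
    n_sleep_bouts_mean = mean(valid$n_sleep_bouts),
    sleep_midpoint_mean_min = mean(valid$sleep_midpoint_min),
    l5_timing_mean_h = mean(valid$l5_timing_h),
    m10_timing_mean_h = mean(valid$m10_timing_h),
    diurnal_inactivity_mean_min = mean(valid$diurnal_inactivity_min)
  )
}

#' Run the full actigraphy pipeline on a recording
#'
#' Splits the recording into noon-to-noon analysis days (trimming any lead
#' before the first noon), then per day: rolls the absolute z-angle change,
#' derives the movement threshold as `threshold_multiplier` times the
#' `percentile` quantile of the rolled series, finds inactivity bouts,
#' merges them into blocks, takes the longest block as the SPT window, and
#' scores sleep episodes and all derived metrics. A day with no inactivity
#' block gets an all-`NA` metrics row.
#'
#' The default multiplier of 15 calibrates the percentile-based threshold
#' so that quiet-wear noise during sleep stays below it; set it to 1 to use
#' the raw percentile.
#'
#' @param trace an [accel_epochs] recording.
#' @param window_min rolling-median window, minutes (default 5).
#' @param percentile threshold quantile level (default 0.1).
#' @param threshold_multiplier scale on the percentile (default 15).
#' @param threshold_scope `"day"` recomputes the threshold per analysis
#'   day; `"recording"` uses one threshold for the whole recording.
#' @param bout_min minimum inactivity-bout duration, minutes (default 30).
#' @param gap_min maximum bridgeable gap between bouts, minutes
#'   (default 60).
#' @param angle_change_deg sleep-episode stability threshold, degrees
#'   (default 5).
#' @param episode_min minimum sleep-episode duration, minutes (default 5).
#' @return An object of class `actigraphy_result`: list with `days`
#'   (per-day metrics, including detected `onset`/`wake` epochs within the
#'   day), `person` (per-person summary), and `params`.
#' @export
run_actigraphy <- function(trace, window_min = 5, percentile = 0.1,
                           threshold_multiplier = 15,
                           threshold_scope = c("day", "recording"),
                           bout_min = 30, gap_min = 60,
                           angle_change_deg = 5, episode_min = 5) {
  stopifnot(inherits(trace, "accel_epochs"))
  threshold_scope <- match.arg(threshold_scope)
  eps <- trace$epoch_seconds
  epd <- round(86400 / eps)
  secs_of_day <- as.numeric(difftime(trace$start_time,
                                     trunc(trace$start_time, "days"),
                                     units = "secs"))
  lead <- round(((43200 - secs_of_day) %% 86400) / eps)  # epochs to noon
  n_days <- (length(trace$z_angle) - lead) %/% epd
  if (n_days < 1L) stop("recording must cover at least one full day")

  rolled_all <- rolling_median_abs_change(trace$z_angle, window_min, eps)
  rec_thr <- movement_threshold(rolled_all, percentile,
                                threshold_multiplier)
  na_row <- compute_day_metrics(numeric(epd),
                                data.frame(onset = 1L, wake = 2L),
                                data.frame(start = integer(0),
                                           end = integer(0)),
                                data.frame(start = integer(0),
                                           end = integer(0)), eps)
  na_row[1L, ] <- NA

  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    idx <- lead + (d - 1L) * epd + seq_len(epd)
    rolled <- rolling_median_abs_change(trace$z_angle[idx], window_min,
                                        eps)
    thr <- if (threshold_scope == "day") {
      movement_threshold(rolled, percentile, threshold_multiplier)
    } else rec_thr
    bouts <- detect_inactivity_bouts(rolled <= thr, bout_min, eps)
    blocks <- merge_bouts_to_blocks(bouts, gap_min, eps)
    spt <- detect_spt_window(blocks)
    if (is.null(spt)) {
      days[[d]] <- cbind(day = d, onset = NA_integer_, wake = NA_integer_,
                         na_row)
      next
    }
    episodes <- detect_sleep_episodes(trace$z_angle[idx], spt,
                                      angle_change_deg, episode_min,
                                      window_min, eps)
    days[[d]] <- cbind(day = d, onset = spt$onset, wake = spt$wake,
                       compute_day_metrics(trace$activity[idx], spt,
                                           episodes, bouts, eps))
  }
  days <- do.call(rbind, days)
  person <- if (all(is.na(days$spt_duration_min))) {
    warning("no day with a detected SPT window; person summary missing")
    NULL
  } else {
    summarize_person(days)
  }
  structure(list(person_id = trace$person_id, days = days,
                 person = person,
                 params = list(window_min = window_min,
                               percentile = percentile,
                               threshold_multiplier = threshold_multiplier,
                               threshold_scope = threshold_scope,
                               bout_min = bout_min, gap_min = gap_min,
                               angle_change_deg = angle_change_deg,
                               episode_min = episode_min)),
            class = "actigraphy_result")
}

#' @export
print.actigraphy_result <- function(x, ...) {
  cat(sprintf("<actigraphy_result> %s: %d day(s)\n", x$person_id,
              nrow(x$days)))
  print(x$person, row.names = FALSE)
  invisible(x)
}
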
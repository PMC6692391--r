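#' Accelerometer epoch series
#'
#' Container for a uniformly sampled wrist-accelerometer recording: one
#' z-angle value (degrees, dorsal--ventral tilt) and one activity magnitude
#' per epoch. The z-angle is near-constant while the wearer holds a posture
#' and jumps at posture changes, which is what the sleep detector exploits;
#' the activity channel only feeds the L5/M10 circadian metrics.
#'
#' @param z_angle numeric vector of tilt angles in degrees, within
#'   \[-90, 90\].
#' @param activity optional numeric vector of nonnegative activity
#'   magnitudes, same length as `z_angle`. Defaults to zeros.
#' @param epoch_seconds positive epoch length in seconds (default 5).
#' @param start_time `POSIXct` timestamp of the first epoch. Analysis days
#'   run noon-to-noon, so recordings conventionally start at 12:00.
#' @param person_id identifier carried through to output tables.
#'
#' @return An object of class `accel_epochs`.
#' @export
accel_epochs <- function(z_angle, activity = NULL, epoch_seconds = 5,
                         start_time = as.POSIXct("2020-01-01 12:00:00",
                                                 tz = "UTC"),
                         person_id = "person_1") {
  z_angle <- as.numeric(z_angle)
  if (length(z_angle) < 2L) {
    stop("an accelerometer series needs at least two epochs")
  }
  if (anyNA(z_angle) || any(z_angle < -90 | z_angle > 90)) {
    stop("z_angle must be finite and within [-90, 90] degrees")
  }
  if (is.null(activity)) activity <- numeric(length(z_angle))
  activity <- as.numeric(activity)
  if (length(activity) != length(z_angle)) {
    stop("activity and z_angle must have the same length")
  }
  if (anyNA(activity) || any(activity < 0)) {
    stop("activity must be finite and nonnegative")
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0) {
    stop("epoch_seconds must be a single positive number")
  }
  structure(
    list(person_id = person_id, epoch_seconds = epoch_seconds,
         start_time = start_time, z_angle = z_angle, activity = activity),
    class = "accel_epochs"
  )
}

#' @export
print.accel_epochs <- function(x, ...) {
  hours <- length(x$z_angle) * x$epoch_seconds / 3600
  cat(sprintf("<accel_epochs> %s: %d epochs of %gs (%.1f h) from %s\n",
              x$person_id, length(x$z_angle), x$epoch_seconds, hours,
              format(x$start_time)))
  invisible(x)
}

#' @export
length.accel_epochs <- function(x) length(x$z_angle)

#' z-angle from raw triaxial acceleration
#'
#' Converts calibrated triaxial acceleration (gravitational units) to the
#' dorsal--ventral tilt angle used by the sleep detector:
#' `atan(z / sqrt(x^2 + y^2))` in degrees.
#'
#' @param ax,ay,az numeric vectors of per-epoch mean acceleration.
#' @return numeric vector of angles in degrees within \[-90, 90\].
#' @export
z_angle_from_xyz <- function(ax, ay, az) {
  atan(az / sqrt(ax^2 + ay^2)) * 180 / pi
}

#' Read an accelerometer epoch series from CSV
#'
#' Expects columns `timestamp` (ISO-8601), either `z_angle_deg` or the raw
#' triaxial trio `ax`, `ay`, `az`, and optionally `activity`. The epoch
#' length is inferred from the first two timestamps unless given.
#'
#' @param path CSV file path.
#' @param epoch_seconds optional epoch length override in seconds.
#' @param person_id identifier for the recording; defaults to the file name.
#' @return An [accel_epochs] object.
#' @export
read_accel_csv <- function(path, epoch_seconds = NULL, person_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(df)) stop("missing 'timestamp' column")
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (is.null(epoch_seconds)) {
    epoch_seconds <- as.numeric(difftime(ts[2L], ts[1L], units = "secs"))
  }
  if ("z_angle_deg" %in% names(df)) {
    z <- df$z_angle_deg
  } else if (all(c("ax", "ay", "az") %in% names(df))) {
    z <- z_angle_from_xyz(df$ax, df$ay, df$az)
  } else {
    stop("need either a 'z_angle_deg' column or raw 'ax','ay','az' columns")
  }
  act <- if ("activity" %in% names(df)) df$activity else NULL
  accel_epochs(z, act, epoch_seconds = epoch_seconds, start_time = ts[1L],
               person_id = person_id %||% basename(path))
}

#' Write an accelerometer epoch series to CSV
#'
#' @param trace an [accel_epochs] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_epochs"))
  ts <- trace$start_time + (seq_along(trace$z_angle) - 1L) * trace$epoch_seconds
  utils::write.csv(
    data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
               z_angle_deg = trace$z_angle, activity = trace$activity),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
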
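#' Circular target trajectory
#'
#' Describes the pursuit stimulus: a dot moving on a circle of given radius
#' (degrees of visual angle) at a fixed rotational frequency, sampled at a
#' nominal tracker rate. Defaults match the standard circular-pursuit
#' paradigm: 10 degree radius, 0.4 Hz, 500 Hz sampling.
#'
#' @param radius circle radius in degrees of visual angle (> 0).
#' @param frequency rotational frequency in Hz (> 0).
#' @param direction `"counterclockwise"` or `"clockwise"`.
#' @param phase_origin starting polar angle in radians.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param duration recording duration in seconds (> 0).
#' @return An object of class `target_trajectory`.
#' @export
target_trajectory <- function(radius = 10, frequency = 0.4,
                              direction = c("counterclockwise", "clockwise"),
                              phase_origin = 0, sample_rate = 500,
                              duration = 30) {
  direction <- match.arg(direction)
  stopifnot(radius > 0, frequency > 0, sample_rate > 0, duration > 0)
  structure(
    list(radius = radius, frequency = frequency, direction = direction,
         phase_origin = phase_origin, sample_rate = sample_rate,
         duration = duration),
    class = "target_trajectory"
  )
}

#' @export
print.target_trajectory <- function(x, ...) {
  cat(sprintf(
    "Circular target: radius %g deg, %g Hz (%s), %g s at %g Hz\n",
    x$radius, x$frequency, x$direction, x$duration, x$sample_rate))
  invisible(x)
}

direction_sign <- function(trajectory) {
  if (trajectory$direction == "counterclockwise") 1 else -1
}

#' Target polar angle at given times
#' @param trajectory a [target_trajectory()].
#' @param times times in seconds.
#' @return angles in radians (unwrapped).
#' @keywords internal
target_angle <- function(trajectory, times) {
  trajectory$phase_origin +
    direction_sign(trajectory) * 2 * pi * trajectory$frequency * times
}

#' Target position at given times
#' @inheritParams target_angle
#' @return a two-column matrix `x`, `y` in degrees.
#' @export
target_position <- function(trajectory, times) {
  th <- target_angle(trajectory, times)
  cbind(x = trajectory$radius * cos(th), y = trajectory$radius * sin(th))
}

#' Target velocity at given times
#' @inheritParams target_angle
#' @return a two-column matrix `vx`, `vy` in degrees/second.
#' @export
target_velocity <- function(trajectory, times) {
  th <- target_angle(trajectory, times)
  om <- direction_sign(trajectory) * 2 * pi * trajectory$frequency
  cbind(vx = -trajectory$radius * om * sin(th),
        vy = trajectory$radius * om * cos(th))
}

sample_times <- function(trajectory) {
  n <- round(trajectory$duration * trajectory$sample_rate)
  (seq_len(n) - 1L) / trajectory$sample_rate
}
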
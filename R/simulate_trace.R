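#' Gaze simulator parameters
#'
#' Knobs controlling the synthetic eye-movement record: per-axis pursuit
#' gains, a phase offset (degrees of arc along the circle; negative = lag),
#' Gaussian positional noise expressed in the target's radial/tangential
#' frame, out-and-back ballistic saccades, blink-like missing runs, and a
#' constant calibration offset.
#'
#' @param gain_h,gain_v horizontal / vertical pursuit gain (>= 0, 1 = veridical).
#' @param phase_offset phase of the gaze relative to the target, in degrees
#'   of arc; negative values mean the gaze lags the target.
#' @param radial_noise_sd,tangential_noise_sd SD of Gaussian positional noise
#'   (degrees) along the radial / tangential directions of the target.
#' @param saccade_rate expected saccade count per second (Poisson).
#' @param saccade_amplitude peak saccade displacement in degrees.
#' @param saccade_speed_range range of saccade speeds in degrees/second.
#' @param missing_fraction fraction of samples marked invalid, in [0, 1).
#' @param missing_run_range range of missing-run durations in seconds
#'   (contiguous, blink-like).
#' @param calibration_offset length-2 constant gaze offset (degrees).
#' @param seed integer seed; the trace is a pure function of it.
#' @return An object of class `gaze_sim_params`.
#' @export
gaze_sim_params <- function(gain_h = 1, gain_v = 1, phase_offset = 0,
                            radial_noise_sd = 0, tangential_noise_sd = 0,
                            saccade_rate = 0, saccade_amplitude = 2,
                            saccade_speed_range = c(150, 300),
                            missing_fraction = 0,
                            missing_run_range = c(0.1, 0.3),
                            calibration_offset = c(0, 0), seed = NULL) {
  stopifnot(gain_h >= 0, gain_v >= 0,
            radial_noise_sd >= 0, tangential_noise_sd >= 0,
            saccade_rate >= 0, saccade_amplitude >= 0,
            missing_fraction >= 0, missing_fraction < 1,
            length(calibration_offset) == 2,
            length(missing_run_range) == 2, length(saccade_speed_range) == 2)
  structure(
    list(gain_h = gain_h, gain_v = gain_v, phase_offset = phase_offset,
         radial_noise_sd = radial_noise_sd,
         tangential_noise_sd = tangential_noise_sd,
         saccade_rate = saccade_rate, saccade_amplitude = saccade_amplitude,
         saccade_speed_range = saccade_speed_range,
         missing_fraction = missing_fraction,
         missing_run_range = missing_run_range,
         calibration_offset = calibration_offset, seed = seed),
    class = "gaze_sim_params"
  )
}

# Run `expr` under a local RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_gaze_trace <- function(times, x, y, valid, trajectory,
                           subject_id = NA_character_) {
  structure(
    list(times = times, x = x, y = y, valid = valid,
         trajectory = trajectory, subject_id = subject_id),
    class = "gaze_trace"
  )
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "Gaze trace '%s': %d samples at %g Hz, %.1f%% invalid\n",
    x$subject_id, length(x$times), x$trajectory$sample_rate,
    100 * mean(!x$valid)))
  invisible(x)
}

# Random composition of `total` into k non-negative gaps (for placing runs).
random_gaps <- function(total, k) {
  if (k == 1L) return(total)
  cuts <- sort(sample.int(total + k - 1L, k - 1L))
  diff(c(0L, cuts, total + k - 1L)) - 1L
}

#' Simulate a circular-pursuit gaze trace
#'
#' The smooth component is the target rotated along its circle by
#' `phase_offset` and scaled per axis by the gains; radial/tangential
#' Gaussian noise, out-and-back saccadic excursions, a calibration offset
#' and contiguous missing runs are then layered on. The result is a pure
#' function of `params$seed`.
#'
#' @param trajectory a [target_trajectory()].
#' @param params a [gaze_sim_params()].
#' @param subject_id identifier carried on the trace.
#' @return A `gaze_trace` with fields `times`, `x`, `y`, `valid`,
#'   `trajectory`, `subject_id`. Injected ground truth (saccade intervals,
#'   invalid count) is attached as attribute `"sim"` for validation.
#' @export
simulate_gaze_trace <- function(trajectory, params = gaze_sim_params(),
                                subject_id = "sim") {
  stopifnot(inherits(trajectory, "target_trajectory"),
            inherits(params, "gaze_sim_params"))
  with_seed(params$seed, {
    times <- sample_times(trajectory)
    n <- length(times)
    th <- target_angle(trajectory, times) +
      direction_sign(trajectory) * params$phase_offset * pi / 180
    x <- params$gain_h * trajectory$radius * cos(th)
    y <- params$gain_v * trajectory$radius * sin(th)

    # positional noise in the target's radial/tangential frame
    if (params$radial_noise_sd > 0 || params$tangential_noise_sd > 0) {
      th0 <- target_angle(trajectory, times)
      er <- stats::rnorm(n, 0, params$radial_noise_sd)
      et <- stats::rnorm(n, 0, params$tangential_noise_sd)
      ds <- direction_sign(trajectory)
      x <- x + er * cos(th0) + et * ds * (-sin(th0))
      y <- y + er * sin(th0) + et * ds * cos(th0)
    }

    # out-and-back ballistic saccades (triangular displacement profile)
    saccades <- matrix(numeric(0), ncol = 2)
    n_sac <- if (params$saccade_rate > 0)
      stats::rpois(1, params$saccade_rate * trajectory$duration) else 0L
    if (n_sac > 0) {
      speeds <- stats::runif(n_sac, params$saccade_speed_range[1],
                             params$saccade_speed_range[2])
      durs <- 2 * params$saccade_amplitude / speeds
      onsets <- sort(stats::runif(n_sac, 0, trajectory$duration - max(durs)))
      dirs <- stats::runif(n_sac, 0, 2 * pi)
      keep <- rep(TRUE, n_sac)
      if (n_sac > 1) # drop overlapping injections
        keep[-1] <- diff(onsets) > durs[-n_sac]
      for (i in which(keep)) {
        rel <- times - onsets[i]
        half <- durs[i] / 2
        disp <- ifelse(rel >= 0 & rel <= half, speeds[i] * rel,
                ifelse(rel > half & rel <= durs[i],
                       params$saccade_amplitude - speeds[i] * (rel - half), 0))
        x <- x + disp * cos(dirs[i])
        y <- y + disp * sin(dirs[i])
      }
      saccades <- cbind(onsets[keep], onsets[keep] + durs[keep])
    }

    x <- x + params$calibration_offset[1]
    y <- y + params$calibration_offset[2]

    # contiguous blink-like missing runs totalling missing_fraction
    valid <- rep(TRUE, n)
    m <- round(params$missing_fraction * n)
    if (m > 0) {
      fs <- trajectory$sample_rate
      lens <- integer(0)
      while (sum(lens) < m) {
        lens <- c(lens, max(1L, round(stats::runif(
          1, params$missing_run_range[1], params$missing_run_range[2]) * fs)))
      }
      over <- sum(lens) - m
      lens[length(lens)] <- lens[length(lens)] - over
      lens <- lens[lens > 0L]
      k <- length(lens)
      gaps <- random_gaps(n - m, k + 1L)
      pos <- 0L
      for (i in seq_len(k)) {
        start <- pos + gaps[i] + 1L
        valid[start:(start + lens[i] - 1L)] <- FALSE
        pos <- start + lens[i] - 1L
      }
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_

    tr <- new_gaze_trace(times, x, y, valid, trajectory, subject_id)
    attr(tr, "sim") <- list(saccade_intervals = saccades,
                            n_invalid = sum(!valid))
    tr
  })
}

#' Write / read a gaze trace as tab-delimited text
#'
#' The file carries a `#`-prefixed header block recording the trajectory
#' parameters and subject id, then columns `t_s`, `x_deg`, `y_deg`, `valid`.
#' Invalid samples have empty position fields.
#'
#' @param trace a `gaze_trace`.
#' @param path file path.
#' @return `write_gaze_trace()` returns `path` invisibly; `read_gaze_trace()`
#'   returns a `gaze_trace`.
#' @export
write_gaze_trace <- function(trace, path) {
  tj <- trace$trajectory
  header <- c(
    sprintf("# radius=%.17g", tj$radius),
    sprintf("# frequency=%.17g", tj$frequency),
    sprintf("# direction=%s", tj$direction),
    sprintf("# phase_origin=%.17g", tj$phase_origin),
    sprintf("# sample_rate=%.17g", tj$sample_rate),
    sprintf("# duration=%.17g", tj$duration),
    sprintf("# subject_id=%s", trace$subject_id),
    "t_s\tx_deg\ty_deg\tvalid")
  body <- sprintf("%.6f\t%s\t%s\t%d", trace$times,
                  ifelse(trace$valid, sprintf("%.6f", trace$x), ""),
                  ifelse(trace$valid, sprintf("%.6f", trace$y), ""),
                  as.integer(trace$valid))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_gaze_trace
#' @export
read_gaze_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# *", "", hdr), "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  tj <- target_trajectory(
    radius = as.numeric(vals["radius"]),
    frequency = as.numeric(vals["frequency"]),
    direction = vals[["direction"]],
    phase_origin = as.numeric(vals["phase_origin"]),
    sample_rate = as.numeric(vals["sample_rate"]),
    duration = as.numeric(vals["duration"]))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           na.strings = "")
  new_gaze_trace(tab$t_s, tab$x_deg, tab$y_deg, tab$valid == 1L, tj,
                 subject_id = vals[["subject_id"]])
}
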
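#' Screening thresholds for eye-movement records
#'
#' @param max_missing maximum tolerated invalid-sample fraction; a record is
#'   rejected when its missing fraction is strictly greater than this.
#' @param max_mean_offset calibration proxy: maximum magnitude (degrees) of
#'   the mean gaze-minus-target error vector.
#' @param max_median_jump head-stability proxy: maximum jump (degrees) of the
#'   200-ms running median of the gaze-minus-target position across one
#'   window width.
#' @param median_window running-median window in seconds.
#' @return An object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(max_missing = 0.10, max_mean_offset = 3,
                              max_median_jump = 5, median_window = 0.2) {
  structure(list(max_missing = max_missing,
                 max_mean_offset = max_mean_offset,
                 max_median_jump = max_median_jump,
                 median_window = median_window),
            class = "screen_thresholds")
}

#' Automated screening of a gaze record
#'
#' Applies the automated quality gate: a record fails for more than 10%
#' missing data (strict inequality), for a calibration artifact (mean
#' gaze-error vector larger than `max_mean_offset`), or for poor head
#' stabilization (a jump in the running median of gaze-minus-target larger
#' than `max_median_jump`).
#'
#' @param trace a `gaze_trace`.
#' @param thresholds a [screen_thresholds()].
#' @return A list of class `screen_verdict` with fields `valid`, `reasons`,
#'   `missing_fraction`.
#' @export
screen_trace <- function(trace, thresholds = screen_thresholds()) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (length(trace$times) < 2) stop("trace must have at least 2 samples")
  reasons <- character(0)
  missing_fraction <- mean(!trace$valid)
  if (missing_fraction > thresholds$max_missing)
    reasons <- c(reasons, "missing_fraction_exceeded")

  ok <- trace$valid
  if (any(ok)) {
    tp <- target_position(trace$trajectory, trace$times)
    ex <- trace$x - tp[, "x"]
    ey <- trace$y - tp[, "y"]
    off <- sqrt(mean(ex[ok])^2 + mean(ey[ok])^2)
    if (is.finite(off) && off > thresholds$max_mean_offset)
      reasons <- c(reasons, "calibration_artifact")

    k <- round(thresholds$median_window * trace$trajectory$sample_rate)
    if (k %% 2 == 0) k <- k + 1L
    exv <- ex[ok]; eyv <- ey[ok]
    if (length(exv) > 2L * k) {
      mx <- stats::runmed(exv, k)
      my <- stats::runmed(eyv, k)
      idx <- seq_len(length(mx) - k)
      jump <- sqrt((mx[idx + k] - mx[idx])^2 + (my[idx + k] - my[idx])^2)
      if (max(jump) > thresholds$max_median_jump)
        reasons <- c(reasons, "head_instability")
    }
  }
  structure(list(valid = length(reasons) == 0L, reasons = reasons,
                 missing_fraction = missing_fraction),
            class = "screen_verdict")
}

#' @export
print.screen_verdict <- function(x, ...) {
  cat(sprintf("Screening: %s (missing %.1f%%)%s\n",
              if (x$valid) "VALID" else "INVALID",
              100 * x$missing_fraction,
              if (x$valid) "" else paste0(" [", paste(x$reasons, collapse = ", "), "]")))
  invisible(x)
}

wrap_deg <- function(a) ((a + 180) %% 360) - 180

#' Gaze error in the target's moving frame
#'
#' Decomposes the per-sample error vector (gaze minus target) onto the unit
#' radial vector at the target's angular position (positive = outside the
#' circle) and the unit tangential vector along the direction of motion
#' (positive = lead). The phase error is the wrapped difference between the
#' gaze's and the target's polar angles, signed so that positive = lead.
#'
#' @param trace a `gaze_trace`.
#' @param trajectory the [target_trajectory()]; defaults to the one carried
#'   by the trace.
#' @return A data.frame with per-sample columns `radial_error`,
#'   `tangential_error`, `phase_error` (degrees; `NA` on invalid samples and,
#'   for phase, at gaze positions on the origin).
#' @export
to_target_frame <- function(trace, trajectory = trace$trajectory) {
  stopifnot(inherits(trace, "gaze_trace"))
  th <- target_angle(trajectory, trace$times)
  ds <- direction_sign(trajectory)
  ex <- trace$x - trajectory$radius * cos(th)
  ey <- trace$y - trajectory$radius * sin(th)
  radial <- ex * cos(th) + ey * sin(th)
  tangential <- ds * (-ex * sin(th) + ey * cos(th))
  gaze_angle <- atan2(trace$y, trace$x)
  phase <- ds * wrap_deg((gaze_angle - th) * 180 / pi)
  at_origin <- trace$valid & trace$x == 0 & trace$y == 0
  phase[at_origin] <- NA_real_
  out <- data.frame(radial_error = radial, tangential_error = tangential,
                    phase_error = phase)
  out[!trace$valid, ] <- NA_real_
  out
}

# Savitzky-Golay derivative of a (possibly gappy) series: applied per run of
# consecutive valid samples; runs shorter than the window give NA.
sg_derivative <- function(v, valid, fs, window = 21L, order = 2L) {
  out <- rep(NA_real_, length(v))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= window)) {
    idx <- starts[i]:ends[i]
    out[idx] <- signal::sgolayfilt(v[idx], p = order, n = window, m = 1,
                                   ts = 1 / fs)
  }
  out
}

#' Detect saccades by a speed threshold
#'
#' Gaze speed is computed from a Savitzky-Golay local-polynomial derivative
#' of the filtered position; contiguous runs with speed strictly above the
#' threshold are padded and merged into saccade intervals.
#'
#' @param trace a `gaze_trace` (uniformly sampled).
#' @param speed_threshold speed threshold in degrees/second (strict).
#' @param pad padding added to each side of a detected run, in seconds.
#' @param window,order Savitzky-Golay derivative window (samples) and
#'   polynomial order.
#' @return A two-column matrix of (start_time, end_time) pairs in seconds;
#'   zero rows when no saccade is found.
#' @export
detect_saccades <- function(trace, speed_threshold = 50, pad = 0.010,
                            window = 21L, order = 2L) {
  stopifnot(inherits(trace, "gaze_trace"))
  dt <- diff(trace$times)
  if (max(abs(dt - dt[1])) > 1e-6) stop("trace is not uniformly sampled")
  fs <- trace$trajectory$sample_rate
  vx <- sg_derivative(trace$x, trace$valid, fs, window, order)
  vy <- sg_derivative(trace$y, trace$valid, fs, window, order)
  speed <- sqrt(vx^2 + vy^2)
  # strict threshold, with a hair of slack so a plateau exactly at the
  # threshold is never flagged through floating-point jitter
  fast <- !is.na(speed) & speed > speed_threshold * (1 + 1e-9)
  if (!any(fast)) return(matrix(numeric(0), ncol = 2,
                                dimnames = list(NULL, c("start", "end"))))
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(trace$times[starts[r$values]] - pad,
                trace$times[ends[r$values]] + pad)
  runs[, 1] <- pmax(runs[, 1], trace$times[1])
  runs[, 2] <- pmin(runs[, 2], trace$times[length(trace$times)])
  # merge overlapping padded runs
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs[i, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], runs[i, 2])
    else merged <- rbind(merged, runs[i, ])
  }
  dimnames(merged) <- list(NULL, c("start", "end"))
  merged
}

in_intervals <- function(times, intervals) {
  hit <- rep(FALSE, length(times))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (times >= intervals[i, 1] & times <= intervals[i, 2])
  hit
}

#' Circular-pursuit performance metrics
#'
#' Screens the record, then computes the six pursuit performance metrics over
#' valid, non-saccadic samples: SDs of the radial and tangential gaze
#' positional errors, the mean signed radial error, the circular mean phase
#' error (positive = lead, so a pursuit lag is negative), and the horizontal
#' and vertical gains — least-squares slopes through the origin of the
#' desaccaded, filtered eye velocity on the target velocity, per axis.
#'
#' @param trace a `gaze_trace`.
#' @param trajectory the target trajectory (defaults to the trace's).
#' @param thresholds a [screen_thresholds()].
#' @param speed_threshold,pad saccade-detection settings, see
#'   [detect_saccades()].
#' @param signed_radial if `FALSE`, `mean_radial_error` uses absolute radial
#'   error instead of the signed default.
#' @param desaccade_sds if `FALSE`, error SDs are computed over all valid
#'   samples, including saccadic ones.
#' @return An object of class `pursuit_metrics`: a list with `sd_radial`,
#'   `sd_tangential`, `mean_radial_error`, `phase_error_mean`, `gain_h`,
#'   `gain_v` and the screening `verdict`. When the verdict is invalid the
#'   metric fields are `NA` and only the verdict is meaningful.
#' @export
compute_pursuit_metrics <- function(trace, trajectory = trace$trajectory,
                                    thresholds = screen_thresholds(),
                                    speed_threshold = 50, pad = 0.010,
                                    signed_radial = TRUE,
                                    desaccade_sds = TRUE) {
  verdict <- screen_trace(trace, thresholds)
  na_metrics <- function() structure(
    list(sd_radial = NA_real_, sd_tangential = NA_real_,
         mean_radial_error = NA_real_, phase_error_mean = NA_real_,
         gain_h = NA_real_, gain_v = NA_real_, verdict = verdict),
    class = "pursuit_metrics")
  if (!verdict$valid) return(na_metrics())

  fs <- trace$trajectory$sample_rate
  sacc <- detect_saccades(trace, speed_threshold, pad)
  saccadic <- if (nrow(sacc)) in_intervals(trace$times, sacc)
              else rep(FALSE, length(trace$times))
  usable <- trace$valid & !saccadic
  if (sum(usable) < fs) stop("fewer than 1 s of usable samples after desaccading")

  err <- to_target_frame(trace, trajectory)
  sd_idx <- if (desaccade_sds) usable else trace$valid
  rad <- if (signed_radial) err$radial_error else abs(err$radial_error)
  ph <- err$phase_error[usable] * pi / 180
  ph <- ph[!is.na(ph)]
  phase_mean <- atan2(mean(sin(ph)), mean(cos(ph))) * 180 / pi

  vx <- sg_derivative(trace$x, trace$valid, fs)
  vy <- sg_derivative(trace$y, trace$valid, fs)
  tv <- target_velocity(trajectory, trace$times)
  # the derivative filter spreads saccadic velocity half a window beyond the
  # detected interval; widen the exclusion accordingly for the gain fit
  vel_ok <- usable
  if (any(saccadic)) {
    half <- 10L
    bad <- which(saccadic)
    spread <- unique(pmin(pmax(rep(bad, each = 2 * half + 1) +
                                 (-half):half, 1L), length(saccadic)))
    vel_ok[spread] <- FALSE
  }
  gfit <- function(ve, vt) {
    ok <- vel_ok & !is.na(ve)
    sum(ve[ok] * vt[ok]) / sum(vt[ok]^2)
  }
  structure(
    list(sd_radial = stats::sd(err$radial_error[sd_idx], na.rm = TRUE),
         sd_tangential = stats::sd(err$tangential_error[sd_idx], na.rm = TRUE),
         mean_radial_error = mean(rad[usable], na.rm = TRUE),
         phase_error_mean = phase_mean,
         gain_h = gfit(vx, tv[, "vx"]),
         gain_v = gfit(vy, tv[, "vy"]),
         verdict = verdict),
    class = "pursuit_metrics")
}

#' @export
print.pursuit_metrics <- function(x, ...) {
  if (!x$verdict$valid) {
    cat("Pursuit metrics: record rejected by screening\n")
    print(x$verdict)
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "Pursuit metrics: SD radial %.3f, SD tangential %.3f deg\n",
    "  mean radial error %.3f deg, mean phase %.2f deg (%s)\n",
    "  gain H %.3f, gain V %.3f\n"),
    x$sd_radial, x$sd_tangential, x$mean_radial_error, x$phase_error_mean,
    if (x$phase_error_mean < 0) "lag" else "lead", x$gain_h, x$gain_v))
  invisible(x)
}
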
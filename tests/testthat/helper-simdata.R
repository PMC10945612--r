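# Shared simulation helpers for the test suite.

# planted logistic problem: n x p Gaussian design, outcome from known betas
planted_logistic <- function(n, beta, intercept = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  y <- rbinom(n, 1, plogis(intercept + drop(X %*% beta)))
  list(X = X, y = y)
}

# manual gaze trace from explicit position series (uniform grid)
manual_trace <- function(x, y, trajectory, valid = rep(TRUE, length(x))) {
  times <- (seq_along(x) - 1) / trajectory$sample_rate
  structure(list(times = times, x = x, y = y, valid = valid,
                 trajectory = trajectory, subject_id = "manual"),
            class = "gaze_trace")
}

# trace that follows the target after a pure time delay (seconds)
delayed_trace <- function(trajectory, delay) {
  times <- (seq_len(round(trajectory$duration * trajectory$sample_rate)) - 1) /
    trajectory$sample_rate
  tp <- target_position(trajectory, times - delay)
  manual_trace(tp[, "x"], tp[, "y"], trajectory)
}
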
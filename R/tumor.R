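#' Ground-truth tumor motion model
#'
#' The generative twin of the fitted motion model: the simulated tumor moves
#' as \eqn{x(t) = x_0 + v(t) x_A + v'(t) x_{A'} + s} where `v` is the latent
#' breathing signal, `v'` its time derivative (central differences, the same
#' convention the fitting side uses) and `s` a per-session offset emulating
#' inter-fraction changes in the internal-external correlation.
#'
#' @param x0_true Resting position (mm, 3-vector).
#' @param xA_true Amplitude sensitivity (mm per latent-signal mm).
#' @param xAprime_true Derivative (hysteresis) sensitivity (mm s per
#'   latent-signal mm).
#' @param obs_noise_sd SD of isotropic registration noise added to each cine
#'   observation (mm).
#' @param session_shift Per-session offset (mm, 3-vector).
#' @return An object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(x0_true = c(0, 0, 0),
                               xA_true = c(0.25, -1.2, 0.5),
                               xAprime_true = c(0.03, -0.25, 0.08),
                               obs_noise_sd = 0.5,
                               session_shift = c(0, 0, 0)) {
  structure(list(x0_true = check_vec3(x0_true, "x0_true"),
                 xA_true = check_vec3(xA_true, "xA_true"),
                 xAprime_true = check_vec3(xAprime_true, "xAprime_true"),
                 obs_noise_sd = check_scalar(obs_noise_sd, "obs_noise_sd", 0),
                 session_shift = check_vec3(session_shift, "session_shift")),
            class = "ground_truth_model")
}

#' Cine acquisition schedule
#'
#' Quasi-random sparse imaging schedule: acquisition start times accumulate
#' as `mean_interval` plus uniform jitter in `[-interval_jitter,
#' interval_jitter]`; each image integrates the tumor position over an
#' `exposure`-second window and is timestamped at the window midpoint.
#' Defaults emulate about one acquisition every 5th second (0.2 Hz), 100
#' acquisitions over an 8-minute session, 0.3 s recording time.
#'
#' @param n_acquisitions Number of acquisitions.
#' @param mean_interval Mean spacing between acquisitions (s).
#' @param interval_jitter Half-width of the uniform jitter (s).
#' @param exposure Recording time of one image (s).
#' @return An object of class `cine_schedule`.
#' @export
cine_schedule <- function(n_acquisitions = 100, mean_interval = 4.3,
                          interval_jitter = 2, exposure = 0.3) {
  check_scalar(n_acquisitions, "n_acquisitions", 1)
  check_scalar(mean_interval, "mean_interval", 0, strict = TRUE)
  check_scalar(interval_jitter, "interval_jitter", 0)
  check_scalar(exposure, "exposure", 0, strict = TRUE)
  if (mean_interval <= exposure)
    stop_surromod("mean_interval must exceed exposure",
                  class = "surromod_parameter_error")
  if (interval_jitter >= mean_interval - exposure)
    stop_surromod("interval_jitter too large for mean_interval",
                  class = "surromod_parameter_error")
  structure(list(n_acquisitions = as.integer(n_acquisitions),
                 mean_interval = mean_interval,
                 interval_jitter = interval_jitter, exposure = exposure),
            class = "cine_schedule")
}

#' Simulate the continuous tumor trajectory
#'
#' Evaluates the ground-truth motion model on a latent breathing signal. The
#' derivative of the latent signal uses central differences on the signal's
#' own samples — the same convention as [estimate_derivative()] — so that a
#' noiseless round trip through the fitting side is exact.
#'
#' @param signal A `latent_signal`.
#' @param gt A [ground_truth_model()].
#' @return A `tumor_trajectory`: list with `time` (s) and `pos` (n x 3 matrix,
#'   mm); between samples the trajectory is interpreted as piecewise linear.
#' @export
simulate_tumor_trajectory <- function(signal, gt) {
  if (!inherits(signal, "latent_signal") || length(signal$time) < 3L)
    stop_surromod("signal must be a latent_signal with >= 3 samples")
  if (!inherits(gt, "ground_truth_model"))
    stop_surromod("gt must be a ground_truth_model",
                  class = "surromod_parameter_error")
  v <- signal$value
  vp <- central_diff(signal$time, v)
  pos <- cbind(gt$x0_true[1] + v * gt$xA_true[1] + vp * gt$xAprime_true[1],
               gt$x0_true[2] + v * gt$xA_true[2] + vp * gt$xAprime_true[2],
               gt$x0_true[3] + v * gt$xA_true[3] + vp * gt$xAprime_true[3])
  pos <- sweep(pos, 2, gt$session_shift, "+")
  colnames(pos) <- c("x", "y", "z")
  structure(list(time = signal$time, pos = pos,
                 obs_noise_sd = gt$obs_noise_sd),
            class = "tumor_trajectory")
}

#' Sample sparse cine-like tumor observations
#'
#' Draws a quasi-random acquisition schedule and reads the tumor position
#' from the trajectory as the exact time-average over each exposure window
#' (trapezoid integral of the piecewise-linear trajectory), adding isotropic
#' registration noise. Timestamps are the exposure midpoints.
#'
#' @param trajectory A `tumor_trajectory`.
#' @param schedule A [cine_schedule()].
#' @param seed Integer seed (jitter and registration noise).
#' @return A data frame of class `tumor_observations` with columns `time`,
#'   `x`, `y`, `z` (s, mm).
#' @export
sample_cine_sessions <- function(trajectory, schedule, seed = 1L) {
  if (!inherits(trajectory, "tumor_trajectory"))
    stop_surromod("trajectory must be a tumor_trajectory")
  if (!inherits(schedule, "cine_schedule"))
    stop_surromod("schedule must be a cine_schedule",
                  class = "surromod_parameter_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- schedule$n_acquisitions
  jit <- if (schedule$interval_jitter > 0)
    stats::runif(n, -schedule$interval_jitter, schedule$interval_jitter)
  else rep(0, n)
  starts <- cumsum(schedule$mean_interval + jit)
  ends <- starts + schedule$exposure
  span <- range(trajectory$time)
  if (ends[n] > span[2] || starts[1] < span[1])
    stop_surromod("cine schedule exceeds the trajectory span (",
                  signif(ends[n], 6), " > ", signif(span[2], 6), " s)",
                  class = "surromod_span_error")

  pos <- t(vapply(seq_len(n), function(i) {
    vapply(1:3, function(j)
      pwl_window_mean(trajectory$time, trajectory$pos[, j],
                      starts[i], ends[i]), numeric(1))
  }, numeric(3)))
  if (trajectory$obs_noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(3 * n, 0, trajectory$obs_noise_sd),
                        ncol = 3)
  out <- data.frame(time = starts + schedule$exposure / 2,
                    x = pos[, 1], y = pos[, 2], z = pos[, 3])
  class(out) <- c("tumor_observations", "data.frame")
  out
}
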
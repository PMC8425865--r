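#' Breathing-signal generator parameters
#'
#' Parametrizes the latent respiratory signal \eqn{v(t)} that drives both the
#' deforming torso surface and the tumor trajectory. The signal is built
#' cycle by cycle: each cycle draws its own period and amplitude (truncated
#' Gaussians), the within-cycle shape is a squared raised cosine so that full
#' exhalation is a flat, well-defined minimum at zero, and a linear baseline
#' drift plus white noise are added on top. This emulates irregular free
#' breathing with cycle-to-cycle period/amplitude variability and slow
#' non-respiratory drift.
#'
#' @param nominal_period Mean breathing period (s).
#' @param period_sd Cycle-to-cycle SD of the period (s).
#' @param nominal_amplitude Mean peak amplitude of the latent signal (mm).
#' @param amplitude_sd Cycle-to-cycle SD of the amplitude (mm).
#' @param drift_rate Linear baseline drift (mm/min).
#' @param noise_sd SD of additive white measurement noise (mm).
#' @param duration Length of the session (s). Default 480 s (an 8-minute
#'   session).
#' @param sample_rate Sampling rate of the signal (Hz). Default 3, the
#'   surface scanner's frame rate.
#' @return An object of class `breathing_params`.
#' @export
breathing_params <- function(nominal_period = 4, period_sd = 0.4,
                             nominal_amplitude = 8, amplitude_sd = 1.2,
                             drift_rate = 0.1, noise_sd = 0.3,
                             duration = 480, sample_rate = 3) {
  check_scalar(nominal_period, "nominal_period", 0, strict = TRUE)
  check_scalar(period_sd, "period_sd", 0)
  check_scalar(nominal_amplitude, "nominal_amplitude", 0)
  check_scalar(amplitude_sd, "amplitude_sd", 0)
  check_scalar(drift_rate, "drift_rate")
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(duration, "duration", 0, strict = TRUE)
  check_scalar(sample_rate, "sample_rate", 0, strict = TRUE)
  structure(list(nominal_period = nominal_period, period_sd = period_sd,
                 nominal_amplitude = nominal_amplitude,
                 amplitude_sd = amplitude_sd, drift_rate = drift_rate,
                 noise_sd = noise_sd, duration = duration,
                 sample_rate = sample_rate),
            class = "breathing_params")
}

#' Simulate an irregular breathing signal
#'
#' Generates the latent respiratory signal \eqn{v(t)} sampled at
#' `params$sample_rate`. Periods and amplitudes are drawn per cycle
#' (Gaussian, truncated below at 40% of the nominal period and at zero
#' amplitude), the within-cycle profile is
#' \eqn{a_k [\tfrac12(1 - \cos 2\pi\phi)]^2} (flat exhalation rest, single
#' inhalation peak per cycle), and `drift_rate`\eqn{\cdot t} plus white noise
#' are added.
#'
#' @param params A [breathing_params()] object.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return A `latent_signal`: list with `time` (s), `value` (mm),
#'   `cycle_starts` (s, exhalation cycle boundaries) and the generating
#'   `params`.
#' @export
simulate_breathing_signal <- function(params, seed = 1L) {
  if (!inherits(params, "breathing_params"))
    stop_surromod("params must be a breathing_params object",
                  class = "surromod_parameter_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n_guess <- ceiling(params$duration / max(params$nominal_period, 0.5)) + 10L
  repeat {
    periods <- pmax(0.4 * params$nominal_period,
                    stats::rnorm(n_guess, params$nominal_period, params$period_sd))
    if (sum(periods) >= params$duration + params$nominal_period) break
    n_guess <- n_guess * 2L
  }
  amps <- pmax(0, stats::rnorm(n_guess, params$nominal_amplitude,
                               params$amplitude_sd))
  starts <- cumsum(c(0, periods))

  n <- floor(params$duration * params$sample_rate)
  t <- (seq_len(n) - 1L) / params$sample_rate
  k <- findInterval(t, starts)
  phi <- (t - starts[k]) / periods[k]
  v <- amps[k] * breathing_profile(phi)
  v <- v + params$drift_rate * t / 60 +
    stats::rnorm(n, 0, params$noise_sd)

  structure(list(time = t, value = v,
                 cycle_starts = starts[starts <= params$duration],
                 params = params, seed = as.integer(seed)),
            class = "latent_signal")
}

#' @export
print.latent_signal <- function(x, ...) {
  cat(sprintf("<latent_signal> %d samples over %.1f s at %.1f Hz\n",
              length(x$time), max(x$time), x$params$sample_rate))
  invisible(x)
}

# Within-cycle breathing shape on phase [0, 1): raised-cosine rise over the
# inspiratory 30% of the cycle, slower raised-cosine fall over the next 55%
# (expiration is passive and slower than inspiration), then a full-exhalation
# rest at exactly zero. The flat rest makes exhalation minima well defined
# for the baseline filter.
breathing_profile <- function(phi) {
  h <- numeric(length(phi))
  i <- phi < 0.3
  h[i] <- (1 - cos(pi * phi[i] / 0.3)) / 2
  i <- phi >= 0.3 & phi < 0.85
  h[i] <- (1 + cos(pi * (phi[i] - 0.3) / 0.55)) / 2
  h
}

# Save/restore the global RNG state so simulators are self-contained.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Evaluate a latent signal (piecewise-linear interpolation) at arbitrary
# times; constant extrapolation before the first sample.
signal_at <- function(signal, times) {
  stats::approx(signal$time, signal$value, xout = times, rule = 2)$y
}
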
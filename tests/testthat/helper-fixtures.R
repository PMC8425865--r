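# Fixtures are built in code; nothing is read from disk.

# A frame whose lines sample an affine height field z = a + b*x + c*y.
plane_frame <- function(a = 0, b = 0, c = 0, time = 0,
                        line_y = seq(-100, 100, by = 25),
                        xs = seq(-120, 120, by = 10)) {
  surface_frame(time, lapply(line_y, function(yl) {
    list(x = xs, y = rep(yl, length(xs)), z = a + b * xs + c * yl)
  }))
}

flat_frame <- function(z, ...) plane_frame(a = z, ...)

# Wrap an arbitrary sampled signal as a latent_signal.
as_latent <- function(time, value, sample_rate = 1 / mean(diff(time))) {
  structure(list(time = time, value = value, cycle_starts = numeric(0),
                 params = list(sample_rate = sample_rate), seed = NA_integer_),
            class = "latent_signal")
}

# Sinusoidal surrogate trace amp*sin(2*pi*t/period) + drift_per_min*t/60.
sinus_trace <- function(amp = 5, period = 4, duration = 60, rate = 3,
                        drift_per_min = 0, label = "AP") {
  t <- seq(0, duration, by = 1 / rate)
  surrogate_trace(t, amp * sin(2 * pi * t / period) + drift_per_min * t / 60,
                  label)
}

# Small, fast study for orchestration tests.
tiny_study <- function(seed = 1L, ...) {
  simulate_study(
    breathing = breathing_params(duration = 150),
    torso = torso_params(points_per_line = 31),
    schedule = cine_schedule(n_acquisitions = 25, mean_interval = 4.3,
                             interval_jitter = 1.5),
    seed = seed, ...)
}

# A noise-free piston world: the whole torso moves rigidly with the latent
# signal, so AP reproduces it exactly and the pipeline round trip is exact.
piston_world <- function(duration = 240, seed = 3L,
                         gt = ground_truth_model(x0_true = c(1, 2, 3),
                                                 obs_noise_sd = 0)) {
  bp <- breathing_params(period_sd = 0, amplitude_sd = 0, drift_rate = 0,
                         noise_sd = 0, duration = duration)
  sig <- simulate_breathing_signal(bp, seed)
  torso <- torso_params(abdominal_weight_map = function(x, y) 1 + 0 * x,
                        thoracic_weight_map = function(x, y) 0 * x,
                        thorax_lag = 0, point_noise_sd = 0,
                        dropout_rate_edges = 0)
  frames <- simulate_surface_sequence(sig, torso, seed + 1L)
  traj <- simulate_tumor_trajectory(sig, gt)
  obs <- sample_cine_sessions(
    traj, cine_schedule(n_acquisitions = 40, mean_interval = 5,
                        interval_jitter = 1.5), seed + 2L)
  list(signal = sig, torso = torso, frames = frames, trajectory = traj,
       observations = obs, gt = gt)
}

# Training pairs drawn directly from a latent signal and ground truth
# (skipping the surface stage) at the cine observation times.
latent_pairs <- function(signal, gt, schedule = cine_schedule(), seed = 1L,
                         correct = FALSE, center = FALSE) {
  traj <- simulate_tumor_trajectory(signal, gt)
  obs <- sample_cine_sessions(traj, schedule, seed)
  tr <- surrogate_trace(signal$time, signal$value, "AP")
  if (correct) tr <- correct_trace(tr)
  d <- estimate_derivative(tr)
  sam <- sample_surrogate_at(tr, d, obs$time, schedule$exposure)
  pos <- as.matrix(obs[, c("x", "y", "z")])
  if (center) pos <- center_positions(pos)
  cbind(sam, as.data.frame(pos))
}

# Explicit normal-equations solve, the independent oracle for the OLS fit.
normal_equations_fit <- function(training) {
  X <- cbind(1, training$A, training$Aprime)
  Y <- as.matrix(training[, c("x", "y", "z")])
  solve(crossprod(X), crossprod(X, Y))
}

expect_vec_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
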
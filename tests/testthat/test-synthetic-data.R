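test_that("degenerate breathing parameters give an exactly periodic signal", {
  bp <- breathing_params(period_sd = 0, amplitude_sd = 0, drift_rate = 0,
                         noise_sd = 0, duration = 60, sample_rate = 3)
  sig <- simulate_breathing_signal(bp, 1)
  # period 4 s at 3 Hz = 12 samples per cycle
  v <- sig$value
  expect_vec_equal(v[1:36], v[1:36 + 12], tol = 1e-12)
  expect_equal(min(v), 0)
  # samples need not hit the profile peak exactly (3 Hz sampling)
  expect_lt(abs(max(v) - bp$nominal_amplitude), 0.1)
})

test_that("identical seeds reproduce the whole generator bit-for-bit", {
  a <- simulate_breathing_signal(breathing_params(duration = 60), 42)
  b <- simulate_breathing_signal(breathing_params(duration = 60), 42)
  expect_identical(a$value, b$value)
  expect_false(identical(
    a$value, simulate_breathing_signal(breathing_params(duration = 60), 43)$value))

  s1 <- tiny_study(seed = 9)
  s2 <- tiny_study(seed = 9)
  expect_identical(s1$sessions[[2]]$observations, s2$sessions[[2]]$observations)
  expect_identical(s1$sessions[[1]]$frames$lines[[4]]$Z,
                   s2$sessions[[1]]$frames$lines[[4]]$Z)
})

test_that("detected mean cycle length matches the drawn periods", {
  bp <- breathing_params(period_sd = 0.4, amplitude_sd = 0, drift_rate = 0,
                         noise_sd = 0, duration = 410)
  sig <- simulate_breathing_signal(bp, 7)
  # independent oracle: boundaries of the exact-zero exhalation rest runs
  zero <- sig$value == 0
  starts <- which(zero & !c(FALSE, zero[-length(zero)]))
  cycles <- diff(sig$time[starts])
  expect_gt(length(cycles), 90)
  se <- bp$period_sd / sqrt(length(cycles))
  expect_lt(abs(mean(cycles) - bp$nominal_period), 2 * se + 1 / 3)
})

test_that("breathing parameter validation rejects bad inputs", {
  expect_error(breathing_params(duration = 0), class = "surromod_parameter_error")
  expect_error(breathing_params(sample_rate = -1), class = "surromod_parameter_error")
  expect_error(breathing_params(period_sd = -0.1), class = "surromod_parameter_error")
})

test_that("surface sequence has floor(duration x rate) frames; zero signal is static", {
  bp <- breathing_params(duration = 48.5, sample_rate = 3)
  sig <- simulate_breathing_signal(bp, 1)
  sig$value[] <- 0
  torso <- torso_params(point_noise_sd = 0, dropout_rate_edges = 0)
  seqs <- simulate_surface_sequence(sig, torso, 1)
  expect_length(seqs$times, floor(48.5 * 3))
  f1 <- as_frame_list(seqs)[[1]]
  for (k in c(20, 77)) {
    fk <- as_frame_list(seqs)[[k]]
    expect_identical(fk$lines, f1$lines)
  }
  # static heights equal the base height map
  l5 <- seqs$lines[[5]]
  expect_vec_equal(l5$Z[, 1], default_base_height(l5$x, rep(l5$y, length(l5$x))))
})

test_that("AP-location heights reconstruct the latent signal within noise", {
  sig <- simulate_breathing_signal(breathing_params(duration = 60, noise_sd = 0), 5)
  torso <- torso_params(abdominal_weight_map = function(x, y) 1 + 0 * x,
                        thoracic_weight_map = function(x, y) 0 * x,
                        point_noise_sd = 0.3)
  seqs <- simulate_surface_sequence(sig, torso, 6)
  ap <- extract_point_surrogate(seqs, c(0, -150), surrogate_config(), "AP")
  target <- sig$value + default_base_height(0, -150)
  expect_lt(max(abs(ap$values - target)), 3 * 0.3)
})

test_that("dropout only removes edge points and counts stay bounded", {
  sig <- simulate_breathing_signal(breathing_params(duration = 30), 2)
  torso <- torso_params(dropout_rate_edges = 0.5)
  seqs <- simulate_surface_sequence(sig, torso, 3)
  frames <- as_frame_list(seqs)
  for (f in frames[c(1, 40, 88)]) {
    n <- sum(vapply(f$lines, function(l) length(l$x), integer(1)))
    expect_lte(n, torso$points_per_line * 11)
    for (l in f$lines) {
      central <- abs(l$x) <= torso$dropout_extent
      expect_equal(sum(central), sum(abs(seq(-175, 175, length.out = 61)) <= 130))
    }
  }
  expect_error(simulate_surface_sequence(list(), torso_params()),
               class = "surromod_error")
})

test_that("zero hysteresis gives collinear trajectories", {
  sig <- simulate_breathing_signal(breathing_params(duration = 60), 3)
  gt <- ground_truth_model(xAprime_true = c(0, 0, 0), obs_noise_sd = 0)
  traj <- simulate_tumor_trajectory(sig, gt)
  sv <- svd(scale(traj$pos, scale = FALSE))$d
  expect_lt(sv[2] / sv[1], 1e-12)
})

test_that("noiseless trajectory refit recovers the ground truth exactly", {
  sig <- simulate_breathing_signal(breathing_params(duration = 120, noise_sd = 0), 8)
  gt <- ground_truth_model(x0_true = c(2, -1, 4), obs_noise_sd = 0)
  pairs <- latent_pairs(sig, gt, cine_schedule(n_acquisitions = 20,
                                               mean_interval = 5,
                                               interval_jitter = 1), 4)
  fit <- fit_low_model(pairs)
  expect_vec_equal(fit$x0, gt$x0_true, 1e-9)
  expect_vec_equal(fit$xA, gt$xA_true, 1e-9)
  expect_vec_equal(fit$xAprime, gt$xAprime_true, 1e-9)
})

test_that("hysteresis loop area matches the analytic ellipse", {
  # pure sinusoid: the (v, x_j) loop is an ellipse of area pi A^2 w |xA'_j|
  A0 <- 3; Tper <- 4; w <- 2 * pi / Tper
  t <- seq(0, 8, by = 1 / 50)
  sig <- as_latent(t, A0 * sin(w * t))
  gt <- ground_truth_model(xA_true = c(0, -1, 0.5),
                           xAprime_true = c(0, -0.3, 0.1), obs_noise_sd = 0)
  traj <- simulate_tumor_trajectory(sig, gt)
  one_cycle <- t >= 2 & t < 2 + Tper
  shoelace <- function(x, y) {
    n <- length(x)
    abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  }
  for (j in 2:3) {
    area <- shoelace(sig$value[one_cycle], traj$pos[one_cycle, j])
    expect_lt(abs(area / (pi * A0^2 * w * abs(gt$xAprime_true[j])) - 1), 0.01)
  }
})

test_that("cine sampling: counts, constant case, and linear window mean", {
  t <- seq(0, 200, by = 0.1)
  const <- as_latent(t, rep(0, length(t)))
  gt0 <- ground_truth_model(x0_true = c(5, 6, 7), xA_true = c(0, 0, 0),
                            xAprime_true = c(0, 0, 0), obs_noise_sd = 0)
  traj <- simulate_tumor_trajectory(const, gt0)
  sch <- cine_schedule(n_acquisitions = 30, mean_interval = 5,
                       interval_jitter = 0)
  obs <- sample_cine_sessions(traj, sch, 1)
  expect_equal(nrow(obs), 30)
  expect_vec_equal(as.matrix(obs[, c("x", "y", "z")]),
                   matrix(rep(c(5, 6, 7), each = 30), ncol = 3), 1e-12)

  # linear trajectory: window mean equals the midpoint value
  lin <- as_latent(t, 0.5 * t)
  gt1 <- ground_truth_model(xA_true = c(1, 2, -1), xAprime_true = c(0, 0, 0),
                            obs_noise_sd = 0)
  traj <- simulate_tumor_trajectory(lin, gt1)
  obs <- sample_cine_sessions(traj, cine_schedule(n_acquisitions = 10,
                                                  mean_interval = 6,
                                                  interval_jitter = 1.5), 2)
  expect_vec_equal(obs$x, 0.5 * obs$time * 1, 1e-10)
  expect_vec_equal(obs$y, 0.5 * obs$time * 2, 1e-10)

  expect_error(
    sample_cine_sessions(traj, cine_schedule(n_acquisitions = 100,
                                             mean_interval = 5), 1),
    class = "surromod_span_error")
})
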
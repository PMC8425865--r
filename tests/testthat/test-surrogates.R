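test_that("height interpolation reproduces affine fields exactly", {
  set.seed(101)
  for (i in 1:20) {
    a <- runif(1, -50, 150); b <- runif(1, -0.5, 0.5); c_ <- runif(1, -0.5, 0.5)
    f <- plane_frame(a, b, c_)
    q <- cbind(runif(5, -110, 110), runif(5, -95, 95))
    expect_vec_equal(interpolate_height(f, q),
                     a + b * q[, 1] + c_ * q[, 2], 1e-9)
  }
})

test_that("interpolation hits captured nodes and hand-checked midpoints", {
  f <- plane_frame(10, 0.2, -0.1)
  expect_equal(interpolate_height(f, c(30, -50)), 10 + 0.2 * 30 - 0.1 * -50)
  # two flat lines at z = 10 and 20, query midway in y
  f2 <- surface_frame(0, list(
    list(x = -2:2 * 10, y = rep(0, 5), z = rep(10, 5)),
    list(x = -2:2 * 10, y = rep(40, 5), z = rep(20, 5))))
  expect_equal(interpolate_height(f2, c(0, 20), n_lines = 2), 15)
  expect_error(interpolate_height(f2, c(0, 60), n_lines = 2),
               class = "surromod_interpolation_error")
  expect_error(interpolate_height(f2, c(999, 20), n_lines = 2),
               class = "surromod_interpolation_error")
})

test_that("point surrogate extraction follows the surface and skips bad frames", {
  frames <- lapply(0:29, function(k) flat_frame(10 + sin(k / 3), time = k / 3))
  tr <- extract_point_surrogate(frames, c(0, 0), surrogate_config(), "TP")
  expect_equal(tr$label, "TP")
  expect_vec_equal(tr$values, 10 + sin((0:29) / 3), 1e-9)

  # a frame whose lines end at x = 50 fails at query x = 80 and is skipped
  frames[[10]] <- plane_frame(10, time = 3, xs = seq(-50, 50, by = 10))
  tr <- extract_point_surrogate(frames, c(80, 0), surrogate_config(), "TP")
  expect_length(tr$values, 29)
  expect_equal(attr(tr, "skipped"), 3)
  expect_true(all(diff(tr$times) > 0))
})

test_that("missing nearest line falls back to the remaining lines", {
  mk_line <- function(yl, z) list(x = -3:3 * 20, y = rep(yl, 7), z = rep(z, 7))
  full <- surface_frame(0, list(mk_line(-20, 5), mk_line(0, 11), mk_line(20, 19)))
  # query at y = 2: nearest line is y = 0
  expect_equal(interpolate_height(full, c(0, 2)), 11 + (19 - 11) * 2 / 20)
  reduced <- surface_frame(0, list(mk_line(-20, 5), list(x = numeric(0),
    y = numeric(0), z = numeric(0)), mk_line(20, 19)))
  # hand interpolation between the two remaining lines
  expect_equal(interpolate_height(reduced, c(0, 2)),
               5 + (19 - 5) * 22 / 40)
})

test_that("RDM equals the brute-force mean of point norms", {
  d_frame <- surface_frame(0, list(list(x = c(3, 0), y = c(4, 0), z = c(0, 5))))
  expect_equal(compute_rdm(d_frame), 5)

  set.seed(7)
  pts <- matrix(rnorm(600, sd = 50), ncol = 3)
  f <- surface_frame(0, list(
    list(x = pts[1:100, 1], y = pts[1:100, 2], z = pts[1:100, 3]),
    list(x = pts[101:200, 1], y = pts[101:200, 2], z = pts[101:200, 3])))
  oracle <- mean(apply(pts, 1, function(p) sqrt(sum(p^2))))
  expect_lt(abs(compute_rdm(f) - oracle), 1e-12)

  # invariance under point reordering / line permutation
  perm <- sample(200)
  f2 <- surface_frame(0, list(
    list(x = pts[perm[1:150], 1], y = pts[perm[1:150], 2], z = pts[perm[1:150], 3]),
    list(x = pts[perm[151:200], 1], y = pts[perm[151:200], 2], z = pts[perm[151:200], 3])))
  expect_equal(compute_rdm(f2), compute_rdm(f))
  empty <- structure(list(time = 0, lines = list(
    list(x = numeric(0), y = numeric(0), z = numeric(0)))),
    class = "surface_frame")
  expect_error(compute_rdm(empty), class = "surromod_empty_frame")
})

test_that("SDV is exact for planes and linear in the height field", {
  cfg <- surrogate_config(roi_center = c(0, 0))
  flat <- flat_frame(100)
  expect_equal(compute_sdv(flat, cfg), 150 * 150 * 100)
  # adding delta to every height adds delta * ROI area
  expect_equal(compute_sdv(flat_frame(103.5), cfg) - compute_sdv(flat, cfg),
               3.5 * 22500)
  # tilted plane over a centered ROI: the linear term integrates to zero
  expect_equal(compute_sdv(plane_frame(100, 0.1, 0), cfg), 2.25e6)
  expect_equal(compute_sdv(plane_frame(100, 0.07, -0.04), cfg), 2.25e6,
               tolerance = 1e-12)
})

test_that("all four surrogates extract with the expected structure and lag", {
  # thorax lag of 1 s = 3 frames at 3 Hz; noiseless, no dropout
  sig <- simulate_breathing_signal(
    breathing_params(duration = 120, noise_sd = 0, drift_rate = 0), 11)
  torso <- torso_params(thorax_lag = 1, point_noise_sd = 0,
                        dropout_rate_edges = 0)
  seqs <- simulate_surface_sequence(sig, torso, 1)
  tr <- extract_all_surrogates(seqs, surrogate_config())
  expect_named(tr, c("AP", "TP", "RDM", "SDV"))
  for (x in tr) expect_length(x$values, 360)

  lagcor <- function(k) {
    ap <- scale(tr$AP$values); tp <- scale(tr$TP$values); n <- length(ap)
    cor(ap[1:(n - k)], tp[(1 + k):n])
  }
  best <- which.max(vapply(0:8, lagcor, numeric(1))) - 1L
  expect_true(abs(best - 3L) <= 1L)

  # static torso: four constant traces
  sig0 <- sig; sig0$value[] <- 0
  tr0 <- extract_all_surrogates(simulate_surface_sequence(sig0, torso, 1))
  for (x in tr0) expect_lt(diff(range(x$values)), 1e-9)
})

test_that("dense fast paths agree with per-frame extraction", {
  sig <- simulate_breathing_signal(breathing_params(duration = 20), 5)
  seqs <- simulate_surface_sequence(
    sig, torso_params(points_per_line = 41, dropout_rate_edges = 0.3), 7)
  frames <- as_frame_list(seqs)
  cfg <- surrogate_config()
  for (lab in c("AP", "TP", "RDM", "SDV")) {
    fast <- surrogate_trace_for(seqs, lab, cfg)
    slow <- surrogate_trace_for(frames, lab, cfg)
    expect_equal(fast$times, slow$times)
    expect_vec_equal(fast$values, slow$values, 1e-8)
  }
})

test_that("doubling point density barely changes RDM on a smooth surface", {
  mk <- function(n) {
    xs <- seq(-150, 150, length.out = n)
    surface_frame(0, lapply(seq(-150, 50, by = 25), function(yl) {
      list(x = xs, y = rep(yl, n), z = default_base_height(xs, rep(yl, n)))
    }))
  }
  expect_lt(abs(compute_rdm(mk(30)) - compute_rdm(mk(60))), 0.5)
})
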
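test_that("derivative estimation is exact for affine traces and bounded for sinusoids", {
  t <- 0:30 / 3
  lin <- surrogate_trace(t, 2.5 * t - 4, "AP")
  expect_vec_equal(estimate_derivative(lin)$values, rep(2.5, 31), 1e-10)
  expect_vec_equal(estimate_derivative(
    surrogate_trace(t, rep(7, 31), "AP"))$values, rep(0, 31), 1e-12)

  # sin(2 pi 0.25 t) at 3 Hz: interior central-difference error is bounded by
  # the Taylor term w^3 h^2 / 6
  w <- 2 * pi * 0.25; h <- 1 / 3
  t <- seq(0, 40, by = h)
  d <- estimate_derivative(surrogate_trace(t, sin(w * t), "AP"))
  interior <- 2:(length(t) - 1)
  err <- abs(d$values[interior] - w * cos(w * t[interior]))
  expect_lt(max(err), w^3 * h^2 / 6)

  expect_error(estimate_derivative(surrogate_trace(0:1, 0:1, "AP")),
               class = "surromod_error")
  expect_error(estimate_derivative(lin, smooth_window = 4),
               class = "surromod_error")
})

test_that("exposure-window sampling averages the traces exactly", {
  t <- seq(0, 60, by = 1 / 3)
  const <- surrogate_trace(t, rep(3.3, length(t)), "AP")
  dc <- estimate_derivative(const)
  s <- sample_surrogate_at(const, dc, c(5, 20, 40), exposure = 0.9)
  expect_vec_equal(s$A, rep(3.3, 3), 1e-12)
  expect_vec_equal(s$Aprime, rep(0, 3), 1e-12)

  lin <- surrogate_trace(t, 1.5 * t, "AP")
  s <- sample_surrogate_at(lin, estimate_derivative(lin), c(7, 33), 0.3)
  expect_vec_equal(s$A, 1.5 * c(7, 33), 1e-10)

  # dense sinusoid: analytic window mean of sin
  w <- 2 * pi / 5
  td <- seq(0, 30, by = 1e-3)
  tr <- surrogate_trace(td, sin(w * td), "AP")
  s <- sample_surrogate_at(tr, estimate_derivative(tr), c(4, 11.3), 0.3)
  win_mean <- function(t0, t1) (cos(w * t0) - cos(w * t1)) / (w * (t1 - t0))
  expect_lt(max(abs(s$A / win_mean(c(4, 11.3) - 0.15, c(4, 11.3) + 0.15) - 1)),
            1e-6)

  expect_error(sample_surrogate_at(const, dc, 70, 0.3),
               class = "surromod_span_error")
  gap <- surrogate_trace(c(t[t < 20], t[t > 25]), sin(c(t[t < 20], t[t > 25])), "AP")
  expect_error(sample_surrogate_at(gap, estimate_derivative(gap), 22, 0.3),
               class = "surromod_span_error")
})

test_that("median centering matches a sort-based oracle", {
  expect_equal(center_positions(matrix(c(4, -2, 7), 1)),
               matrix(c(0, 0, 0), 1, dimnames = list(NULL, c("x", "y", "z"))))
  set.seed(3)
  m <- matrix(rnorm(150, sd = 4), ncol = 3)
  cm <- center_positions(m)
  expect_vec_equal(apply(cm, 2, median), c(0, 0, 0), 1e-12)
  oracle <- vapply(1:3, function(j) {
    s <- sort(m[, j]); (s[25] + s[26]) / 2
  }, numeric(1))
  expect_vec_equal(m - cm, matrix(oracle, 50, 3, byrow = TRUE), 1e-12)
  expect_error(center_positions(matrix(numeric(0), 0, 3)), class = "surromod_error")
})

test_that("model fitting: constant response, exact recovery, degeneracy", {
  set.seed(11)
  tp <- data.frame(A = rnorm(10), Aprime = rnorm(10),
                   x = 3, y = -1, z = 0.5)
  fit <- fit_low_model(tp)
  expect_vec_equal(fit$x0, c(3, -1, 0.5), 1e-10)
  expect_vec_equal(fit$xA, c(0, 0, 0), 1e-10)
  expect_vec_equal(fit$xAprime, c(0, 0, 0), 1e-10)

  true <- motion_model_params(c(1, 2, 3), c(0.5, -2, 1), c(0.1, 0.3, -0.2))
  A <- rnorm(10); Ap <- rnorm(10)
  pos <- predict_position(true, A, Ap)
  fit <- fit_low_model(data.frame(A = A, Aprime = Ap, x = pos[, 1],
                                  y = pos[, 2], z = pos[, 3]))
  expect_vec_equal(unlist(fit[c("x0", "xA", "xAprime")]),
                   unlist(true[c("x0", "xA", "xAprime")]), 1e-9)

  degen <- data.frame(A = rep(2, 6), Aprime = rnorm(6), x = rnorm(6),
                      y = rnorm(6), z = rnorm(6))
  err <- tryCatch(fit_low_model(degen), error = identity)
  expect_s3_class(err, "surromod_degenerate_design")
  expect_match(conditionMessage(err), "A")
  expect_error(fit_low_model(tp[1:3, ]), "4 training pairs")
})

test_that("fitted coefficients match the explicit normal-equations oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    tp <- data.frame(A = rnorm(n, sd = 3), Aprime = rnorm(n, sd = 8),
                     x = rnorm(n), y = rnorm(n, sd = 5), z = rnorm(n))
    fit <- fit_low_model(tp)
    beta <- normal_equations_fit(tp)
    got <- rbind(fit$x0, fit$xA, fit$xAprime)
    expect_lt(max(abs(got - beta) / pmax(abs(beta), 1e-6)), 1e-8)
  }
})

test_that("prediction is affine and superposes", {
  p <- motion_model_params(c(0, 0, 0), c(1, 0, 2), c(0, -1, 0))
  expect_equal(drop(predict_position(p, 0, 0)), c(x = 0, y = 0, z = 0))
  expect_equal(drop(predict_position(p, 2, 3)), c(x = 2, y = -3, z = 4))
  p2 <- motion_model_params(c(5, -2, 1), c(0.3, 1, -1), c(2, 0, 0.5))
  a <- predict_position(p2, 1.2, -0.7); b <- predict_position(p2, -0.4, 2.2)
  ab <- predict_position(p2, 1.2 - 0.4, -0.7 + 2.2)
  expect_vec_equal(ab, a + b - rbind(p2$x0), 1e-12)
})

test_that("residual summaries follow the stated conventions", {
  zero <- motion_model_params(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  val345 <- data.frame(A = rnorm(8), Aprime = rnorm(8),
                       x = -3, y = -4, z = 0)
  rs <- compute_residuals(zero, val345)
  expect_equal(rs$magnitudes, rep(5, 8))
  expect_equal(rs$mean, 5)

  val <- data.frame(A = 0, Aprime = 0, x = -(1:10), y = 0, z = 0)
  rs <- compute_residuals(zero, val)
  expect_equal(sort(rs$magnitudes), as.numeric(1:10))
  expect_equal(rs$mean, 5.5)
  expect_equal(rs$p90, 9.1)

  perfect <- data.frame(A = 1:5, Aprime = 0, x = 0, y = 0, z = 0)
  expect_equal(compute_residuals(zero, perfect)$mean, 0)
})

test_that("training residuals are orthogonal to the design columns", {
  set.seed(5)
  tp <- data.frame(A = rnorm(40), Aprime = rnorm(40),
                   x = rnorm(40), y = rnorm(40), z = rnorm(40))
  fit <- fit_low_model(tp)
  pred <- predict_position(fit, tp$A, tp$Aprime)
  resid <- as.matrix(tp[, c("x", "y", "z")]) - pred
  X <- cbind(1, tp$A, tp$Aprime)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("residual magnitudes follow the chi(3) law under isotropic noise", {
  set.seed(99)
  sigma <- 2
  zero <- motion_model_params(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  val <- data.frame(A = 0, Aprime = 0, x = rnorm(1000, sd = sigma),
                    y = rnorm(1000, sd = sigma), z = rnorm(1000, sd = sigma))
  rs <- compute_residuals(zero, val)
  expect_lt(abs(rs$mean / (sigma * 2 * sqrt(2 / pi)) - 1), 0.05)
  expect_lt(abs(rs$p90 / (sigma * sqrt(qchisq(0.9, 3))) - 1), 0.05)
})

test_that("fitting is equivariant under affine surrogate rescaling", {
  set.seed(13)
  tp <- data.frame(A = rnorm(30, 4, 2), Aprime = rnorm(30, 0, 5),
                   x = rnorm(30), y = rnorm(30), z = rnorm(30))
  fit1 <- fit_low_model(tp)
  tp2 <- tp; tp2$A <- -1.7 * tp$A + 3.2
  fit2 <- fit_low_model(tp2)
  Aval <- rnorm(10); Apval <- rnorm(10)
  expect_vec_equal(predict_position(fit1, Aval, Apval),
                   predict_position(fit2, -1.7 * Aval + 3.2, Apval), 1e-9)
})

test_that("the derivative term helps on hysteretic data", {
  wins <- 0
  for (r in 1:10) {
    sig <- simulate_breathing_signal(breathing_params(duration = 200), 300 + r)
    gt <- ground_truth_model()
    sch <- cine_schedule(n_acquisitions = 40, mean_interval = 4.5,
                         interval_jitter = 1.5)
    train <- latent_pairs(sig, gt, sch, seed = r, correct = TRUE)
    sig2 <- simulate_breathing_signal(breathing_params(duration = 200), 600 + r)
    val <- latent_pairs(sig2, gt, sch, seed = 100 + r, correct = TRUE)
    full <- compute_residuals(fit_low_model(train), val)$mean
    amp <- compute_residuals(fit_low_model(train, amplitude_only = TRUE), val)$mean
    wins <- wins + (full < amp)
  }
  expect_gte(wins, 9)
})
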
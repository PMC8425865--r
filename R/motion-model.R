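# Low-type internal-external correlation model: tumor position as a linear
# function of a surrogate amplitude and its time derivative,
#   x(A, A') = x0 + A * xA + A' * xA',
# fitted by ordinary least squares and evaluated by the mean and 90th
# percentile of the residual magnitudes.

#' Motion model parameters
#'
#' @param x0 Offset (mm, 3-vector).
#' @param xA Amplitude sensitivity (mm per surrogate unit, 3-vector).
#' @param xAprime Derivative sensitivity (mm s per surrogate unit,
#'   3-vector).
#' @param surrogate Label of the driving surrogate (informational).
#' @return An object of class `motion_model_params`.
#' @export
motion_model_params <- function(x0, xA, xAprime, surrogate = NA_character_) {
  structure(list(x0 = check_vec3(x0, "x0"), xA = check_vec3(xA, "xA"),
                 xAprime = check_vec3(xAprime, "xAprime"),
                 surrogate = surrogate),
            class = "motion_model_params")
}

#' @export
print.motion_model_params <- function(x, ...) {
  cat("<motion_model_params>",
      if (!is.na(x$surrogate)) paste0(" driven by ", x$surrogate), "\n",
      sprintf("  x0      = (%8.4f, %8.4f, %8.4f) mm\n", x$x0[1], x$x0[2], x$x0[3]),
      sprintf("  xA      = (%8.4f, %8.4f, %8.4f) mm/unit\n", x$xA[1], x$xA[2], x$xA[3]),
      sprintf("  xA'     = (%8.4f, %8.4f, %8.4f) mm s/unit\n",
              x$xAprime[1], x$xAprime[2], x$xAprime[3]), sep = "")
  invisible(x)
}

# Central differences on irregular samples; one-sided at the ends.
central_diff <- function(times, values) {
  n <- length(values)
  if (n < 3L) stop_surromod("need >= 3 samples for a derivative")
  d <- numeric(n)
  d[1L] <- (values[2L] - values[1L]) / (times[2L] - times[1L])
  d[n] <- (values[n] - values[n - 1L]) / (times[n] - times[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (values[i + 1L] - values[i - 1L]) / (times[i + 1L] - times[i - 1L])
  d
}

#' Time derivative of a surrogate trace
#'
#' Central differences on the native samples (one-sided at the ends), with
#' optional moving-average pre-smoothing (off by default). Computed on the
#' baseline-corrected trace at the native frame rate, before any sparse
#' sampling at cine times.
#'
#' @param trace A `surrogate_trace` with >= 3 samples.
#' @param smooth_window Odd moving-average length applied before
#'   differentiation; 0 or 1 disables smoothing.
#' @return A `surrogate_trace` of the derivative (units/s), carrying the same
#'   label and a `derivative` attribute.
#' @export
estimate_derivative <- function(trace, smooth_window = 0L) {
  stopifnot(inherits(trace, "surrogate_trace"))
  if (length(trace$times) < 3L)
    stop_surromod("need >= 3 samples for a derivative")
  v <- trace$values
  if (smooth_window > 1L) {
    k <- as.integer(smooth_window)
    if (k %% 2L == 0L) stop_surromod("smooth_window must be odd")
    f <- stats::filter(v, rep(1 / k, k), sides = 2)
    v <- ifelse(is.na(f), v, as.numeric(f))
  }
  out <- surrogate_trace(trace$times, central_diff(trace$times, v),
                         trace$label, trace$baseline_corrected)
  attr(out, "derivative") <- TRUE
  out
}

#' Sample a surrogate and its derivative at acquisition times
#'
#' Pairs the surrogate with sparse imaging: for each acquisition timestamp t
#' (the exposure midpoint), A and A' are the exact time-averages of the
#' linearly interpolated traces over the exposure window centered on t,
#' mirroring the image's finite recording time.
#'
#' @param trace Baseline-corrected `surrogate_trace`.
#' @param derivative_trace Its derivative, from [estimate_derivative()].
#' @param acquisition_times Exposure-midpoint timestamps (s).
#' @param exposure Exposure duration (s).
#' @param max_gap Largest tolerated sampling gap (s) under a window; an
#'   acquisition over a larger gap (skipped frames) errors.
#' @return Data frame with columns `time`, `A`, `Aprime`.
#' @export
sample_surrogate_at <- function(trace, derivative_trace, acquisition_times,
                                exposure = 0.3, max_gap = 2) {
  stopifnot(inherits(trace, "surrogate_trace"))
  t0 <- acquisition_times - exposure / 2
  t1 <- acquisition_times + exposure / 2
  span <- range(trace$times)
  if (any(t0 < span[1]) || any(t1 > span[2]))
    stop_surromod("acquisition outside the surrogate trace span",
                  class = "surromod_span_error")
  for (i in seq_along(t0))
    if (max_gap_in(trace$times, t0[i], t1[i]) > max_gap)
      stop_surromod("acquisition at t = ", signif(acquisition_times[i], 6),
                    " s falls in a surrogate gap > ", max_gap, " s",
                    class = "surromod_span_error")
  A <- vapply(seq_along(t0), function(i)
    pwl_window_mean(trace$times, trace$values, t0[i], t1[i]), numeric(1))
  Ap <- vapply(seq_along(t0), function(i)
    pwl_window_mean(derivative_trace$times, derivative_trace$values,
                    t0[i], t1[i]), numeric(1))
  data.frame(time = acquisition_times, A = A, Aprime = Ap)
}

#' Center positions by the per-session median
#'
#' Subtracts the component-wise median of all registrations of a session so
#' positions are intra-fractional, independent of inter-session setup
#' differences.
#'
#' @param positions n x 3 numeric matrix (or data frame with columns x, y,
#'   z) of positions (mm).
#' @return Matrix of the same shape with component-wise medians of zero.
#' @export
center_positions <- function(positions) {
  m <- as_pos_matrix(positions)
  if (nrow(m) == 0L) stop_surromod("no positions to center")
  sweep(m, 2, apply(m, 2, stats::median), "-")
}

as_pos_matrix <- function(positions) {
  if (is.data.frame(positions))
    positions <- as.matrix(positions[, c("x", "y", "z")])
  m <- as.matrix(positions)
  if (ncol(m) != 3L) stop_surromod("positions must be n x 3")
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

#' Fit the amplitude + derivative motion model
#'
#' Ordinary least squares per spatial component with the shared design
#' [1, A, A'], minimizing the summed squared residual vectors over the
#' training pairs. Requires at least 4 pairs and a full-rank design.
#'
#' @param training Data frame with columns `A`, `Aprime`, `x`, `y`, `z`
#'   (surrogate units / mm); e.g. the output of [sample_surrogate_at()]
#'   joined with centered tumor observations.
#' @param amplitude_only If `TRUE`, drop the derivative term (xA' fixed at
#'   zero) — the amplitude-only comparator.
#' @param surrogate Optional label recorded on the result.
#' @return A [motion_model_params()] object.
#' @export
fit_low_model <- function(training, amplitude_only = FALSE,
                          surrogate = NA_character_) {
  req <- c("A", if (!amplitude_only) "Aprime", "x", "y", "z")
  if (!all(req %in% names(training)))
    stop_surromod("training must have columns ", paste(req, collapse = ", "))
  n <- nrow(training)
  if (n < 4L)
    stop_surromod("need >= 4 training pairs, got ", n)
  X <- if (amplitude_only) cbind(`(intercept)` = 1, A = training$A)
       else cbind(`(intercept)` = 1, A = training$A, Aprime = training$Aprime)
  Y <- as.matrix(training[, c("x", "y", "z")])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    deficient <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_surromod("degenerate design: column(s) ",
                  paste(deficient, collapse = ", "),
                  " carry no independent information",
                  class = "surromod_degenerate_design")
  }
  beta <- qr.coef(qx, Y)
  motion_model_params(
    x0 = beta[1L, ],
    xA = beta[2L, ],
    xAprime = if (amplitude_only) c(0, 0, 0) else beta[3L, ],
    surrogate = surrogate)
}

#' Predict tumor position from surrogate values
#'
#' @param params A [motion_model_params()].
#' @param A,Aprime Surrogate amplitude(s) and derivative(s); equal length.
#' @return n x 3 matrix of predicted positions (mm).
#' @export
predict_position <- function(params, A, Aprime) {
  stopifnot(inherits(params, "motion_model_params"))
  cbind(x = params$x0[1] + A * params$xA[1] + Aprime * params$xAprime[1],
        y = params$x0[2] + A * params$xA[2] + Aprime * params$xAprime[2],
        z = params$x0[3] + A * params$xA[3] + Aprime * params$xAprime[3])
}

#' Summarize residual vectors
#'
#' Magnitudes are Euclidean norms of the modeled-minus-measured vectors; the
#' summary reports their mean and 90th percentile (linear interpolation
#' between order statistics).
#'
#' @param residual_vectors n x 3 matrix of residuals (mm).
#' @return A `residual_summary` with fields `residual_vectors`, `magnitudes`,
#'   `mean`, `p90`, `n`.
#' @export
summarize_residuals <- function(residual_vectors) {
  m <- as_pos_matrix(residual_vectors)
  if (nrow(m) == 0L) stop_surromod("no residuals to summarize")
  mag <- sqrt(rowSums(m^2))
  structure(list(residual_vectors = m, magnitudes = mag,
                 mean = mean(mag),
                 p90 = unname(stats::quantile(mag, 0.9, type = 7)),
                 n = length(mag)),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat(sprintf("<residual_summary> n = %d, mean = %.3f mm, p90 = %.3f mm\n",
              x$n, x$mean, x$p90))
  invisible(x)
}

#' Residuals of a fitted model on validation pairs
#'
#' Computes modeled minus measured position for every validation pair and
#' summarizes the residual magnitudes.
#'
#' @param params A [motion_model_params()].
#' @param validation Data frame with columns `A`, `Aprime`, `x`, `y`, `z`.
#' @return A `residual_summary`.
#' @export
compute_residuals <- function(params, validation) {
  if (nrow(validation) == 0L) stop_surromod("empty validation set")
  pred <- predict_position(params, validation$A, validation$Aprime)
  summarize_residuals(pred - as.matrix(validation[, c("x", "y", "z")]))
}
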
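#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. All quantities are mm and seconds;
# axes follow the scanner convention: x lateral, y craniocaudal (cranial
# positive), z vertical (anterior positive).

stop_surromod <- function(..., class = "surromod_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "surromod_error")))
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stop_surromod(name, " must be a finite numeric scalar",
                  class = "surromod_parameter_error")
  if (strict && x <= lower)
    stop_surromod(name, " must be > ", lower, class = "surromod_parameter_error")
  if (!strict && x < lower)
    stop_surromod(name, " must be >= ", lower, class = "surromod_parameter_error")
  x
}

check_vec3 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop_surromod(name, " must be a finite numeric 3-vector",
                  class = "surromod_parameter_error")
  as.numeric(x)
}

# Derive a stream-specific 32-bit seed from a master seed. Keeps derived
# seeds strictly below 2^31 and reproducible.
derive_seed <- function(seed, stream) {
  s <- abs(as.numeric(seed)) %% 2147483629
  as.integer((s * 7919 + as.numeric(stream) * 104729) %% 2147483629)
}

# Mean of a piecewise-linear function (knots `times`, ordinates `values`)
# over the window [t0, t1], computed exactly from the trapezoid areas of the
# sub-segments. Errors if the window leaves the knot span.
pwl_window_mean <- function(times, values, t0, t1) {
  if (t1 <= t0) stop_surromod("window must have positive width")
  if (t0 < times[1L] || t1 > times[length(times)])
    stop_surromod("window [", signif(t0, 6), ", ", signif(t1, 6),
                  "] outside the trace span",
                  class = "surromod_span_error")
  knots <- times[times > t0 & times < t1]
  tt <- c(t0, knots, t1)
  vv <- stats::approx(times, values, xout = tt, rule = 1)$y
  dt <- diff(tt)
  sum((vv[-length(vv)] + vv[-1L]) / 2 * dt) / (t1 - t0)
}

# Largest gap (in seconds) between consecutive samples whose spans cover
# the window [t0, t1].
max_gap_in <- function(times, t0, t1) {
  i0 <- max(1L, findInterval(t0, times))
  i1 <- min(length(times), findInterval(t1, times) + 1L)
  if (i1 <= i0) return(0)
  max(diff(times[i0:i1]))
}
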
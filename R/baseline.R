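#' Detect full-exhalation extrema of a surrogate trace
#'
#' Segments the trace into breathing cycles and locates one full-exhalation
#' minimum per cycle. Cycles are delimited by crossings of the mid-level
#' between the 10th and 90th value percentiles; within each below-mid
#' segment bounded by crossings on both sides, the minimum is the numeric
#' argmin. Cycles whose prominence (lower adjacent peak minus the minimum)
#' falls below `prominence_threshold` times the median peak-to-peak
#' amplitude are rejected, and minima closer than `min_cycle_duration` are
#' deduplicated keeping the deeper one.
#'
#' @param trace A `surrogate_trace`.
#' @param prominence_threshold Fraction of the median peak-to-peak amplitude
#'   a cycle must reach (default 0.3).
#' @param min_cycle_duration Minimum time between consecutive minima (s).
#' @return A `cycle_segmentation`: `minima_times`, `minima_values`, plus the
#'   thresholds used.
#' @export
detect_exhalation_extrema <- function(trace, prominence_threshold = 0.3,
                                      min_cycle_duration = 1.5) {
  stopifnot(inherits(trace, "surrogate_trace"))
  v <- trace$values; t <- trace$times
  if (length(v) < 5L)
    stop_surromod("no cycles detected: trace too short",
                  class = "surromod_no_cycles")
  mid <- mean(stats::quantile(v, c(0.1, 0.9), names = FALSE))
  below <- v < mid
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  seg <- which(r$values)
  # only segments bounded by above-mid runs on both sides are full cycles
  seg <- seg[seg > 1L & seg < length(r$values)]
  if (length(seg) == 0L)
    stop_surromod("no cycles detected", class = "surromod_no_cycles")

  min_idx <- vapply(seg, function(s) {
    i <- starts[s]:ends[s]
    i[which.min(v[i])]
  }, integer(1))
  # prominence: the lower of the two adjacent above-mid peaks minus the min
  peak <- vapply(seq_along(r$values), function(s) {
    if (r$values[s]) return(NA_real_)
    max(v[starts[s]:ends[s]])
  }, numeric(1))
  prom <- vapply(seq_along(seg), function(j) {
    s <- seg[j]
    min(peak[s - 1L], peak[s + 1L]) - v[min_idx[j]]
  }, numeric(1))
  keep <- prom >= prominence_threshold * stats::median(prom)
  min_idx <- min_idx[keep]
  if (length(min_idx) == 0L)
    stop_surromod("no cycles detected", class = "surromod_no_cycles")

  # enforce minimum separation, dropping the shallower of offending pairs
  repeat {
    gaps <- diff(t[min_idx])
    bad <- which(gaps < min_cycle_duration)
    if (length(bad) == 0L) break
    b <- bad[1L]
    drop <- if (v[min_idx[b]] <= v[min_idx[b + 1L]]) b + 1L else b
    min_idx <- min_idx[-drop]
  }

  structure(list(minima_times = t[min_idx], minima_values = v[min_idx],
                 prominence_threshold = prominence_threshold,
                 min_cycle_duration = min_cycle_duration),
            class = "cycle_segmentation")
}

#' Running-median exhalation baseline
#'
#' Builds the baseline drift function as a running median over the
#' full-exhalation minima: the knot at minimum k is the median of the minima
#' values in the symmetric window of seven cycles (k-3 ... k+3). Near the
#' edges the window shrinks symmetrically; if fewer than seven minima exist
#' in total, every knot uses all of them. The baseline is evaluated by
#' linear interpolation between knots and constant extrapolation beyond the
#' first and last knot.
#'
#' @param trace A `surrogate_trace` (unused except for validation; the knots
#'   come from `seg`).
#' @param seg A `cycle_segmentation`.
#' @param window Running-median window length in cycles (odd, default 7).
#' @return A `baseline_function` with `knot_times` and `knot_values`.
#' @export
compute_baseline <- function(trace, seg, window = 7L) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  m <- seg$minima_values
  n <- length(m)
  if (n == 0L) stop_surromod("empty cycle segmentation")
  half <- (as.integer(window) - 1L) %/% 2L
  knots <- vapply(seq_len(n), function(k) {
    if (n < window) return(stats::median(m))
    h <- min(half, k - 1L, n - k)
    stats::median(m[(k - h):(k + h)])
  }, numeric(1))
  structure(list(knot_times = seg$minima_times, knot_values = knots),
            class = "baseline_function")
}

#' Evaluate a baseline function
#'
#' @param baseline A `baseline_function`.
#' @param times Times (s) at which to evaluate.
#' @return Baseline values (trace units).
#' @export
evaluate_baseline <- function(baseline, times) {
  stopifnot(inherits(baseline, "baseline_function"))
  if (length(baseline$knot_times) == 1L)
    return(rep(baseline$knot_values, length(times)))
  stats::approx(baseline$knot_times, baseline$knot_values, xout = times,
                rule = 2)$y
}

#' Subtract the exhalation baseline from a trace
#'
#' Removes the slow drift so that full-exhalation minima sit near zero
#' across the whole session; the result carries the `baseline_corrected`
#' flag.
#'
#' @param trace A `surrogate_trace`.
#' @param baseline A `baseline_function` (from [compute_baseline()]).
#' @return The corrected `surrogate_trace`.
#' @export
baseline_correct <- function(trace, baseline) {
  stopifnot(inherits(trace, "surrogate_trace"))
  surrogate_trace(trace$times,
                  trace$values - evaluate_baseline(baseline, trace$times),
                  trace$label, baseline_corrected = TRUE)
}

#' One-call baseline correction
#'
#' Convenience wrapper: detect exhalation extrema, build the running-median
#' baseline and subtract it.
#'
#' @inheritParams detect_exhalation_extrema
#' @return The corrected `surrogate_trace`.
#' @export
correct_trace <- function(trace, prominence_threshold = 0.3,
                          min_cycle_duration = 1.5) {
  seg <- detect_exhalation_extrema(trace, prominence_threshold,
                                   min_cycle_duration)
  baseline_correct(trace, compute_baseline(trace, seg))
}
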
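# 4DCT-style phase-binning comparator: tumor positions are looked up from
# the phase of the breathing surrogate alone, ignoring amplitude and
# derivative. Phase is defined exhale-to-exhale, linear in time, so equal
# phase can carry different amplitudes — the weakness the amplitude +
# derivative model addresses.

#' Breathing phase at query times
#'
#' Phase is the linear fraction of elapsed time between the two enclosing
#' full-exhalation minima: 0 at exhalation, approaching 1 just before the
#' next exhalation.
#'
#' @param trace The `surrogate_trace` the segmentation came from (validation
#'   only).
#' @param seg A `cycle_segmentation` from [detect_exhalation_extrema()].
#' @param times Query times (s); each must lie between the first and last
#'   minimum.
#' @return Phases in [0, 1).
#' @export
compute_phase <- function(trace, seg, times) {
  stopifnot(inherits(seg, "cycle_segmentation"))
  mt <- seg$minima_times
  if (length(mt) < 2L)
    stop_surromod("need >= 2 exhalation minima to define phase")
  if (any(times < mt[1L] | times >= mt[length(mt)]))
    stop_surromod("time outside the first/last exhalation minimum",
                  class = "surromod_span_error")
  i <- findInterval(times, mt)
  (times - mt[i]) / (mt[i + 1L] - mt[i])
}

#' Build a 4DCT-style phase-bin table
#'
#' Equal-width bins on [0, 1); each occupied bin's representative position is
#' the mean of its member positions, and empty bins inherit the position of
#' the nearest occupied bin (circular distance, ties toward the preceding
#' bin).
#'
#' @param phases Training phases in [0, 1).
#' @param positions n x 3 matrix of training tumor positions (mm).
#' @param n_bins Number of phase bins (default 10, standard 4DCT practice).
#' @return A `phase_bin_table` with `bin_positions` (n_bins x 3),
#'   `bin_counts`, and the bin edges.
#' @export
build_phase_bins <- function(phases, positions, n_bins = 10L) {
  m <- as_pos_matrix(positions)
  if (length(phases) != nrow(m) || length(phases) == 0L)
    stop_surromod("phases and positions must be non-empty and matched")
  if (any(phases < 0 | phases >= 1))
    stop_surromod("phases must lie in [0, 1)")
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(phases * n_bins) + 1L, n_bins)
  pos <- matrix(NA_real_, n_bins, 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  counts <- integer(n_bins)
  for (b in unique(bin)) {
    pos[b, ] <- colMeans(m[bin == b, , drop = FALSE])
    counts[b] <- sum(bin == b)
  }
  occupied <- which(counts > 0L)
  if (length(occupied) == 0L) stop_surromod("all phase bins empty")
  for (b in which(counts == 0L)) {
    d <- pmin((b - occupied) %% n_bins, (occupied - b) %% n_bins)
    nearest <- occupied[order(d, (b - occupied) %% n_bins)][1L]
    pos[b, ] <- pos[nearest, ]
  }
  structure(list(n_bins = n_bins,
                 phase_lo = (seq_len(n_bins) - 1L) / n_bins,
                 phase_hi = seq_len(n_bins) / n_bins,
                 bin_positions = pos, bin_counts = counts),
            class = "phase_bin_table")
}

#' Evaluate the phase method on validation data
#'
#' Looks up the binned tumor position for each validation phase and
#' summarizes bin-position minus measured-position residuals.
#'
#' @param table A `phase_bin_table`.
#' @param phases Validation phases in [0, 1).
#' @param positions n x 3 matrix of measured validation positions (mm).
#' @return A `residual_summary`.
#' @export
evaluate_phase_method <- function(table, phases, positions) {
  stopifnot(inherits(table, "phase_bin_table"))
  m <- as_pos_matrix(positions)
  bin <- pmin(floor(phases * table$n_bins) + 1L, table$n_bins)
  summarize_residuals(table$bin_positions[bin, , drop = FALSE] - m)
}
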
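#' Torso surface generator parameters
#'
#' Describes the deforming torso emulated by the surface generator. The
#' resting surface is a height field `base_height_map(x, y)`; breathing
#' displaces it vertically by `abdominal_weight_map(x, y) * v(t) +
#' thoracic_weight_map(x, y) * v(t - thorax_lag)`, i.e. the abdomen follows
#' the latent signal directly while the thorax follows with a lag (the
#' abdomen rises before the thorax during inspiration). The surface is
#' sampled as 11 laser lines of points at fixed lateral positions; Gaussian
#' point noise is added and points beyond `dropout_extent` from the midline
#' may drop out (poor reflection at the patient's sides).
#'
#' Defaults place the thoracic reference (xiphoid) at the origin and the
#' abdominal monitoring point 150 mm caudal to it; the abdominal weight map
#' peaks at exactly 1 there, so the abdominal point height reproduces the
#' latent signal (plus the static base height).
#'
#' @param base_height_map Function of (x, y) giving the resting height (mm).
#' @param abdominal_weight_map,thoracic_weight_map Functions of (x, y) giving
#'   the dimensionless motion weights of the abdominal and thoracic
#'   components.
#' @param thorax_lag Lag of the thoracic component behind the abdomen (s).
#' @param line_positions Craniocaudal y-coordinates of the laser lines (mm);
#'   strictly increasing. Default: 11 lines evenly spanning 225 mm.
#' @param points_per_line Number of captured points per line.
#' @param half_width Lateral half-extent of each line (mm).
#' @param dropout_rate_edges Per-frame dropout probability for points beyond
#'   `dropout_extent`; in [0, 1).
#' @param dropout_extent Lateral distance (mm) beyond which dropout applies.
#' @param point_noise_sd SD of isotropic-in-z point measurement noise (mm).
#' @return An object of class `torso_params`.
#' @export
torso_params <- function(base_height_map = default_base_height,
                         abdominal_weight_map = default_abdominal_weight,
                         thoracic_weight_map = default_thoracic_weight,
                         thorax_lag = 0.9,
                         line_positions = seq(-175, 50, length.out = 11),
                         points_per_line = 61,
                         half_width = 175,
                         dropout_rate_edges = 0.1,
                         dropout_extent = 130,
                         point_noise_sd = 0.1) {
  stopifnot(is.function(base_height_map), is.function(abdominal_weight_map),
            is.function(thoracic_weight_map))
  check_scalar(thorax_lag, "thorax_lag", 0)
  if (length(line_positions) < 2L || any(diff(line_positions) <= 0))
    stop_surromod("line_positions must be strictly increasing",
                  class = "surromod_parameter_error")
  check_scalar(points_per_line, "points_per_line", 2)
  check_scalar(half_width, "half_width", 0, strict = TRUE)
  check_scalar(dropout_rate_edges, "dropout_rate_edges", 0)
  if (dropout_rate_edges >= 1)
    stop_surromod("dropout_rate_edges must be < 1",
                  class = "surromod_parameter_error")
  check_scalar(dropout_extent, "dropout_extent", 0)
  check_scalar(point_noise_sd, "point_noise_sd", 0)
  structure(list(base_height_map = base_height_map,
                 abdominal_weight_map = abdominal_weight_map,
                 thoracic_weight_map = thoracic_weight_map,
                 thorax_lag = thorax_lag,
                 line_positions = as.numeric(line_positions),
                 points_per_line = as.integer(points_per_line),
                 half_width = half_width,
                 dropout_rate_edges = dropout_rate_edges,
                 dropout_extent = dropout_extent,
                 point_noise_sd = point_noise_sd),
            class = "torso_params")
}

#' @rdname torso_params
#' @param x,y Coordinates (mm): x lateral, y craniocaudal (cranial positive).
#' @export
default_base_height <- function(x, y) {
  (180 + 0.1 * y) * sqrt(pmax(0, 1 - (x / 220)^2))
}

#' @rdname torso_params
#' @export
default_abdominal_weight <- function(x, y) {
  exp(-(y + 150)^2 / (2 * 50^2)) * exp(-x^2 / (2 * 120^2))
}

#' @rdname torso_params
#' @export
default_thoracic_weight <- function(x, y) {
  0.7 * exp(-y^2 / (2 * 60^2)) * exp(-x^2 / (2 * 120^2))
}

#' Simulate a laser-line surface sequence
#'
#' Samples the deforming torso of [torso_params()] at the times of the latent
#' signal, producing one point-cloud frame per signal sample (frame count =
#' floor(duration x sample_rate)). Each frame holds, per laser line, points
#' at fixed (x, y) with height `z0 + w_ab * v(t) + w_th * v(t - lag)` plus
#' point noise; edge points beyond `dropout_extent` drop out independently
#' per frame with probability `dropout_rate_edges`.
#'
#' @param signal A `latent_signal` from [simulate_breathing_signal()].
#' @param torso A [torso_params()] object.
#' @param seed Integer seed for point noise and dropout.
#' @return A `surface_sequence`: a dense column-per-frame representation
#'   (per-line point coordinates, height matrix `Z`, dropout mask `keep`)
#'   from which individual `surface_frame` objects are materialized on
#'   demand via [as_frame_list()].
#' @export
simulate_surface_sequence <- function(signal, torso, seed = 1L) {
  if (!inherits(signal, "latent_signal") || length(signal$time) == 0L)
    stop_surromod("signal must be a non-empty latent_signal")
  if (!inherits(torso, "torso_params"))
    stop_surromod("torso must be a torso_params object",
                  class = "surromod_parameter_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  times <- signal$time
  nf <- length(times)
  v <- signal$value
  v_lag <- signal_at(signal, times - torso$thorax_lag)

  xs <- seq(-torso$half_width, torso$half_width,
            length.out = torso$points_per_line)
  edge <- which(abs(xs) > torso$dropout_extent)

  lines <- lapply(torso$line_positions, function(yl) {
    yv <- rep(yl, length(xs))
    Z <- torso$base_height_map(xs, yv) +
      torso$abdominal_weight_map(xs, yv) %o% v +
      torso$thoracic_weight_map(xs, yv) %o% v_lag
    if (torso$point_noise_sd > 0)
      Z <- Z + matrix(stats::rnorm(length(Z), 0, torso$point_noise_sd),
                      nrow = length(xs))
    keep <- NULL
    if (torso$dropout_rate_edges > 0 && length(edge)) {
      keep <- matrix(TRUE, length(xs), nf)
      keep[edge, ] <- matrix(stats::runif(length(edge) * nf) >=
                               torso$dropout_rate_edges,
                             length(edge), nf)
    }
    list(x = xs, y = yl, Z = Z, keep = keep)
  })
  structure(list(times = times, lines = lines,
                 line_positions = torso$line_positions),
            class = "surface_sequence")
}

#' Materialize surface frames from a sequence
#'
#' Converts the dense `surface_sequence` representation into a list of
#' `surface_frame` objects (dropping masked-out points); lists of frames
#' pass through unchanged.
#'
#' @param frames A `surface_sequence` or list of `surface_frame`s.
#' @return List of `surface_frame` objects.
#' @export
as_frame_list <- function(frames) {
  if (!inherits(frames, "surface_sequence")) return(frames)
  lapply(seq_along(frames$times), function(k) get_frame(frames, k))
}

# Materialize frame k of a dense sequence.
get_frame <- function(seq, k) {
  lines <- lapply(seq$lines, function(l) {
    ok <- if (is.null(l$keep)) TRUE else l$keep[, k]
    list(x = l$x[ok], y = rep(l$y, length(l$x))[ok], z = l$Z[ok, k])
  })
  structure(list(time = seq$times[k], lines = lines), class = "surface_frame")
}

#' Construct a single surface frame
#'
#' Builds a `surface_frame` from per-line point coordinates; used for tests
#' and when reading frames from CSV.
#'
#' @param time Timestamp (s).
#' @param lines List of lists with numeric `x`, `y`, `z` (mm), one per laser
#'   line, ordered caudal to cranial.
#' @return A `surface_frame`.
#' @export
surface_frame <- function(time, lines) {
  ok <- vapply(lines, function(l) {
    length(l$x) == length(l$y) && length(l$y) == length(l$z) &&
      all(is.finite(c(l$x, l$y, l$z)))
  }, logical(1))
  if (length(lines) == 0L || !all(ok))
    stop_surromod("lines must hold equal-length finite x, y, z vectors")
  if (all(vapply(lines, function(l) length(l$x) == 0L, logical(1))))
    stop_surromod("frame has no points", class = "surromod_empty_frame")
  structure(list(time = time, lines = lines), class = "surface_frame")
}

#' @export
print.surface_sequence <- function(x, ...) {
  cat(sprintf("<surface_sequence> %d frames, %d laser lines\n",
              length(x$times), length(x$line_positions)))
  invisible(x)
}
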
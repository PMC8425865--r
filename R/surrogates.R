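#' Surrogate extraction configuration
#'
#' Fixed lateral-plane coordinates and integration settings for the four
#' surface surrogates. The thoracic point (TP) sits at the xiphoid reference
#' (the coordinate origin in the lateral plane); the abdominal point (AP)
#' sits nominally 150 mm caudal to it, near the umbilicus. The
#' surface-derived volume (SDV) integrates heights over a centered 150 x 150
#' mm region of interest on a rectilinear grid of 20 mm spacing; the radial
#' distance mean (RDM) uses the raw captured points and needs no fixed
#' coordinates.
#'
#' @param ap_location (x, y) of the abdominal point (mm).
#' @param tp_location (x, y) of the thoracic point (mm).
#' @param roi ROI side lengths (mm) for the SDV, lateral then craniocaudal.
#' @param roi_center ROI center (x, y) (mm); the default centers it over the
#'   mid abdomen-thorax region covered by the laser lines.
#' @param grid_spacing SDV integration grid spacing (mm).
#' @param n_nearest_lines Laser lines used for fixed-coordinate height
#'   interpolation.
#' @param rdm_origin Origin for the radial distances (mm, 3-vector); the
#'   scanner/room origin by default.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(ap_location = c(0, -150),
                             tp_location = c(0, 0),
                             roi = c(150, 150),
                             roi_center = c(0, -75),
                             grid_spacing = 20,
                             n_nearest_lines = 3,
                             rdm_origin = c(0, 0, 0)) {
  if (length(roi) != 2L || any(roi <= 0))
    stop_surromod("roi sides must be positive", class = "surromod_parameter_error")
  check_scalar(grid_spacing, "grid_spacing", 0, strict = TRUE)
  if (grid_spacing >= min(roi))
    stop_surromod("grid_spacing must be smaller than the ROI sides",
                  class = "surromod_parameter_error")
  check_scalar(n_nearest_lines, "n_nearest_lines", 1)
  structure(list(ap_location = as.numeric(ap_location),
                 tp_location = as.numeric(tp_location),
                 roi = as.numeric(roi), roi_center = as.numeric(roi_center),
                 grid_spacing = grid_spacing,
                 n_nearest_lines = as.integer(n_nearest_lines),
                 rdm_origin = check_vec3(rdm_origin, "rdm_origin")),
            class = "surrogate_config")
}

#' Construct a surrogate trace
#'
#' A timestamped scalar surrogate signal, before or after baseline
#' correction.
#'
#' @param times Sample times (s), strictly increasing.
#' @param values Surrogate values (mm for AP/TP/RDM, mm^3 for SDV).
#' @param label One of `"AP"`, `"TP"`, `"RDM"`, `"SDV"`.
#' @param baseline_corrected Logical flag.
#' @return An object of class `surrogate_trace`.
#' @export
surrogate_trace <- function(times, values, label,
                            baseline_corrected = FALSE) {
  if (length(times) != length(values))
    stop_surromod("times and values must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop_surromod("times must be strictly increasing")
  if (!label %in% c("AP", "TP", "RDM", "SDV"))
    stop_surromod("label must be one of AP, TP, RDM, SDV")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label,
                 baseline_corrected = isTRUE(baseline_corrected)),
            class = "surrogate_trace")
}

#' @export
print.surrogate_trace <- function(x, ...) {
  cat(sprintf("<surrogate_trace> %s, %d samples%s\n", x$label,
              length(x$times),
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

# Usable lines of a frame (>= 2 points), with their mean craniocaudal
# coordinate, ordered as stored.
usable_lines <- function(frame) {
  n <- vapply(frame$lines, function(l) length(l$x), integer(1))
  idx <- which(n >= 2L)
  list(idx = idx,
       y = vapply(frame$lines[idx], function(l) mean(l$y), numeric(1)))
}

#' Interpolate surface height at fixed lateral-plane coordinates
#'
#' Compensates for the sliding of captured points along the body during
#' breathing by reading the surface height at fixed (x, y): within each of
#' the `n_lines` nearest laser lines the height at the query x is obtained by
#' linear interpolation along the polygonal chain, and the per-line heights
#' are then linearly interpolated in y. Exact for affine height fields.
#'
#' @param frame A `surface_frame`.
#' @param query Numeric (x, y) pair, or an n x 2 matrix of queries (mm).
#' @param n_lines Number of nearest lines to use (default 3; falls back to
#'   the available lines if some are missing, errors below 2 when the query
#'   is not bracketed).
#' @return Height(s) in mm.
#' @export
interpolate_height <- function(frame, query, n_lines = 3) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 2, byrow = TRUE)
  ul <- usable_lines(frame)
  if (length(ul$idx) < 1L)
    stop_surromod("frame has no usable laser lines",
                  class = "surromod_interpolation_error")
  out <- numeric(nrow(query))
  for (g in split(seq_len(nrow(query)), query[, 2])) {
    yq <- query[g[1L], 2]
    xq <- query[g, 1]
    sel <- ul$idx[order(abs(ul$y - yq))][seq_len(min(n_lines, length(ul$idx)))]
    ys <- vapply(frame$lines[sel], function(l) mean(l$y), numeric(1))
    o <- order(ys)
    sel <- sel[o]; ys <- ys[o]
    if (yq < ys[1L] - 1e-9 || yq > ys[length(ys)] + 1e-9)
      stop_surromod("query y = ", yq,
                    " mm outside the span of available laser lines",
                    class = "surromod_interpolation_error")
    zl <- vapply(sel, function(i) {
      l <- frame$lines[[i]]
      z <- stats::approx(l$x, l$z, xout = xq, rule = 1, ties = mean)$y
      if (anyNA(z))
        stop_surromod("query x outside the captured extent of line ", i,
                      class = "surromod_interpolation_error")
      z
    }, numeric(length(xq)))
    zl <- matrix(zl, nrow = length(xq))
    if (length(sel) == 1L) {
      out[g] <- zl[, 1L]
    } else {
      i <- max(1L, min(findInterval(yq, ys), length(ys) - 1L))
      w <- (yq - ys[i]) / (ys[i + 1L] - ys[i])
      out[g] <- (1 - w) * zl[, i] + w * zl[, i + 1L]
    }
  }
  out
}

#' Extract a fixed-point height surrogate (AP or TP)
#'
#' Reads the interpolated surface height at one fixed lateral-plane location
#' for every frame. Frames where interpolation fails (missing lines, query
#' outside the captured extent) are skipped and recorded in the trace's
#' `skipped` attribute; the returned trace stays strictly increasing in time.
#'
#' @param frames A `surface_sequence` or list of `surface_frame`s.
#' @param location (x, y) query location (mm).
#' @param config A [surrogate_config()].
#' @param label `"AP"` or `"TP"`.
#' @return A `surrogate_trace`.
#' @export
extract_point_surrogate <- function(frames, location, config = surrogate_config(),
                                    label = "AP") {
  if (inherits(frames, "surface_sequence"))
    return(fast_extract_point(frames, location, config, label))
  if (length(frames) == 0L) stop_surromod("frames must be non-empty")
  times <- vapply(frames, function(f) f$time, numeric(1))
  vals <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    vals[k] <- tryCatch(
      interpolate_height(frames[[k]], location, config$n_nearest_lines),
      surromod_interpolation_error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  tr <- surrogate_trace(times[ok], vals[ok], label)
  attr(tr, "skipped") <- times[!ok]
  tr
}

#' Radial distance mean of one frame
#'
#' Mean Euclidean distance from the origin to every captured point of all
#' polygonal chains; the only surrogate that uses the raw points rather than
#' fixed-coordinate interpolation.
#'
#' @param frame A `surface_frame`.
#' @param origin Reference origin (mm, 3-vector).
#' @return Mean radial distance (mm).
#' @export
compute_rdm <- function(frame, origin = c(0, 0, 0)) {
  px <- unlist(lapply(frame$lines, `[[`, "x"), use.names = FALSE)
  py <- unlist(lapply(frame$lines, `[[`, "y"), use.names = FALSE)
  pz <- unlist(lapply(frame$lines, `[[`, "z"), use.names = FALSE)
  if (length(px) == 0L)
    stop_surromod("frame has no points", class = "surromod_empty_frame")
  mean(sqrt((px - origin[1])^2 + (py - origin[2])^2 + (pz - origin[3])^2))
}

# Integration grid along one axis: regular spacing plus a final partial
# interval so the ROI is covered exactly.
sdv_axis <- function(lo, hi, spacing) {
  g <- seq(lo, hi, by = spacing)
  if (g[length(g)] < hi - 1e-9) g <- c(g, hi)
  g
}

# Trapezoid weights for a (possibly non-uniform) axis.
trap_weights <- function(g) {
  d <- diff(g)
  c(d[1L] / 2, (d[-length(d)] + d[-1L]) / 2, d[length(d)] / 2)
}

#' Surface-derived volume of one frame
#'
#' Volume between the horizontal plane z = 0 and the surface over the ROI,
#' integrated numerically: heights are interpolated on a rectilinear grid of
#' `grid_spacing` (with a final partial interval so the ROI is covered
#' exactly) and summed with 2-D trapezoid weights. Exact for planar
#' surfaces; positive when the surface lies above the plane.
#'
#' @param frame A `surface_frame`.
#' @param config A [surrogate_config()].
#' @return Volume (mm^3).
#' @export
compute_sdv <- function(frame, config = surrogate_config()) {
  gx <- sdv_axis(config$roi_center[1] - config$roi[1] / 2,
                 config$roi_center[1] + config$roi[1] / 2,
                 config$grid_spacing)
  gy <- sdv_axis(config$roi_center[2] - config$roi[2] / 2,
                 config$roi_center[2] + config$roi[2] / 2,
                 config$grid_spacing)
  q <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  z <- tryCatch(interpolate_height(frame, q, config$n_nearest_lines),
                surromod_interpolation_error = function(e)
                  stop_surromod("SDV grid node uninterpolable: ",
                                conditionMessage(e)))
  z <- matrix(z, nrow = length(gx))
  wx <- trap_weights(gx); wy <- trap_weights(gy)
  as.numeric(wx %*% z %*% wy)
}

#' Extract all four surface surrogates
#'
#' Applies the AP, TP, RDM and SDV extractors to a frame sequence. AP and TP
#' use fixed-coordinate interpolation at the configured locations; RDM uses
#' the raw points; SDV integrates over the configured ROI.
#'
#' @param frames A `surface_sequence` or list of `surface_frame`s.
#' @param config A [surrogate_config()].
#' @return Named list of four `surrogate_trace`s (`AP`, `TP`, `RDM`, `SDV`).
#' @export
extract_all_surrogates <- function(frames, config = surrogate_config()) {
  lapply(stats::setNames(nm = c("AP", "TP", "RDM", "SDV")),
         function(lab) surrogate_trace_for(frames, lab, config))
}

# ---- vectorized fast paths over dense surface sequences ------------------
#
# The dense representation makes every fixed-coordinate height a static
# linear functional of the per-line height columns, as long as none of the
# bracketing points is masked out by dropout. Frames where a needed point
# IS dropped are recomputed through the generic per-frame interpolation, so
# the fast and generic routes agree exactly.

# Heights at a single fixed (xq, yq) for every frame of a dense sequence.
# Returns list(values, bad): `bad` flags frames needing the generic path.
fast_point_heights <- function(seq, xq, yq, n_lines) {
  ys <- vapply(seq$lines, `[[`, numeric(1), "y")
  sel <- order(abs(ys - yq))[seq_len(min(n_lines, length(ys)))]
  sel <- sel[order(ys[sel])]
  ysel <- ys[sel]
  if (yq < ysel[1L] - 1e-9 || yq > ysel[length(ysel)] + 1e-9)
    stop_surromod("query y = ", yq,
                  " mm outside the span of available laser lines",
                  class = "surromod_interpolation_error")
  nf <- length(seq$times)
  bad <- rep(FALSE, nf)
  line_h <- lapply(sel, function(li) {
    l <- seq$lines[[li]]
    i <- findInterval(xq, l$x)
    if (i < 1L || i >= length(l$x)) {
      if (xq == l$x[length(l$x)]) i <- length(l$x) - 1L
      else stop_surromod("query x outside the captured extent of line ", li,
                         class = "surromod_interpolation_error")
    }
    w <- (xq - l$x[i]) / (l$x[i + 1L] - l$x[i])
    if (!is.null(l$keep))
      bad <<- bad | !(l$keep[i, ] & l$keep[i + 1L, ])
    (1 - w) * l$Z[i, ] + w * l$Z[i + 1L, ]
  })
  if (length(sel) == 1L) {
    values <- line_h[[1L]]
  } else {
    i <- max(1L, min(findInterval(yq, ysel), length(ysel) - 1L))
    w <- (yq - ysel[i]) / (ysel[i + 1L] - ysel[i])
    values <- (1 - w) * line_h[[i]] + w * line_h[[i + 1L]]
  }
  list(values = values, bad = bad)
}

# Vectorized point-surrogate extraction over a dense sequence; falls back to
# the generic route for dropout-affected frames.
fast_extract_point <- function(seq, location, config, label) {
  fp <- fast_point_heights(seq, location[1L], location[2L],
                           config$n_nearest_lines)
  vals <- fp$values
  for (k in which(fp$bad)) {
    vals[k] <- tryCatch(
      interpolate_height(get_frame(seq, k), location, config$n_nearest_lines),
      surromod_interpolation_error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  tr <- surrogate_trace(seq$times[ok], vals[ok], label)
  attr(tr, "skipped") <- seq$times[!ok]
  tr
}

# Vectorized SDV over a dense sequence.
fast_sdv <- function(seq, config) {
  gx <- sdv_axis(config$roi_center[1] - config$roi[1] / 2,
                 config$roi_center[1] + config$roi[1] / 2,
                 config$grid_spacing)
  gy <- sdv_axis(config$roi_center[2] - config$roi[2] / 2,
                 config$roi_center[2] + config$roi[2] / 2,
                 config$grid_spacing)
  wx <- trap_weights(gx); wy <- trap_weights(gy)
  vol <- numeric(length(seq$times))
  bad <- rep(FALSE, length(seq$times))
  for (j in seq_along(gy)) for (i in seq_along(gx)) {
    fp <- tryCatch(
      fast_point_heights(seq, gx[i], gy[j], config$n_nearest_lines),
      surromod_interpolation_error = function(e)
        stop_surromod("SDV grid node (", gx[i], ", ", gy[j],
                      ") uninterpolable: ", conditionMessage(e)))
    vol <- vol + wx[i] * wy[j] * fp$values
    bad <- bad | fp$bad
  }
  for (k in which(bad))
    vol[k] <- compute_sdv(get_frame(seq, k), config)
  vol
}

# Vectorized RDM over a dense sequence.
fast_rdm <- function(seq, origin) {
  tot <- numeric(length(seq$times))
  n <- numeric(length(seq$times))
  for (l in seq$lines) {
    r2 <- (l$x - origin[1])^2 + (l$y - origin[2])^2
    d <- sqrt(r2 + (l$Z - origin[3])^2)
    if (is.null(l$keep)) {
      tot <- tot + colSums(d)
      n <- n + length(l$x)
    } else {
      tot <- tot + colSums(d * l$keep)
      n <- n + colSums(l$keep)
    }
  }
  if (any(n == 0))
    stop_surromod("frame has no points", class = "surromod_empty_frame")
  tot / n
}
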
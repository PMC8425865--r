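# Plain-text serialization: frames, traces and observations as CSV; model
# parameters, study configs and run manifests as JSON.

#' Write / read surface frames as CSV
#'
#' Long format with columns `time_s`, `line_id`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param frames A `surface_sequence` or list of `surface_frame`s.
#' @param path Output CSV path.
#' @return `write_frames_csv` returns `path` invisibly; `read_frames_csv`
#'   returns a list of `surface_frame`s ordered by time.
#' @export
write_frames_csv <- function(frames, path) {
  frames <- as_frame_list(frames)
  tabs <- lapply(frames, function(f) {
    do.call(rbind, lapply(seq_along(f$lines), function(l) {
      ln <- f$lines[[l]]
      if (length(ln$x) == 0L) return(NULL)
      data.frame(time_s = f$time, line_id = l, x_mm = ln$x, y_mm = ln$y,
                 z_mm = ln$z)
    }))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  d <- utils::read.csv(path)
  times <- sort(unique(d$time_s))
  lapply(times, function(tt) {
    di <- d[d$time_s == tt, ]
    lines <- lapply(sort(unique(di$line_id)), function(l) {
      dl <- di[di$line_id == l, ]
      list(x = dl$x_mm, y = dl$y_mm, z = dl$z_mm)
    })
    surface_frame(tt, lines)
  })
}

#' Write / read a surrogate trace as CSV
#'
#' Columns `time_s`, `value`, `label`, `baseline_corrected`.
#'
#' @param trace A `surrogate_trace`.
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, value = trace$values,
                              label = trace$label,
                              baseline_corrected = trace$baseline_corrected),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  surrogate_trace(d$time_s, d$value, d$label[1L],
                  isTRUE(d$baseline_corrected[1L]))
}

#' Write / read tumor observations as CSV
#'
#' Columns `time_s`, `dx_mm`, `dy_mm`, `dz_mm` (intra-fractional
#' displacements).
#'
#' @param obs A `tumor_observations` data frame.
#' @param path CSV path.
#' @export
write_observations_csv <- function(obs, path) {
  utils::write.csv(data.frame(time_s = obs$time, dx_mm = obs$x,
                              dy_mm = obs$y, dz_mm = obs$z),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- data.frame(time = d$time_s, x = d$dx_mm, y = d$dy_mm, z = d$dz_mm)
  class(out) <- c("tumor_observations", "data.frame")
  out
}

#' Write a cycle segmentation as CSV
#'
#' Columns `time_s`, `value`, `kind` (always `"minimum"`).
#'
#' @param seg A `cycle_segmentation`.
#' @param path CSV path.
#' @export
write_segmentation_csv <- function(seg, path) {
  utils::write.csv(data.frame(time_s = seg$minima_times,
                              value = seg$minima_values, kind = "minimum"),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read fitted model parameters as JSON
#'
#' @param params A `motion_model_params`.
#' @param path JSON path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(
    list(surrogate = params$surrogate,
         units = list(x0 = "mm", xA = "mm per surrogate unit",
                      xAprime = "mm s per surrogate unit"),
         x0 = params$x0, xA = params$xA, xAprime = params$xAprime),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  motion_model_params(d$x0, d$xA, d$xAprime,
                      if (is.null(d$surrogate)) NA_character_ else d$surrogate)
}

#' Write a phase-bin table as CSV
#'
#' Columns `bin_index`, `phase_lo`, `phase_hi`, `x_mm`, `y_mm`, `z_mm`,
#' `count`.
#'
#' @param table A `phase_bin_table`.
#' @param path CSV path.
#' @export
write_bin_table_csv <- function(table, path) {
  utils::write.csv(data.frame(bin_index = seq_len(table$n_bins),
                              phase_lo = table$phase_lo,
                              phase_hi = table$phase_hi,
                              x_mm = table$bin_positions[, 1],
                              y_mm = table$bin_positions[, 2],
                              z_mm = table$bin_positions[, 3],
                              count = table$bin_counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write residual summaries as CSV rows
#'
#' @param table A `comparison_table` from [run_surrogate_comparison()].
#' @param path CSV path.
#' @export
write_comparison_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# Polynomial rolling hash of a string, reported as 8 hex digits; a
# dependency-free config fingerprint for manifests (not cryptographic).
config_fingerprint <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' Records the configuration (and its hash), master seed and package version
#' so a run can be reproduced exactly.
#'
#' @param path JSON path.
#' @param config The configuration list used for the run.
#' @param seed Master seed.
#' @export
write_manifest <- function(path, config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "surromod",
         version = as.character(utils::packageVersion("surromod")),
         r_version = as.character(getRversion()),
         seed = as.integer(seed),
         config_hash = config_fingerprint(as.character(cfg_json)),
         config = config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
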
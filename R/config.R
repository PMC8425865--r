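# Run configuration: a single JSON file with optional sections; every field
# falls back to the package default. Torso height/weight maps are not
# serializable and always come from torso_params() defaults; their scalar
# knobs (lag, noise, dropout, line layout) are configurable.

config_schema <- list(
  breathing = c("nominal_period", "period_sd", "nominal_amplitude",
                "amplitude_sd", "drift_rate", "noise_sd", "duration",
                "sample_rate"),
  torso = c("thorax_lag", "points_per_line", "half_width",
            "dropout_rate_edges", "dropout_extent", "point_noise_sd"),
  ground_truth = c("x0_true", "xA_true", "xAprime_true", "obs_noise_sd",
                   "session_shift"),
  schedule = c("n_acquisitions", "mean_interval", "interval_jitter",
               "exposure"),
  study = c("n_sessions", "session_shift_sd"),
  surrogate = c("ap_location", "tp_location", "roi", "roi_center",
                "grid_spacing", "n_nearest_lines", "rdm_origin")
)

#' Default study configuration
#'
#' @return Nested list mirroring the JSON config schema, filled with the
#'   package defaults.
#' @export
default_study_config <- function() {
  b <- unclass(breathing_params())
  t_ <- unclass(torso_params())[config_schema$torso]
  g <- unclass(ground_truth_model())
  s <- unclass(cine_schedule())
  list(breathing = b, torso = t_, ground_truth = g,
       schedule = s, study = list(n_sessions = 3L, session_shift_sd = 0.5),
       surrogate = unclass(surrogate_config()))
}

#' Validate a study configuration
#'
#' Checks the nested config against the documented schema: only known
#' sections and fields, numeric payloads, and constructor-level invariants
#' (by building the parameter objects).
#'
#' @param config Nested configuration list (e.g. from
#'   [read_study_config()]).
#' @return The validated config, invisibly; errors describe the offending
#'   field.
#' @export
validate_study_config <- function(config) {
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown))
    stop_surromod("unknown config section(s): ", paste(unknown, collapse = ", "),
                  class = "surromod_config_error")
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop_surromod("unknown field(s) in [", sec, "]: ",
                    paste(bad, collapse = ", "),
                    class = "surromod_config_error")
    ok <- vapply(config[[sec]], is.numeric, logical(1))
    if (any(!ok))
      stop_surromod("non-numeric field(s) in [", sec, "]: ",
                    paste(names(config[[sec]])[!ok], collapse = ", "),
                    class = "surromod_config_error")
  }
  study_objects(config)  # constructor invariants
  invisible(config)
}

# Build parameter objects from a (partial) config.
study_objects <- function(config) {
  take <- function(sec, ctor) do.call(ctor, config[[sec]] %||% list())
  list(breathing = take("breathing", breathing_params),
       torso = take("torso", torso_params),
       gt = if (is.null(config$ground_truth)) ground_truth_model() else
         ground_truth_model(config$ground_truth$x0_true %||% c(0, 0, 0),
                            config$ground_truth$xA_true %||% c(0.25, -1.2, 0.5),
                            config$ground_truth$xAprime_true %||% c(0.03, -0.25, 0.08),
                            config$ground_truth$obs_noise_sd %||% 0.5,
                            config$ground_truth$session_shift %||% c(0, 0, 0)),
       schedule = take("schedule", cine_schedule),
       surrogate = take("surrogate", surrogate_config),
       n_sessions = config$study$n_sessions %||% 3L,
       session_shift_sd = config$study$session_shift_sd %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration from JSON
#'
#' @param path JSON config path.
#' @return Validated nested configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_study_config(cfg)
  cfg
}

#' Simulate a study from a configuration
#'
#' @param config Nested configuration list (defaults where absent).
#' @param seed Master seed.
#' @return A `study_dataset`.
#' @export
study_from_config <- function(config = list(), seed = 1L) {
  ob <- study_objects(config)
  simulate_study(ob$breathing, ob$torso, ob$gt, ob$schedule,
                 n_sessions = ob$n_sessions,
                 session_shift_sd = ob$session_shift_sd, seed = seed)
}
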
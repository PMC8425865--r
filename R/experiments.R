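# Study drivers: three-session synthetic studies, the surrogate-comparison
# analysis (train on session 1, validate on sessions 2-3) and the
# training-set-size sweep, plus principal-axes projection utilities.

#' Simulate a multi-session study
#'
#' Generates a complete synthetic study: per session an independent
#' irregular breathing signal, a deforming-torso surface sequence, the
#' ground-truth hysteretic tumor trajectory and sparse quasi-random cine
#' observations. Session 1 plays the role of the planning (training)
#' session; later sessions get an independent random offset of the
#' internal-external correlation (`session_shift_sd`), emulating
#' inter-fraction change.
#'
#' @param breathing A [breathing_params()].
#' @param torso A [torso_params()].
#' @param gt A [ground_truth_model()]; its `session_shift` applies to
#'   session 1.
#' @param schedule A [cine_schedule()].
#' @param n_sessions Number of sessions (default 3).
#' @param session_shift_sd SD (mm) of the per-session correlation shift for
#'   sessions after the first.
#' @param seed Master integer seed; all per-session streams derive from it.
#' @return A `study_dataset`: list with `sessions` (each holding `signal`,
#'   `frames`, `trajectory`, `observations`, `shift`) and the generating
#'   parameter objects.
#' @export
simulate_study <- function(breathing = breathing_params(),
                           torso = torso_params(),
                           gt = ground_truth_model(),
                           schedule = cine_schedule(),
                           n_sessions = 3L, session_shift_sd = 0.5,
                           seed = 1L) {
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    signal <- simulate_breathing_signal(breathing, derive_seed(seed, 100L + s))
    frames <- simulate_surface_sequence(signal, torso,
                                        derive_seed(seed, 200L + s))
    shift <- gt$session_shift
    if (s > 1L && session_shift_sd > 0) {
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, 400L + s))
      shift <- shift + stats::rnorm(3, 0, session_shift_sd)
      .Random.seed_restore(old)
    }
    gt_s <- ground_truth_model(gt$x0_true, gt$xA_true, gt$xAprime_true,
                               gt$obs_noise_sd, shift)
    trajectory <- simulate_tumor_trajectory(signal, gt_s)
    obs <- sample_cine_sessions(trajectory, schedule,
                                derive_seed(seed, 300L + s))
    sessions[[s]] <- list(id = s, signal = signal, frames = frames,
                          trajectory = trajectory, observations = obs,
                          shift = shift)
  }
  structure(list(sessions = sessions, breathing = breathing, torso = torso,
                 gt = gt, schedule = schedule,
                 session_shift_sd = session_shift_sd, seed = as.integer(seed)),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d sessions, %d cine acquisitions each, seed %d\n",
              length(x$sessions), x$schedule$n_acquisitions, x$seed))
  invisible(x)
}

# Extract one surrogate trace from a frame sequence (vectorized over dense
# sequences, per-frame otherwise).
surrogate_trace_for <- function(frames, label, config = surrogate_config()) {
  dense <- inherits(frames, "surface_sequence")
  if (label %in% c("AP", "TP")) {
    loc <- if (label == "AP") config$ap_location else config$tp_location
    return(extract_point_surrogate(frames, loc, config, label))
  }
  if (!label %in% c("RDM", "SDV"))
    stop_surromod("unknown surrogate label: ", label)
  if (dense) {
    vals <- if (label == "RDM") fast_rdm(frames, config$rdm_origin)
            else fast_sdv(frames, config)
    return(surrogate_trace(frames$times, vals, label))
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  vals <- if (label == "RDM")
    vapply(frames, compute_rdm, numeric(1), origin = config$rdm_origin)
  else vapply(frames, compute_sdv, numeric(1), config = config)
  surrogate_trace(times, vals, label)
}

#' Session-level surrogate/position training pairs
#'
#' Runs the per-session pipeline for one surrogate: extract the trace,
#' baseline-correct it, differentiate it at the native frame rate, average
#' trace and derivative over each cine exposure window, and pair them with
#' the (optionally session-median-centered) measured tumor positions.
#'
#' @param dataset A `study_dataset`.
#' @param session Session index.
#' @param surrogate `"AP"`, `"TP"`, `"RDM"` or `"SDV"`.
#' @param config A [surrogate_config()].
#' @param deriv_smooth Moving-average window for [estimate_derivative()].
#' @param center Center positions with the session median (default `TRUE`).
#' @return List with `pairs` (data frame `time`, `A`, `Aprime`, `x`, `y`,
#'   `z`), the cycle segmentation `seg` of the corrected trace, and the
#'   corrected `trace`.
#' @export
session_pairs <- function(dataset, session, surrogate = "AP",
                          config = surrogate_config(), deriv_smooth = 0L,
                          center = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  ses <- dataset$sessions[[session]]
  raw <- surrogate_trace_for(ses$frames, surrogate, config)
  seg <- detect_exhalation_extrema(raw)
  trace <- baseline_correct(raw, compute_baseline(raw, seg))
  deriv <- estimate_derivative(trace, deriv_smooth)
  sam <- sample_surrogate_at(trace, deriv, ses$observations$time,
                             dataset$schedule$exposure)
  pos <- as_pos_matrix(ses$observations)
  if (center) pos <- center_positions(pos)
  pairs <- cbind(sam, as.data.frame(pos))
  list(pairs = pairs, seg = seg, trace = trace)
}

#' Compare the four surface surrogates (analysis part 1)
#'
#' Trains the amplitude + derivative model on all acquisitions of session 1
#' and evaluates it on the pooled acquisitions of the remaining sessions,
#' once per surrogate; optionally adds the phase-method comparator (driven
#' by AP) and an amplitude-only variant. The winner attribute ranks the
#' full-model rows by mean residual, ties broken by the 90th percentile.
#'
#' @param dataset A `study_dataset` with >= 2 sessions.
#' @param config A [surrogate_config()].
#' @param surrogates Surrogate labels to evaluate.
#' @param methods Subset of `c("low", "amplitude_only", "phase")`; the phase
#'   method always runs on AP.
#' @param deriv_smooth Moving-average window for the derivative.
#' @param n_bins Phase bins for the phase method.
#' @param center Apply per-session median centering of tumor positions
#'   (default `TRUE`, the paper-faithful setting; disable only for perfectly
#'   aligned synthetic worlds).
#' @return A `comparison_table` data frame with columns `surrogate`,
#'   `method`, `mean_mm`, `p90_mm`, `n_train`, `n_val`; attribute `winner`
#'   holds the best surrogate, attribute `summaries` the underlying
#'   `residual_summary` objects.
#' @export
run_surrogate_comparison <- function(dataset, config = surrogate_config(),
                                     surrogates = c("AP", "RDM", "SDV", "TP"),
                                     methods = c("low", "phase"),
                                     deriv_smooth = 0L, n_bins = 10L,
                                     center = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"),
            length(dataset$sessions) >= 2L)
  labels <- unique(c(surrogates, if ("phase" %in% methods) "AP"))
  n_ses <- length(dataset$sessions)
  per <- lapply(labels, function(lab) {
    lapply(seq_len(n_ses), function(s)
      tryCatch(session_pairs(dataset, s, lab, config, deriv_smooth, center),
               surromod_error = function(e)
                 stop_surromod("surrogate ", lab, ", session ", s, ": ",
                               conditionMessage(e))))
  })
  names(per) <- labels

  rows <- list()
  sums <- list()
  add_row <- function(surr, method, summ, n_train) {
    rows[[length(rows) + 1L]] <<- data.frame(
      surrogate = surr, method = method, mean_mm = summ$mean,
      p90_mm = summ$p90, n_train = n_train, n_val = summ$n)
    sums[[paste(surr, method, sep = ".")]] <<- summ
  }

  for (lab in surrogates) {
    train <- per[[lab]][[1L]]$pairs
    val <- do.call(rbind, lapply(per[[lab]][-1L], `[[`, "pairs"))
    if ("low" %in% methods) {
      fit <- fit_low_model(train, surrogate = lab)
      add_row(lab, "low", compute_residuals(fit, val), nrow(train))
    }
    if ("amplitude_only" %in% methods) {
      fit <- fit_low_model(train, amplitude_only = TRUE, surrogate = lab)
      add_row(lab, "amplitude_only", compute_residuals(fit, val), nrow(train))
    }
  }

  if ("phase" %in% methods) {
    ph <- phase_subset(per$AP[[1L]])
    table <- build_phase_bins(ph$phases, ph$pos, n_bins)
    res <- do.call(rbind, lapply(per$AP[-1L], function(sp) {
      v <- phase_subset(sp)
      evaluate_phase_method(table, v$phases, v$pos)$residual_vectors
    }))
    add_row("AP", "phase", summarize_residuals(res), length(ph$phases))
  }

  out <- do.call(rbind, rows)
  low <- out[out$method == "low", , drop = FALSE]
  if (nrow(low)) {
    o <- order(low$mean_mm, low$p90_mm)
    attr(out, "winner") <- low$surrogate[o[1L]]
  }
  attr(out, "summaries") <- sums
  class(out) <- c("comparison_table", "data.frame")
  out
}

# Observations of a session_pairs result that fall between the first and
# last exhalation minimum (the only ones with a defined phase).
phase_subset <- function(sp) {
  mt <- sp$seg$minima_times
  keep <- sp$pairs$time >= mt[1L] & sp$pairs$time < mt[length(mt)]
  list(phases = compute_phase(sp$trace, sp$seg, sp$pairs$time[keep]),
       pos = as_pos_matrix(sp$pairs[keep, ]))
}

#' Training-set-size sweep (analysis part 2)
#'
#' Varies the number of concurrent surrogate and image acquisitions used for
#' training: for each size n the model is fitted on the first n
#' chronological acquisitions of session 1 and the residual summary is
#' computed on the pooled later sessions. With `replicates > 1`, fresh
#' studies are generated from derived seeds and the aggregate curve is the
#' across-replicate median.
#'
#' @param dataset A `study_dataset`, or `NULL` to generate `replicates`
#'   studies internally from `study_args`.
#' @param sizes Training sizes (all >= 4), strictly increasing.
#' @param surrogate Driving surrogate (default AP, the part-1 winner).
#' @param replicates Number of replicate studies.
#' @param seed Master seed for replicate generation.
#' @param config A [surrogate_config()].
#' @param study_args List of arguments passed to [simulate_study()] when
#'   generating replicates.
#' @param random_subsets If `TRUE`, draw random (rather than chronological
#'   first-n) training subsets; off by default.
#' @param center Per-session median centering (see
#'   [run_surrogate_comparison()]).
#' @return A `sweep_result`: list with `sizes`, matrices `p90` and `mean`
#'   (replicates x sizes) and the median `aggregate_p90` curve.
#' @export
run_training_size_sweep <- function(dataset = NULL,
                                    sizes = c(4, 6, 8, 10, 15, 20, 30, 50, 75, 100),
                                    surrogate = "AP", replicates = 1L,
                                    seed = 1L, config = surrogate_config(),
                                    study_args = list(),
                                    random_subsets = FALSE, center = TRUE) {
  sizes <- as.integer(sizes)
  if (any(sizes < 4L)) stop_surromod("training sizes below 4 are rejected")
  if (any(diff(sizes) <= 0)) stop_surromod("sizes must be strictly increasing")
  p90 <- mean_mm <- matrix(NA_real_, replicates, length(sizes))
  for (r in seq_len(replicates)) {
    ds <- if (is.null(dataset))
      do.call(simulate_study, c(study_args,
                                list(seed = derive_seed(seed, 7000L + r))))
    else dataset
    train_all <- session_pairs(ds, 1L, surrogate, config, center = center)$pairs
    val <- do.call(rbind, lapply(seq_along(ds$sessions)[-1L], function(s)
      session_pairs(ds, s, surrogate, config, center = center)$pairs))
    if (max(sizes) > nrow(train_all))
      stop_surromod("largest size exceeds the ", nrow(train_all),
                    " training acquisitions")
    for (j in seq_along(sizes)) {
      idx <- if (random_subsets)
        sort(sample.int(nrow(train_all), sizes[j])) else seq_len(sizes[j])
      fit <- fit_low_model(train_all[idx, ], surrogate = surrogate)
      summ <- compute_residuals(fit, val)
      p90[r, j] <- summ$p90
      mean_mm[r, j] <- summ$mean
    }
  }
  structure(list(sizes = sizes, p90 = p90, mean = mean_mm,
                 aggregate_p90 = apply(p90, 2, stats::median),
                 surrogate = surrogate),
            class = "sweep_result")
}

#' Principal axes of a tumor trajectory
#'
#' Mean-centers the positions and expresses them in the orthonormal
#' eigenvectors of their covariance, ordered by decreasing variance, with a
#' deterministic sign convention (each axis's largest-magnitude component is
#' positive). Used to view trajectories in the plane of the two major
#' motion axes.
#'
#' @param positions n x 3 matrix of positions (mm), n >= 2.
#' @return List with `scores` (rotated coordinates), `axes` (3 x 3, columns
#'   are axes), `variances`, `center` and the numerical `rank`.
#' @export
project_principal_axes <- function(positions) {
  m <- as_pos_matrix(positions)
  if (nrow(m) < 2L) stop_surromod("need >= 2 positions")
  center <- colMeans(m)
  mc <- sweep(m, 2, center)
  e <- eigen(stats::cov(mc), symmetric = TRUE)
  axes <- e$vectors
  for (j in 1:3) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  variances <- pmax(e$values, 0)
  list(scores = mc %*% axes, axes = axes, variances = variances,
       center = center,
       rank = sum(variances > max(variances) * 1e-12))
}

#' Correlation between modeled and measured positions along principal axes
#'
#' Projects both position sets onto the principal axes of the measured
#' positions and reports the Pearson correlation per axis. Axes with zero
#' variance in either set are flagged `NA` (undefined), never silently 0.
#'
#' @param modeled,measured n x 3 matrices of positions (mm), n >= 3.
#' @return Named numeric vector `PA1`, `PA2`, `PA3` of correlations, with a
#'   logical `degenerate` attribute marking undefined axes.
#' @export
compute_modeled_measured_correlation <- function(modeled, measured) {
  mm <- as_pos_matrix(measured)
  md <- as_pos_matrix(modeled)
  if (nrow(mm) < 3L || nrow(mm) != nrow(md))
    stop_surromod("need >= 3 matched position pairs")
  pa <- project_principal_axes(mm)
  sm <- pa$scores
  sd_ <- sweep(md, 2, pa$center) %*% pa$axes
  scale_ <- max(stats::sd(sm[, 1]), stats::sd(sd_[, 1]))
  r <- vapply(1:3, function(j) {
    # an axis with (numerically) zero variance has no defined correlation
    if (stats::sd(sm[, j]) <= scale_ * 1e-8 ||
        stats::sd(sd_[, j]) <= scale_ * 1e-8) NA_real_
    else stats::cor(sm[, j], sd_[, j])
  }, numeric(1))
  names(r) <- c("PA1", "PA2", "PA3")
  attr(r, "degenerate") <- is.na(r)
  r
}
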
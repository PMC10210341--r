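# Per-trial kinematic features: movement time (T_M), average speed (AS),
# curvature index (CI), submovement count (NS), plus the curvature-based
# outlier rule used before model fitting.

#' Tangential speed profile of a trial
#'
#' Returns the recorded speed column verbatim when present; otherwise
#' differentiates the sampled path with centered finite differences over
#' possibly non-uniform time steps (one-sided at the endpoints).
#'
#' @param trial a `reach_trial`.
#' @return Numeric vector of speeds in m/s, one per sample.
#' @export
tangential_speed <- function(trial) {
  validate_trial(trial)
  if (!is.null(trial$v)) return(trial$v)
  t <- trial$t
  if (any(diff(t) == 0)) nr_validation_error("duplicate timestamps")
  n <- length(t)
  dxdt <- numeric(n); dydt <- numeric(n)
  i <- 2:(n - 1)
  dxdt[i] <- (trial$x[i + 1] - trial$x[i - 1]) / (t[i + 1] - t[i - 1])
  dydt[i] <- (trial$y[i + 1] - trial$y[i - 1]) / (t[i + 1] - t[i - 1])
  dxdt[1] <- (trial$x[2] - trial$x[1]) / (t[2] - t[1])
  dydt[1] <- (trial$y[2] - trial$y[1]) / (t[2] - t[1])
  dxdt[n] <- (trial$x[n] - trial$x[n - 1]) / (t[n] - t[n - 1])
  dydt[n] <- (trial$y[n] - trial$y[n - 1]) / (t[n] - t[n - 1])
  sqrt(dxdt^2 + dydt^2) / 100  # cm/s -> m/s
}

#' Movement window of a trial
#'
#' Finds the sample indices of movement onset and offset: the first and last
#' samples whose tangential speed reaches `onset_fraction` of the peak speed.
#' The trailing sub-threshold dwell (e.g. the 1 s hold inside the target that
#' ends a robot trial) therefore falls outside the window.
#'
#' @param trial a `reach_trial`.
#' @param onset_fraction speed threshold as a fraction of peak speed,
#'   in (0, 1).
#' @return Integer vector `c(onset_index, offset_index)`.
#' @export
movement_window <- function(trial, onset_fraction = 0.02) {
  if (!is.numeric(onset_fraction) || onset_fraction <= 0 || onset_fraction >= 1)
    nr_validation_error("onset_fraction must be in (0, 1)")
  v <- tangential_speed(trial)
  peak <- max(v)
  if (peak <= 0) nr_degenerate_error("stationary trial: peak speed is zero")
  above <- which(v >= onset_fraction * peak)
  c(above[1], above[length(above)])
}

#' Movement time of a trial
#'
#' Prefers the robot-recorded movement time when present (`use_recorded`);
#' otherwise measures the duration of the thresholded movement window.
#'
#' @inheritParams movement_window
#' @param use_recorded return `recorded_tm_ms` verbatim when available.
#' @return Movement time T_M in milliseconds.
#' @export
movement_time <- function(trial, onset_fraction = 0.02, use_recorded = TRUE) {
  if (use_recorded && !is.null(trial$recorded_tm_ms))
    return(trial$recorded_tm_ms)
  w <- movement_window(trial, onset_fraction)
  if (w[1] == w[2]) nr_degenerate_error("movement window is a single sample")
  (trial$t[w[2]] - trial$t[w[1]]) * 1000
}

polyline_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Path length of a trial in cm
#'
#' Polyline arc length of the sampled path, restricted to the movement
#' window by default.
#'
#' @inheritParams movement_window
#' @param window `"movement"` (thresholded window) or `"full"`.
#' @export
path_length <- function(trial, window = c("movement", "full"),
                        onset_fraction = 0.02) {
  window <- match.arg(window)
  idx <- if (window == "movement") {
    w <- movement_window(trial, onset_fraction)
    w[1]:w[2]
  } else seq_along(trial$t)
  polyline_length(trial$x[idx], trial$y[idx])
}

#' Average speed of a trial
#'
#' AS = traversed path length / movement time, in m/s.
#'
#' @param trial a `reach_trial`.
#' @param tm_ms movement time in ms (defaults to [movement_time()]).
#' @inheritParams path_length
#' @export
average_speed <- function(trial, tm_ms = NULL,
                          window = c("movement", "full"),
                          onset_fraction = 0.02, use_recorded = TRUE) {
  window <- match.arg(window)
  if (is.null(tm_ms)) tm_ms <- movement_time(trial, onset_fraction, use_recorded)
  if (!is.finite(tm_ms) || tm_ms <= 0) nr_domain_error("T_M must be > 0")
  len_cm <- path_length(trial, window, onset_fraction)
  if (len_cm <= 0) nr_degenerate_error("zero path length")
  (len_cm / 100) / (tm_ms / 1000)
}

#' Curvature index of a trial
#'
#' CI = path length / straight-line distance between the window endpoints.
#' A perfectly straight reach has CI = 1; corrective, meandering reaches have
#' larger values.
#'
#' @inheritParams average_speed
#' @export
curvature_index <- function(trial, window = c("movement", "full"),
                            onset_fraction = 0.02) {
  window <- match.arg(window)
  idx <- if (window == "movement") {
    w <- movement_window(trial, onset_fraction)
    w[1]:w[2]
  } else seq_along(trial$t)
  x <- trial$x[idx]; y <- trial$y[idx]
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord < 1e-9)
    nr_degenerate_error("closed path: window start equals window end")
  polyline_length(x, y) / chord
}

#' Extract kinematic features from a session
#'
#' Computes one (T_M, AS, CI, NS, path length) row per trial. Trials that are
#' degenerate (stationary, zero path, closed path) are skipped and reported
#' separately, mirroring protocols where unreachable targets are skipped.
#'
#' @param session a `reach_session`.
#' @param onset_fraction threshold for the movement window.
#' @param use_recorded prefer robot-recorded movement times.
#' @param window `"movement"` or `"full"` for AS/CI path accounting.
#' @param ns compute the submovement count by minimum-jerk decomposition
#'   (the expensive step); when `FALSE`, `NS` is `NA`.
#' @param ns_tolerance,max_pulses passed to [decompose_submovements()].
#' @return A data frame of class `reach_features` with columns `subject, arm,
#'   target_id, direction_deg, A_cm, W_cm, TM_ms, AS_mps, CI, NS, path_cm,
#'   outlier_flag`, and an attribute `"skipped"` describing skipped trials.
#' @export
extract_features <- function(session, onset_fraction = 0.02,
                             use_recorded = TRUE,
                             window = c("movement", "full"),
                             ns = TRUE, ns_tolerance = 0.05,
                             max_pulses = 10) {
  validate_session(session)
  window <- match.arg(window)
  if (length(session$trials) == 0)
    nr_validation_error("session has no trials")
  rows <- list(); skipped <- list()
  for (i in seq_along(session$trials)) {
    trial <- session$trials[[i]]
    res <- tryCatch({
      tm <- movement_time(trial, onset_fraction, use_recorded)
      len <- path_length(trial, window, onset_fraction)
      as_mps <- (len / 100) / (tm / 1000)
      ci <- curvature_index(trial, window, onset_fraction)
      ns_val <- NA_integer_
      if (ns) {
        w <- movement_window(trial, onset_fraction)
        v <- tangential_speed(trial)[w[1]:w[2]]
        dt <- stats::median(diff(trial$t[w[1]:w[2]]))
        dec <- decompose_submovements(v, dt,
                                      rmse_tolerance_fraction = ns_tolerance,
                                      max_pulses = max_pulses)
        ns_val <- dec$ns
      }
      tgt <- target_of(session, trial$target_id)
      data.frame(subject = trial$subject, arm = trial$arm,
                 target_id = trial$target_id,
                 direction_deg = tgt$direction_deg, A_cm = tgt$A_cm,
                 W_cm = tgt$W_cm, TM_ms = tm, AS_mps = as_mps, CI = ci,
                 NS = ns_val, path_cm = len, outlier_flag = FALSE)
    }, nr_degenerate_error = function(e) e$message)
    if (is.character(res))
      skipped[[length(skipped) + 1]] <- data.frame(trial = i, reason = res)
    else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0)
    nr_validation_error("all trials degenerate; no features extracted")
  out <- do.call(rbind, rows)
  class(out) <- c("reach_features", "data.frame")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(trial = integer(), reason = character())
  out
}

#' Reject curvature-index outliers
#'
#' Flags trials whose CI lies beyond two interquartile ranges outside the
#' quartiles: below `Q1 - 2 IQR` or above `Q3 + 2 IQR`. Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' Extreme CI marks reaching-by-mistake, which should not inform a normal
#' reaching model.
#'
#' @param features a `reach_features` data frame (>= 5 rows).
#' @return A list with `kept` and `rejected` feature frames (rejected rows
#'   have `outlier_flag = TRUE`; input order preserved within each) and
#'   `fences = c(lower, upper)`.
#' @export
reject_ci_outliers <- function(features) {
  if (nrow(features) < 5)
    nr_validation_error("need at least 5 trials for CI outlier rejection")
  ci <- features$CI
  q <- stats::quantile(ci, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 2 * iqr, q[2] + 2 * iqr)
  out <- ci < fences[1] | ci > fences[2]
  kept <- features[!out, , drop = FALSE]
  rejected <- features[out, , drop = FALSE]
  if (nrow(rejected)) rejected$outlier_flag <- TRUE
  list(kept = kept, rejected = rejected, fences = fences)
}
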
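# Seeded synthetic reaching sessions. Generation is feature-first: kinematic
# features (AS, T_M, CI, NS) are sampled from the generative law, then a
# trajectory consistent with them is realized, so the law parameters are
# exactly recoverable from the ground truth and approximately from the
# re-extracted trajectories.
#
# Normal mode: T_M = e^k A^alpha AS^beta x lognormal noise; the path is a
# single circular arc of chord A and arc length AS*T_M traversed with one
# minimum-jerk speed pulse.
#
# Erroneous mode: T_M = e^k A^alpha AS^beta (NS+1)^d CI^f x lognormal noise;
# the path is NS overlapping minimum-jerk pulses with alternating direction
# jitter solved so the realized polyline curvature index matches the sampled
# CI.

#' Configuration for synthetic reaching sessions
#'
#' Defaults emulate a robot-aided center-out protocol: 8 directions at 45
#' degree spacing, distances 6--14 cm with a 2 cm target, 3 repetitions
#' (120 trials), average speeds around 0.045 m/s, movement times of roughly
#' 1.4--3.1 s, normal-mode curvature near 1.2, and erroneous reaching with
#' 3--6 submovements and inflated curvature.
#'
#' @param directions target directions in degrees.
#' @param distances_cm target distances in cm.
#' @param width_cm target width in cm.
#' @param reps repetitions per target.
#' @param k,alpha,beta normal-law parameters (`T_M = e^k A^alpha AS^beta`,
#'   A in m, AS in m/s, T_M in s).
#' @param d,f erroneous-law exponents on `NS+1` and `CI`.
#' @param as_log_mean,as_log_sd lognormal law for average speed (m/s).
#' @param sigma movement-time noise log-sd.
#' @param ns_support,ns_weights erroneous-mode submovement count law
#'   (integers >= 1 and their sampling weights).
#' @param ci_shape,ci_scale erroneous-mode curvature law `CI = 1 +
#'   Gamma(shape, scale)`.
#' @param rate_hz trajectory sampling rate.
#' @param seed integer seed; recorded in every output.
#' @param subject,arm identifiers stamped on the session.
#' @param realize realize full trajectories (`TRUE`) or produce only the
#'   ground-truth feature table (fast path; the sampled features are
#'   identical because realization consumes no randomness).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(directions = seq(0, 315, by = 45),
                         distances_cm = c(6, 8, 10, 12, 14),
                         width_cm = 2,
                         reps = 3,
                         k = 0.361, alpha = 0.95, beta = -0.9,
                         d = 0.5, f = 0.5,
                         as_log_mean = log(0.045), as_log_sd = 0.25,
                         sigma = 0.1,
                         ns_support = 3:6,
                         ns_weights = c(0.4, 0.3, 0.2, 0.1),
                         ci_shape = 1, ci_scale = 0.5,
                         rate_hz = 75,
                         seed = 1,
                         subject = "SYN01",
                         arm = NULL,
                         realize = TRUE) {
  cfg <- structure(list(
    directions = directions, distances_cm = distances_cm,
    width_cm = width_cm, reps = as.integer(reps),
    k = k, alpha = alpha, beta = beta, d = d, f = f,
    as_log_mean = as_log_mean, as_log_sd = as_log_sd, sigma = sigma,
    ns_support = as.integer(ns_support), ns_weights = ns_weights,
    ci_shape = ci_shape, ci_scale = ci_scale,
    rate_hz = rate_hz, seed = as.integer(seed),
    subject = as.character(subject), arm = arm, realize = isTRUE(realize)
  ), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$reps < 1) nr_config_error("reps must be >= 1")
  if (any(cfg$distances_cm <= 0) || cfg$width_cm <= 0)
    nr_config_error("distances and width must be positive")
  if (cfg$as_log_sd < 0 || cfg$sigma < 0)
    nr_config_error("noise scales must be non-negative")
  if (length(cfg$ns_support) != length(cfg$ns_weights) ||
      any(cfg$ns_weights < 0) || sum(cfg$ns_weights) <= 0)
    nr_config_error("ns_weights must be non-negative, matching ns_support")
  if (any(cfg$ns_support < 1)) nr_config_error("ns_support must be >= 1")
  if (cfg$ci_shape <= 0 || cfg$ci_scale < 0)
    nr_config_error("ci_shape must be > 0, ci_scale >= 0")
  if (cfg$rate_hz <= 0) nr_config_error("rate_hz must be > 0")
  invisible(cfg)
}

#' Read a synthetic configuration from YAML or JSON
#'
#' Keys map one-to-one onto [synth_config()] arguments; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) nr_io_error(sprintf("file does not exist: %s", path))
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else if (grepl("\\.json$", path))
            jsonlite::read_json(path, simplifyVector = TRUE)
          else nr_format_error("config must be .yaml, .yml or .json")
  if (!is.list(vals)) nr_config_error("config file must hold a mapping")
  known <- setdiff(names(formals(synth_config)), "...")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    nr_config_error(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  do.call(synth_config, vals)
}

normal_law_tm <- function(cfg, A_m, AS) {
  exp(cfg$k) * A_m^cfg$alpha * AS^cfg$beta
}

# circular-arc path of chord A and arc length L in the chord frame
# (origin -> (A, 0)), evaluated at arc-length positions svec
arc_points <- function(A, L, svec) {
  if (L <= A * (1 + 1e-12)) {
    frac <- if (L > 0) svec / L else 0
    return(cbind(frac * A, 0))
  }
  phi <- stats::uniroot(function(p) p / sin(p) - L / A,
                        c(1e-9, pi - 1e-9), tol = 1e-12)$root
  R <- A / (2 * sin(phi))
  C <- c(A / 2, -R * cos(phi))
  a0 <- pi / 2 + phi
  ang <- a0 - svec / R
  cbind(C[1] + R * cos(ang), C[2] + R * sin(ang))
}

rotate_xy <- function(xy, theta_rad) {
  cbind(xy[, 1] * cos(theta_rad) - xy[, 2] * sin(theta_rad),
        xy[, 1] * sin(theta_rad) + xy[, 2] * cos(theta_rad))
}

time_grid <- function(TM_s, rate_hz) {
  t <- seq(0, TM_s, by = 1 / rate_hz)
  if (TM_s - t[length(t)] > 1e-9) t <- c(t, TM_s)
  t
}

# single-pulse arc trial: chord A_cm at theta, length L_cm, duration TM_s
realize_arc_trial <- function(cfg, subject, arm, target_id, theta_deg,
                              A_cm, L_cm, TM_s) {
  t <- time_grid(TM_s, cfg$rate_hz)
  tau <- t / TM_s
  s <- L_cm * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  xy <- rotate_xy(arc_points(A_cm, L_cm, s), theta_deg * pi / 180)
  v <- (L_cm / 100 / TM_s) * (30 * tau^4 - 60 * tau^3 + 30 * tau^2)
  reach_trial(subject, arm, target_id, t, xy[, 1], xy[, 2], v = v,
              recorded_tm_ms = TM_s * 1000, rate_hz = cfg$rate_hz)
}

# multi-pulse trial with direction jitter solved for a target curvature index
realize_jitter_trial <- function(cfg, subject, arm, target_id, theta_deg,
                                 A_cm, CI, NS, TM_s, overlap = 0.3,
                                 decay = 0.75) {
  t <- time_grid(TM_s, cfg$rate_hz)
  D <- TM_s / (1 + (NS - 1) * (1 - overlap))
  onsets <- (seq_len(NS) - 1) * (1 - overlap) * D
  w <- decay^(seq_len(NS) - 1); w <- w / sum(w)
  signs <- (-1)^(seq_len(NS) - 1)
  kernels <- vapply(seq_len(NS),
                    function(j) minjerk_speed(t, onsets[j], D, w[j]),
                    numeric(length(t)))
  geom <- function(delta) {
    vx <- kernels %*% cos(signs * delta)
    vy <- kernels %*% sin(signs * delta)
    dt <- diff(t)
    px <- cumsum(c(0, (vx[-1] + vx[-length(vx)]) / 2 * dt))
    py <- cumsum(c(0, (vy[-1] + vy[-length(vy)]) / 2 * dt))
    P <- polyline_length(px, py)
    E <- c(px[length(px)], py[length(py)])
    list(px = px, py = py, P = P, E = E,
         ratio = P / sqrt(sum(E^2)), vx = vx, vy = vy)
  }
  dmax <- 1.45
  if (geom(dmax)$ratio < CI) return(NULL)  # curvature target unreachable
  delta <- if (CI <= 1 + 1e-9) 0 else
    stats::uniroot(function(dd) geom(dd)$ratio - CI, c(0, dmax),
                   tol = 1e-10)$root
  g <- geom(delta)
  gamma <- A_cm / sqrt(sum(g$E^2))
  rot <- theta_deg * pi / 180 - atan2(g$E[2], g$E[1])
  xy <- rotate_xy(cbind(g$px, g$py) * gamma, rot)
  v <- gamma * sqrt(g$vx^2 + g$vy^2) / 100
  reach_trial(subject, arm, target_id, t, xy[, 1], xy[, 2], v = as.numeric(v),
              recorded_tm_ms = TM_s * 1000, rate_hz = cfg$rate_hz)
}

truth_frame <- function(rows) {
  out <- do.call(rbind, rows)
  class(out) <- c("reach_features", "data.frame")
  out
}

#' Generate a synthetic normal reaching session
#'
#' Samples per-trial average speed, applies the normal power law with
#' lognormal noise to obtain the movement time, and realizes each trial as a
#' circular arc of chord A and arc length `AS * T_M` (raised to A when the
#' draw falls short) traversed with a single minimum-jerk pulse. The
#' ground-truth features carry the realized `AS = L / T_M` and `CI = L / A`,
#' so `AS * T_M` equals the path length identically.
#'
#' @param config a [synth_config()].
#' @param arm arm label for the session (default `"less_affected"`, or the
#'   config's `arm` when set).
#' @return A list with `session` (a `reach_session`, or `NULL` when
#'   `config$realize` is `FALSE`) and `truth` (a `reach_features` frame).
#' @export
generate_normal_session <- function(config, arm = NULL) {
  validate_synth_config(config)
  arm <- arm %||% config$arm %||% "less_affected"
  grid <- target_grid(config$directions, config$distances_cm, config$width_cm)
  # median-case sanity: the speed law must roughly cover the distances
  AS_med <- exp(config$as_log_mean)
  L_med <- AS_med * normal_law_tm(config, grid$A_cm / 100, AS_med) * 100
  if (any(L_med < 0.5 * grid$A_cm))
    nr_config_error("inconsistent speed law: median path length < A/2")
  set.seed(config$seed)
  trials <- list(); rows <- list()
  for (rep in seq_len(config$reps)) for (i in seq_len(nrow(grid))) {
    A_cm <- grid$A_cm[i]; A_m <- A_cm / 100
    AS <- exp(stats::rnorm(1, config$as_log_mean, config$as_log_sd))
    z <- stats::rnorm(1)
    TM_s <- normal_law_tm(config, A_m, AS) * exp(config$sigma * z)
    L_m <- AS * TM_s
    if (L_m < A_m) L_m <- A_m
    AS_real <- L_m / TM_s
    rows[[length(rows) + 1]] <- data.frame(
      subject = config$subject, arm = arm, target_id = grid$target_id[i],
      direction_deg = grid$direction_deg[i], A_cm = A_cm,
      W_cm = config$width_cm, TM_ms = TM_s * 1000, AS_mps = AS_real,
      CI = L_m / A_m, NS = 1L, path_cm = L_m * 100, outlier_flag = FALSE)
    if (config$realize)
      trials[[length(trials) + 1]] <- realize_arc_trial(
        config, config$subject, arm, grid$target_id[i],
        grid$direction_deg[i], A_cm, L_m * 100, TM_s)
  }
  session <- if (config$realize)
    reach_session(config$subject, arm, trials, grid, seed = config$seed)
  else NULL
  list(session = session, truth = truth_frame(rows), config = config)
}

#' Generate a synthetic erroneous reaching session
#'
#' Samples average speed, submovement count and curvature index, applies the
#' erroneous power law (`(NS+1)^d CI^f` factors on top of the normal law)
#' with lognormal noise, and realizes each trial as `NS` overlapping
#' minimum-jerk pulses whose alternating direction jitter is solved so the
#' realized polyline curvature matches the sampled CI. Curvature targets the
#' pulse geometry cannot reach are resampled a bounded number of times.
#'
#' Ground truth records the sampled feature values; note that the average
#' speed re-extracted from a realized trajectory is `CI * A / T_M` by
#' construction, not the sampled AS (see the package vignette).
#'
#' @inheritParams generate_normal_session
#' @param arm arm label (default `"affected"`).
#' @return As [generate_normal_session()].
#' @export
generate_erroneous_session <- function(config, arm = NULL) {
  validate_synth_config(config)
  arm <- arm %||% config$arm %||% "affected"
  grid <- target_grid(config$directions, config$distances_cm, config$width_cm)
  set.seed(config$seed)
  trials <- list(); rows <- list()
  degenerate_ns <- length(config$ns_support) == 1
  degenerate_ci <- config$ci_scale == 0
  for (rep in seq_len(config$reps)) for (i in seq_len(nrow(grid))) {
    A_cm <- grid$A_cm[i]; A_m <- A_cm / 100
    AS <- exp(stats::rnorm(1, config$as_log_mean, config$as_log_sd))
    z <- stats::rnorm(1)
    trial <- NULL
    for (attempt in 1:20) {
      NS <- if (degenerate_ns) config$ns_support else
        sample(config$ns_support, 1, prob = config$ns_weights)
      CI <- 1 + (if (degenerate_ci) 0 else
        stats::rgamma(1, shape = config$ci_shape, scale = config$ci_scale))
      TM_s <- normal_law_tm(config, A_m, AS) * (NS + 1)^config$d *
        CI^config$f * exp(config$sigma * z)
      if (!config$realize) { trial <- NA; break }
      trial <- if (NS == 1)
        realize_arc_trial(config, config$subject, arm, grid$target_id[i],
                          grid$direction_deg[i], A_cm, CI * A_cm, TM_s)
      else
        realize_jitter_trial(config, config$subject, arm, grid$target_id[i],
                             grid$direction_deg[i], A_cm, CI, NS, TM_s)
      if (!is.null(trial)) break
      if (degenerate_ns && degenerate_ci)
        nr_config_error("curvature target unreachable with degenerate laws")
    }
    if (is.null(trial))
      nr_config_error(sprintf(
        "could not realize CI after 20 resamples at target %d",
        grid$target_id[i]))
    rows[[length(rows) + 1]] <- data.frame(
      subject = config$subject, arm = arm, target_id = grid$target_id[i],
      direction_deg = grid$direction_deg[i], A_cm = A_cm,
      W_cm = config$width_cm, TM_ms = TM_s * 1000, AS_mps = AS,
      CI = CI, NS = as.integer(NS), path_cm = CI * A_cm,
      outlier_flag = FALSE)
    if (config$realize) trials[[length(trials) + 1]] <- trial
  }
  session <- if (config$realize)
    reach_session(config$subject, arm, trials, grid, seed = config$seed)
  else NULL
  list(session = session, truth = truth_frame(rows), config = config)
}

#' Convert ground-truth features to measurement-equivalent features
#'
#' Replaces the average-speed column by the value a measurement pipeline
#' produces: traversed path length divided by movement time. For normal-mode
#' ground truth this is an identity (the generator already stores the
#' realized speed); for erroneous-mode ground truth it substitutes the
#' observable `AS = CI * A / T_M` for the generative law's sampled speed.
#' Model comparisons on clinical-style data should use these observed
#' features; generative parameter recovery should use the raw ground truth.
#'
#' @param features a ground-truth `reach_features` frame with `path_cm`.
#' @return The frame with `AS_mps` recomputed from path and time.
#' @export
observed_features <- function(features) {
  if (!"path_cm" %in% names(features))
    nr_validation_error("features must carry path_cm")
  features$AS_mps <- (features$path_cm / 100) / (features$TM_ms / 1000)
  features
}

#' Generate a synthetic patient: less-affected and affected sessions
#'
#' The less-affected session follows the normal law of `config_normal`; the
#' affected session follows the erroneous law of `config_err`, which should
#' share the subject, grid and `(k, alpha, beta)` so that the affected arm's
#' inflation is attributable to the `(NS+1)^d CI^f` factors. Optionally a
#' set of unreachable targets is removed from the affected session,
#' emulating trials skipped because the subject could not reach.
#'
#' @param config_normal,config_err [synth_config()]s sharing subject and
#'   grid (use different seeds for independent noise).
#' @param unreachable integer target ids absent from the affected session.
#' @return A list with `less_affected` and `affected`, each as returned by
#'   the session generators.
#' @export
generate_patient <- function(config_normal, config_err, unreachable = NULL) {
  same_grid <- identical(config_normal$directions, config_err$directions) &&
    identical(config_normal$distances_cm, config_err$distances_cm) &&
    identical(config_normal$width_cm, config_err$width_cm)
  if (!same_grid) nr_validation_error("patient configs must share the grid")
  if (!identical(config_normal$subject, config_err$subject))
    nr_validation_error("patient configs must share the subject")
  less <- generate_normal_session(config_normal, arm = "less_affected")
  aff <- generate_erroneous_session(config_err, arm = "affected")
  if (!is.null(unreachable)) {
    keep <- !(aff$truth$target_id %in% unreachable)
    aff$truth <- aff$truth[keep, , drop = FALSE]
    if (!is.null(aff$session)) {
      ids <- vapply(aff$session$trials, function(tr) tr$target_id, integer(1))
      aff$session$trials <- aff$session$trials[!(ids %in% unreachable)]
    }
  }
  list(less_affected = less, affected = aff)
}
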
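# Domain containers and plain-text I/O for planar center-out reaching data.
#
# Canonical units throughout: positions and target distance/width in cm,
# sample time in seconds, movement time in milliseconds, speeds in m/s.
# Coordinates are planar Cartesian with the start position at the origin;
# a target at direction theta (degrees, counter-clockwise from +x) and
# distance A sits at (A cos theta, A sin theta).

#' Build a center-out target grid
#'
#' Creates the Cartesian product of reaching directions and distances with a
#' fixed target width, the standard layout of robot-aided center-out reaching
#' protocols (e.g. 8 directions at 45 degree spacing crossed with distances of
#' 6--14 cm and a 2 cm target).
#'
#' Targets are indexed deterministically: sorted by distance, then direction.
#'
#' @param directions numeric vector of target directions in degrees, each in
#'   `[0, 360)`, measured counter-clockwise from +x.
#' @param distances_cm numeric vector of start-to-target distances in cm.
#' @param width_cm single positive target width (diameter) in cm.
#' @return A data frame with columns `target_id`, `direction_deg`, `A_cm`,
#'   `W_cm`, one row per target.
#' @examples
#' grid <- target_grid(seq(0, 315, by = 45), c(6, 10, 14), 3)
#' nrow(grid) # 24 movement conditions
#' @export
target_grid <- function(directions, distances_cm, width_cm) {
  if (length(directions) == 0 || length(distances_cm) == 0)
    nr_validation_error("directions and distances_cm must be non-empty")
  if (!is.numeric(width_cm) || length(width_cm) != 1 || !is.finite(width_cm) ||
      width_cm <= 0)
    nr_validation_error("width_cm must be a single positive number")
  if (any(!is.finite(directions)) || any(directions < 0 | directions >= 360))
    nr_validation_error("directions must be finite and in [0, 360)")
  if (any(!is.finite(distances_cm)) || any(distances_cm <= 0))
    nr_validation_error("distances_cm must be finite and positive")
  grid <- expand.grid(direction_deg = as.numeric(directions),
                      A_cm = as.numeric(distances_cm),
                      KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(grid))
    nr_validation_error("duplicate (direction, distance) pair in target grid")
  grid <- grid[order(grid$A_cm, grid$direction_deg), , drop = FALSE]
  data.frame(target_id = seq_len(nrow(grid)),
             direction_deg = grid$direction_deg,
             A_cm = grid$A_cm,
             W_cm = width_cm,
             row.names = NULL)
}

#' Construct a single reaching trial
#'
#' @param subject subject identifier (string).
#' @param arm one of `"dominant"`, `"less_affected"`, `"affected"`.
#' @param target_id integer id of the target reached for (must exist in the
#'   session grid when the trial is put into a session).
#' @param t sample times in seconds, strictly increasing, length >= 5.
#' @param x,y sample positions in cm.
#' @param v optional recorded tangential speed in m/s (same length as `t`).
#' @param recorded_tm_ms optional robot-recorded movement time in ms.
#' @param rate_hz nominal sampling rate in Hz.
#' @return An object of class `reach_trial`.
#' @export
reach_trial <- function(subject, arm, target_id, t, x, y, v = NULL,
                        recorded_tm_ms = NULL, rate_hz = 75) {
  trial <- structure(list(
    subject = as.character(subject),
    arm = as.character(arm),
    target_id = as.integer(target_id),
    t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
    v = if (is.null(v)) NULL else as.numeric(v),
    recorded_tm_ms = if (is.null(recorded_tm_ms)) NULL
                     else as.numeric(recorded_tm_ms),
    rate_hz = as.numeric(rate_hz)
  ), class = "reach_trial")
  validate_trial(trial)
  trial
}

validate_trial <- function(trial, label = "trial") {
  arms <- c("dominant", "less_affected", "affected")
  if (!trial$arm %in% arms)
    nr_validation_error(sprintf("%s: arm must be one of %s", label,
                                paste(arms, collapse = ", ")))
  n <- length(trial$t)
  if (n < 5)
    nr_validation_error(sprintf("%s: needs >= 5 samples, got %d", label, n))
  if (length(trial$x) != n || length(trial$y) != n)
    nr_validation_error(sprintf("%s: t, x, y lengths differ", label))
  if (!is.null(trial$v) && length(trial$v) != n)
    nr_validation_error(sprintf("%s: v length differs from t", label))
  if (any(!is.finite(trial$t)) || any(!is.finite(trial$x)) ||
      any(!is.finite(trial$y)))
    nr_validation_error(sprintf("%s: non-finite sample value", label))
  if (any(diff(trial$t) <= 0))
    nr_validation_error(sprintf("%s: sample times not strictly increasing",
                                label))
  if (!is.finite(trial$rate_hz) || trial$rate_hz <= 0)
    nr_validation_error(sprintf("%s: sampling_rate must be > 0", label))
  if (!is.null(trial$recorded_tm_ms) &&
      (!is.finite(trial$recorded_tm_ms) || trial$recorded_tm_ms <= 0))
    nr_validation_error(sprintf("%s: recorded movement time must be > 0",
                                label))
  invisible(trial)
}

#' Construct a reaching session
#'
#' A session bundles the trials of one subject and one arm with the target
#' grid they were reaching over. Every trial's target must exist in the grid
#' and all trials must share the session's subject and arm.
#'
#' @param subject subject id.
#' @param arm arm label shared by all trials.
#' @param trials list of [reach_trial()] objects (may be empty).
#' @param grid target grid from [target_grid()].
#' @param seed optional integer seed recorded for provenance of simulated
#'   sessions.
#' @return An object of class `reach_session`.
#' @export
reach_session <- function(subject, arm, trials, grid, seed = NULL) {
  session <- structure(list(
    subject = as.character(subject),
    arm = as.character(arm),
    trials = trials,
    grid = grid,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "reach_session")
  validate_session(session)
  session
}

validate_session <- function(session) {
  grid <- session$grid
  need <- c("target_id", "direction_deg", "A_cm", "W_cm")
  if (!is.data.frame(grid) || !all(need %in% names(grid)))
    nr_validation_error("session grid must have target_id, direction_deg, A_cm, W_cm")
  if (anyDuplicated(grid$target_id))
    nr_validation_error("session grid target ids must be unique")
  for (i in seq_along(session$trials)) {
    trial <- session$trials[[i]]
    validate_trial(trial, label = sprintf("trial %d", i))
    if (!trial$target_id %in% grid$target_id)
      nr_validation_error(sprintf("trial %d: target_id %d not in session grid",
                                  i, trial$target_id))
    if (!identical(trial$subject, session$subject))
      nr_validation_error(sprintf("trial %d: subject differs from session", i))
    if (!identical(trial$arm, session$arm))
      nr_validation_error(sprintf("trial %d: arm differs from session", i))
  }
  invisible(session)
}

#' @export
print.reach_session <- function(x, ...) {
  cat(sprintf("Reaching session: subject %s, %s arm\n", x$subject, x$arm))
  cat(sprintf("  %d trials over %d targets (%d directions x %d distances)\n",
              length(x$trials), nrow(x$grid),
              length(unique(x$grid$direction_deg)),
              length(unique(x$grid$A_cm))))
  if (!is.null(x$seed)) cat(sprintf("  simulated with seed %d\n", x$seed))
  invisible(x)
}

target_of <- function(session, target_id) {
  session$grid[match(target_id, session$grid$target_id), , drop = FALSE]
}

# --- file I/O ---------------------------------------------------------------

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a session to a trial-table CSV with a JSON sidecar
#'
#' The CSV holds one row per sample with columns `subject, arm, trial,
#' target_id, t_s, x_cm, y_cm` and, when any trial carries a recorded speed,
#' `v_mps`. A JSON sidecar (same basename, `.json` extension) stores the
#' target grid, per-trial metadata (sampling rate, recorded movement time)
#' and the simulation seed, so that [read_trial_table()] reproduces the
#' session exactly. Numeric fields are serialized with 12 significant digits.
#'
#' @param session a valid `reach_session`.
#' @param path output CSV path.
#' @return Invisibly, the sidecar path.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir <- dirname(path)
  if (!dir.exists(dir)) nr_io_error(sprintf("directory does not exist: %s", dir))
  has_v <- any(vapply(session$trials, function(tr) !is.null(tr$v), logical(1)))
  rows <- lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    df <- data.frame(subject = tr$subject, arm = tr$arm, trial = i,
                     target_id = tr$target_id, t_s = tr$t,
                     x_cm = tr$x, y_cm = tr$y)
    if (has_v) df$v_mps <- if (is.null(tr$v)) NA_real_ else tr$v
    df
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), arm = character(), trial = integer(),
               target_id = integer(), t_s = numeric(), x_cm = numeric(),
               y_cm = numeric())
  for (col in c("t_s", "x_cm", "y_cm", "v_mps"))
    if (col %in% names(tab)) tab[[col]] <- fmt_num(tab[[col]])
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) nr_io_error(sprintf("cannot write %s", path))
  meta <- list(
    subject = session$subject,
    arm = session$arm,
    seed = session$seed,
    grid = session$grid,
    trials = lapply(session$trials, function(tr) list(
      target_id = tr$target_id,
      rate_hz = tr$rate_hz,
      recorded_tm_ms = tr$recorded_tm_ms
    ))
  )
  side <- sidecar_path(path)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(side)
}

#' Read a trial-table CSV back into a session
#'
#' Expects the CSV layout written by [write_session()]. Metadata comes from
#' the JSON sidecar when present; otherwise a target `grid` must be supplied
#' and trials are split where the time column resets. A `dialect` mapping can
#' rename non-standard column headers to the canonical ones.
#'
#' @param path CSV path.
#' @param grid optional target grid (required when no sidecar exists).
#' @param dialect named character vector mapping canonical column names
#'   (`subject`, `arm`, `target_id`, `t_s`, `x_cm`, `y_cm`, `v_mps`, `trial`)
#'   to the file's actual headers.
#' @return A validated `reach_session`.
#' @export
read_trial_table <- function(path, grid = NULL, dialect = NULL) {
  if (!file.exists(path)) nr_io_error(sprintf("file does not exist: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(tab))
      if (!is.na(j)) names(tab)[j] <- canon
    }
  }
  need <- c("subject", "arm", "target_id", "t_s", "x_cm", "y_cm")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    nr_format_error(sprintf("trial table missing column(s): %s",
                            paste(missing, collapse = ", ")))
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else NULL
  if (is.null(meta) && is.null(grid))
    nr_format_error("no JSON sidecar found; supply a target grid")
  use_grid <- if (!is.null(meta)) as.data.frame(meta$grid) else grid

  if (nrow(tab) == 0) {
    subject <- meta$subject %||% "unknown"
    arm <- meta$arm %||% "dominant"
    return(reach_session(subject, arm, list(), use_grid,
                         seed = meta$seed %||% NULL))
  }
  if (!"trial" %in% names(tab)) {
    # fall back to time resets as trial boundaries
    tab$trial <- cumsum(c(TRUE, diff(tab$t_s) <= 0 |
                                 diff(as.integer(tab$target_id)) != 0))
  }
  idx <- split(seq_len(nrow(tab)), tab$trial)
  tmeta <- if (!is.null(meta)) meta$trials else NULL
  trials <- lapply(seq_along(idx), function(k) {
    rows <- tab[idx[[k]], , drop = FALSE]
    if (any(diff(rows$t_s) <= 0))
      nr_validation_error(sprintf(
        "trial %s: sample times not strictly increasing", names(idx)[k]))
    meta_field <- function(field) {
      if (is.null(tmeta)) return(NULL)
      v <- if (is.data.frame(tmeta)) tmeta[[field]][k] else tmeta[[k]][[field]]
      if (is.null(v) || length(v) == 0 || is.na(v)) NULL else v
    }
    tm <- meta_field("recorded_tm_ms")
    rate <- meta_field("rate_hz")
    if (is.null(rate))
      rate <- 1 / stats::median(diff(rows$t_s))
    v <- if ("v_mps" %in% names(rows) && !all(is.na(rows$v_mps))) rows$v_mps
         else NULL
    reach_trial(rows$subject[1], rows$arm[1], rows$target_id[1],
                rows$t_s, rows$x_cm, rows$y_cm, v = v,
                recorded_tm_ms = tm, rate_hz = rate)
  })
  subject <- if (!is.null(meta)) meta$subject else tab$subject[1]
  arm <- if (!is.null(meta)) meta$arm else tab$arm[1]
  reach_session(subject, arm, trials, use_grid,
                seed = if (!is.null(meta)) meta$seed %||% NULL else NULL)
}
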
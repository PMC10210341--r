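# Individually scaled evaluation: score affected-arm trials against the
# normal-reaching model of the less-affected arm with a normalized error
# index, aggregate per target, and map the index over the workspace.

#' Normalized movement-time error
#'
#' `e_n = (T_Ma - T_Me) / T_Me`: the relative excess of the actual movement
#' time over the model-estimated ideal one. Zero means performance at the
#' individual's normal level; 1.0 means twice the ideal time. Because the
#' ideal time normalizes the discrepancy, the index is not biased by target
#' distance and is comparable across targets and subjects.
#'
#' @param tma_ms actual movement time(s) in ms, > 0.
#' @param tme_ms model-estimated ideal movement time(s) in ms, > 0.
#' @return The normalized error, same length as the inputs; always > -1.
#' @examples
#' normalized_error(3000, 2000) # 0.5
#' @export
normalized_error <- function(tma_ms, tme_ms) {
  if (any(!is.finite(tme_ms) | tme_ms <= 0))
    nr_domain_error("T_M,e must be positive and finite")
  if (any(!is.finite(tma_ms) | tma_ms <= 0))
    nr_domain_error("T_M,a must be positive and finite")
  (tma_ms - tme_ms) / tme_ms
}

#' Evaluate an affected arm against a normal-reaching model
#'
#' For each affected-arm trial, predicts the ideal movement time `T_M,e` from
#' the less-affected-arm model at that trial's distance and average speed,
#' computes the trial-wise normalized error, and averages per target. The
#' aggregation is deliberately trial-wise first (apply the index, then mean),
#' not the index of mean times. Grid targets with no surviving trial are
#' marked unreachable.
#'
#' @param model a fitted `reach_model`, normally of the `"proposed"` family
#'   (comparator families are allowed with a warning, for research use).
#' @param affected_features `reach_features` of the affected arm.
#' @param grid the session target grid (see [target_grid()]).
#' @return An object of class `reach_evaluation`: `trials` (per-trial
#'   `target_id, TM_ms, TMe_ms, en`), `targets` (per-target means with
#'   `reachable` flag), and the `grid`.
#' @export
evaluate_affected <- function(model, affected_features, grid) {
  if (!inherits(model, "reach_model"))
    nr_validation_error("model must be a reach_model")
  if (model$family != "proposed")
    warning(sprintf(
      "evaluating with the %s family; the validated normal model is 'proposed'",
      model$family))
  if (is.null(grid) || nrow(grid) == 0)
    nr_validation_error("empty target grid")
  if (is.null(affected_features) || nrow(affected_features) == 0)
    nr_validation_error("no affected-arm features")
  tme <- predict(model, affected_features)
  en <- normalized_error(affected_features$TM_ms, tme)
  trials <- data.frame(target_id = affected_features$target_id,
                       TM_ms = affected_features$TM_ms,
                       TMe_ms = tme, en = en)
  agg <- lapply(seq_len(nrow(grid)), function(i) {
    id <- grid$target_id[i]
    sel <- trials$target_id == id
    n <- sum(sel)
    data.frame(target_id = id,
               direction_deg = grid$direction_deg[i],
               A_cm = grid$A_cm[i],
               n_trials = n,
               mean_TMa_ms = if (n) mean(trials$TM_ms[sel]) else NA_real_,
               mean_TMe_ms = if (n) mean(trials$TMe_ms[sel]) else NA_real_,
               mean_en = if (n) mean(trials$en[sel]) else NA_real_,
               reachable = n > 0)
  })
  structure(list(trials = trials, targets = do.call(rbind, agg), grid = grid,
                 family = model$family),
            class = "reach_evaluation")
}

#' @export
print.reach_evaluation <- function(x, ...) {
  tg <- x$targets
  cat(sprintf(
    "Reaching evaluation over %d targets (%d reachable), %d trials\n",
    nrow(tg), sum(tg$reachable), nrow(x$trials)))
  cat(sprintf("  mean e_n over reachable targets: %.3f\n",
              mean(tg$mean_en[tg$reachable])))
  invisible(x)
}

#' Build a polar workspace map from evaluation records
#'
#' Arranges per-target means on the direction x distance grid as a matrix
#' (rows = distances, columns = directions). When clipping is enabled, the
#' display ceiling is the 95th percentile of the finite cell values (linear
#' interpolation) and the floor is their minimum; this keeps a single
#' extreme target from flattening the color axis. Cell values themselves are
#' stored unclipped — the clip range only governs display.
#'
#' @param evaluation a `reach_evaluation`.
#' @param value `"en"` (mean normalized error) or `"tm"` (mean actual
#'   movement time, ms).
#' @param clip clip the display ceiling at the 95th percentile.
#' @return An object of class `reach_map`: `values` matrix (NA for
#'   unreachable cells), `distances_cm`, `directions_deg`, `value`,
#'   `clip`, `clip_range`.
#' @export
reach_map <- function(evaluation, value = c("en", "tm"), clip = TRUE) {
  value <- match.arg(value)
  tg <- evaluation$targets
  dirs <- sort(unique(tg$direction_deg))
  dists <- sort(unique(tg$A_cm))
  vals <- matrix(NA_real_, nrow = length(dists), ncol = length(dirs),
                 dimnames = list(paste0(dists, "cm"), paste0(dirs, "deg")))
  col <- if (value == "en") "mean_en" else "mean_TMa_ms"
  for (i in seq_len(nrow(tg))) {
    r <- match(tg$A_cm[i], dists); c <- match(tg$direction_deg[i], dirs)
    if (tg$reachable[i]) vals[r, c] <- tg[[col]][i]
  }
  finite <- vals[is.finite(vals)]
  if (clip && length(finite) < 2) {
    warning("fewer than 2 finite cells; returning unclipped map")
    clip <- FALSE
  }
  clip_range <- if (length(finite) == 0) c(NA_real_, NA_real_)
    else if (clip) c(min(finite),
                     stats::quantile(finite, 0.95, type = 7, names = FALSE))
    else range(finite)
  structure(list(values = vals, distances_cm = dists, directions_deg = dirs,
                 value = value, clip = clip, clip_range = clip_range),
            class = "reach_map")
}

#' @export
print.reach_map <- function(x, ...) {
  cat(sprintf("Workspace map of %s: %d distances x %d directions, %d masked\n",
              if (x$value == "en") "mean normalized error"
              else "mean movement time [ms]",
              nrow(x$values), ncol(x$values), sum(!is.finite(x$values))))
  cat(sprintf("  display range: [%.4g, %.4g]%s\n", x$clip_range[1],
              x$clip_range[2],
              if (x$clip) " (ceiling = 95th percentile)" else ""))
  print(round(x$values, 4))
  invisible(x)
}

#' Write the numeric grid of a map to CSV
#'
#' Rows are distances, columns directions; unreachable cells are `NA`.
#'
#' @param map a `reach_map`.
#' @param path output CSV path.
#' @export
write_map <- function(map, path) {
  df <- data.frame(A_cm = map$distances_cm, map$values,
                   check.names = FALSE)
  names(df) <- c("A_cm", paste0("dir_", map$directions_deg))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) nr_io_error(sprintf("cannot write %s", path))
  invisible(path)
}

map_palette <- function(n = 64) grDevices::hcl.colors(n, "Blue-Red 2")

#' Plot a workspace map
#'
#' Draws the polar direction x distance grid as annular sectors, one per
#' target cell, colored blue (best) to red (worst) over the clip range;
#' values above the ceiling are displayed at the ceiling color but are not
#' altered in the map object. Unreachable cells are left uncolored.
#'
#' @param x a `reach_map`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reach_map <- function(x, ...) {
  dists <- x$distances_cm; dirs <- x$directions_deg
  rmax <- max(dists) * 1.15
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = if (x$value == "en") "Normalized error map"
                        else "Movement time map [ms]", ...)
  pal <- map_palette()
  lo <- x$clip_range[1]; hi <- x$clip_range[2]
  span <- if (is.finite(hi - lo) && hi > lo) hi - lo else 1
  # ring edges halfway between distances
  edges <- c(dists[1] - diff(c(0, dists[1])) / 2,
             dists[-length(dists)] + diff(dists) / 2,
             dists[length(dists)] + diff(c(dists[length(dists) - 1],
                                           dists[length(dists)])) / 2)
  half <- if (length(dirs) > 1) min(diff(sort(dirs))) / 2 else 180
  for (r in seq_along(dists)) for (c in seq_along(dirs)) {
    val <- x$values[r, c]
    if (!is.finite(val)) next
    shade <- pal[1 + round(63 * min(max((val - lo) / span, 0), 1))]
    ang <- seq((dirs[c] - half) * pi / 180, (dirs[c] + half) * pi / 180,
               length.out = 24)
    xs <- c(edges[r] * cos(ang), rev(edges[r + 1] * cos(ang)))
    ys <- c(edges[r] * sin(ang), rev(edges[r + 1] * sin(ang)))
    graphics::polygon(xs, ys, col = shade, border = "grey40", lwd = 0.3)
  }
  graphics::symbols(0, 0, circles = edges[1], inches = FALSE, add = TRUE,
                    fg = "grey40")
  graphics::text(0, 0, "start", cex = 0.7)
  invisible(x)
}

#' Render a workspace map to image and numeric files
#'
#' Writes `<base>.png`, `<base>.svg` (when the SVG device is available) and
#' `<base>.csv` next to each other, where `<base>` is `path` without its
#' extension.
#'
#' @param map a `reach_map`.
#' @param path output path; extension is replaced per artifact.
#' @param width,height image size in pixels (PNG) / inches are derived.
#' @return Invisibly, the paths written.
#' @export
render_map <- function(map, path, width = 800, height = 800) {
  base <- sub("\\.[A-Za-z]+$", "", path)
  dir <- dirname(base)
  if (!dir.exists(dir)) nr_io_error(sprintf("directory does not exist: %s", dir))
  paths <- character()
  png_path <- paste0(base, ".png")
  grDevices::png(png_path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(map)
  grDevices::dev.off(); on.exit()
  paths <- c(paths, png_path)
  svg_ok <- isTRUE(grDevices::dev.capabilities()$cairo) ||
    capabilities("cairo")
  if (svg_ok) {
    svg_path <- paste0(base, ".svg")
    grDevices::svg(svg_path, width = width / 100, height = height / 100)
    plot(map)
    grDevices::dev.off()
    paths <- c(paths, svg_path)
  }
  csv_path <- paste0(base, ".csv")
  write_map(map, csv_path)
  invisible(c(paths, csv_path))
}
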
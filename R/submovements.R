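# Minimum-jerk submovement decomposition. A reach is modelled as a
# superposition of bell-shaped speed pulses; the submovement count NS is the
# smallest number of pulses whose least-squares fit reconstructs the speed
# profile to within a tolerance. Keeping NS minimal avoids exaggerating the
# count on noisy profiles.

#' Minimum-jerk speed kernel
#'
#' Speed profile of a single minimum-jerk submovement of displacement `s`
#' and duration `D` starting at `t0`:
#' `v(tau) = (s/D) (30 tau^4 - 60 tau^3 + 30 tau^2)` with
#' `tau = (t - t0)/D` in `[0, 1]`, zero outside. Its peak is `1.875 s/D`
#' at `tau = 1/2` and it integrates to `s`.
#'
#' @param t numeric vector of times (s).
#' @param t0 pulse onset (s).
#' @param D pulse duration (s), > 0.
#' @param s pulse displacement (same length unit as wanted for `v * t`).
#' @return Speed at each `t`.
#' @export
minjerk_speed <- function(t, t0, D, s) {
  tau <- (t - t0) / D
  v <- (s / D) * (30 * tau^4 - 60 * tau^3 + 30 * tau^2)
  v[tau < 0 | tau > 1] <- 0
  v
}

sum_pulses <- function(t, par) {
  # par = c(t0_1..t0_M, logD_1..logD_M, logs_1..logs_M)
  m <- length(par) / 3
  v <- numeric(length(t))
  for (j in seq_len(m))
    v <- v + minjerk_speed(t, par[j], exp(par[m + j]), exp(par[2 * m + j]))
  v
}

pulse_starts <- function(t, speed, m) {
  # candidate initializations: local-maxima based and evenly spaced
  n <- length(speed)
  span <- t[n] - t[1]
  peaks <- which(diff(sign(diff(speed))) < 0) + 1
  if (length(peaks) == 0) peaks <- which.max(speed)
  peaks <- peaks[order(speed[peaks], decreasing = TRUE)]
  starts <- list()

  D0 <- max(span / m, 4 * (span / n))
  k <- min(m, length(peaks))
  tp <- sort(t[peaks[seq_len(k)]])
  if (k < m)  # pad with evenly spaced onsets
    tp <- sort(c(tp, t[1] + span * (seq_len(m - k) - 0.5) / (m - k + 1)))
  s0 <- pmax(stats::approx(t, speed, xout = tp, rule = 2)$y * D0 / 1.875,
             1e-6)
  starts[[1]] <- c(tp - D0 / 2, rep(log(D0), m), log(s0))

  te <- t[1] + span * (seq_len(m) - 1) / m
  De <- span / m * 1.4
  se <- rep(max(sum(speed) * (span / n) / m, 1e-6), m)
  starts[[2]] <- c(te, rep(log(De), m), log(se))
  starts
}

#' Decompose a speed profile into minimum-jerk submovements
#'
#' Finds the smallest pulse count `M <= max_pulses` for which the best
#' nonlinear least-squares fit of `M` overlapping minimum-jerk speed pulses
#' reaches `RMSE <= rmse_tolerance_fraction * peak speed`. Each candidate
#' count is fitted by box-constrained quasi-Newton minimization from
#' multiple deterministic starts (the M largest local speed maxima, and
#' evenly spaced onsets). If no count meets the tolerance, the result carries
#' `max_pulses` pulses with `tolerance_met = FALSE`.
#'
#' @param speed non-negative speed samples (m/s).
#' @param dt sampling interval (s).
#' @param rmse_tolerance_fraction fit tolerance as a fraction of peak speed,
#'   in (0, 1).
#' @param max_pulses largest pulse count considered.
#' @return A list of class `submovement_decomposition`: `ns` (pulse count),
#'   `pulses` (data frame `t0, D, s`), `rmse` (m/s), `tolerance_met`,
#'   `fitted` (reconstructed speed).
#' @export
decompose_submovements <- function(speed, dt,
                                   rmse_tolerance_fraction = 0.05,
                                   max_pulses = 10) {
  if (any(!is.finite(speed)) || any(speed < -1e-12))
    nr_validation_error("speed must be finite and non-negative")
  if (max_pulses < 1) nr_validation_error("max_pulses must be >= 1")
  if (rmse_tolerance_fraction <= 0 || rmse_tolerance_fraction >= 1)
    nr_validation_error("rmse_tolerance_fraction must be in (0, 1)")
  speed <- pmax(speed, 0)
  peak <- max(speed)
  if (peak <= 0) nr_degenerate_error("all-zero speed profile")
  n <- length(speed)
  t <- (seq_len(n) - 1) * dt
  span <- t[n] - t[1]
  tol <- rmse_tolerance_fraction * peak

  obj <- function(par) sum((speed - sum_pulses(t, par))^2)
  best_for <- function(m) {
    lower <- c(rep(t[1] - span, m), rep(log(2 * dt), m), rep(log(1e-8), m))
    upper <- c(rep(t[n], m), rep(log(2 * span + 4 * dt), m), rep(log(1e4), m))
    best <- NULL
    for (start in pulse_starts(t, speed, m)) {
      start <- pmin(pmax(start, lower), upper)
      fit <- tryCatch(
        stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 400)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    best
  }

  final <- NULL
  for (m in seq_len(max_pulses)) {
    fit <- best_for(m)
    if (is.null(fit)) next
    rmse <- sqrt(fit$value / n)
    final <- list(m = m, fit = fit, rmse = rmse)
    if (rmse <= tol) break
  }
  if (is.null(final)) nr_degenerate_error("submovement fit failed")
  m <- final$m; par <- final$fit$par
  pulses <- data.frame(t0 = par[seq_len(m)],
                       D = exp(par[m + seq_len(m)]),
                       s = exp(par[2 * m + seq_len(m)]))
  pulses <- pulses[order(pulses$t0), , drop = FALSE]
  structure(list(ns = m, pulses = pulses, rmse = final$rmse,
                 tolerance_met = final$rmse <= tol,
                 fitted = sum_pulses(t, final$fit$par)),
            class = "submovement_decomposition")
}

#' @export
print.submovement_decomposition <- function(x, ...) {
  cat(sprintf("Submovement decomposition: NS = %d, RMSE = %.4g m/s (%s)\n",
              x$ns, x$rmse,
              if (x$tolerance_met) "within tolerance" else "tolerance not met"))
  print(x$pulses, row.names = FALSE)
  invisible(x)
}
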
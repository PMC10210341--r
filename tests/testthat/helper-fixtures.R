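# Programmatic fixtures shared across the suite. Everything is built in
# code; no data files.

# straight constant-speed trial: A_cm over T_s seconds at direction theta
straight_trial <- function(A_cm = 10, T_s = 2, rate = 75, theta_deg = 0,
                           subject = "T01", arm = "dominant", target_id = 1L,
                           recorded_tm_ms = NULL) {
  t <- seq(0, T_s, by = 1 / rate)
  frac <- t / T_s
  th <- theta_deg * pi / 180
  reach_trial(subject, arm, target_id, t,
              frac * A_cm * cos(th), frac * A_cm * sin(th),
              recorded_tm_ms = recorded_tm_ms, rate_hz = rate)
}

# single minimum-jerk pulse along a straight line
mj_trial <- function(A_cm = 10, T_s = 2, rate = 75, theta_deg = 0,
                     subject = "T01", arm = "dominant", target_id = 1L) {
  t <- seq(0, T_s, by = 1 / rate)
  tau <- t / T_s
  s <- A_cm * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  th <- theta_deg * pi / 180
  reach_trial(subject, arm, target_id, t, s * cos(th), s * sin(th),
              rate_hz = rate)
}

default_grid <- function() target_grid(seq(0, 315, 45), c(6, 8, 10, 12, 14), 2)

# independent closed-form OLS: normal equations
ols_solve <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# random positive feature table (not tied to any generative law)
rand_features <- function(n = 120, seed = 1) {
  set.seed(seed)
  A <- sample(c(6, 8, 10, 12, 14), n, replace = TRUE)
  data.frame(
    subject = "R01", arm = "dominant", target_id = seq_len(n),
    direction_deg = 0, A_cm = A, W_cm = 2,
    TM_ms = exp(rnorm(n, log(2200), 0.3)),
    AS_mps = exp(rnorm(n, log(0.045), 0.25)),
    CI = 1 + rgamma(n, 2, scale = 0.2),
    NS = sample(1:6, n, replace = TRUE),
    path_cm = A * 1.2, outlier_flag = FALSE)
}

# noiseless or noisy features drawn exactly from the normal power law
law_features <- function(k, alpha, beta, sigma = 0, seed = 1, reps = 3,
                         distances = c(6, 8, 10, 12, 14)) {
  set.seed(seed)
  grid <- target_grid(seq(0, 315, 45), distances, 2)
  n <- nrow(grid) * reps
  A_cm <- rep(grid$A_cm, reps)
  AS <- exp(rnorm(n, log(0.045), 0.25))
  TM_s <- exp(k) * (A_cm / 100)^alpha * AS^beta * exp(sigma * rnorm(n))
  data.frame(
    subject = "L01", arm = "less_affected",
    target_id = rep(grid$target_id, reps),
    direction_deg = rep(grid$direction_deg, reps),
    A_cm = A_cm, W_cm = 2, TM_ms = TM_s * 1000, AS_mps = AS,
    CI = 1 + rgamma(n, 2, scale = 0.05), NS = 1L,
    path_cm = A_cm * 1.1, outlier_flag = FALSE)
}

design_for <- function(features, family) {
  switch(family,
    fitts = cbind(1, log2(2 * features$A_cm / features$W_cm)),
    proposed = cbind(1, log(features$A_cm / 100), log(features$AS_mps)),
    almanji = cbind(1, log(features$A_cm / 100), log(features$AS_mps),
                    log(features$NS + 1), log(features$CI)))
}

response_for <- function(features, family) {
  if (family == "fitts") features$TM_ms else log(features$TM_ms / 1000)
}

# brute-force oracle: dictionary of minimum-jerk atoms on a coarse (t0, D)
# lattice; for a candidate pulse count, amplitudes are solved by least
# squares for every atom combination and the best RMSE is kept.
grid_search_rmse <- function(t, speed, m, t0s, Ds) {
  atoms <- list()
  for (t0 in t0s) for (D in Ds)
    atoms[[length(atoms) + 1]] <- minjerk_speed(t, t0, D, 1)
  A <- do.call(cbind, atoms)
  keep <- colSums(A^2) > 0
  A <- A[, keep, drop = FALSE]
  best <- Inf
  combos <- utils::combn(ncol(A), m)
  for (j in seq_len(ncol(combos))) {
    X <- A[, combos[, j], drop = FALSE]
    G <- crossprod(X)
    if (rcond(G) < 1e-10) next
    amp <- solve(G, crossprod(X, speed))
    if (any(amp < 0)) next
    rss <- sum((speed - X %*% amp)^2)
    best <- min(best, sqrt(rss / length(speed)))
  }
  best
}
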
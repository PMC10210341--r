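test_that("tangential speed matches analytic derivatives", {
  # uniform straight motion: 10 cm in 2 s -> 0.05 m/s at interior samples
  tr <- straight_trial(A_cm = 10, T_s = 2)
  v <- tangential_speed(tr)
  expect_equal(v[2:(length(v) - 1)],
               rep(0.05, length(v) - 2), tolerance = 1e-9)

  # circular motion radius r, angular rate w -> speed r*w + O(dt^2)
  r <- 5; w <- 2; t <- seq(0, 1.5, by = 1 / 200)
  tr <- reach_trial("c", "dominant", 1, t, r * cos(w * t), r * sin(w * t),
                    rate_hz = 200)
  v <- tangential_speed(tr)
  interior <- v[3:(length(v) - 2)]
  expect_equal(interior, rep(r * w / 100, length(interior)),
               tolerance = 1e-4)

  # a provided speed column is returned verbatim
  vcol <- seq(0.01, 0.05, length.out = 5)
  tr <- reach_trial("c", "dominant", 1, seq(0, 0.4, 0.1), 0:4, rep(0, 5),
                    v = vcol)
  expect_identical(tangential_speed(tr), vcol)
})

test_that("movement time prefers the recorded value and thresholds otherwise", {
  tr <- straight_trial(recorded_tm_ms = 1894)
  expect_equal(movement_time(tr, use_recorded = TRUE), 1894)

  # single minimum-jerk pulse, D = 2 s, threshold 2% of peak speed:
  # 30 tau^2 (1 - tau)^2 = 0.02 * 1.875 has roots tau = 0.036702 / 0.963298,
  # so the window is 1853.19 ms (frozen from the analytic kernel)
  tr <- mj_trial(A_cm = 10, T_s = 2, rate = 150)
  expect_equal(movement_time(tr, onset_fraction = 0.02, use_recorded = FALSE),
               1853.19, tolerance = 1 / 150 * 1000 / 1853)

  # constant-speed segment of 1.5 s flanked by rest dwells
  t <- seq(0, 3.5, by = 0.01)
  x <- pmin(pmax(t - 1, 0), 1.5) * 8
  tr <- reach_trial("s", "dominant", 1, t, x, rep(0, length(t)), rate_hz = 100)
  tm <- movement_time(tr, use_recorded = FALSE)
  expect_lt(abs(tm - 1500), 2 * 10 + 1e-9)

  expect_error(movement_time(straight_trial(A_cm = 0), use_recorded = FALSE),
               class = "nr_degenerate_error")
})

test_that("average speed times movement time recovers the path length", {
  tr <- straight_trial(A_cm = 10, T_s = 2)
  expect_equal(average_speed(tr, tm_ms = 2000, window = "full"), 0.05,
               tolerance = 1e-9)

  # unit consistency AS * T_M = path length, on irregular noisy paths
  set.seed(7)
  for (i in 1:10) {
    t <- cumsum(runif(40, 0.005, 0.02))
    x <- cumsum(rnorm(40, 0.3, 0.1)); y <- cumsum(rnorm(40, 0, 0.1))
    tr <- reach_trial("p", "dominant", 1, t, x, y, rate_hz = 75)
    tm <- 1234
    as_mps <- average_speed(tr, tm_ms = tm, window = "full")
    len_m <- sum(sqrt(diff(x)^2 + diff(y)^2)) / 100
    expect_equal(as_mps * tm / 1000, len_m, tolerance = 1e-9)
  }
})

test_that("curvature index is the path/chord ratio with its invariances", {
  expect_equal(curvature_index(straight_trial(), window = "full"), 1,
               tolerance = 1e-9)

  # semicircular arc: path/chord = pi/2
  t <- seq(0, 2, by = 1 / 500)
  ang <- pi * (1 - t / 2)
  r <- 5
  tr <- reach_trial("a", "dominant", 1, t, r + r * cos(ang), r * sin(ang),
                    rate_hz = 500)
  expect_equal(curvature_index(tr, window = "full"), pi / 2, tolerance = 1e-3)

  # CI >= 1, equals the polyline oracle, invariant under rotation + scaling
  set.seed(11)
  for (i in 1:8) {
    t <- seq(0, 2, by = 1 / 75)
    x <- seq(0, 10, length.out = length(t)) + rnorm(length(t), 0, 0.05)
    y <- rnorm(length(t), 0, 0.05)
    tr <- reach_trial("j", "dominant", 1, t, x, y, rate_hz = 75)
    ci <- curvature_index(tr, window = "full")
    oracle <- sum(sqrt(diff(x)^2 + diff(y)^2)) /
      sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
    expect_equal(ci, oracle, tolerance = 1e-12)
    expect_gte(ci, 1 - 1e-9)

    th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.5, 3)
    tr2 <- reach_trial("j", "dominant", 1, t,
                       sc * (x * cos(th) - y * sin(th)),
                       sc * (x * sin(th) + y * cos(th)), rate_hz = 75)
    expect_equal(curvature_index(tr2, window = "full"), ci, tolerance = 1e-9)
  }

  # closed path is degenerate
  t <- seq(0, 1, by = 0.05)
  tr <- reach_trial("c", "dominant", 1, t, 5 * cos(2 * pi * t),
                    5 * sin(2 * pi * t), rate_hz = 20)
  expect_error(curvature_index(tr, window = "full"),
               class = "nr_degenerate_error")
})

test_that("feature extraction skips degenerate trials and reports them", {
  cfg <- synth_config(distances_cm = c(6, 14), directions = c(0, 90, 180),
                      reps = 1, seed = 21)
  syn <- generate_normal_session(cfg)
  ses <- syn$session
  # make one trial stationary
  ses$trials[[3]]$x[] <- 1; ses$trials[[3]]$y[] <- 1
  ses$trials[[3]]$v <- NULL; ses$trials[[3]]$recorded_tm_ms <- NULL
  feats <- extract_features(ses, ns = FALSE)
  expect_equal(nrow(feats), 5)
  expect_equal(attr(feats, "skipped")$trial, 3)

  expect_error(extract_features(reach_session("x", "dominant", list(),
                                              default_grid())),
               class = "nr_validation_error")
})

test_that("extracted features reproduce generator ground truth", {
  cfg <- synth_config(distances_cm = c(6, 10, 14), directions = c(0, 135),
                      reps = 1, seed = 33)
  syn <- generate_normal_session(cfg)
  feats <- extract_features(syn$session, ns = FALSE)
  expect_equal(feats$TM_ms, syn$truth$TM_ms, tolerance = 1e-9) # recorded
  expect_equal(feats$CI, syn$truth$CI, tolerance = 1e-3)
  expect_equal(feats$AS_mps, syn$truth$AS_mps, tolerance = 2e-3)
  expect_true(all(feats$CI < 1.6))
})

test_that("the CI outlier rule applies 2*IQR fences with type-7 quartiles", {
  base <- rand_features(6)

  # all-equal CI: fences collapse, nothing rejected
  base$CI <- rep(1.2, 6)
  res <- reject_ci_outliers(base)
  expect_equal(nrow(res$rejected), 0)
  expect_equal(nrow(res$kept), 6)

  # hand-computed: CI = (1.00 1.05 1.10 1.20 1.25 3.00)
  # Q1 = 1.0625, Q3 = 1.2375 (linear interpolation), IQR = 0.175,
  # fences = (0.7125, 1.5875) -> only the 3.00 row is beyond
  base$CI <- c(1.00, 1.05, 1.10, 1.20, 1.25, 3.00)
  res <- reject_ci_outliers(base)
  expect_equal(res$fences, c(0.7125, 1.5875), tolerance = 1e-12)
  expect_equal(res$rejected$CI, 3.00)
  expect_equal(res$kept$CI, base$CI[1:5])
  expect_true(all(res$rejected$outlier_flag))

  # partition + idempotence against the original fences
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(base))
  expect_true(all(res$kept$CI >= res$fences[1] & res$kept$CI <= res$fences[2]))

  expect_error(reject_ci_outliers(base[1:4, ]), class = "nr_validation_error")
})

test_that("injected CI spikes are exactly the rows rejected", {
  for (seed in c(5, 17)) {
    syn <- generate_normal_session(synth_config(seed = seed, realize = FALSE))
    feats <- reject_ci_outliers(syn$truth)$kept
    set.seed(seed + 100)
    spikes <- sample(nrow(feats), 5)
    feats$CI[spikes] <- 4 + runif(5)
    res <- reject_ci_outliers(feats)
    expect_setequal(which(feats$CI %in% res$rejected$CI), spikes)
    expect_equal(nrow(res$rejected), 5)
  }
})
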
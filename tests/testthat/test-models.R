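test_that("noiseless power-law data is recovered exactly with R2 = 1", {
  feats <- law_features(k = 2.0, alpha = 0.9, beta = -0.8, sigma = 0, seed = 2)
  fit <- suppressWarnings(reach_model(feats, "proposed"))
  expect_equal(unname(coef(fit)), c(2.0, 0.9, -0.8), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("all three families agree with the normal-equations oracle", {
  for (seed in 1:5) {
    feats <- rand_features(120, seed = seed)
    for (family in c("proposed", "almanji", "fitts")) {
      fit <- reach_model(feats, family)
      oracle <- ols_solve(design_for(feats, family),
                          response_for(feats, family))
      expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8,
                   label = sprintf("%s seed %d", family, seed))
    }
  }
})

test_that("fitts on two distance levels gives the two-point slope", {
  feats <- rand_features(40, seed = 9)
  feats$A_cm <- rep(c(6, 12), 20)
  id <- log2(2 * feats$A_cm / feats$W_cm)
  feats$TM_ms <- 800 + 450 * id    # exactly linear in ID
  fit <- reach_model(feats, "fitts")
  m1 <- mean(feats$TM_ms[feats$A_cm == 6]); i1 <- log2(12 / 2)
  m2 <- mean(feats$TM_ms[feats$A_cm == 12]); i2 <- log2(24 / 2)
  expect_equal(unname(coef(fit)["b"]), (m2 - m1) / (i2 - i1),
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)["b"]), 450, tolerance = 1e-10)

  feats$A_cm <- 10   # single ID level is unusable
  expect_error(reach_model(feats, "fitts"), class = "nr_singular_error")
})

test_that("AIC follows the Gaussian ML formula in the fitted space", {
  # one extra coefficient at identical RSS costs exactly +2
  expect_equal(reach_aic(5, 100, 4) - reach_aic(5, 100, 3), 2)
  # plug-in identity at RSS/n = 1
  expect_equal(reach_aic(10, 10, 3), 10 * log(2 * pi) + 10 + 2 * 4)
  expect_warning(aicv <- reach_aic(0, 10, 2))
  expect_identical(aicv, -Inf)

  # direct log-likelihood summation oracle on a fitted model
  feats <- law_features(k = 0.4, alpha = 0.95, beta = -0.9, sigma = 0.1,
                        seed = 4)
  fit <- reach_model(feats, "proposed")
  res <- residuals(fit, type = "fitted")
  n <- length(res)
  loglik <- sum(stats::dnorm(res, 0, sqrt(fit$rss / n), log = TRUE))
  expect_equal(fit$aic, -2 * loglik + 2 * (3 + 1), tolerance = 1e-8)
  # and it coincides with stats::AIC on the underlying linear model
  expect_equal(fit$aic, stats::AIC(fit$lm), tolerance = 1e-8)
})

test_that("predictions satisfy the family identities", {
  feats <- law_features(k = 0.3, alpha = 0.9, beta = -0.9, sigma = 0.05,
                        seed = 6)
  fit <- reach_model(feats, "proposed")

  # dimensional identity: k=0, alpha=1, beta=-1 means T = A / AS
  ideal <- fit; ideal$coefficients <- c(k = 0, alpha = 1, beta = -1)
  nd <- data.frame(A_cm = 10, AS_mps = 0.05)
  expect_equal(predict(ideal, nd), 2000)

  # alpha = beta = 0 predicts the constant e^k
  const <- fit; const$coefficients <- c(k = 0.7, alpha = 0, beta = 0)
  nd <- data.frame(A_cm = c(6, 10, 14), AS_mps = c(0.02, 0.05, 0.08))
  expect_equal(predict(const, nd), rep(exp(0.7) * 1000, 3))

  # the almanji family with d = f = 0 nests the proposed prediction
  afeats <- feats; afeats$NS <- sample(2:5, nrow(feats), TRUE)
  afit <- reach_model(afeats, "almanji")
  afit$coefficients <- c(coef(fit), d = 0, f = 0)
  nd <- data.frame(A_cm = c(8, 12), AS_mps = c(0.03, 0.06), NS = c(3, 5),
                   CI = c(1.2, 1.8))
  expect_equal(predict(afit, nd), predict(fit, nd))

  expect_error(predict(fit, data.frame(A_cm = 10)),
               class = "nr_validation_error")
  expect_error(predict(fit, data.frame(A_cm = 10, AS_mps = -1)),
               class = "nr_domain_error")
})

test_that("the almanji family nests the proposed one in log space", {
  for (seed in 1:6) {
    feats <- rand_features(80, seed = seed + 50)
    r2p <- reach_model(feats, "proposed")$r_squared
    r2a <- reach_model(feats, "almanji")$r_squared
    expect_gte(r2a, r2p - 1e-12)
  }
  # with constant NS the almanji fit degrades gracefully to d = 0
  feats <- law_features(k = 0.4, alpha = 0.95, beta = -0.9, sigma = 0.1,
                        seed = 8)
  afit <- reach_model(feats, "almanji")
  expect_equal(unname(coef(afit)["d"]), 0)
  expect_gte(afit$r_squared, reach_model(feats, "proposed")$r_squared - 1e-12)
})

test_that("model comparison reproduces the discrimination pattern", {
  syn <- generate_normal_session(synth_config(seed = 31, realize = FALSE))
  obs_n <- observed_features(syn$truth)
  cmp_n <- compare_reach_models(obs_n)
  r2 <- setNames(cmp_n$table$R2, cmp_n$table$family)
  expect_gt(r2["proposed"], 0.7)
  expect_gte(r2["almanji"], r2["proposed"])
  expect_gt(r2["proposed"], r2["fitts"])

  err <- generate_erroneous_session(synth_config(seed = 1031, realize = FALSE))
  cmp_e <- compare_reach_models(observed_features(err$truth))
  tab <- cmp_e$table
  expect_lt(tab$mean_abs_residual_ms[tab$family == "almanji"],
            tab$mean_abs_residual_ms[tab$family == "proposed"])
  expect_equal(sort(unique(cmp_e$residuals$family)),
               sort(c("fitts", "almanji", "proposed")))
  expect_equal(nrow(cmp_e$residuals), 3 * nrow(err$truth))
})

test_that("models round-trip through JSON and still predict", {
  feats <- law_features(k = 0.4, alpha = 0.95, beta = -0.9, sigma = 0.1,
                        seed = 12)
  fit <- reach_model(feats, "proposed")
  path <- file.path(withr::local_tempdir(), "model.json")
  write_reach_model(fit, path)
  back <- read_reach_model(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  nd <- data.frame(A_cm = c(6, 14), AS_mps = c(0.03, 0.06))
  expect_equal(predict(back, nd), predict(fit, nd), tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-12)
})

test_that("simulate draws from the fitted law at the residual scale", {
  feats <- law_features(k = 0.4, alpha = 0.95, beta = -0.9, sigma = 0.1,
                        seed = 13)
  fit <- reach_model(feats, "proposed")
  sims <- simulate(fit, nsim = 3, seed = 99)
  expect_length(sims, 3)
  refit <- reach_model(sims[[1]], "proposed")
  expect_equal(unname(coef(refit)), unname(coef(fit)), tolerance = 0.15)
})
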
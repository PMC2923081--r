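test_that("prediction matches the direct logistic formula", {
  tfs <- c("X", "Y")
  spec <- data.frame(tf = tfs, order = 1L)
  conc <- list(X = axis_profile(rep(0.5, 100)), Y = axis_profile(rep(0.2, 100)))

  m0 <- regression_model(c(X = 0, Y = 0), c(l = 0), spec)
  expect_equal(predict_expression(m0, c(X = 1, Y = 1), conc, crm = "l")$values,
               rep(0.5, 100))

  # single term: sig(-1 + 1 * 2 * 1) = sig(1)
  conc1 <- list(X = axis_profile(rep(1, 100)))
  m1 <- regression_model(c(X = 1), c(l = -1), data.frame(tf = "X", order = 1L))
  pred <- predict_expression(m1, c(X = 2), conc1, crm = "l")
  expect_equal(pred$values, rep(plogis(1), 100), tolerance = 1e-12)
  expect_equal(pred$values[1], 0.7311, tolerance = 1e-4)

  # random inputs against a one-line oracle, including a squared term
  spec2 <- data.frame(tf = c("X", "Y", "X"), order = c(1L, 1L, 2L))
  withr::with_seed(5, {
    cx <- runif(100); cy <- runif(100)
    w <- c(X = 0.8, Y = -1.1, `X^2` = 0.3)
    m2 <- regression_model(w, c(l = -0.4), spec2)
    s <- c(X = 2.5, Y = 1.5)
    got <- predict_expression(
      m2, s, list(X = axis_profile(cx), Y = axis_profile(cy)), crm = "l")$values
    want <- plogis(-0.4 + 0.8 * cx * 2.5 - 1.1 * cy * 1.5 +
                     0.3 * (cx * 2.5)^2)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got < 1))
  })

  expect_error(predict_expression(m1, c(Z = 1), conc1, crm = "l"),
               "missing motif score for TF: X")
  expect_error(
    predict_expression(m1, c(X = 1), list(Q = axis_profile(rep(0, 100))),
                       crm = "l"),
    "missing concentration profile for TF: X")
})

test_that("a repressor term suppresses prediction only in its domain", {
  spec <- data.frame(tf = c("A", "R"), order = 1L)
  conc <- list(A = axis_profile(rep(0.8, 100)),
               R = make_concentrations(list(R = list("stripe", 40, 60)))$R)
  with_rep <- regression_model(c(A = 1, R = -5), c(l = -1), spec)
  without <- regression_model(c(A = 1, R = 0), c(l = -1), spec)
  s <- c(A = 2, R = 3)
  p1 <- predict_expression(with_rep, s, conc, crm = "l")$values
  p0 <- predict_expression(without, s, conc, crm = "l")$values
  inside <- 41:59  # stripe support is bins 40-60, zero at the edges
  expect_true(all(p1[inside] < p0[inside]))
  expect_equal(p1[-(40:60)], p0[-(40:60)])
})

test_that("IWLS recovers designed activator/repressor signs (3+ / 7-)", {
  fx <- ap_fixture(seed = 1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$clean)
  w <- fit$model$weights[AP_TFS]
  expect_identical(sign(w), sign(fx$w_true))
  expect_true(all(w[c("BCD", "CAD", "FKH")] > 0))
  expect_true(all(w[c("HB", "KR", "KNI", "GT", "TLL", "HKB", "CIC")] < 0))
  expect_true(fit$model$converged)
})

test_that("sign recovery survives 10% bin-flip noise", {
  fx <- ap_fixture(seed = 2, n_crm = 20, noise = 0.1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  w <- fit$model$weights[AP_TFS]
  expect_gte(sum(sign(w) == sign(fx$w_true)), 9)
})

test_that("IWLS is deterministic and drops zero-variance covariates", {
  fx <- ap_fixture(seed = 3, n_crm = 8)
  f1 <- fit_model(fx$S, fx$conc, fx$sim$clean)
  f2 <- fit_model(fx$S, fx$conc, fx$sim$clean)
  expect_identical(f1$model$weights, f2$model$weights)

  S0 <- fx$S
  S0[, "KR"] <- 0  # zero motif score everywhere: zero-variance covariate
  expect_warning(f3 <- fit_model(S0, fx$conc, fx$sim$clean),
                 "zero-variance covariate")
  expect_false("KR" %in% names(f3$model$weights))
})

test_that("coefficient significance follows the z = w/SE convention", {
  m <- regression_model(c(X = 0, Y = 1.96), c(l = 0),
                        data.frame(tf = c("X", "Y"), order = 1L),
                        se_weights = c(X = 0.5, Y = 1))
  sig <- coefficient_significance(m)
  expect_equal(sig$z, c(0, 1.96))
  expect_equal(sig$p[1], 1)
  expect_equal(sig$p[2], 0.05, tolerance = 1e-3)

  m0 <- regression_model(c(X = 1), c(l = 0), data.frame(tf = "X", order = 1L),
                         se_weights = c(X = 0))
  sig0 <- coefficient_significance(m0)
  expect_true(is.na(sig0$z) && is.na(sig0$p))
})

test_that("planted-effect z-scores grow with the number of CRMs", {
  z_at <- function(n) {
    fx <- ap_fixture(seed = 7, n_crm = n, noise = 0.1)
    fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
    sig <- coefficient_significance(fit$model)
    mean(abs(sig$z[match(c("BCD", "KR"), sig$term)]))
  }
  expect_gt(z_at(40), z_at(10))
})

test_that("goodness of fit matches analytic cases and the AIC oracle", {
  spec <- data.frame(tf = "X", order = 1L)
  conc <- list(X = axis_profile(rep(0, 100)))
  S <- matrix(0, 2, 1, dimnames = list(c("c1", "c2"), "X"))
  targets <- list(c1 = axis_profile(rep(c(1, 0), c(50, 50)), "binary"),
                  c2 = axis_profile(rep(c(0, 1), c(30, 70)), "binary"))

  # constant prediction 0.5 against any binary target: every residual is 0.5
  m5 <- regression_model(c(X = 0), c(c1 = 0, c2 = 0), spec)
  rep5 <- goodness_of_fit(m5, S, conc, targets)
  expect_equal(rep5$rmse, 0.5)
  expect_equal(rep5$n_cc_excluded, 2)  # flat predictions have no CC

  # near-perfect predictions: RMSE ~ 0, mean CC ~ 1
  fx <- ap_fixture(seed = 4, n_crm = 10)
  fit <- fit_model(fx$S, fx$conc, fx$sim$clean)
  expect_lt(fit$report$rmse, 0.05)
  expect_gt(fit$report$mean_cc, 0.99)

  # AIC against direct likelihood summation
  ll <- direct_loglik(fit$model, fx$S, fx$conc, fx$sim$clean)
  k <- length(fit$model$weights) + length(fit$model$baselines)
  expect_equal(fit$report$aic, 2 * k - 2 * ll, tolerance = 1e-6)
})

test_that("IWLS agrees with an independent optimizer on small instances", {
  fx <- ap_fixture(seed = 5, n_crm = 8, noise = 0.1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  ll_oracle <- lbfgs_loglik(fx$S, fx$conc, fx$sim$noisy)
  expect_equal(fit$model$loglik, ll_oracle, tolerance = 1e-6)
})

test_that("adding the squared anterior-gradient term never hurts the fit", {
  fx <- ap_fixture(seed = 6, n_crm = 12, noise = 0.1)
  base <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  spec2 <- rbind(data.frame(tf = AP_TFS, order = 1L),
                 data.frame(tf = "BCD", order = 2L))
  quad <- fit_model(fx$S, fx$conc, fx$sim$noisy, covariate_spec = spec2)
  expect_gte(quad$model$loglik, base$model$loglik - 1e-6)
  expect_true("BCD^2" %in% names(quad$model$weights))
})

test_that("cross-validation is seeded, deterministic and validated", {
  fx <- ap_fixture(seed = 8, n_crm = 8, noise = 0.05)
  cv1 <- cross_validate(fx$S, fx$conc, fx$sim$noisy, reps = 5, seed = 3)
  cv2 <- cross_validate(fx$S, fx$conc, fx$sim$noisy, reps = 5, seed = 3)
  expect_identical(cv1, cv2)
  expect_length(cv1, 5)
  expect_error(cross_validate(fx$S, fx$conc, fx$sim$noisy, reps = 0), "reps")
  expect_error(cross_validate(fx$S[1:3, ], fx$conc, fx$sim$noisy, reps = 1),
               "at least 4 CRMs")
})

test_that("shuffling CRM-profile assignment degrades test RMSE", {
  fx <- ap_fixture(seed = 9, n_crm = 12, noise = 0.05)
  real <- cross_validate(fx$S, fx$conc, fx$sim$noisy, reps = 20, seed = 10)
  shuf <- cross_validate(fx$S, fx$conc, fx$sim$noisy, reps = 20, seed = 11,
                         shuffle = TRUE)
  expect_lt(median(real), median(shuf))
  expect_lt(wilcox.test(real, shuf, alternative = "less")$p.value, 0.01)
})

test_that("pure-noise targets show no real/shuffled separation", {
  conc <- make_concentrations(ap_shapes())
  rejections <- 0L
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      S <- matrix(runif(80, 0, 4), 8, 10,
                  dimnames = list(sprintf("c%d", 1:8), AP_TFS))
      targets <- setNames(lapply(1:8, function(i) {
        axis_profile(rbinom(100, 1, 0.4), "binary")
      }), rownames(S))
    })
    real <- cross_validate(S, conc, targets, reps = 15, seed = 200 + s)
    shuf <- cross_validate(S, conc, targets, reps = 15, seed = 300 + s,
                           shuffle = TRUE)
    p <- wilcox.test(real, shuf, alternative = "less")$p.value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2)  # overlap in at least 8 of 10 seeds
})

test_that("knockdown zeroes one factor's concentration only", {
  fx <- ap_fixture(seed = 12, n_crm = 6)
  fit <- fit_model(fx$S, fx$conc, fx$sim$clean)
  crm <- rownames(fx$S)[1]

  # weight-zero TF: prediction unchanged
  m <- fit$model
  m$weights["TLL"] <- 0
  wt <- predict_expression(m, fx$S[crm, ], fx$conc, crm = crm)
  kd <- knockdown(m, "TLL", fx$S[crm, ], fx$conc, crm = crm)
  expect_equal(kd$values, wt$values)

  # knocking down a repressor with sites raises activity in its domain
  spec <- data.frame(tf = c("A", "R"), order = 1L)
  conc <- list(A = axis_profile(rep(0.8, 100)),
               R = make_concentrations(list(R = list("stripe", 40, 60)))$R)
  mr <- regression_model(c(A = 1, R = -5), c(l = -1), spec)
  s <- c(A = 2, R = 3)
  wt <- predict_expression(mr, s, conc, crm = "l")$values
  kd <- knockdown(mr, "R", s, conc, crm = "l")$values
  expect_true(all(kd[41:59] > wt[41:59]))
  expect_equal(kd[-(40:60)], wt[-(40:60)])

  # knocking down the sole activator can only lower the prediction
  kd_a <- knockdown(mr, "A", s, conc, crm = "l")$values
  expect_true(all(kd_a <= wt + 1e-12))

  expect_error(knockdown(mr, "ZZZ", s, conc, crm = "l"), "unknown TF")
})

test_that("models serialize to JSON and back", {
  fx <- ap_fixture(seed = 13, n_crm = 5)
  fit <- fit_model(fx$S, fx$conc, fx$sim$clean)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit$model, f)
  back <- read_model_json(f)
  expect_equal(back$weights, fit$model$weights)
  expect_equal(back$baselines, fit$model$baselines)
  p1 <- predict_expression(fit$model, fx$S[1, ], fx$conc, crm = rownames(fx$S)[1])
  p2 <- predict_expression(back, fx$S[1, ], fx$conc, crm = rownames(fx$S)[1])
  expect_equal(p1$values, p2$values)
})
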
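test_that("a TF with zero motif score earns edge p = 1 exactly", {
  fx <- net_fixture(seed = 1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  # crm1 is wired to A1 only; R1 has no sites there
  expect_equal(fx$S["crm1", "R1"], 0)
  et <- edge_pvalue(fit$model, "R1", "crm1", fx$S["crm1", ], fx$conc,
                    fx$sim$noisy$crm1, n_perm = 200, seed = 5)
  expect_equal(et$p, 1)
  expect_true(all(et$null_rmse == et$rmse_wt))
  expect_length(et$null_rmse, 200)
})

test_that("edge tests are seeded and deterministic", {
  fx <- net_fixture(seed = 1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  e1 <- edge_pvalue(fit$model, "A1", "crm1", fx$S["crm1", ], fx$conc,
                    fx$sim$noisy$crm1, n_perm = 100, seed = 9)
  e2 <- edge_pvalue(fit$model, "A1", "crm1", fx$S["crm1", ], fx$conc,
                    fx$sim$noisy$crm1, n_perm = 100, seed = 9)
  expect_identical(e1$null_rmse, e2$null_rmse)
  expect_identical(e1$p, e2$p)
  expect_error(edge_pvalue(fit$model, "A1", "crm1", fx$S["crm1", ], fx$conc,
                           fx$sim$noisy$crm1, n_perm = 0), "n_perm")
})

test_that("an involved TF is detected, an uninvolved one is not", {
  fx <- net_fixture(seed = 1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  pa <- edge_pvalue(fit$model, "A1", "crm1", fx$S["crm1", ], fx$conc,
                    fx$sim$noisy$crm1, n_perm = 500, seed = 3)$p
  pb <- edge_pvalue(fit$model, "A2", "crm1", fx$S["crm1", ], fx$conc,
                    fx$sim$noisy$crm1, n_perm = 500, seed = 3)$p
  expect_lt(pa, 0.05)
  expect_equal(pb, 1)  # no sites: permutations cannot move the prediction
})

test_that("the planted 3x6 network is recovered with correct signs", {
  fx <- net_fixture(seed = 1)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  net <- build_network(fit$model, fx$S, fx$conc, fx$sim$noisy,
                       alpha_level = 0.05, n_perm = 500, seed = 5)
  truth <- which(fx$wiring == 1, arr.ind = TRUE)
  true_set <- paste(fx$tfs[truth[, 2]], rownames(fx$wiring)[truth[, 1]])
  called <- paste(net$tf, net$crm)
  expect_gte(mean(called %in% true_set), 0.9)              # precision
  expect_gte(mean(true_set %in% called), 0.9)              # recall
  expect_true(all(net$sign[net$tf == "R1"] == "repressor"))
  expect_true(all(net$sign[net$tf != "R1"] == "activator"))

  all_edges <- attr(net, "all_edges")
  expect_equal(nrow(all_edges), 18)
  expect_false(anyDuplicated(paste(all_edges$tf, all_edges$crm)) > 0)

  empty <- build_network(fit$model, fx$S, fx$conc, fx$sim$noisy,
                         alpha_level = 0, n_perm = 50, seed = 5)
  expect_equal(nrow(empty), 0)
})

test_that("edge p-values are permutation-invariant to joint bin relabeling", {
  fx <- net_fixture(seed = 2)
  fit <- fit_model(fx$S, fx$conc, fx$sim$noisy)
  perm <- withr::with_seed(4, sample(100))
  conc_p <- lapply(fx$conc, function(p) axis_profile(p$values[perm]))
  targ_p <- axis_profile(fx$sim$noisy$crm6$values[perm], "binary")
  e0 <- edge_pvalue(fit$model, "R1", "crm6", fx$S["crm6", ], fx$conc,
                    fx$sim$noisy$crm6, n_perm = 300, seed = 8)
  e1 <- edge_pvalue(fit$model, "R1", "crm6", fx$S["crm6", ], conc_p,
                    targ_p, n_perm = 300, seed = 8)
  expect_equal(e0$rmse_wt, e1$rmse_wt, tolerance = 1e-12)
  expect_equal(e0$p, e1$p, tolerance = 0.05)  # same null law, same seed
})

test_that("null edge p-values are approximately uniform", {
  fx <- net_fixture(seed = 3)
  model <- regression_model(fx$w_true, fx$alpha,
                            data.frame(tf = fx$tfs, order = 1L))
  # crm1 carries sites for A1 only, so under a target independent of A1 the
  # wild-type arrangement is exchangeable with its permutations
  ps <- vapply(1:150, function(i) {
    target <- withr::with_seed(5000 + i,
                               axis_profile(rbinom(100, 1, 0.4), "binary"))
    edge_pvalue(model, "A1", "crm1", fx$S["crm1", ], fx$conc, target,
                n_perm = 99, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("rank-sum discrimination matches exact enumeration and is calibrated", {
  # one-sided exact: all 3 bound above all 3 random -> 1 / C(6,3)
  expect_equal(chip_discrimination(c(10, 11, 12), c(1, 2, 3)), 0.05)
  # identical samples: p near 1/2 by symmetry
  expect_equal(chip_discrimination(c(1, 2, 3), c(1, 2, 3)), 0.5,
               tolerance = 0.2)
  expect_error(chip_discrimination(numeric(0), 1:3), "non-empty")

  ps <- vapply(1:300, function(i) {
    withr::with_seed(i, chip_discrimination(rnorm(20), rnorm(20)))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("positional motif-score summaries separate activators from repressors", {
  conc <- make_concentrations(list(A = "anterior", R = list("stripe", 40, 60)))
  # 10 CRMs tiling the axis; activator sites only in anterior-active CRMs,
  # repressor sites only in CRMs active outside its stripe
  targets <- setNames(lapply(0:9, function(i) {
    v <- rep(0, 100)
    v[(i * 10 + 1):(i * 10 + 10)] <- 1
    axis_profile(v, "binary")
  }), sprintf("c%d", 1:10))
  act_scores <- setNames(c(5, 4, 3, 2, 1, 0, 0, 0, 0, 0), names(targets))
  rep_scores <- setNames(c(4, 4, 4, 0, 0, 0, 0, 4, 4, 4), names(targets))

  a <- positional_motif_summary(act_scores, targets, conc$A)
  expect_gt(a$correlation, 0.5)
  r <- positional_motif_summary(rep_scores, targets, conc$R)
  expect_lt(r$correlation, -0.5)

  # constant scores: no variance, correlation undefined
  cs <- positional_motif_summary(setNames(rep(2, 10), names(targets)),
                                 targets, conc$A)
  expect_true(is.na(cs$correlation))

  # bins with no active CRM are reported missing
  t2 <- list(c1 = axis_profile(rep(c(1, 0), c(50, 50)), "binary"))
  s2 <- positional_motif_summary(c(c1 = 3), t2, conc$A)
  expect_true(all(is.na(s2$mean_score[51:100])))
  expect_error(
    positional_motif_summary(c(c1 = 3),
                             list(c1 = axis_profile(rep(0, 100), "binary")),
                             conc$A),
    "no CRM is active")
})

test_that("incongruous occupancy requires overlap AND binding", {
  act <- axis_profile(rep(c(0, 1, 0), c(44, 11, 45)), "binary")  # bins 45-55
  doms <- list(KR = data.frame(start = 40, end = 60),
               GT = data.frame(start = c(20, 70), end = c(40, 80)),
               KNI = data.frame(start = 60, end = 70))
  res <- incongruous_occupancy(
    act, doms,
    occupancy = c(KR = TRUE, GT = TRUE, KNI = TRUE),
    motif_z = c(KR = -0.3, GT = 2.5, KNI = 1.0))
  kr <- res[res$repressor == "KR", ]
  expect_true(kr$incongruous)
  expect_equal(kr$motif_support, "absent")
  # KNI domain 60-70 does not overlap activity 45-55
  expect_false(res[res$repressor == "KNI", ]$incongruous)

  res2 <- incongruous_occupancy(act, doms, c(KR = FALSE),
                                c(KR = 2.5))
  expect_false(res2$incongruous)  # unbound: never incongruous
  expect_equal(res2$motif_support, "significant")

  expect_error(incongruous_occupancy(act, doms, c(XX = TRUE), c(XX = 1)),
               "unknown repressor")
})
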
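# Missingness mechanisms: linear predictor, masking, pmiss, calibration.

test_that("linear predictor assembles the logistic terms", {
  cfg0 <- miss_config(center_values = FALSE)
  expect_equal(miss_linear_predictor(cfg0, arm = 1, week = 5, y0 = 4500,
                                     y_last = 8000, y_current = 9000,
                                     y_stage2_mean = 8500), 0)
  cfg <- miss_config(alpha_m = -1.5, center_values = FALSE)
  lp <- miss_linear_predictor(cfg, 1, 5, 4500, 8000, 9000, 8500)
  expect_equal(lp, -1.5)
  # expit(-1.5), evaluated independently
  expect_equal(plogis(lp), 1 / (1 + exp(1.5)), tolerance = 1e-12)
  expect_equal(round(plogis(lp), 5), 0.18243)

  # stage-2 term only contributes from week 13
  cfgr <- miss_config(beta_mr = -0.002, center_values = FALSE)
  expect_equal(miss_linear_predictor(cfgr, 0, 12, 0, 0, 0, 1000), 0)
  expect_equal(miss_linear_predictor(cfgr, 0, 13, 0, 0, 0, 1000), -2)

  # centering subtracts the stated centers
  cfgc <- miss_config(beta_ml = 1, centers = c(y0 = 1, y = 8000,
                                               stage2 = 2))
  expect_equal(miss_linear_predictor(cfgc, 0, 3, 0, 8500, 0, 0), 500)
})

test_that("masking matches its Bernoulli rates", {
  tab <- collapse_runin(simulate_trial(gen_config(n = 2000), 11))
  # expit(-50) ~ 0: nothing masked
  none <- apply_missingness(tab, miss_config(alpha_m = -50), seed = 1)
  expect_equal(compute_pmiss(none), 0)
  expect_true(all(none$observed[none$week == 0L] == 1L))
  # alpha_m = 0: half masked (binomial 3-SE band on 2000*24 cells)
  half <- apply_missingness(tab, miss_config(alpha_m = 0), seed = 2)
  expect_lt(abs(compute_pmiss(half) - 0.5), 3 * sqrt(0.25 / (2000 * 24)))
  # direct MCAR
  mc <- apply_missingness(tab, miss_config(mcar_p = 0.2), seed = 3)
  expect_lt(abs(compute_pmiss(mc) - 0.2), 3 * sqrt(0.2 * 0.8 / (2000 * 24)))
  expect_true(all(mc$observed[mc$week == 0L] == 1L))
  # determinism
  mc2 <- apply_missingness(tab, miss_config(mcar_p = 0.2), seed = 3)
  expect_identical(mc$observed, mc2$observed)
})

test_that("pmiss is monotone in the intercept and responds to the arm", {
  tab <- collapse_runin(simulate_trial(gen_config(n = 3000), 21))
  pm <- vapply(c(-3, -1.5, 0, 1), function(a)
    compute_pmiss(apply_missingness(tab, miss_config(alpha_m = a),
                                    seed = 4)), numeric(1))
  expect_monotone_nondecreasing(pm)

  # positive arm coefficient raises the arm-1 masked fraction
  ma <- apply_missingness(tab, miss_config(alpha_m = -1.5, beta_ma = 1),
                          seed = 5)
  post <- ma[ma$week >= 1L, ]
  f1 <- mean(post$observed[post$arm == 1] == 0L)
  f0 <- mean(post$observed[post$arm == 0] == 0L)
  expect_gt(f1 - f0, 3 * sqrt(0.25 / sum(post$arm == 1) +
                                0.25 / sum(post$arm == 0)))
})

test_that("compute_pmiss counts masked post-baseline cells", {
  tab <- toy_table(npid = 5)
  expect_equal(compute_pmiss(tab), 0)
  tab$observed[tab$week >= 1L] <- 0L
  expect_equal(compute_pmiss(tab), 1)
  tab$observed <- 1L
  # 12 masked of 5*24
  tab$observed[tab$week %in% 1:12 & tab$pid == 3] <- 0L
  expect_equal(compute_pmiss(tab), 12 / 120)
})

test_that("intercept calibration inverts the mechanism", {
  gen <- gen_config(n = 200)
  cfg <- miss_config(center_values = FALSE)
  a50 <- calibrate_intercept(cfg, 0.5, gen, reps = 20, seed = 8)
  expect_lt(abs(a50), 0.1)
  a18 <- calibrate_intercept(cfg, 0.18243, gen, reps = 20, seed = 8)
  expect_lt(abs(a18 - (-1.5)), 0.15)
  # calibrated mechanism reproduces the target on fresh seeds
  cfg2 <- miss_config(alpha_m = NA, beta_ma = 1, beta_mt = 1 / 12,
                      centers = miss_centers(gen))
  a <- calibrate_intercept(cfg2, 0.21, gen, reps = 30, seed = 9)
  cfg2$alpha_m <- a
  pm <- mean(vapply(1:20, function(r) {
    tab <- collapse_runin(simulate_trial(gen, 5000 + r))
    compute_pmiss(apply_missingness(tab, cfg2, seed = 6000 + r))
  }, numeric(1)))
  expect_lt(abs(pm - 0.21), 0.01)
  expect_error(calibrate_intercept(cfg, 1.2, gen), "target_pmiss")
})

test_that("MAR mechanisms read only observed quantities", {
  # structural MAR check: with current/future-value coefficients zero the
  # mask depends only on (arm, t, y0, last OBSERVED value); masking the
  # current value's generated y must not change the mask
  gen <- gen_config(n = 300)
  tab <- collapse_runin(simulate_trial(gen, 13))
  cfg <- miss_config(alpha_m = -1.5, beta_ma = 1, beta_mt = 1 / 12,
                     beta_ml = 0.001, centers = miss_centers(gen))
  m1 <- apply_missingness(tab, cfg, seed = 14)
  tab2 <- tab
  # perturb generated values only where m1 masked them (unobserved world)
  tab2$y[m1$observed == 0L] <- tab2$y[m1$observed == 0L] + 1e6
  m2 <- apply_missingness(tab2, cfg, seed = 14)
  expect_identical(m1$observed, m2$observed)
  # whereas an MNAR coefficient makes the mask value-dependent
  cfgn <- miss_config(alpha_m = -1.5, beta_my = -0.002,
                      centers = miss_centers(gen))
  n1 <- apply_missingness(tab, cfgn, seed = 15)
  tab3 <- tab
  tab3$y[tab3$week >= 1L] <- tab3$y[tab3$week >= 1L] - 3000
  n2 <- apply_missingness(tab3, cfgn, seed = 15)
  expect_false(identical(n1$observed, n2$observed))
})
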
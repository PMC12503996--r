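# Delta grid, shifts, SIR/SIC metrics, and the sweep driver.

test_that("delta grid is symmetric with increment 2/S", {
  expect_equal(delta_grid(8),
               c(-1, -3 / 4, -1 / 2, -1 / 4, 0, 1 / 4, 1 / 2, 3 / 4, 1))
  expect_equal(delta_grid(2), c(-1, 0, 1))
  expect_equal(sum(delta_grid(12)), 0)
  expect_length(delta_grid(10), 11)
  expect_error(delta_grid(7), "even")
  expect_error(delta_grid(0), "even")
})

test_that("delta_max scales the residual SD", {
  tab <- small_table(12, 81)
  f <- fit_lmm(tab)
  expect_equal(compute_delta_max(f, 2), 2 * f$sigma_res)
  expect_equal(compute_delta_max(f, 0), 0)
  f$converged <- FALSE
  expect_error(compute_delta_max(f), "converge")
})

test_that("delta shifts move only masked cells and invert cleanly", {
  tab <- small_table(15, 83)
  tab <- apply_missingness(tab, miss_config(mcar_p = 0.3), seed = 84)
  w <- pivot_wide(tab)
  cs <- mice_chain(w, impute_config(M = 2), seed = 85)
  sh <- apply_delta_shift(cs, 0.5, 2000)
  expect_identical(apply_delta_shift(cs, 0, 2000), cs)
  for (m in 1:2) {
    expect_equal(sh$imputations[[m]][!w$mask], cs$imputations[[m]][!w$mask])
    expect_equal(mean(sh$imputations[[m]][w$mask]) -
                   mean(cs$imputations[[m]][w$mask]), 1000,
                 tolerance = 1e-9)
  }
  back <- apply_delta_shift(sh, -0.5, 2000)
  expect_equal(back$imputations, cs$imputations, tolerance = 1e-12)
  # treated-only shift leaves control-arm cells alone
  sht <- apply_delta_shift(cs, 1, 1000, shift_arms = "treated")
  ctrl <- w$mask & (w$arm == 0L)
  expect_equal(sht$imputations[[1]][ctrl], cs$imputations[[1]][ctrl])
})

test_that("SIR/SIC half-widths follow the worked example", {
  grid <- delta_grid(8)
  # observed rejects positive; rejecting set {-1/2, -1/4, 0, 1/4}
  dirs <- ifelse(grid %in% c(-1 / 2, -1 / 4, 0, 1 / 4), 1, 0)
  expect_equal(sir_half_width(1, dirs, grid), 1 / 4)
  expect_equal(sic_half_width(1, dirs, grid), 1 / 4)

  # no observed rejection -> SIR 0
  expect_equal(sir_half_width(0, dirs, grid), 0)
  # all nine reject with the observed direction -> full interval
  expect_equal(sir_half_width(1, rep(1, 9), grid), 1)
  expect_equal(sic_half_width(1, rep(1, 9), grid), 1)
  # only delta = 0 agrees -> SIC 0
  dirs0 <- ifelse(grid == 0, 1, 0)
  expect_equal(sic_half_width(1, dirs0, grid), 0)
  # direction flip inside the interval breaks the SIR
  dirs2 <- ifelse(abs(grid) <= 0.5, -1, 0)
  dirs2[grid == 0.25] <- 1
  expect_equal(sir_half_width(-1, dirs2, grid), 0)
  # SIC with a non-rejecting observed analysis counts agreement on 0
  dirs3 <- ifelse(abs(grid) <= 0.5, 0, 1)
  expect_equal(sic_half_width(0, dirs3, grid), 1 / 2)
})

test_that("half-width invariants hold over random decision patterns", {
  grid <- delta_grid(8)
  set.seed(87)
  for (i in 1:200) {
    obs <- sample(c(-1, 0, 1), 1)
    dirs <- sample(c(-1, 0, 1), 9, replace = TRUE)
    sir <- sir_half_width(obs, dirs, grid)
    sic <- sic_half_width(obs, dirs, grid)
    expect_true(sir %in% c(0, grid[grid > 0]))
    expect_true(sic %in% c(0, grid[grid > 0]))
    if (obs != 0) {
      # when the observed test rejects, agreement == same-direction
      # rejection, so the two intervals coincide
      expect_equal(sir, sic)
    } else {
      expect_equal(sir, 0)
    }
  }
})

test_that("sweep reduces to the observed contrast without missing cells", {
  tab <- small_table(12, 89)
  sw <- run_sensitivity(tab, S = 4, impute = impute_config(M = 2),
                        seed = 90)
  con <- policy_contrast(fit_lmm(tab))
  for (r in sw$results) expect_equal(r$theta_hat, con$theta_hat)
  expect_equal(sw$sic_half, 1)  # every delta trivially agrees
})

test_that("sweep estimates respond monotonically to delta", {
  tab <- small_table(40, 91)
  # arm-imbalanced missingness: treated participants lose more cells
  tab <- apply_missingness(tab, miss_config(alpha_m = -2, beta_ma = 1.5),
                           seed = 92)
  sw <- run_sensitivity(tab, S = 4, impute = impute_config(M = 3),
                        seed = 93)
  est <- vapply(sw$results, `[[`, 0, "theta_hat")
  # completed datasets are shared across deltas, so the contrast moves
  # monotonically with the shift; direction follows the arm imbalance
  # (more treated cells shifted -> increasing in delta)
  expect_monotone_nondecreasing(est)

  # lambda = 0 collapses the sweep to plain MI at every delta
  sw0 <- run_sensitivity(tab, S = 4, lambda = 0,
                         impute = impute_config(M = 2), seed = 94)
  est0 <- vapply(sw0$results, `[[`, 0, "theta_hat")
  expect_equal(diff(range(est0)), 0, tolerance = 1e-9)

  # delta = 0 column equals mi_analyze under the same seed
  mi <- mi_analyze(tab, impute_config(M = 3), seed = 93)
  expect_equal(sw$results[[which(sw$grid == 0)]]$theta_hat, mi$theta_hat,
               tolerance = 1e-12)
  expect_equal(sw$results[[which(sw$grid == 0)]]$T, mi$T,
               tolerance = 1e-12)
})
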
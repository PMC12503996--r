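# Longitudinal mixed model: marginal covariance, observed-data likelihood
# (dense-MVN oracle), fitting, policy contrast.

test_that("marginal covariance matches a hand construction", {
  V <- lmm_marginal_covariance(c(0, 1, 2), 1, 1, 1, 0.5)
  hand <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3) {
    tj <- j - 1; tk <- k - 1
    hand[j, k] <- 1 + tj * tk + 0.5^abs(tj - tk)
  }
  expect_equal(V, hand, tolerance = 1e-12)
  # iid limit
  expect_equal(lmm_marginal_covariance(0:4, 0, 0, 3, 0), diag(9, 5),
               tolerance = 1e-12)
  # with sigma_b1 = 0 the covariance is translation invariant
  V1 <- lmm_marginal_covariance(0:3, 2, 0, 1, 0.4)
  V2 <- lmm_marginal_covariance(10:13, 2, 0, 1, 0.4)
  expect_equal(V1, V2, tolerance = 1e-12)
  expect_error(lmm_marginal_covariance(0:2, 1, 1, 1, 1), "rho")
})

test_that("observed-data log-likelihood agrees with a dense MVN oracle", {
  tab <- small_table(5, 29)
  tab$observed[tab$week %in% c(3, 7, 15) & tab$pid <= 2] <- 0L
  params <- list(
    beta = setNames(c(-50, 5900, 9900, 10, -0.5, 0.01, seq(50, 280, by = 10)),
                    c("age", "runin", "post", "t", "t2", "t3",
                      paste0("arm_w", 1:24))),
    sigma_b0 = 300, sigma_b1 = 20, sigma_res = 1800, rho = 0.95)
  ll <- lmm_loglik(params, tab)

  # oracle: mvtnorm dense density per participant
  obs <- tab[tab$observed == 1L, ]
  ll_or <- 0
  for (p in unique(obs$pid)) {
    d <- obs[obs$pid == p, ]
    w <- d$week
    age0 <- d$age[d$week == 0L]
    X <- cbind(age0, w == 0, w > 0, w, w^2, w^3,
               outer(w, 1:24, "==") * d$arm[1])
    mu <- as.numeric(X %*% params$beta)
    V <- params$sigma_b0^2 + params$sigma_b1^2 * outer(w, w) +
      params$sigma_res^2 * params$rho^abs(outer(w, w, "-"))
    ll_or <- ll_or + mvtnorm::dmvnorm(d$y, mu, V, log = TRUE)
  }
  expect_equal(ll, ll_or, tolerance = 1e-8)

  # marginalization: dropping a week equals evaluating on the subvector
  tab2 <- tab[!(tab$pid == 4 & tab$week == 11L), ]
  tab2b <- tab
  tab2b$observed[tab2b$pid == 4 & tab2b$week == 11L] <- 0L
  expect_equal(lmm_loglik(params, tab2), lmm_loglik(params, tab2b),
               tolerance = 1e-10)

  # location invariance: shift y and the week-level intercepts together
  tab3 <- tab
  tab3$y <- tab3$y + 500
  params3 <- params
  params3$beta[c("runin", "post")] <- params3$beta[c("runin", "post")] + 500
  expect_equal(lmm_loglik(params3, tab3), ll, tolerance = 1e-9)
})

test_that("the compiled ML objective equals the R likelihood", {
  tab <- small_table(6, 37)
  tab$observed[tab$week %in% c(2, 9) & tab$pid %in% c(1, 4)] <- 0L
  f <- fit_lmm(tab, method = "ML")
  params <- list(beta = coef(f), sigma_b0 = f$sigma_b0,
                 sigma_b1 = f$sigma_b1, sigma_res = f$sigma_res,
                 rho = f$rho)
  expect_equal(f$logLik, lmm_loglik(params, tab), tolerance = 1e-6)
})

test_that("GLS reduces to OLS with iid errors", {
  tab <- small_table(14, 43)
  f <- fit_lmm(tab, vc_fixed = c(tau0 = 0, tau1 = 0, rho = 0))
  obs <- tab[tab$observed == 1L, ]
  age0 <- obs$age[obs$week == 0L][match(obs$pid, unique(obs$pid))]
  X <- cbind(age0, obs$week == 0, obs$week > 0, obs$week, obs$week^2,
             obs$week^3, outer(obs$week, 1:24, "==") * obs$arm)
  beta_ols <- solve(t(X) %*% X, t(X) %*% obs$y)
  expect_equal(unname(coef(f)), as.numeric(beta_ols), tolerance = 1e-6)
})

test_that("the fitted likelihood dominates the truth and recovers theta", {
  gen <- gen_config(n = 1000)
  tab <- collapse_runin(simulate_trial(gen, 47))
  f <- fit_lmm(tab)
  expect_true(f$converged)
  # optimality: maximized loglik >= loglik at the generating variance
  # parameters (profiled comparison through the compiled objective)
  prep <- deltami:::lmm_prepare(tab)
  at_truth <- deltami:::lmm_neg2ll_cpp(50 / 2000, 50 / 2000, exp(-1 / 52),
                                       prep$pat_weeks, prep$pat_G,
                                       prep$pid_pat, prep$pid_y, prep$pid_d,
                                       TRUE)
  expect_lte(-2 * f$logLik, at_truth + 1e-6)

  # parameter recovery: null policy effect within 3 SE
  con <- policy_contrast(f)
  expect_lt(abs(con$theta_hat), 3 * con$se)
  # fixed-effect covariance PSD
  ev <- eigen(vcov(f), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-6))
})

test_that("fit agrees with nlme::lme on one masked dataset", {
  tab <- collapse_runin(simulate_trial(gen_config(), 42))
  tab <- apply_missingness(tab, miss_config(mcar_p = 0.2), seed = 1)
  f <- fit_lmm(tab)

  obs <- tab[tab$observed == 1L, ]
  obs$age0 <- obs$age - obs$week / 52
  obs$runin <- as.numeric(obs$week == 0)
  obs$post <- as.numeric(obs$week > 0)
  obs$t1 <- obs$week
  obs$t2 <- obs$week^2
  obs$t3 <- obs$week^3
  for (w in 1:24) obs[[paste0("aw", w)]] <- (obs$week == w) * obs$arm
  fml <- stats::as.formula(paste(
    "y ~ 0 + age0 + runin + post + t1 + t2 + t3 +",
    paste(paste0("aw", 1:24), collapse = "+")))
  m <- nlme::lme(fml, random = list(pid = nlme::pdDiag(~ 1 + t1)),
                 correlation = nlme::corExp(form = ~ week | pid),
                 data = obs, method = "REML",
                 control = nlme::lmeControl(returnObject = TRUE))
  expect_equal(unname(coef(f)), unname(nlme::fixef(m)), tolerance = 0.05)
  expect_equal(f$sigma_res, m$sigma, tolerance = 0.02)
  rng <- as.numeric(coef(m$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(f$rho, exp(-1 / rng), tolerance = 0.005)
  L <- setNames(rep(0, 30), names(nlme::fixef(m)))
  L[paste0("aw", 21:24)] <- 0.25
  con <- policy_contrast(f)
  expect_equal(con$theta_hat, sum(L * nlme::fixef(m)), tolerance = 0.01)
  expect_equal(con$se, sqrt(drop(t(L) %*% vcov(m) %*% L)), tolerance = 0.01)
})

test_that("fit is invariant to pid relabeling and row order", {
  tab <- small_table(10, 53)
  tab$observed[tab$week %in% c(5, 12, 20) & tab$pid %in% c(2, 7)] <- 0L
  f1 <- fit_lmm(tab)
  set.seed(60)
  tab2 <- tab
  tab2$pid <- 1000 - tab2$pid          # reverse labels
  tab2 <- tab2[sample(nrow(tab2)), ]   # shuffle rows
  f2 <- fit_lmm(tab2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-4)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-7)
})

test_that("policy contrast combines the week 21-24 coefficients", {
  tab <- small_table(12, 59)
  f <- fit_lmm(tab)
  con <- policy_contrast(f)
  wn <- paste0("arm_w", 21:24)
  # independent dot product
  cw <- setNames(rep(0, 30), names(coef(f)))
  cw[wn] <- 0.25
  expect_equal(con$theta_hat, sum(cw * coef(f)), tolerance = 1e-12)
  expect_equal(con$se, sqrt(drop(t(cw) %*% vcov(f) %*% cw)),
               tolerance = 1e-12)
  expect_equal(con$z, con$theta_hat / con$se)

  # identity covariance block on the four coefficients -> se = 1/2
  f2 <- f
  f2$vcov[, ] <- 0
  f2$vcov[wn, wn] <- diag(4)
  expect_equal(policy_contrast(f2)$se, 0.5, tolerance = 1e-12)
  # constant coefficients with zero covariance -> degenerate, flagged
  f3 <- f
  f3$coefficients[wn] <- 7
  f3$vcov[, ] <- 0
  con3 <- policy_contrast(f3)
  expect_equal(con3$theta_hat, 7)
  expect_true(con3$degenerate)
  expect_equal(con3$onesided_direction, 0)
})
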
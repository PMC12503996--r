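#' Missingness mechanism configuration
#'
#' Parameterizes a per-week logistic model for the probability that a
#' post-baseline outcome is missing.  For participant i at week t >= 1 the
#' linear predictor is
#' \deqn{\eta_{it} = \alpha_m + \beta_{ma} A_i + \beta_{mt} t +
#'   \beta_{m0} v(Y_{i0}) + \beta_{ml} v(Y_{ilt}) +
#'   \beta_{mla} v(Y_{ilt}) A_i + \beta_{my} v(Y_{it}) +
#'   \beta_{mya} v(Y_{it}) A_i + I(t \ge 13)\, \beta_{mr} v(\bar Y_{i,21-24}),}
#' where \eqn{Y_{ilt}} is the last outcome observed strictly before week t
#' (the never-masked baseline is always eligible) and
#' \eqn{\bar Y_{i,21-24}} is the stage-2 outcome average.  Missingness is
#' drawn Bernoulli(expit(\eqn{\eta_{it}})) sequentially in week order so
#' \eqn{Y_{ilt}} reflects earlier masking.
#'
#' When `center_values = TRUE` (the default) the value-scale covariates
#' (baseline, last-observed, current, stage-2 average) enter as deviations
#' from their marginal means under the generation model (see
#' [miss_centers()]): with raw step counts around 8500/day, coefficient
#' magnitudes of 0.001-0.002 would saturate the logistic.
#'
#' Setting `mcar_p` bypasses the logistic model entirely: every
#' post-baseline cell is masked independently with that probability (pure
#' MCAR).  An `alpha_m` of `NA` marks the intercept as "to be calibrated"
#' against a target missingness proportion, see [calibrate_intercept()].
#'
#' @param alpha_m logistic intercept (or `NA` to calibrate later).
#' @param beta_ma arm coefficient.
#' @param beta_m0 baseline (run-in average) coefficient, per step/day.
#' @param beta_mt week coefficient.
#' @param beta_ml last-observed-value coefficient, per step/day.
#' @param beta_mla last-observed-value by arm interaction.
#' @param beta_my current-value coefficient (MNAR when nonzero).
#' @param beta_mya current-value by arm interaction (MNAR when nonzero).
#' @param beta_mr stage-2 outcome-average coefficient, active weeks 13-24
#'   (MNAR when nonzero).
#' @param center_values center value-scale covariates at `centers`.
#' @param centers named vector `c(y0=, y=, stage2=)` of centering constants;
#'   see [miss_centers()].  Required only when centering is on and a
#'   value-scale coefficient is nonzero.
#' @param mcar_p optional direct per-week missing probability in `[0, 1]`.
#' @param target_pmiss optional overall missingness proportion used by the
#'   replication driver to calibrate `alpha_m`.
#' @return An object of class `miss_config`.
#' @export
miss_config <- function(alpha_m = 0, beta_ma = 0, beta_m0 = 0, beta_mt = 0,
                        beta_ml = 0, beta_mla = 0, beta_my = 0, beta_mya = 0,
                        beta_mr = 0, center_values = TRUE, centers = NULL,
                        mcar_p = NULL, target_pmiss = NULL) {
  coefs <- c(beta_ma, beta_m0, beta_mt, beta_ml, beta_mla, beta_my,
             beta_mya, beta_mr)
  if (any(!is.finite(coefs))) stop("miss_config: coefficients must be finite")
  if (!is.null(mcar_p) && (mcar_p < 0 || mcar_p > 1))
    stop("miss_config: mcar_p must be in [0, 1]")
  structure(list(alpha_m = alpha_m, beta_ma = beta_ma, beta_m0 = beta_m0,
                 beta_mt = beta_mt, beta_ml = beta_ml, beta_mla = beta_mla,
                 beta_my = beta_my, beta_mya = beta_mya, beta_mr = beta_mr,
                 center_values = isTRUE(center_values), centers = centers,
                 mcar_p = mcar_p, target_pmiss = target_pmiss),
            class = "miss_config")
}

#' Marginal-mean centering constants for a generation model
#'
#' Computes the marginal means, under a [gen_config()], of the value-scale
#' missingness covariates: the collapsed run-in baseline (`y0`), a
#' post-baseline weekly outcome averaged over weeks 1-24 (`y`), and the
#' stage-2 outcome average over weeks 21-24 (`stage2`).  Arm enters at its
#' randomization mean of 1/2.
#'
#' @param gen a [gen_config()].
#' @return Named numeric vector `c(y0, y, stage2)`.
#' @export
miss_centers <- function(gen) {
  agebar <- (gen$age_low + gen$age_high) / 2
  mu <- function(tbar, runin, arm_eff) {
    gen$alpha_star + gen$beta_age_star * (agebar + tbar / 52) +
      runin * gen$beta0_star + arm_eff * 0.5 * gen$betaA_star
  }
  c(y0 = mu(-0.5, 1, 0), y = mu(12.5, 0, 1), stage2 = mu(22.5, 0, 1))
}

#' Missingness linear predictor
#'
#' Evaluates the logistic-model linear predictor for one row context; mostly
#' useful for testing and for documenting the mechanism.  See
#' [miss_config()] for the formula.
#'
#' @param config a [miss_config()].
#' @param arm 0/1 treatment assignment.
#' @param week post-baseline week (>= 1).
#' @param y0 baseline outcome.
#' @param y_last last previously observed outcome.
#' @param y_current current (possibly unobserved) outcome.
#' @param y_stage2_mean average outcome over weeks 21-24.
#' @return The linear predictor (real scalar, vectorized over inputs).
#' @export
miss_linear_predictor <- function(config, arm, week, y0, y_last, y_current,
                                  y_stage2_mean) {
  v <- miss_value_transform(config)
  config$alpha_m + config$beta_ma * arm + config$beta_mt * week +
    config$beta_m0 * v(y0, "y0") +
    config$beta_ml * v(y_last, "y") +
    config$beta_mla * v(y_last, "y") * arm +
    config$beta_my * v(y_current, "y") +
    config$beta_mya * v(y_current, "y") * arm +
    (week >= 13) * config$beta_mr * v(y_stage2_mean, "stage2")
}

## centering transform; identity when center_values is off
miss_value_transform <- function(config) {
  if (!config$center_values) return(function(x, what) x)
  cen <- config$centers
  value_coefs <- c(config$beta_m0, config$beta_ml, config$beta_mla,
                   config$beta_my, config$beta_mya, config$beta_mr)
  if (is.null(cen)) {
    if (any(value_coefs != 0))
      stop("miss_config: centering requested but no centers supplied; ",
           "set centers = miss_centers(gen)")
    cen <- c(y0 = 0, y = 0, stage2 = 0)
  }
  function(x, what) x - cen[[what]]
}

#' Mask post-baseline outcomes according to a missingness mechanism
#'
#' Applies the logistic mechanism of [miss_config()] (or direct Bernoulli
#' masking when `mcar_p` is set) to a collapsed trial table over weeks
#' 0-24.  Weeks are processed in increasing order so the last-observed
#' covariate is updated sequentially; week 0 is never masked.  Masked rows
#' keep their `y` value internally (flagged by `observed = 0`); analysis
#' code must not use it.
#'
#' @param table collapsed trial table (weeks 0-24, week 0 present for all).
#' @param config a [miss_config()].
#' @param seed optional integer seed.
#' @return The table with updated `observed` flags.
#' @export
apply_missingness <- function(table, config, seed = NULL) {
  stopifnot(inherits(config, "miss_config"))
  if (!is.null(seed)) set.seed(seed)
  wide <- pivot_wide(table)
  n <- length(wide$pid)
  if (any(is.na(wide$Y[, "w0"])))
    stop("apply_missingness: week 0 must be present and observed")

  u <- matrix(runif(n * 24), n, 24)
  if (!is.null(config$mcar_p)) {
    miss <- u < config$mcar_p
  } else {
    v <- miss_value_transform(config)
    y0 <- wide$Y_full[, "w0"]
    arm <- wide$arm
    stage2 <- rowMeans(wide$Y_full[, paste0("w", 21:24), drop = FALSE])
    y_last <- y0
    miss <- matrix(FALSE, n, 24)
    for (t in 1:24) {
      yt <- wide$Y_full[, paste0("w", t)]
      lp <- config$alpha_m + config$beta_ma * arm + config$beta_mt * t +
        config$beta_m0 * v(y0, "y0") +
        config$beta_ml * v(y_last, "y") +
        config$beta_mla * v(y_last, "y") * arm +
        config$beta_my * v(yt, "y") +
        config$beta_mya * v(yt, "y") * arm +
        (if (t >= 13) config$beta_mr * v(stage2, "stage2") else 0)
      miss[, t] <- u[, t] < plogis(lp)
      y_last <- ifelse(miss[, t], y_last, yt)
    }
  }

  post <- table$week >= 1L
  i <- match(table$pid[post], wide$pid)
  j <- table$week[post]
  table$observed[post] <- ifelse(miss[cbind(i, j)], 0L, 1L)
  table
}

#' Overall proportion of missing post-baseline outcomes
#'
#' @param table a trial table with weeks 1-24.
#' @return Fraction of week 1-24 cells with `observed == 0`.
#' @export
compute_pmiss <- function(table) {
  post <- table$week >= 1L
  mean(table$observed[post] == 0L)
}

#' Calibrate the missingness intercept to a target missingness proportion
#'
#' The exact intercept that produces a given overall missingness proportion
#' depends on the whole mechanism, so it is found by monotone bisection:
#' `reps` complete trials are simulated once (common random numbers,
#' including the masking uniforms), and `alpha_m` is bisected until the
#' average simulated missingness proportion matches `target_pmiss`.
#'
#' @param config a [miss_config()] whose `alpha_m` is to be replaced.
#' @param target_pmiss target overall missingness proportion in (0, 1).
#' @param gen the [gen_config()] under which to calibrate.
#' @param reps number of simulated trials averaged per evaluation.
#' @param seed integer seed for the calibration stream.
#' @param tol bisection tolerance on `alpha_m`.
#' @return The calibrated `alpha_m` (numeric scalar).
#' @export
calibrate_intercept <- function(config, target_pmiss, gen, reps = 50,
                                seed = 1L, tol = 1e-4) {
  stopifnot(inherits(config, "miss_config"), inherits(gen, "gen_config"))
  if (target_pmiss <= 0 || target_pmiss >= 1)
    stop("calibrate_intercept: target_pmiss must be in (0, 1)")
  tabs <- lapply(seq_len(reps), function(r)
    collapse_runin(simulate_trial(gen, substream_seed(seed, r))))
  useeds <- vapply(seq_len(reps), function(r)
    substream_seed(seed, 100000L + r), integer(1))

  f <- function(a) {
    cfg <- config
    cfg$alpha_m <- a
    mean(vapply(seq_len(reps), function(r)
      compute_pmiss(apply_missingness(tabs[[r]], cfg, seed = useeds[r])),
      numeric(1)))
  }
  lo <- -20; hi <- 20
  if (f(lo) > target_pmiss || f(hi) < target_pmiss)
    stop("calibrate_intercept: search range does not bracket the target")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_pmiss) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
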
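#' Simulation scenario specification
#'
#' Bundles everything one simulation-study row needs: the generation model,
#' the missingness mechanism, which analyses to run, and the Monte-Carlo
#' scale.  MAR/MNAR mechanisms whose `alpha_m` is `NA` are calibrated by
#' [calibrate_intercept()] against `miss$target_pmiss` (under the null
#' version of the generation model) before the replication loop starts.
#'
#' @param name scenario label.
#' @param gen a [gen_config()].
#' @param miss a [miss_config()] (`mcar_p = 0` means no masking).
#' @param analyses subset of `c("lm", "lmm", "mi", "sweep")`; `"sweep"`
#'   implies the delta grid (and contains the `delta = 0` plain-MI column),
#'   `"mi"` is plain MI only.
#' @param reps default replication count.
#' @param M imputations per replication.
#' @param S delta-grid resolution for `"sweep"`.
#' @param lambda delta_max multiplier for `"sweep"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, gen, miss, analyses = c("lm", "lmm"),
                          reps = 1000, M = 10, S = 8, lambda = 2) {
  stopifnot(inherits(gen, "gen_config"), inherits(miss, "miss_config"),
            reps >= 1)
  analyses <- match.arg(analyses, c("lm", "lmm", "mi", "sweep"),
                        several.ok = TRUE)
  if (any(c("mi", "sweep") %in% analyses) && !("lmm" %in% analyses))
    analyses <- c("lmm", analyses)  # the no-imputation reference is needed
  structure(list(name = name, gen = gen, miss = miss, analyses = analyses,
                 reps = as.integer(reps), M = as.integer(M),
                 S = as.integer(S), lambda = lambda),
            class = "scenario_spec")
}

#' Built-in simulation scenarios
#'
#' Named presets for the package's replication studies, all with n = 130
#' and the default generation parameters of [gen_config()]:
#'
#' * `table1_row1` .. `table1_row5`: complete data, MCAR 20%, MAR (time and
#'   arm), MAR with last-observed-value dependence, and MNAR with
#'   current-value dependence; LM and LMM without imputation, null effect.
#' * `table2_row1` .. `table2_row6`: MCAR 20%/40% and four MAR mechanisms;
#'   MICE-PMM multiple imputation with M = 1 (bias only), null effect.
#' * `k1` .. `k8`: the eight missingness scenarios of the delta-sweep study
#'   (M = 10, S = 8, lambda = 2), null effect.
#' * `k1_power` .. `k8_power`: the same mechanisms with a constant true
#'   policy effect of 1000 steps/day.
#'
#' MAR/MNAR presets carry `alpha_m = NA` plus the target overall missing
#' proportion; the driver calibrates the intercept (the remaining
#' coefficients are `beta_ma = 1`, `beta_mt = 1/12` plus the listed
#' value-scale terms, with mean-centered value covariates).  MCAR presets
#' mask directly with the stated probability.
#'
#' @return Named list of [scenario_spec()]s.
#' @export
scenario_presets <- function() {
  gen0 <- gen_config()
  gen1 <- gen_config(betaA_star = 1000)
  cen <- miss_centers(gen0)
  mar_base <- function(...) {
    miss_config(alpha_m = NA, beta_ma = 1, beta_mt = 1 / 12,
                centers = cen, ...)
  }
  mcar <- function(p) miss_config(mcar_p = p, target_pmiss = p)

  mech <- list(
    none  = miss_config(mcar_p = 0),
    mcar20 = mcar(0.20),
    mcar40 = mcar(0.40),
    mar_t  = mar_base(target_pmiss = 0.21),
    mar_t40 = mar_base(target_pmiss = 0.40),
    mar_l  = mar_base(beta_ml = 0.001, target_pmiss = 0.15),
    mar_la = mar_base(beta_ml = 0.001, beta_mla = 0.001,
                      target_pmiss = 0.15),
    mar_la10 = mar_base(beta_ml = 0.001, beta_mla = 0.001,
                        target_pmiss = 0.10),
    mnar_r = mar_base(beta_m0 = -5e-4, beta_mr = -0.002,
                      target_pmiss = 0.08),
    mnar_y = mar_base(beta_ml = 0.001, beta_mla = 0.001, beta_m0 = -5e-4,
                      beta_my = -0.002, beta_mya = -0.002,
                      target_pmiss = 0.20))

  t1 <- list(mech$none, mech$mcar20, mech$mar_t, mech$mar_la10, mech$mnar_y)
  t2 <- list(mech$mcar20, mech$mcar40, mech$mar_t, mech$mar_t40,
             mech$mar_l, mech$mar_la)
  kk <- list(mech$mcar20, mech$mcar40, mech$mar_t, mech$mar_t40,
             mech$mar_l, mech$mar_la, mech$mnar_r, mech$mnar_y)

  out <- list()
  for (i in seq_along(t1))
    out[[paste0("table1_row", i)]] <-
      scenario_spec(paste0("table1_row", i), gen0, t1[[i]],
                    analyses = c("lm", "lmm"))
  for (i in seq_along(t2))
    out[[paste0("table2_row", i)]] <-
      scenario_spec(paste0("table2_row", i), gen0, t2[[i]],
                    analyses = c("lmm", "mi"), M = 1)
  for (i in seq_along(kk)) {
    out[[paste0("k", i)]] <-
      scenario_spec(paste0("k", i), gen0, kk[[i]],
                    analyses = c("lmm", "sweep"), M = 10)
    out[[paste0("k", i, "_power")]] <-
      scenario_spec(paste0("k", i, "_power"), gen1, kk[[i]],
                    analyses = c("lmm", "sweep"), M = 10)
  }
  out
}

#' Run a replicated simulation study for one scenario
#'
#' Per replication (seeded by an order-independent substream of `seed`):
#' simulate a trial, collapse the run-in, apply the missingness mechanism,
#' run the requested analyses, and record the policy-effect estimate and
#' test decision.  Summaries follow the simulation-table conventions: bias
#' (mean estimate minus the true effect) with twice its standard error,
#' two-sided rejection percentage, percentage of replications whose
#' decision differs from the no-imputation LMM decision, mean missingness
#' proportion, and (for delta sweeps) the rate of a positive-width
#' sensitivity interval of rejection (`psir`) and the mean SIR/SIC
#' half-widths.
#'
#' @param spec a [scenario_spec()].
#' @param reps replication count (defaults to `spec$reps`).
#' @param seed master seed.
#' @param calib_reps simulated trials averaged per calibration evaluation.
#' @return A list of class `replication_result` with `summary` (one row per
#'   analysis and, for sweeps, per delta), the calibrated `alpha_m` (or
#'   `NA`), and `failures` counts per analysis.
#' @export
run_replications <- function(spec, reps = spec$reps, seed = 1L,
                             calib_reps = 50) {
  stopifnot(inherits(spec, "scenario_spec"))
  gen <- spec$gen
  miss <- spec$miss
  gen_null <- gen
  gen_null$betaA_star <- 0

  alpha_cal <- NA_real_
  if (is.null(miss$mcar_p) && is.na(miss$alpha_m)) {
    if (is.null(miss$target_pmiss))
      stop("run_replications: alpha_m is NA but no target_pmiss given")
    if (miss$center_values && is.null(miss$centers))
      miss$centers <- miss_centers(gen_null)
    alpha_cal <- calibrate_intercept(miss, miss$target_pmiss, gen_null,
                                     reps = calib_reps,
                                     seed = substream_seed(seed, 0L))
    miss$alpha_m <- alpha_cal
  }
  no_mask <- !is.null(miss$mcar_p) && miss$mcar_p == 0

  want <- spec$analyses
  grid <- if ("sweep" %in% want) delta_grid(spec$S) else numeric(0)
  icfg <- impute_config(M = spec$M)

  na_rep <- rep(NA_real_, reps)
  rec <- list(
    pmiss = na_rep,
    lm_est = na_rep, lm_dir = na_rep, lm_rej = na_rep,
    lmm_est = na_rep, lmm_dir = na_rep, lmm_rej = na_rep,
    mi_est = na_rep, mi_dir = na_rep, mi_rej = na_rep,
    sweep_est = matrix(NA_real_, reps, length(grid)),
    sweep_dir = matrix(NA_real_, reps, length(grid)),
    sir = na_rep, sic = na_rep)
  fail <- c(lm = 0L, lmm = 0L, mi = 0L, sweep = 0L)
  warm <- NULL

  for (r in seq_len(reps)) {
    sr <- substream_seed(seed, r)
    tab <- collapse_runin(simulate_trial(gen, sr))
    if (!no_mask) tab <- apply_missingness(tab, miss)
    rec$pmiss[r] <- compute_pmiss(tab)

    if ("lm" %in% want) {
      f <- tryCatch(fit_lm(tab), error = function(e) NULL)
      if (is.null(f)) fail["lm"] <- fail["lm"] + 1L else {
        rec$lm_est[r] <- f$contrast$theta_hat
        rec$lm_dir[r] <- f$contrast$onesided_direction
        rec$lm_rej[r] <- f$contrast$reject_two_sided
      }
    }
    flmm <- NULL
    if ("lmm" %in% want) {
      flmm <- tryCatch(fit_lmm(tab, start = warm), error = function(e) NULL)
      if (is.null(flmm) || !flmm$converged) {
        flmm <- NULL
        fail["lmm"] <- fail["lmm"] + 1L
      } else {
        warm <- flmm$par
        con <- policy_contrast(flmm)
        rec$lmm_est[r] <- con$theta_hat
        rec$lmm_dir[r] <- con$onesided_direction
        rec$lmm_rej[r] <- con$reject_two_sided
      }
    }
    if ("sweep" %in% want) {
      sw <- tryCatch(
        run_sensitivity(tab, S = spec$S, lambda = spec$lambda,
                        impute = icfg, seed = substream_seed(sr, 999L),
                        obs_fit = flmm),
        error = function(e) NULL)
      if (is.null(sw)) fail["sweep"] <- fail["sweep"] + 1L else {
        rec$sweep_est[r, ] <- vapply(sw$results, `[[`, 0, "theta_hat")
        rec$sweep_dir[r, ] <- sw$decisions
        rec$sir[r] <- sw$sir_half
        rec$sic[r] <- sw$sic_half
        k0 <- which(sw$grid == 0)
        rec$mi_est[r] <- sw$results[[k0]]$theta_hat
        rec$mi_dir[r] <- sw$results[[k0]]$onesided_direction
        rec$mi_rej[r] <- sw$results[[k0]]$reject_two_sided
      }
    } else if ("mi" %in% want) {
      mi <- tryCatch(
        mi_analyze(tab, icfg, seed = substream_seed(sr, 999L)),
        error = function(e) NULL)
      if (is.null(mi)) fail["mi"] <- fail["mi"] + 1L else {
        rec$mi_est[r] <- mi$theta_hat
        rec$mi_dir[r] <- mi$onesided_direction
        rec$mi_rej[r] <- mi$reject_two_sided
      }
    }
  }

  nfail <- sum(fail)
  if (nfail > 0.01 * reps * length(want))
    stop("run_replications: more than 1% of fits failed (",
         paste(names(fail), fail, collapse = ", "), ")")

  true_eff <- gen$betaA_star
  pmiss_bar <- mean(rec$pmiss, na.rm = TRUE)
  psir <- if ("sweep" %in% want) mean(rec$sir > 0, na.rm = TRUE) else NA
  lsir <- if ("sweep" %in% want) mean(rec$sir, na.rm = TRUE) else NA
  lsic <- if ("sweep" %in% want) mean(rec$sic, na.rm = TRUE) else NA
  n_sw <- sum(!is.na(rec$sic))
  lsir_2se <- if ("sweep" %in% want) 2 * sd(rec$sir, na.rm = TRUE) /
    sqrt(n_sw) else NA
  lsic_2se <- if ("sweep" %in% want) 2 * sd(rec$sic, na.rm = TRUE) /
    sqrt(n_sw) else NA

  row_of <- function(analysis, delta, est, rej, dir) {
    ok <- !is.na(est)
    diffpct <- if (analysis %in% c("mi", "sweep")) {
      both <- ok & !is.na(rec$lmm_rej)
      100 * mean(rej[both] != rec$lmm_rej[both])
    } else NA_real_
    data.frame(scenario = spec$name, analysis = analysis, delta = delta,
               bias = mean(est[ok]) - true_eff,
               bias_2se = 2 * sd(est[ok]) / sqrt(sum(ok)),
               reject_pct = 100 * mean(rej[ok]),
               pct_diff_noimp = diffpct,
               pmiss = pmiss_bar, psir = psir, len_sir = lsir,
               len_sic = lsic, len_sir_2se = lsir_2se,
               len_sic_2se = lsic_2se, reps_used = sum(ok),
               failures = nfail)
  }
  rows <- list()
  if ("lm" %in% want)
    rows <- c(rows, list(row_of("lm", NA, rec$lm_est, rec$lm_rej,
                                rec$lm_dir)))
  if ("lmm" %in% want)
    rows <- c(rows, list(row_of("lmm", NA, rec$lmm_est, rec$lmm_rej,
                                rec$lmm_dir)))
  if ("mi" %in% want && !("sweep" %in% want))
    rows <- c(rows, list(row_of("mi", 0, rec$mi_est, rec$mi_rej,
                                rec$mi_dir)))
  if ("sweep" %in% want)
    for (k in seq_along(grid))
      rows <- c(rows, list(row_of("sweep", grid[k], rec$sweep_est[, k],
                                  abs(rec$sweep_dir[, k]) > 0,
                                  rec$sweep_dir[, k])))
  structure(list(summary = do.call(rbind, rows), alpha_m = alpha_cal,
                 failures = fail, reps = reps, seed = seed),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Replication study (%d reps, seed %d)\n", x$reps, x$seed))
  if (!is.na(x$alpha_m))
    cat(sprintf("  calibrated alpha_m = %.4f\n", x$alpha_m))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write / read a replication summary table
#'
#' Fixed column order `scenario, analysis, delta, bias, bias_2se,
#' reject_pct, pct_diff_noimp, pmiss, psir, len_sir, len_sic, reps_used,
#' failures`; round-trips losslessly through CSV.
#'
#' @param rows summary data frame (possibly `rbind`-ed across scenarios).
#' @param path output file.
#' @return `path`, invisibly (for [write_summary()]); the data frame (for
#'   [read_summary()]).
#' @export
write_summary <- function(rows, path) {
  cols <- c("scenario", "analysis", "delta", "bias", "bias_2se",
            "reject_pct", "pct_diff_noimp", "pmiss", "psir", "len_sir",
            "len_sic", "len_sir_2se", "len_sic_2se", "reps_used",
            "failures")
  if (nrow(rows) > 0) rows <- rows[, cols, drop = FALSE]
  else rows <- rows[, intersect(cols, names(rows)), drop = FALSE]
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
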
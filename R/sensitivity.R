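#' Maximum shift for the SD-sensitivity delta sweep
#'
#' \eqn{\delta_{max} = \lambda \hat\sigma_{res}}, a fixed multiple of the
#' residual SD from the observed-data longitudinal fit.  At the grid edge
#' (\eqn{\delta = \pm 1}) imputed values therefore deviate from the
#' imputation-model prediction by \eqn{\lambda} residual SDs.
#'
#' @param fit a converged `trial_lmm` on the observed data.
#' @param lambda multiplier (default 2).
#' @return `delta_max` in steps/day.
#' @export
compute_delta_max <- function(fit, lambda = 2) {
  stopifnot(inherits(fit, "trial_lmm"))
  if (!fit$converged) stop("compute_delta_max: fit did not converge")
  lambda * fit$sigma_res
}

#' Symmetric delta grid
#'
#' The S+1 sensitivity fractions \eqn{\{-1, -1+2/S, \dots, 0, \dots, 1\}}.
#'
#' @param S even positive integer (grid resolution).
#' @return Numeric vector of length S+1.
#' @export
delta_grid <- function(S) {
  if (S < 2 || S %% 2 != 0) stop("delta_grid: S must be even and >= 2")
  seq(-1, 1, by = 2 / S)
}

#' Shift imputed values by a fraction of delta_max
#'
#' Adds \eqn{\delta \cdot \delta_{max}} to the originally-masked cells of
#' every completed outcome matrix; observed cells are untouched.  By
#' default the shift applies to both arms (the policy contrast still moves
#' when missingness rates differ by arm); `shift_arms = "treated"` shifts
#' only arm-1 participants, the common tipping-point convention.
#'
#' @param completed a `completed_set` from [mice_chain()].
#' @param delta grid fraction in `[-1, 1]`.
#' @param delta_max maximum shift, steps/day.
#' @param shift_arms `"both"` or `"treated"`.
#' @return A `completed_set` with shifted imputations.
#' @export
apply_delta_shift <- function(completed, delta, delta_max,
                              shift_arms = c("both", "treated")) {
  stopifnot(inherits(completed, "completed_set"))
  shift_arms <- match.arg(shift_arms)
  shift <- delta * delta_max
  if (shift == 0) return(completed)
  mk <- completed$mask
  if (shift_arms == "treated") mk <- mk & (completed$arm == 1L)
  completed$imputations <- lapply(completed$imputations, function(Y) {
    Y[mk] <- Y[mk] + shift
    Y
  })
  completed
}

#' Half-width of the sensitivity interval of rejection
#'
#' The SIR is the largest symmetric interval \eqn{[-h, h]} of delta about 0
#' with positive width on which every sensitivity analysis rejects the null
#' in the same (one-sided) direction as the observed-data analysis, which
#' must itself reject.  Half-width 0 when no such interval exists.
#'
#' @param observed_direction observed-data one-sided direction (-1, 0, +1).
#' @param directions per-delta one-sided directions, aligned with `grid`.
#' @param grid the delta grid from [delta_grid()].
#' @return Half-width in grid units (an element of `{0, 2/S, ..., 1}`).
#' @export
sir_half_width <- function(observed_direction, directions, grid) {
  if (observed_direction == 0) return(0)
  hs <- sort(unique(grid[grid > 0]))
  best <- 0
  for (h in hs) {
    if (all(directions[abs(grid) <= h + 1e-12] == observed_direction))
      best <- h
    else break
  }
  best
}

#' Half-width of the sensitivity interval of concordance
#'
#' The SIC is the largest symmetric interval \eqn{[-h, h]} of delta about 0
#' on which every sensitivity analysis reaches the same decision (reject
#' for a positive effect / reject for a negative effect / fail to reject)
#' as the observed-data analysis.  Half-width 0 when no delta beyond 0
#' agrees.
#'
#' @param observed_decision observed-data decision coded -1/0/+1 as above.
#' @param decisions per-delta decisions, aligned with `grid`.
#' @param grid the delta grid from [delta_grid()].
#' @return Half-width in grid units.
#' @export
sic_half_width <- function(observed_decision, decisions, grid) {
  hs <- sort(unique(grid[grid > 0]))
  best <- 0
  for (h in hs) {
    if (all(decisions[abs(grid) <= h + 1e-12] == observed_decision))
      best <- h
    else break
  }
  best
}

#' Delta-based controlled-imputation sensitivity analysis
#'
#' Runs the SD-sensitivity sweep on one dataset: fit the longitudinal model
#' to the observed data, set \eqn{\delta_{max} = \lambda \hat\sigma_{res}},
#' and for every delta on the symmetric S+1 grid obtain a pooled MI policy
#' effect from completed datasets whose imputed cells are shifted by
#' \eqn{\delta \cdot \delta_{max}}.  With `reuse_imputations` (default) the
#' same M completed datasets are shifted for every delta (common random
#' numbers); otherwise imputation is rerun per delta.
#'
#' @param table a collapsed trial table with `observed` flags.
#' @param S even grid resolution (delta increment 2/S).
#' @param lambda delta_max multiplier.
#' @param impute an [impute_config()].
#' @param reuse_imputations share completed datasets across deltas.
#' @param shift_arms see [apply_delta_shift()].
#' @param method passed to [fit_lmm()].
#' @param seed optional integer seed.
#' @param obs_fit optional pre-computed observed-data [fit_lmm()] result
#'   (a replication driver can reuse the fit it already has).
#' @return An object of class `sensitivity_result`: the observed-data
#'   `contrast` and `fit`, `delta_max`, `grid`, per-delta `results`
#'   (`mi_result`s), per-delta `decisions`, and the `sir_half` / `sic_half`
#'   widths.
#' @export
run_sensitivity <- function(table, S = 8, lambda = 2,
                            impute = impute_config(),
                            reuse_imputations = TRUE,
                            shift_arms = c("both", "treated"),
                            method = "REML", seed = NULL, obs_fit = NULL) {
  shift_arms <- match.arg(shift_arms)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(obs_fit)) obs_fit <- fit_lmm(table, method = method)
  obs_con <- policy_contrast(obs_fit)
  dmax <- compute_delta_max(obs_fit, lambda)
  grid <- delta_grid(S)
  wide <- pivot_wide(table)

  if (!any(wide$mask)) {
    res <- rubin_pool(rep(obs_con$theta_hat, impute$M),
                      rep(obs_con$se^2, impute$M))
    results <- rep(list(res), length(grid))
  } else if (dmax == 0 && reuse_imputations) {
    ## lambda = 0: every delta analyzes the same completed data
    cs0 <- mice_chain(wide, impute, seed = seed)
    results <- rep(list(pool_completed(cs0, method = method)), length(grid))
  } else {
    cs0 <- if (reuse_imputations) mice_chain(wide, impute, seed = seed)
           else NULL
    results <- vector("list", length(grid))
    ## process delta = 0 first with the same cold-start protocol as
    ## mi_analyze (so the delta = 0 column matches it exactly), then move
    ## outward, warm-starting each delta from its processed neighbour
    ord <- order(abs(grid), grid)
    warm0 <- warm_pos <- warm_neg <- NULL
    for (k in ord) {
      d <- grid[k]
      cs <- if (reuse_imputations) cs0
            else mice_chain(wide, impute, seed = substream_seed(seed, k))
      cs <- apply_delta_shift(cs, d, dmax, shift_arms = shift_arms)
      st <- if (d == 0) NULL
            else if (d > 0) (if (is.null(warm_pos)) warm0 else warm_pos)
            else (if (is.null(warm_neg)) warm0 else warm_neg)
      results[[k]] <- pool_completed(cs, method = method, start = st)
      lp <- attr(results[[k]], "last_par")
      if (d == 0) warm0 <- lp
      else if (d > 0) warm_pos <- lp
      else warm_neg <- lp
    }
  }
  names(results) <- paste0("delta=", format(grid))
  decisions <- vapply(results, function(r) r$onesided_direction, numeric(1))
  out <- list(observed = obs_con, fit = obs_fit, delta_max = dmax,
              lambda = lambda, S = S, grid = grid, results = results,
              decisions = decisions,
              sir_half = sir_half_width(obs_con$onesided_direction,
                                        decisions, grid),
              sic_half = sic_half_width(obs_con$onesided_direction,
                                        decisions, grid))
  class(out) <- "sensitivity_result"
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Delta-based sensitivity sweep (S=%d, lambda=%g, delta_max=%.1f)\n",
    x$S, x$lambda, x$delta_max))
  cat("observed data: ")
  print(x$observed)
  tab <- data.frame(delta = x$grid,
                    theta_hat = vapply(x$results, `[[`, 0, "theta_hat"),
                    se = vapply(x$results, `[[`, 0, "se"),
                    decision = x$decisions)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("SIR half-width %.3g, SIC half-width %.3g\n",
              x$sir_half, x$sic_half))
  invisible(x)
}

#' Plot a sensitivity sweep
#'
#' Pooled policy effect with 95% intervals against delta; the dashed line
#' marks no effect, the dotted line the observed-data estimate.
#'
#' @param x a `sensitivity_result`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sensitivity_result <- function(x, ...) {
  est <- vapply(x$results, `[[`, 0, "theta_hat")
  se <- vapply(x$results, `[[`, 0, "se")
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  graphics::plot(x$grid, est, type = "b", pch = 19,
                 ylim = range(lo, hi, 0),
                 xlab = expression(delta),
                 ylab = "policy effect (steps/day)", ...)
  graphics::arrows(x$grid, lo, x$grid, hi, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = 0, lty = 2)
  graphics::abline(h = x$observed$theta_hat, lty = 3, col = "grey40")
  invisible(x)
}

#' Per-delta summary of a sensitivity sweep
#'
#' @param x a `sensitivity_result`.
#' @param ... unused.
#' @return Data frame with one row per delta
#'   (`delta,theta_hat,total_var,z,decision`) plus attributes `sir_half`
#'   and `sic_half`.
#' @export
as.data.frame.sensitivity_result <- function(x, ...) {
  out <- data.frame(delta = x$grid,
                    theta_hat = vapply(x$results, `[[`, 0, "theta_hat"),
                    total_var = vapply(x$results, `[[`, 0, "T"),
                    z = vapply(x$results, `[[`, 0, "z"),
                    decision = x$decisions)
  attr(out, "sir_half") <- x$sir_half
  attr(out, "sic_half") <- x$sic_half
  out
}
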
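#' Reshape a collapsed trial table to participant-by-week form
#'
#' @param table a collapsed trial table (weeks 0-24 for every pid).
#' @return An object of class `trial_wide`: `pid`, `age` (baseline), `arm`,
#'   outcome matrix `Y` (columns `w0`-`w24`, `NA` where masked), logical
#'   `mask` of originally missing cells, and `Y_full` retaining the masked
#'   values for simulation oracles.
#' @export
pivot_wide <- function(table) {
  tab <- table[table$week >= 0L, , drop = FALSE]
  if (anyDuplicated(paste(tab$pid, tab$week)))
    stop("pivot_wide: duplicate (pid, week) rows")
  pids <- sort(unique(tab$pid))
  n <- length(pids)
  i <- match(tab$pid, pids)
  j <- tab$week + 1L
  Yf <- matrix(NA_real_, n, 25, dimnames = list(NULL, paste0("w", 0:24)))
  Yf[cbind(i, j)] <- tab$y
  if (anyNA(Yf)) stop("pivot_wide: weeks 0-24 required for every pid")
  mask <- matrix(FALSE, n, 25, dimnames = dimnames(Yf))
  mask[cbind(i, j)] <- tab$observed == 0L
  Y <- Yf
  Y[mask] <- NA_real_
  b <- tab[tab$week == 0L, , drop = FALSE]
  bi <- match(pids, b$pid)
  structure(list(pid = pids, age = b$age[bi], arm = b$arm[bi],
                 Y = Y, mask = mask, Y_full = Yf),
            class = "trial_wide")
}

#' Long trial table from a wide outcome matrix
#'
#' Inverse of [pivot_wide()]; used to hand completed (imputed) data back to
#' the analysis models.  Ages advance weekly from the baseline age.
#'
#' @param wide a `trial_wide` (supplies pid, age, arm and, by default, mask).
#' @param Y outcome matrix to use (default the wide table's own).
#' @param observed optional logical/0-1 matrix; default marks the wide
#'   table's masked cells, pass `TRUE` for completed data.
#' @return A collapsed long trial table.
#' @export
pivot_long <- function(wide, Y = wide$Y_full, observed = !wide$mask) {
  n <- length(wide$pid)
  if (isTRUE(observed)) observed <- matrix(TRUE, n, 25)
  weeks <- 0:24
  data.frame(pid = rep(wide$pid, each = 25),
             week = rep(weeks, n),
             age = rep(wide$age, each = 25) + rep(weeks, n) / 52,
             arm = rep(wide$arm, each = 25),
             y = as.vector(t(Y)),
             observed = as.integer(as.vector(t(observed))))
}

#' Predictive-mean-matching imputation for one variable
#'
#' Type-1 matching: the regression of the target on the predictors is fit by
#' least squares on the observed rows; coefficients for the *target* rows
#' are drawn from their large-sample Gaussian approximation (with the
#' residual variance drawn from its scaled chi-square), while donor
#' predictions use the fitted coefficients.  Each missing row receives the
#' actual observed value of a donor drawn uniformly from the `donors`
#' observed rows with closest predictions.
#'
#' @param y_obs observed target values.
#' @param X_obs predictor matrix for the observed rows (include an
#'   intercept column).
#' @param X_mis predictor matrix for the rows to impute.
#' @param donors donor-pool size.
#' @return Imputed values (one per row of `X_mis`), each an element of
#'   `y_obs`.
#' @export
pmm_impute <- function(y_obs, X_obs, X_mis, donors = 5) {
  n <- length(y_obs)
  if (n == 0) stop("pmm_impute: no observed rows for the target")
  fast <- pmm_match_cpp(y_obs, X_obs, X_mis, as.integer(donors))
  if (length(fast)) return(as.numeric(fast))
  ## (near-)singular normal equations: pivoted-QR fallback dropping
  ## aliased columns
  qrx <- qr(X_obs)
  if (qrx$rank < ncol(X_obs)) {   # drop aliased columns, keep pivot order
    keep <- qrx$pivot[seq_len(qrx$rank)]
    X_obs <- X_obs[, keep, drop = FALSE]
    X_mis <- X_mis[, keep, drop = FALSE]
    qrx <- qr(X_obs)
  }
  r <- qrx$rank
  beta <- qr.coef(qrx, y_obs)
  res <- y_obs - as.numeric(X_obs %*% beta)
  df <- max(n - r, 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  piv <- qrx$pivot
  bstar <- beta
  bstar[piv] <- beta[piv] +
    sqrt(sigma2_star) * backsolve(qr.R(qrx), rnorm(r))
  yhat_obs <- as.numeric(X_obs %*% beta)
  yhat_mis <- as.numeric(X_mis %*% bstar)
  k <- min(donors, n)
  idx <- vapply(yhat_mis, function(pm) {
    cand <- order(abs(yhat_obs - pm))[seq_len(k)]
    cand[sample.int(k, 1)]
  }, integer(1))
  y_obs[idx]
}

#' Multiple imputation configuration
#'
#' @param M number of imputations (>= 1).
#' @param donors PMM donor-pool size.
#' @param iterations chained-equation sweeps over the incomplete weeks.
#' @param include_arm add the randomized arm to every predictor set (off by
#'   default: the imputation predictor set is baseline age, the baseline
#'   outcome, the last outcome observed before the target week, and the
#'   other weekly outcomes).
#' @return An object of class `impute_config`.
#' @export
impute_config <- function(M = 10, donors = 5, iterations = 5,
                          include_arm = FALSE) {
  if (M < 1 || donors < 1 || iterations < 1)
    stop("impute_config: M, donors, iterations must all be >= 1")
  structure(list(M = as.integer(M), donors = as.integer(donors),
                 iterations = as.integer(iterations),
                 include_arm = isTRUE(include_arm)),
            class = "impute_config")
}

## last outcome observed (per the ORIGINAL mask) strictly before each
## post-baseline week; the never-masked baseline backstops week 1
last_observed_matrix <- function(wide) {
  n <- nrow(wide$Y)
  LO <- matrix(NA_real_, n, 24, dimnames = list(NULL, paste0("w", 1:24)))
  last <- wide$Y[, "w0"]
  for (t in 1:24) {
    LO[, t] <- last
    o <- !wide$mask[, t + 1]
    last[o] <- wide$Y[o, t + 1]
  }
  LO
}

#' Chained-equation imputation with predictive mean matching
#'
#' Produces `M` completed copies of the outcome matrix.  Masked cells are
#' initialized by resampling each column's observed values, then the
#' incomplete weeks are swept in increasing order `iterations` times, each
#' imputed by [pmm_impute()] with predictors: baseline age, baseline
#' outcome, the last outcome observed (per the original mask) before the
#' target week, all other post-baseline weeks at their current working
#' values, and optionally the arm.  If a target's observed rows cannot
#' support the full predictor set, the other-week predictors farthest in
#' time from the target are dropped first.
#'
#' @param wide a `trial_wide` from [pivot_wide()].
#' @param config an [impute_config()].
#' @param seed optional integer seed (independent substream per
#'   imputation).
#' @return An object of class `completed_set`: list `imputations` of `M`
#'   completed outcome matrices plus the original `mask`, `pid`, `age`,
#'   `arm`.
#' @export
mice_chain <- function(wide, config = impute_config(), seed = NULL) {
  stopifnot(inherits(wide, "trial_wide"), inherits(config, "impute_config"))
  if (anyNA(wide$Y[, "w0"]) || anyNA(wide$age) || anyNA(wide$arm))
    stop("mice_chain: baseline outcome, age and arm must be complete")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  n <- nrow(wide$Y)
  LO <- last_observed_matrix(wide)
  incomplete <- which(colSums(wide$mask[, -1, drop = FALSE]) > 0)  # weeks

  ## predictor scaffolding per target week is loop-invariant: the base
  ## columns (intercept, age, baseline, last-observed, optional arm), the
  ## time-ordered other-week predictors after pruning, and the row split
  info <- lapply(incomplete, function(t) {
    mk <- wide$mask[, t + 1]
    base_p <- cbind(1, age = wide$age, y0 = wide$Y[, "w0"],
                    ylast = LO[, t])
    if (config$include_arm) base_p <- cbind(base_p, arm = wide$arm)
    others <- setdiff(1:24, t)
    others <- others[order(abs(others - t))]
    max_other <- max(0, sum(!mk) - config$donors - ncol(base_p))
    others <- others[seq_len(min(length(others), max_other))]
    list(t = t, mk = mk, base_p = base_p, ocol = others + 1,
         y_obs = wide$Y[!mk, t + 1])
  })

  imputations <- vector("list", config$M)
  for (m in seq_len(config$M)) {
    set.seed(substream_seed(seed, m))
    Ym <- wide$Y
    for (f in info)
      Ym[f$mk, f$t + 1] <- sample(f$y_obs, sum(f$mk), replace = TRUE)
    for (it in seq_len(config$iterations)) {
      for (f in info) {
        P <- cbind(f$base_p, Ym[, f$ocol, drop = FALSE])
        Ym[f$mk, f$t + 1] <- pmm_impute(f$y_obs,
                                        P[!f$mk, , drop = FALSE],
                                        P[f$mk, , drop = FALSE],
                                        donors = config$donors)
      }
    }
    imputations[[m]] <- Ym
  }
  structure(list(imputations = imputations, mask = wide$mask,
                 pid = wide$pid, age = wide$age, arm = wide$arm),
            class = "completed_set")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is \eqn{T = \bar W + (1 + 1/M) B} with \eqn{\bar W} the
#' mean within-imputation variance and \eqn{B} the between-imputation
#' sample variance (0 when M = 1).  The Wald decisions use \eqn{\sqrt T}.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation (within) variances, same length.
#' @return An object of class `mi_result`: `theta_hat`, `W`, `B`, `T`,
#'   `se`, `z`, `reject_two_sided`, `onesided_direction`, `M`,
#'   `estimates`.
#' @export
rubin_pool <- function(estimates, variances) {
  M <- length(estimates)
  if (M == 0 || length(variances) != M)
    stop("rubin_pool: need equal-length, non-empty inputs")
  theta <- mean(estimates)
  W <- mean(variances)
  B <- if (M > 1) var(estimates) else 0
  Tt <- W + (1 + 1 / M) * B
  con <- make_contrast(theta, sqrt(Tt))
  structure(list(theta_hat = theta, W = W, B = B, T = Tt,
                 se = con$se, z = con$z,
                 reject_two_sided = con$reject_two_sided,
                 onesided_direction = con$onesided_direction,
                 M = M, estimates = estimates),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf(
    "MI pooled policy effect (M=%d): %.1f (se %.1f, W %.1f, B %.1f), %s\n",
    x$M, x$theta_hat, x$se, x$W, x$B,
    if (x$reject_two_sided) sprintf("reject (direction %+d)",
                                    x$onesided_direction)
    else "no rejection"))
  invisible(x)
}

#' Multiple imputation analysis of the policy effect
#'
#' The general MI pipeline: impute by [mice_chain()], fit the longitudinal
#' model ([fit_lmm()]) and its policy contrast on each completed dataset,
#' and pool by [rubin_pool()].  With no missing cells the result reduces to
#' the observed-data contrast (B = 0) for any M.
#'
#' @param table a collapsed trial table with `observed` flags.
#' @param config an [impute_config()].
#' @param method passed to [fit_lmm()].
#' @param seed optional integer seed.
#' @return An `mi_result`.
#' @export
mi_analyze <- function(table, config = impute_config(), method = "REML",
                       seed = NULL) {
  wide <- pivot_wide(table)
  if (!any(wide$mask)) {
    con <- policy_contrast(fit_lmm(table, method = method))
    return(rubin_pool(rep(con$theta_hat, config$M),
                      rep(con$se^2, config$M)))
  }
  cs <- mice_chain(wide, config, seed = seed)
  pool_completed(cs, method = method)
}

#' Export a completed set as CSV files
#'
#' Writes one `imputation_<m>.csv` per completed dataset (columns
#' `pid,age,arm,y0,...,y24`) plus `mask.csv` listing the originally
#' missing `(pid, week)` cells.
#'
#' @param cs a `completed_set` from [mice_chain()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_completed_set <- function(cs, dir) {
  stopifnot(inherits(cs, "completed_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_along(cs$imputations)) {
    df <- data.frame(pid = cs$pid, age = cs$age, arm = cs$arm,
                     cs$imputations[[m]])
    names(df) <- c("pid", "age", "arm", paste0("y", 0:24))
    write.csv(df, file.path(dir, sprintf("imputation_%d.csv", m)),
              row.names = FALSE)
  }
  idx <- which(cs$mask, arr.ind = TRUE)
  write.csv(data.frame(pid = cs$pid[idx[, 1]], week = idx[, 2] - 1L),
            file.path(dir, "mask.csv"), row.names = FALSE)
  invisible(dir)
}

## fit the LMM policy contrast on each completed table and pool;
## warm-starts each fit from the previous imputation's variance parameters
## (optionally seeded by `start`); the final parameters are kept in the
## "last_par" attribute so a delta sweep can chain warm starts
pool_completed <- function(cs, method = "REML", start = NULL) {
  M <- length(cs$imputations)
  est <- numeric(M)
  v <- numeric(M)
  if (length(unique(cs$arm)) < 2 || min(table(cs$arm)) < 2)
    stop("pool_completed: need at least 2 participants per arm")
  ## completed data share one fully-observed week pattern: prepare the
  ## fitting structures once and swap in each imputation's outcomes
  n <- length(cs$pid)
  weeks <- as.numeric(0:24)
  prep <- list(pat_weeks = list(weeks),
               pat_G = list(lmm_base_design(weeks)),
               pid_pat = rep(0L, n), pid_y = NULL,
               pid_d = t(vapply(seq_len(n), function(i)
                 lmm_d_vector(cs$age[i], cs$arm[i]), numeric(30))),
               pids = cs$pid, age0 = cs$age, arm = cs$arm,
               w_arm1 = 1:24, N = 25L * n)
  warm <- start
  for (m in seq_len(M)) {
    Y <- cs$imputations[[m]]
    prep$pid_y <- lapply(seq_len(n), function(i) Y[i, ])
    fit <- lmm_fit_core(prep, method = method, start = warm)
    warm <- fit$par
    con <- policy_contrast(fit)
    est[m] <- con$theta_hat
    v[m] <- con$se^2
  }
  out <- rubin_pool(est, v)
  attr(out, "last_par") <- warm
  out
}
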
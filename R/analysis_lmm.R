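## Fixed-effect design for the longitudinal analysis model.  The base design
## G depends only on the observed weeks; the participant-specific design is
## X_i = G %*% diag(d_i) with d_i carrying baseline age (first column) and
## arm (the 24 treatment-week columns).  Time polynomial columns are scaled
## by 24^-k internally for conditioning; estimates are reported on the raw
## scale.

lmm_coef_names <- c("age", "runin", "post", "t", "t2", "t3",
                    paste0("arm_w", 1:24))

lmm_col_scale <- c(1, 1, 1, 1 / 24, 1 / 24^2, 1 / 24^3, rep(1, 24))

lmm_base_design <- function(weeks, scaled = TRUE) {
  ts <- if (scaled) weeks / 24 else weeks
  G <- cbind(1, as.numeric(weeks == 0), as.numeric(weeks > 0),
             ts, ts^2, ts^3,
             outer(weeks, 1:24, function(w, k) as.numeric(w == k)))
  colnames(G) <- lmm_coef_names
  G
}

lmm_d_vector <- function(age0, arm) c(age0, rep(1, 5), rep(arm, 24))

## Split a collapsed trial table into the per-pattern/per-pid pieces the
## compiled likelihood consumes.
lmm_prepare <- function(table) {
  obs <- table[table$observed == 1L & table$week >= 0L, , drop = FALSE]
  obs <- obs[order(obs$pid, obs$week), , drop = FALSE]
  pids <- unique(obs$pid)
  sp_w <- split(obs$week, obs$pid)[as.character(pids)]
  sp_y <- split(obs$y, obs$pid)[as.character(pids)]
  base <- table[table$week == 0L, , drop = FALSE]
  bidx <- match(pids, base$pid)
  age0 <- base$age[bidx]
  arm <- base$arm[bidx]

  keys <- vapply(sp_w, paste, character(1), collapse = ",")
  ukeys <- unique(keys)
  pat_weeks <- lapply(sp_w[match(ukeys, keys)], as.numeric)
  pat_G <- lapply(pat_weeks, lmm_base_design)
  pid_pat <- match(keys, ukeys) - 1L
  w_arm1 <- sort(unique(obs$week[obs$arm == 1L & obs$week >= 1L]))

  pid_d <- t(vapply(seq_along(pids), function(i)
    lmm_d_vector(age0[i], arm[i]), numeric(30)))
  list(pat_weeks = pat_weeks, pat_G = pat_G, pid_pat = pid_pat,
       pid_y = sp_y, pid_d = pid_d, pids = pids, age0 = age0, arm = arm,
       w_arm1 = w_arm1, N = nrow(obs))
}

lmm_detail_at <- function(prep, tau0, tau1, rho, reml) {
  lmm_detail_cpp(tau0, tau1, rho, prep$pat_weeks, prep$pat_G, prep$pid_pat,
                 prep$pid_y, prep$pid_d, reml)
}

## crude moment start: residual lag-1 correlation and between-participant
## spread of mean residuals from a near-OLS fit
lmm_mom_start <- function(prep, reml) {
  det0 <- lmm_detail_at(prep, 1e-3, 1e-4, 0, reml)
  beta <- det0$beta
  sigma <- sqrt(det0$sigma2)
  num <- 0; den1 <- 0; den2 <- 0; means <- numeric(length(prep$pid_y))
  for (i in seq_along(prep$pid_y)) {
    q <- prep$pid_pat[i] + 1L
    r <- prep$pid_y[[i]] -
      as.numeric(prep$pat_G[[q]] %*% (prep$pid_d[i, ] * beta))
    w <- prep$pat_weeks[[q]]
    adj <- which(diff(w) == 1)
    if (length(adj)) {
      num <- num + sum(r[adj] * r[adj + 1])
      den1 <- den1 + sum(r[adj]^2)
      den2 <- den2 + sum(r[adj + 1]^2)
    }
    means[i] <- mean(r)
  }
  rho <- if (den1 > 0 && den2 > 0) num / sqrt(den1 * den2) else 0
  rho <- min(max(rho, -0.95), 0.995)
  tau0 <- min(max(sd(means) / sigma, 0.005), 2)
  c(log(tau0), log(max(tau0 / 5, 1e-3)), atanh(rho))
}

#' Fit the longitudinal mixed model for the treatment policy effect
#'
#' Fits, by maximum likelihood or REML, the linear mixed model
#' \deqn{Y_{it} = \beta_{age} AGE_i + \beta_0 I(t=0) + \beta_1 I(t>0) +
#'   \beta_t t + \beta_{t2} t^2 + \beta_{t3} t^3 + \beta_{A,t} A_i I(t>0) +
#'   b_i + b_{1i} t + \epsilon_{it}}
#' over the observed outcomes at weeks 0-24, with one treatment coefficient
#' per post-baseline week (no assumption about the effect's time course),
#' independent Gaussian random intercept and slope, and AR(1) residual
#' correlation \eqn{\rho^{|t_1 - t_2|}} across observed weeks (missing
#' visits are marginalized, i.e. the lag is the integer week difference).
#'
#' The fixed effects and residual scale are profiled out; the optimizer
#' works on \eqn{(\log \tau_0, \log \tau_1, \mathrm{atanh}\, \rho)} where
#' \eqn{\tau_k = \sigma_{bk} / \sigma_{res}}, with a moment-based and an
#' iid start (Nelder-Mead, relative tolerance `reltol`).
#'
#' @param table a collapsed trial table (weeks 0-24) with `observed` flags.
#' @param method `"REML"` (default) or `"ML"`.
#' @param start optional transformed-parameter start vector (length 3), e.g.
#'   a previous fit's `$par` for warm starts in replication loops.
#' @param vc_fixed optional named vector `c(tau0=, tau1=, rho=)` fixing the
#'   variance parameters (no optimization); `tau0 = tau1 = rho = 0` gives
#'   generalized least squares with iid errors, i.e. OLS.
#' @param reltol relative convergence tolerance on the objective.
#' @param maxit maximum Nelder-Mead iterations.
#' @return An object of class `trial_lmm` with components `coefficients`
#'   (30 fixed effects), `vcov`, `sigma_res`, `sigma_b0`, `sigma_b1`, `rho`,
#'   `logLik`, `converged`, `par` (transformed optimum), `N`, `method`.
#' @export
fit_lmm <- function(table, method = c("REML", "ML"), start = NULL,
                    vc_fixed = NULL, reltol = 1e-8, maxit = 400) {
  method <- match.arg(method)
  prep <- lmm_prepare(table)
  if (length(unique(prep$arm)) < 2 || min(table(prep$arm)) < 2)
    stop("fit_lmm: need at least 2 participants per arm")
  ## estimability of the week-specific treatment columns: every
  ## post-baseline week needs at least one observed treated outcome
  if (!all(1:24 %in% prep$w_arm1))
    stop("fit_lmm: no observed treated outcome at week(s) ",
         paste(setdiff(1:24, prep$w_arm1), collapse = ","))
  lmm_fit_core(prep, method, start, vc_fixed, reltol, maxit)
}

## fit given prepared data; replication/imputation loops reuse a prepared
## structure across outcome vectors
lmm_fit_core <- function(prep, method = "REML", start = NULL,
                         vc_fixed = NULL, reltol = 1e-8, maxit = 400) {
  reml <- method == "REML"
  if (!is.null(vc_fixed)) {
    tau0 <- vc_fixed[["tau0"]]; tau1 <- vc_fixed[["tau1"]]
    rho <- vc_fixed[["rho"]]
    if (abs(rho) >= 1) stop("fit_lmm: |rho| must be < 1")
    det <- lmm_detail_at(prep, tau0, tau1, rho, reml)
    if (!is.finite(det$neg2ll) || det$neg2ll >= 1e9)
      stop("fit_lmm: likelihood not defined at fixed variance parameters")
    par <- c(log(max(tau0, 1e-12)), log(max(tau1, 1e-12)), atanh(rho))
    conv <- TRUE
    evals <- 0L
  } else {
    warm <- !is.null(start)
    starts <- if (warm) list(start)
              else list(lmm_mom_start(prep, reml),
                        c(log(0.05), log(0.01), 0))
    step <- if (warm) 0.04 else 0.1   # smaller simplex near a warm start
    best <- NULL
    for (s in starts) {
      opt <- lmm_optim_cpp(s, prep$pat_weeks, prep$pat_G, prep$pid_pat,
                           prep$pid_y, prep$pid_d, reml, reltol, maxit,
                           step)
      if (is.null(best) || opt$neg2ll < best$neg2ll) best <- opt
    }
    par <- as.numeric(best$par)
    tau0 <- exp(par[1]); tau1 <- exp(par[2]); rho <- tanh(par[3])
    conv <- is.finite(best$neg2ll) && best$neg2ll < 1e9
    evals <- best$evals
    det <- best
  }

  s <- lmm_col_scale
  beta <- as.numeric(det$beta) * s
  names(beta) <- lmm_coef_names
  Ainv <- tryCatch(solve(det$XtWiX), error = function(e) NULL)
  if (is.null(Ainv)) stop("fit_lmm: singular fixed-effect information")
  vc <- det$sigma2 * (Ainv * tcrossprod(s))
  dimnames(vc) <- list(lmm_coef_names, lmm_coef_names)
  sigma_res <- sqrt(det$sigma2)

  out <- list(coefficients = beta, vcov = vc,
              sigma_res = sigma_res, sigma_b0 = tau0 * sigma_res,
              sigma_b1 = tau1 * sigma_res, rho = rho,
              logLik = -det$neg2ll / 2, converged = conv, par = par,
              N = det$N, n_pid = length(prep$pids), method = method,
              evals = evals)
  class(out) <- "trial_lmm"
  out
}

#' Marginal covariance of the longitudinal analysis model
#'
#' \eqn{V = \sigma_{b0}^2 11' + \sigma_{b1}^2 t t' +
#'   \sigma_{res}^2 \rho^{|t_j - t_k|}} over the given weeks.
#'
#' @param weeks sorted integer weeks.
#' @param sigma_b0,sigma_b1 random intercept/slope SDs.
#' @param sigma_res residual SD.
#' @param rho AR(1) parameter, |rho| < 1.
#' @return A symmetric positive semi-definite matrix.
#' @export
lmm_marginal_covariance <- function(weeks, sigma_b0, sigma_b1, sigma_res,
                                    rho) {
  if (abs(rho) >= 1) stop("lmm_marginal_covariance: |rho| must be < 1")
  lag <- abs(outer(weeks, weeks, "-"))
  sigma_b0^2 + sigma_b1^2 * outer(weeks, weeks) + sigma_res^2 * rho^lag
}

#' Observed-data log-likelihood of the longitudinal model
#'
#' Sum over participants of the multivariate-normal log-density of the
#' observed outcomes, with mean from the fixed effects and covariance from
#' [lmm_marginal_covariance()] restricted to the observed weeks.
#'
#' @param params list with `beta` (named length-30 coefficient vector on the
#'   raw scale, see [fit_lmm()]), `sigma_b0`, `sigma_b1`, `sigma_res`,
#'   `rho`.
#' @param table a collapsed trial table with `observed` flags.
#' @return Log-likelihood (scalar).
#' @export
lmm_loglik <- function(params, table) {
  prep <- lmm_prepare(table)
  beta <- params$beta[lmm_coef_names]
  ll <- 0
  for (i in seq_along(prep$pid_y)) {
    q <- prep$pid_pat[i] + 1L
    w <- prep$pat_weeks[[q]]
    X <- lmm_base_design(w, scaled = FALSE) *
      rep(prep$pid_d[i, ], each = length(w))
    mu <- as.numeric(X %*% beta)
    V <- lmm_marginal_covariance(w, params$sigma_b0, params$sigma_b1,
                                 params$sigma_res, params$rho)
    L <- tryCatch(chol(V), error = function(e)
      stop("lmm_loglik: covariance not positive definite"))
    z <- backsolve(L, prep$pid_y[[i]] - mu, transpose = TRUE)
    ll <- ll - 0.5 * (length(w) * log(2 * pi) + 2 * sum(log(diag(L))) +
                        sum(z^2))
  }
  ll
}

#' Treatment policy contrast from a fitted longitudinal model
#'
#' The policy effect is the average of the week 21-24 treatment
#' coefficients, \eqn{\hat\theta_A = (\hat\beta_{A,21} + \hat\beta_{A,22} +
#' \hat\beta_{A,23} + \hat\beta_{A,24})/4}, with variance \eqn{c' \Sigma c}
#' for the 1/4-weight contrast vector.
#'
#' @param fit a `trial_lmm` from [fit_lmm()].
#' @return A `policy_contrast`: `theta_hat`, `se`, `z`, `reject_two_sided`,
#'   `onesided_direction`.
#' @export
policy_contrast <- function(fit) {
  stopifnot(inherits(fit, "trial_lmm"))
  if (!fit$converged) stop("policy_contrast: fit did not converge")
  wn <- paste0("arm_w", 21:24)
  if (!all(wn %in% names(fit$coefficients)))
    stop("policy_contrast: treatment-week coefficients missing")
  cw <- setNames(numeric(length(fit$coefficients)),
                 names(fit$coefficients))
  cw[wn] <- 1 / 4
  est <- sum(cw * fit$coefficients)
  v <- as.numeric(cw %*% fit$vcov %*% cw)
  make_contrast(est, sqrt(max(v, 0)))
}

#' @export
print.trial_lmm <- function(x, ...) {
  cat(sprintf(
    "Longitudinal mixed model (%s): %d obs, %d participants\n",
    x$method, x$N, x$n_pid))
  cat(sprintf(
    "  sigma_b0 %.2f  sigma_b1 %.3f  sigma_res %.1f  rho %.4f  logLik %.1f\n",
    x$sigma_b0, x$sigma_b1, x$sigma_res, x$rho, x$logLik))
  print(policy_contrast(x))
  invisible(x)
}

#' @export
coef.trial_lmm <- function(object, ...) object$coefficients

#' @export
vcov.trial_lmm <- function(object, ...) object$vcov

#' @export
logLik.trial_lmm <- function(object, ...) {
  structure(object$logLik, df = 34, class = "logLik")
}

#' @export
summary.trial_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(estimate = object$coefficients, se = se,
               z = object$coefficients / se)
  list(coefficients = tab, sigma_res = object$sigma_res,
       sigma_b0 = object$sigma_b0, sigma_b1 = object$sigma_b1,
       rho = object$rho, logLik = object$logLik,
       contrast = policy_contrast(object))
}
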
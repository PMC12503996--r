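#' Wald test of a scalar estimate
#'
#' Two-sided rejection at the 5% level uses the asymptotic criterion
#' |estimate/se| > 1.96; the signed one-sided direction (+1/-1 when
#' rejecting, 0 otherwise) is also reported, since the sensitivity-interval
#' metrics require the one-sided tests to agree.
#'
#' @param estimate point estimate.
#' @param se standard error (> 0).
#' @param level two-sided significance level.
#' @return List with `z`, `reject_two_sided`, `onesided_direction`.
#' @export
wald_test <- function(estimate, se, level = 0.05) {
  if (!is.finite(se) || se <= 0) stop("wald_test: se must be positive")
  crit <- if (identical(level, 0.05)) 1.96 else qnorm(1 - level / 2)
  z <- estimate / se
  rej <- abs(z) > crit
  list(z = z, reject_two_sided = rej,
       onesided_direction = if (rej) sign(estimate) else 0)
}

## contrast container shared by LM, LMM and MI results
make_contrast <- function(theta_hat, se) {
  if (is.finite(se) && se > 0) {
    wt <- wald_test(theta_hat, se)
    out <- list(theta_hat = theta_hat, se = se, z = wt$z,
                reject_two_sided = wt$reject_two_sided,
                onesided_direction = wt$onesided_direction,
                degenerate = FALSE)
  } else {
    out <- list(theta_hat = theta_hat, se = se, z = NA_real_,
                reject_two_sided = FALSE, onesided_direction = 0,
                degenerate = TRUE)
  }
  class(out) <- "policy_contrast"
  out
}

#' @export
print.policy_contrast <- function(x, ...) {
  cat(sprintf("policy effect: %.1f steps/day (se %.1f, z %.2f), %s\n",
              x$theta_hat, x$se, x$z,
              if (x$reject_two_sided) sprintf("reject (direction %+d)",
                                              x$onesided_direction)
              else "no rejection"))
  invisible(x)
}

#' Cross-sectional linear model of the trial's primary outcome
#'
#' Fits, by ordinary least squares, the model
#' \deqn{Y_i = \alpha + \beta_{age} AGE_i + \beta_r Y_{i0} + \beta_A A_i +
#'   \epsilon_i,}
#' where \eqn{Y_i} is the per-participant mean of the observed outcomes over
#' weeks 21-24 (a participant is dropped only when all four are missing),
#' \eqn{Y_{i0}} is the baseline (run-in) value and \eqn{AGE_i} the baseline
#' age.  The treatment policy effect is the arm coefficient.  This
#' complete-case analysis is unbiased under MCAR (given the baseline
#' covariates) but not in general under MAR.
#'
#' @param table a collapsed trial table (weeks 0-24) with `observed` flags.
#' @return An object of class `trial_lm`: coefficients, their covariance,
#'   residual SD, `n_used`, and the policy `contrast`.
#' @export
fit_lm <- function(table) {
  sub <- table[table$week %in% 21:24 & table$observed == 1L, , drop = FALSE]
  if (nrow(sub) == 0) stop("fit_lm: no observed outcomes in weeks 21-24")
  resp <- tapply(sub$y, sub$pid, mean)
  base <- table[table$week == 0L, , drop = FALSE]
  idx <- match(as.numeric(names(resp)), base$pid)
  X <- cbind("(Intercept)" = 1, age = base$age[idx], y0 = base$y[idx],
             arm = base$arm[idx])
  n <- length(resp)
  if (n < 4) stop("fit_lm: fewer than 4 usable participants")
  fit <- lm.fit(X, as.numeric(resp))
  if (fit$rank < 4) stop("fit_lm: collinear design")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - 4)
  piv <- fit$qr$pivot
  XtXi <- matrix(NA_real_, 4, 4, dimnames = list(colnames(X), colnames(X)))
  XtXi[piv, piv] <- chol2inv(qr.R(fit$qr))
  vc <- sigma2 * XtXi
  est <- fit$coefficients
  out <- list(coefficients = est, vcov = vc, sigma = sqrt(sigma2),
              n_used = n,
              contrast = make_contrast(est[["arm"]], sqrt(vc["arm", "arm"])))
  class(out) <- "trial_lm"
  out
}

#' @export
print.trial_lm <- function(x, ...) {
  cat("Linear model of the weeks 21-24 average outcome\n")
  cat(sprintf("  n used: %d, residual SD: %.1f\n", x$n_used, x$sigma))
  print(round(x$coefficients, 3))
  print(x$contrast)
  invisible(x)
}

#' @export
coef.trial_lm <- function(object, ...) object$coefficients

#' @export
vcov.trial_lm <- function(object, ...) object$vcov
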
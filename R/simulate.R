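#' Generation model configuration
#'
#' Bundles the parameters of the data-generating linear mixed model for a
#' two-arm trial with a weekly step-count outcome observed over a two-week
#' run-in (weeks -1 and 0) and 24 post-baseline weeks:
#' \deqn{Y_{it} = \alpha^* + \beta_{age}^* AGE_{it} + \beta_0^* I(t<1) +
#'   \beta_A^* A_i + c_{0i} + c_{1i} t + \eta_{it}, \quad t = -1, \dots, 24,}
#' where \eqn{c_{0i} \sim N(0, \sigma_{c0}^2)} and
#' \eqn{c_{1i} \sim N(0, \sigma_{c1}^2)} are independent random intercept and
#' slope, and \eqn{\eta_i} is a 26-dimensional zero-mean Gaussian vector with
#' exponential ("spatial") correlation \eqn{\exp(-|t_1 - t_2|/decay)} and
#' common standard deviation \code{sigma_e}.
#'
#' The defaults are the trial-like simulation conditions used throughout the
#' package's replication studies: n = 130 participants, intercept 10000
#' steps/day, age slope -50 steps/day per year, run-in offset -4000
#' steps/day, null policy effect, \eqn{\sigma_{c0} = \sigma_{c1} = 50},
#' \eqn{\sigma_e = 2000} steps/day, and a 52-week correlation time constant.
#'
#' @param n number of participants (>= 2).
#' @param alpha_star model intercept, steps/day.
#' @param beta_age_star age slope, steps/day per year of age.
#' @param beta0_star run-in offset applied at weeks t < 1, steps/day.
#' @param betaA_star constant treatment policy effect, steps/day.
#' @param sigma_c0,sigma_c1 SDs of the random intercept and slope.
#' @param sigma_e residual ("spatial") error SD, steps/day.
#' @param decay correlation time constant in weeks (> 0).
#' @param age_low,age_high bounds of the uniform baseline age distribution.
#' @return An object of class `gen_config` (a named list).
#' @export
gen_config <- function(n = 130, alpha_star = 10000, beta_age_star = -50,
                       beta0_star = -4000, betaA_star = 0,
                       sigma_c0 = 50, sigma_c1 = 50, sigma_e = 2000,
                       decay = 52, age_low = 20, age_high = 40) {
  if (n < 2) stop("gen_config: n must be >= 2")
  if (sigma_c0 < 0 || sigma_c1 < 0 || sigma_e < 0)
    stop("gen_config: standard deviations must be >= 0")
  if (decay <= 0) stop("gen_config: decay must be > 0")
  if (age_low >= age_high) stop("gen_config: need age_low < age_high")
  structure(list(n = as.integer(n), alpha_star = alpha_star,
                 beta_age_star = beta_age_star, beta0_star = beta0_star,
                 betaA_star = betaA_star, sigma_c0 = sigma_c0,
                 sigma_c1 = sigma_c1, sigma_e = sigma_e, decay = decay,
                 age_low = age_low, age_high = age_high),
            class = "gen_config")
}

#' Simulate trial covariates
#'
#' Draws the participant-level skeleton of a trial: randomized arm
#' (Bernoulli(0.5)) and baseline age (uniform on
#' \code{[age_low, age_high]}).
#'
#' @param config a [gen_config()].
#' @param seed optional integer; when given, `set.seed(seed)` is called first.
#' @return A data frame with columns `pid`, `arm`, `age0`.
#' @export
simulate_covariates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  data.frame(pid = seq_len(n),
             arm = rbinom(n, 1L, 0.5),
             age0 = runif(n, config$age_low, config$age_high))
}

#' Exponential within-participant error covariance
#'
#' Covariance matrix of the spatially correlated error process at the given
#' weeks: entry (j, k) is
#' \eqn{\sigma_e^2 \exp(-|w_j - w_k| / decay)}.
#'
#' @param weeks distinct integer weeks.
#' @param sigma_e error SD.
#' @param decay correlation time constant in weeks.
#' @return A symmetric positive semi-definite matrix.
#' @export
spatial_covariance <- function(weeks, sigma_e, decay = 52) {
  if (anyDuplicated(weeks)) stop("spatial_covariance: weeks must be distinct")
  if (sigma_e < 0) stop("spatial_covariance: sigma_e must be >= 0")
  lag <- abs(outer(weeks, weeks, "-"))
  sigma_e^2 * exp(-lag / decay)
}

#' Simulate weekly outcomes for a trial skeleton
#'
#' Fills in the outcome for weeks -1 through 24 from the generation model in
#' [gen_config()].  Age advances weekly: `AGE_it = age0 + t/52`.  The draw
#' order given a fresh seed is: random intercepts, random slopes, then the
#' correlated error matrix (participants in rows).
#'
#' @param config a [gen_config()].
#' @param skeleton data frame from [simulate_covariates()].
#' @param seed optional integer seed.
#' @return A long-format trial table: columns `pid`, `week`, `age`, `arm`,
#'   `y`, `observed` (all 1), with 26 rows per participant.
#' @export
simulate_outcomes <- function(config, skeleton, seed = NULL) {
  stopifnot(inherits(config, "gen_config"))
  if (!all(c("pid", "arm", "age0") %in% names(skeleton)))
    stop("simulate_outcomes: skeleton must have pid, arm, age0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(skeleton)
  weeks <- -1:24
  nt <- length(weeks)

  c0 <- rnorm(n, 0, config$sigma_c0)
  c1 <- rnorm(n, 0, config$sigma_c1)
  corr <- exp(-abs(outer(weeks, weeks, "-")) / config$decay)
  eta <- matrix(rnorm(n * nt), n, nt) %*% chol(corr) * config$sigma_e

  age <- outer(skeleton$age0, weeks / 52, "+")   # n x nt
  ## the policy effect applies post-baseline only: randomization happens
  ## after the run-in, and the analysis models constrain the arms to be
  ## equal during it
  fixed <- config$alpha_star + config$beta_age_star * age +
    config$beta0_star * outer(rep(1, n), as.numeric(weeks < 1)) +
    config$betaA_star * outer(skeleton$arm, as.numeric(weeks > 0))
  y <- fixed + c0 + outer(c1, weeks) + eta

  data.frame(pid = rep(skeleton$pid, each = nt),
             week = rep(weeks, n),
             age = as.vector(t(age)),
             arm = rep(skeleton$arm, each = nt),
             y = as.vector(t(y)),
             observed = 1L)
}

#' Simulate a complete trial table
#'
#' Convenience wrapper: one seed drives covariates and outcomes in a single
#' stream, so the same seed always yields a bitwise-identical table.
#'
#' @inheritParams simulate_outcomes
#' @return A long-format trial table over weeks -1 to 24.
#' @export
simulate_trial <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sk <- simulate_covariates(config)
  simulate_outcomes(config, sk)
}

#' Collapse the two-week run-in to a single baseline value
#'
#' The analysis models use a single baseline outcome `Y0`, the average steps
#' per day during the run-in.  This replaces the week-0 record's outcome by
#' the mean of the generated week -1 and week 0 values and drops the week -1
#' rows.  The week-0 observed flag is forced to 1 (the baseline is never
#' masked).
#'
#' @param table a trial table containing weeks -1 and 0 for every pid.
#' @param use_week0_only if `TRUE`, keep the generated week-0 value as the
#'   baseline instead of averaging weeks -1 and 0.
#' @return The table restricted to weeks 0 through 24.
#' @export
collapse_runin <- function(table, use_week0_only = FALSE) {
  idx_m1 <- table$week == -1L
  idx_0 <- table$week == 0L
  pids <- unique(table$pid)
  if (!all(pids %in% table$pid[idx_m1]) || !all(pids %in% table$pid[idx_0]))
    stop("collapse_runin: weeks -1 and 0 required for every pid")
  ym1 <- table$y[idx_m1][match(table$pid[idx_0], table$pid[idx_m1])]
  out <- table[!idx_m1, , drop = FALSE]
  i0 <- out$week == 0L
  if (!use_week0_only) out$y[i0] <- (out$y[i0] + ym1) / 2
  out$observed[i0] <- 1L
  rownames(out) <- NULL
  out
}
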
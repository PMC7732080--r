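#' Power specification for the endpoint comparison
#'
#' The trial endpoint is compared between arms with a two-sided two-sample
#' t-test (equal allocation, equal SD). `sigma` is the common per-arm SD of
#' the endpoint thickness; by convention it is the RMSE of the layer's
#' pooled decay fit, the regression estimate of the experimental error.
#'
#' @param alpha Two-sided significance level, in (0, 1); default 0.05.
#' @param power Target power, in (0, 1); default 0.8.
#' @param sigma Per-arm SD (um), > 0.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.8, sigma) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stopf("alpha must be in (0, 1)")
  if (!is.finite(power) || power <= 0 || power >= 1)
    stopf("power must be in (0, 1)")
  if (!is.finite(sigma) || sigma <= 0) stopf("sigma must be > 0")
  structure(list(alpha = alpha, power = power, sigma = sigma),
            class = "power_spec")
}

#' Efficacy-adjusted endpoint thickness
#'
#' A drug with decimal efficacy `e` is assumed to prevent the fraction `e`
#' of the untreated thickness loss: the predicted treated thickness at the
#' endpoint day is `(t0 - t_day) * e + t_day`, which equals the untreated
#' endpoint at `e = 0` and the baseline at `e = 1`.
#'
#' @param t0 Baseline (day-0) thickness, um, > 0.
#' @param t_day Untreated thickness at the endpoint day, um, > 0.
#' @param efficacy Decimal drug efficacy in \[0, 1\].
#' @return Adjusted thickness (um), full precision.
#' @export
#' @examples
#' efficacy_adjusted_thickness(47.5, 23.8, 0.20)  # 28.54
efficacy_adjusted_thickness <- function(t0, t_day, efficacy) {
  if (any(!is.finite(t0) | t0 <= 0)) stopf("t0 must be > 0")
  if (any(!is.finite(t_day) | t_day <= 0)) stopf("t_day must be > 0")
  if (any(!is.finite(efficacy) | efficacy < 0 | efficacy > 1))
    stopf("efficacy must be a fraction in [0, 1]")
  (t0 - t_day) * efficacy + t_day
}

#' Between-arm effect size implied by a drug efficacy
#'
#' The mean difference between treated and untreated arms at the endpoint:
#' `delta = efficacy * (t0 - t_day)`, i.e. the adjusted minus the untreated
#' endpoint thickness.
#'
#' @inheritParams efficacy_adjusted_thickness
#' @return Effect size delta (um).
#' @export
effect_size <- function(t0, t_day, efficacy) {
  efficacy_adjusted_thickness(t0, t_day, efficacy) - t_day
}

#' Per-group sample size for the two-sample t-test
#'
#' Smallest integer n per arm such that a two-sided two-sample t-test with
#' equal allocation and common SD `spec$sigma` reaches power `spec$power`
#' at true difference `delta`, by the noncentral-t power calculation of
#' [stats::power.t.test()] (ceiling of the continuous solution; power is
#' monotone in n). A floor of `n_floor` (default 2, the minimum for a
#' t-test) is applied.
#'
#' @param delta True between-arm mean difference (um), > 0.
#' @param spec A [power_spec()].
#' @param n_floor Minimum returned n (default 2).
#' @return Integer sample size per group.
#' @export
#' @examples
#' sample_size_per_group(5, power_spec(sigma = 5))  # delta = sigma -> 17
sample_size_per_group <- function(delta, spec, n_floor = 2L) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is.finite(delta) || delta <= 0)
    stopf("effect size must be positive")
  # power already reached at the floor?
  p_floor <- stats::power.t.test(n = n_floor, delta = delta,
                                 sd = spec$sigma, sig.level = spec$alpha,
                                 type = "two.sample",
                                 alternative = "two.sided")$power
  if (p_floor >= spec$power) return(as.integer(n_floor))
  sol <- stats::power.t.test(delta = delta, sd = spec$sigma,
                             sig.level = spec$alpha, power = spec$power,
                             type = "two.sample",
                             alternative = "two.sided")
  n <- as.integer(ceiling(sol$n - 1e-9))
  max(as.integer(n_floor), n)
}

# Normal-approximation sample size, kept as an internal cross-check:
# n0 = 2 * (z_{1-alpha/2} + z_power)^2 * (sigma/delta)^2, ceiled.
sample_size_normal_approx <- function(delta, spec) {
  z <- stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power)
  max(2L, as.integer(ceiling(2 * z^2 * (spec$sigma / delta)^2)))
}

#' Empirical power of the two-sample t-test by simulation
#'
#' Monte-Carlo oracle for [sample_size_per_group()]: simulates `reps`
#' two-arm experiments with `n` per arm, arm means differing by `delta`,
#' common SD `sigma`, and reports the fraction rejected by the pooled
#' two-sided t-test at level `alpha`. Fully reproducible given `seed`.
#'
#' @param n Per-arm sample size, >= 2.
#' @param delta True mean difference.
#' @param sigma Common SD, > 0.
#' @param alpha Two-sided level.
#' @param reps Number of simulated experiments (>= 1000).
#' @param seed Integer seed.
#' @return Rejection proportion.
#' @export
empirical_power <- function(n, delta, sigma, alpha = 0.05, reps = 10000,
                            seed = 1) {
  if (n < 2) stopf("n must be >= 2")
  if (reps < 1000) stopf("reps must be >= 1000")
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)

  x <- matrix(stats::rnorm(n * reps, mean = delta, sd = sigma), nrow = n)
  y <- matrix(stats::rnorm(n * reps, mean = 0, sd = sigma), nrow = n)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
  vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
  sp2 <- (vx + vy) / 2
  tstat <- (mx - my) / sqrt(2 * sp2 / n)
  crit <- stats::qt(1 - alpha / 2, df = 2 * n - 2)
  mean(abs(tstat) > crit)
}
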
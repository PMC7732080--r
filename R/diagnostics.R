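#' D'Agostino–Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe–Glynn (1983) transformed kurtosis statistic, each an approximate
#' standard-normal deviate under normality, into the omnibus statistic
#' \eqn{K^2 = Z_1^2 + Z_2^2}, referred to a chi-square distribution with 2
#' degrees of freedom. The moment transforms are asymptotic; below `min_n`
#' observations (default 20, hard floor 8) the test refuses to run.
#'
#' @param x Numeric sample (e.g. fit residuals).
#' @param min_n Minimum sample size; values below 20 (but >= 8) are accepted
#'   with a warning that the approximation is unstable.
#' @return List with `k2_stat`, `k2_p`, `skew_z`, `kurt_z`.
#' @references D'Agostino, R. B. (1970) Biometrika 57, 679-681;
#'   Anscombe, F. J. and Glynn, W. J. (1983) Biometrika 70, 227-234.
#' @export
#' @examples
#' set.seed(1)
#' dagostino_pearson_k2(rnorm(60))
dagostino_pearson_k2 <- function(x, min_n = 20) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (min_n < 8) stopf("min_n below the hard floor of 8")
  if (n < min_n)
    stopf("sample size %d is below the floor of %d for the K2 moment transforms",
          n, min_n)
  if (min_n < 20)
    warnf("K2 transforms are asymptotic; n = %d is small and p-values may be unstable", n)
  if (stats::sd(x) == 0) stopf("zero-variance sample: K2 undefined")

  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transform to a normal deviate
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe-Glynn (1983) transform
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2_stat = k2,
       k2_p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       skew_z = z1, kurt_z = z2)
}

#' Breusch–Pagan-type heteroscedasticity score test
#'
#' Regresses the squared residuals on the fitted values; the studentized
#' score statistic `n * R_aux^2` is referred to a chi-square distribution
#' with 1 degree of freedom. The null is homoscedasticity (residual variance
#' unrelated to the fitted thickness).
#'
#' @param residuals Numeric residuals (um).
#' @param fitted Numeric fitted values (um), same length, at least 10 pairs.
#' @return List with `stat` and `p`.
#' @export
homoscedasticity_test <- function(residuals, fitted) {
  if (length(residuals) != length(fitted))
    stopf("residuals and fitted values must have the same length")
  n <- length(residuals)
  if (n < 10) stopf("need at least 10 residual/fitted pairs")
  if (stats::sd(fitted) == 0)
    stopf("constant fitted values: no spread to regress the squared residuals on")
  if (all(abs(residuals) <= 1e-8 * max(1, max(abs(fitted)))))
    stopf("residuals are (numerically) zero: score statistic undefined")
  e2 <- residuals^2
  if (stats::sd(e2) == 0)
    stopf("squared residuals are constant: score statistic undefined")
  aux <- stats::lm(e2 ~ fitted)
  r2aux <- summary(aux)$r.squared
  stat <- n * r2aux
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Residual diagnostics for a decay fit
#'
#' Bundles the D'Agostino–Pearson omnibus normality test and the
#' heteroscedasticity score test on the fit residuals, with pass flags at
#' `alpha`. Diagnostics never block fitting or trial design: a test that
#' cannot be evaluated (too few residuals, degenerate variance) is reported
#' as not evaluable (`NA` flag with a reason) rather than raising an error.
#'
#' @param fit A converged `decay_fit`.
#' @param alpha Significance level for the pass flags (default 0.05).
#' @param min_n Minimum residual count for the normality test.
#' @return Object of class `decay_diagnostics`: fields `k2_stat`, `k2_p`,
#'   `skew_z`, `kurt_z`, `homosced_stat`, `homosced_p`, `normality_pass`,
#'   `homosced_pass` (logical or `NA`), and `notes`.
#' @export
diagnostics_report <- function(fit, alpha = 0.05, min_n = 20) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!fit$converged) stopf("fit did not converge; diagnostics undefined")
  notes <- character(0)

  norm <- tryCatch(dagostino_pearson_k2(fit$residuals, min_n = min_n),
                   error = function(e) e)
  if (inherits(norm, "error")) {
    notes <- c(notes, paste("normality not evaluable:",
                            conditionMessage(norm)))
    norm <- list(k2_stat = NA_real_, k2_p = NA_real_,
                 skew_z = NA_real_, kurt_z = NA_real_)
    normality_pass <- NA
  } else {
    normality_pass <- norm$k2_p > alpha
  }

  hom <- tryCatch(homoscedasticity_test(fit$residuals, fit$fitted.values),
                  error = function(e) e)
  if (inherits(hom, "error")) {
    notes <- c(notes, paste("homoscedasticity not evaluable:",
                            conditionMessage(hom)))
    hom <- list(stat = NA_real_, p = NA_real_)
    homosced_pass <- NA
  } else {
    homosced_pass <- hom$p > alpha
  }

  structure(list(k2_stat = norm$k2_stat, k2_p = norm$k2_p,
                 skew_z = norm$skew_z, kurt_z = norm$kurt_z,
                 homosced_stat = hom$stat, homosced_p = hom$p,
                 normality_pass = normality_pass,
                 homosced_pass = homosced_pass,
                 alpha = alpha, notes = notes),
            class = "decay_diagnostics")
}

#' @export
print.decay_diagnostics <- function(x, ...) {
  flag <- function(f) if (is.na(f)) "not evaluable" else if (f) "pass" else "FAIL"
  cat("Residual diagnostics (alpha =", x$alpha, "):\n")
  cat(sprintf("  normality (D'Agostino-Pearson K2): K2 = %s, p = %s  [%s]\n",
              format(x$k2_stat, digits = 4), format(x$k2_p, digits = 4),
              flag(x$normality_pass)))
  cat(sprintf("  homoscedasticity (score test):     stat = %s, p = %s  [%s]\n",
              format(x$homosced_stat, digits = 4),
              format(x$homosced_p, digits = 4), flag(x$homosced_pass)))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
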
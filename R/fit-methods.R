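#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential thinning fit: thickness = plateau + (initial - plateau) * exp(-k * day)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, R-squared = %s, RMSE = %s um%s\n", x$n,
              format(x$r.squared, digits = digits),
              format(x$rmse, digits = digits),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
vcov.decay_fit <- function(object, ...) object$cov

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
confint.decay_fit <- function(object, parm = c("initial", "plateau", "k"),
                              level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  se <- sqrt(diag(object$cov))[parm]
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df.residual)
  est <- object$coefficients[parm]
  out <- cbind(est - tq * se, est + tq * se)
  colnames(out) <- paste0(format(100 * c((1 - level) / 2,
                                         1 - (1 - level) / 2)), " %")
  out
}

#' Predict thickness from a decay fit
#'
#' @param object A `decay_fit`.
#' @param newdata data.frame with a `day` column, or `NULL` to use the
#'   fitting days.
#' @param interval `"none"` for point predictions or `"confidence"` for a
#'   pointwise band via [confidence_band()].
#' @param level Band coverage level.
#' @param ... Ignored.
#' @return Numeric vector, or a data.frame with `fit`, `lower`, `upper` when
#'   an interval is requested.
#' @export
predict.decay_fit <- function(object, newdata = NULL,
                              interval = c("none", "confidence"),
                              level = 0.95, ...) {
  interval <- match.arg(interval)
  days <- if (is.null(newdata)) object$data$day else newdata$day
  if (interval == "none") return(predict_thickness(object$params, days))
  confidence_band(object, days, level = level)[, c("fit", "lower", "upper")]
}

#' @export
summary.decay_fit <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  tval <- object$coefficients / se
  ctab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                `t value` = tval,
                `Pr(>|t|)` = 2 * stats::pt(abs(tval),
                                           df = object$df.residual,
                                           lower.tail = FALSE))
  diag_rep <- tryCatch(diagnostics_report(object), error = function(e) NULL)
  structure(list(fit = object, coefficients = ctab,
                 r.squared = object$r.squared, rmse = object$rmse,
                 gate = significance_gate(object),
                 diagnostics = diag_rep),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nParameters:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nR-squared gate (> 0.4): %s\n",
              if (isTRUE(x$gate)) "pass" else "fail"))
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  invisible(x)
}

#' Plot a decay fit with its confidence band
#'
#' Scatter of the observed (day, thickness) points with the fitted decay
#' curve (solid) and pointwise confidence band (dashed), the conventional
#' display for a pooled layer trajectory.
#'
#' @param x A `decay_fit`.
#' @param level Band coverage level.
#' @param n_grid Number of grid days for the curve.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.decay_fit <- function(x, level = 0.95, n_grid = 200, ...) {
  d <- x$data
  grid <- seq(min(d$day), max(d$day), length.out = n_grid)
  band <- tryCatch(confidence_band(x, grid, level = level),
                   error = function(e) NULL)
  graphics::plot(d$day, d$thickness_um, xlab = "Days since onset",
                 ylab = "Thickness (um)", ...)
  graphics::lines(grid, predict_thickness(x$params, grid), lwd = 2)
  if (!is.null(band)) {
    graphics::lines(grid, band$lower, lty = 2)
    graphics::lines(grid, band$upper, lty = 2)
  }
  invisible(x)
}

#' Simulate new thickness observations from a fitted decay curve
#'
#' Draws `nsim` replicate response vectors at the fitting days: fitted curve
#' plus i.i.d. Gaussian noise with SD equal to the fit RMSE.
#'
#' @param object A `decay_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed, handled as in [stats::simulate()].
#' @param ... Ignored.
#' @return data.frame with `nsim` columns, one row per fitting day.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
  }
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$rmse)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
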
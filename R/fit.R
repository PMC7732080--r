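#' Fit the exponential thinning model by nonlinear least squares
#'
#' Estimates `(initial, plateau, k)` of the decay model
#' `thickness = plateau + (initial - plateau) * exp(-k * day)` by
#' Levenberg–Marquardt least squares (via \pkg{minpack.lm}), with a
#' deterministic multi-start over five initializations so that a single poor
#' starting point cannot trap the fit in a local minimum. `plateau` and `k`
#' are bounded below by zero; `initial` is unconstrained relative to
#' `plateau` so that early-phase swelling is representable.
#'
#' Goodness of fit is summarized by the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (total sum of squares about the mean
#' observed thickness) and the root mean squared error
#' \eqn{RMSE = \sqrt{SS_{res}/(n - 3)}}, the regression estimate of the
#' experimental error used downstream as the per-arm SD in sample-size
#' calculations.
#'
#' @param x A formula such as `thickness_um ~ day`, or a numeric vector of
#'   days.
#' @param ... Passed to methods.
#' @return An object of class `decay_fit`; see Details.
#' @details The returned object has components `params` ([decay_params()]),
#'   `coefficients` (named vector `initial`, `plateau`, `k`), `fitted.values`,
#'   `residuals` (observed minus fitted), `r.squared`, `rmse` (also `sigma`),
#'   `cov` (3x3 parameter covariance), `converged`, `n`, `df.residual`,
#'   `data` (the (day, thickness) points used) and `call`. Standard methods
#'   (`print`, `summary`, `coef`, `vcov`, `predict`, `plot`, `residuals`,
#'   `fitted`, `simulate`, `confint`) are provided.
#' @export
#' @examples
#' gcl <- subset(crao_reference_thickness(), layer == "GCL")
#' fit <- fit_decay(thickness_um ~ day, data = gcl)
#' summary(fit)
#' predict(fit, newdata = data.frame(day = 90))
fit_decay <- function(x, ...) UseMethod("fit_decay")

#' @rdname fit_decay
#' @param data data.frame holding the formula variables.
#' @export
fit_decay.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  if (ncol(mf) != 2)
    stopf("formula must have the form thickness ~ day")
  fit <- fit_decay.default(mf[[2]], mf[[1]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname fit_decay
#' @param thickness Numeric vector of thicknesses (um), same length as the
#'   day vector.
#' @param max_iter Maximum Levenberg–Marquardt iterations per start.
#' @param ftol Relative sum-of-squares convergence tolerance.
#' @export
fit_decay.default <- function(x, thickness, max_iter = 500, ftol = 1e-10,
                              ...) {
  day <- as.numeric(x)
  th <- as.numeric(thickness)
  keep <- is.finite(day) & is.finite(th)
  day <- day[keep]; th <- th[keep]
  n <- length(day)
  if (n < 4)
    stopf("insufficient data: need at least 4 points to fit 3 parameters (got %d)", n)
  if (length(unique(day)) < 2)
    stopf("unidentifiable model: all observations share the same day")
  if (any(day < 0)) stopf("days must be non-negative")

  if (stats::sd(th) == 0) {
    # constant observations: the flat curve fits exactly but R-squared is
    # undefined (zero total sum of squares) and the gate must fail
    params <- decay_params(initial = th[1], plateau = th[1], k = 0)
    return(structure(list(
      params = params,
      coefficients = c(initial = th[1], plateau = th[1], k = 0),
      fitted.values = rep(th[1], n), residuals = rep(0, n),
      r.squared = NA_real_, rmse = 0, sigma = 0, ssr = 0,
      cov = matrix(NA_real_, 3, 3,
                   dimnames = rep(list(c("initial", "plateau", "k")), 2)),
      converged = TRUE, n = n, df.residual = n - 3L,
      data = data.frame(day = day, thickness_um = th),
      call = match.call()
    ), class = "decay_fit"))
  }

  resid_fn <- function(par)
    th - (par[2] + (par[1] - par[2]) * exp(-par[3] * day))
  starts <- decay_starts(day, th)
  best <- NULL
  for (s in starts) {
    f <- try(suppressWarnings(
      minpack.lm::nls.lm(
        par = c(initial = s$initial, plateau = s$plateau, k = s$k),
        fn = resid_fn,
        # initial is unconstrained relative to plateau (early swelling is
        # representable) but must stay in the model domain initial > 0
        lower = c(initial = 1e-8, plateau = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                             ftol = ftol, ptol = 1e-10)
      )), silent = TRUE)
    if (inherits(f, "try-error")) next
    ssr <- sum(f$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12)
      best <- list(fit = f, ssr = ssr)
  }
  if (is.null(best))
    stopf("decay fit failed from every starting point")

  lmfit <- best$fit
  cf <- stats::coef(lmfit)
  # nls.lm info codes 1-3: ftol/ptol criteria met; 4: gradient orthogonality
  # (the criterion reached by exact-interpolation fits)
  converged <- lmfit$info %in% 1:4
  res <- lmfit$fvec
  fitted <- th - res
  ssr <- sum(res^2)
  sst <- sum((th - mean(th))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  rmse <- sqrt(ssr / (n - 3))
  # delta-method parameter covariance from the Gauss-Newton hessian J'J
  covm <- try(rmse^2 * solve(lmfit$hessian), silent = TRUE)
  if (inherits(covm, "try-error")) covm <- matrix(NA_real_, 3, 3)
  dimnames(covm) <- list(c("initial", "plateau", "k"),
                         c("initial", "plateau", "k"))

  params <- decay_params(initial = unname(cf["initial"]),
                         plateau = unname(cf["plateau"]),
                         k = unname(cf["k"]))
  structure(list(
    params = params,
    coefficients = c(initial = unname(cf["initial"]),
                     plateau = unname(cf["plateau"]),
                     k = unname(cf["k"])),
    fitted.values = fitted,
    residuals = res,
    r.squared = r2,
    rmse = rmse,
    sigma = rmse,
    ssr = ssr,
    cov = covm,
    converged = converged,
    n = n,
    df.residual = n - 3L,
    data = data.frame(day = day, thickness_um = th),
    call = match.call()
  ), class = "decay_fit")
}

# Five deterministic starting points. The heuristic start takes the
# thickness at the earliest day as initial, the minimum thickness as
# plateau, and k from a log-linear regression of (thickness - 0.9*plateau)
# on day; the remaining starts perturb these to cover slow/fast decay and
# a zero plateau.
decay_starts <- function(day, th) {
  init0 <- max(th[which.min(day)][1], 1e-3)
  plat0 <- max(min(th), 0)
  shifted <- th - 0.9 * plat0
  k0 <- 0.01
  pos <- shifted > 0
  if (sum(pos) >= 2 && stats::sd(day[pos]) > 0) {
    sl <- stats::coef(stats::lm(log(shifted[pos]) ~ day[pos]))[2]
    if (is.finite(sl) && sl < 0) k0 <- -as.numeric(sl)
  }
  k0 <- min(max(k0, 1e-5), 1)
  list(
    list(initial = init0, plateau = plat0, k = k0),
    list(initial = init0, plateau = plat0, k = k0 / 5),
    list(initial = init0, plateau = plat0, k = k0 * 5),
    list(initial = init0, plateau = 0, k = k0),
    list(initial = max(max(th), 1e-3), plateau = 0.5 * plat0, k = k0)
  )
}

#' Goodness-of-fit summary of a decay fit
#'
#' @param fit A `decay_fit`.
#' @return List with `r_squared` (NA when the observed thicknesses are
#'   constant, in which case the R-squared gate cannot pass) and `rmse`
#'   (um, denominator n - 3).
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  list(r_squared = fit$r.squared, rmse = fit$rmse)
}

#' Biological-significance gate on the coefficient of determination
#'
#' A pooled layer fit is considered biologically meaningful only when its
#' R-squared strictly exceeds the threshold (default 0.4). An undefined
#' R-squared fails the gate, with the reason recorded in the `"reason"`
#' attribute.
#'
#' @param fit A `decay_fit`, or a single numeric R-squared value.
#' @param threshold Gate threshold (default 0.4); strict inequality.
#' @return `TRUE` or `FALSE`.
#' @export
significance_gate <- function(fit, threshold = 0.4) {
  r2 <- if (inherits(fit, "decay_fit")) fit$r.squared else as.numeric(fit)
  if (is.na(r2))
    return(structure(FALSE, reason = "R-squared undefined"))
  isTRUE(r2 > threshold)
}

#' Pointwise confidence band for the fitted decay curve
#'
#' First-order (delta-method) propagation of the parameter covariance
#' through the model gradient, with a Student-t quantile on n - 3 degrees of
#' freedom. The band always contains the point estimate.
#'
#' @param fit A converged `decay_fit` with a valid covariance.
#' @param days Numeric grid of days.
#' @param level Coverage level (default 0.95).
#' @return data.frame with columns `day`, `fit`, `lower`, `upper` (um).
#' @export
confidence_band <- function(fit, days, level = 0.95) {
  stopifnot(inherits(fit, "decay_fit"))
  if (!fit$converged) stopf("fit did not converge; no confidence band")
  V <- fit$cov
  if (any(!is.finite(V)))
    stopf("singular or unavailable parameter covariance; collect more data or rescale")
  p <- fit$params
  est <- predict_thickness(p, days)
  ek <- exp(-p$k * days)
  G <- cbind(initial = ek,
             plateau = 1 - ek,
             k = -(p$initial - p$plateau) * days * ek)
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  data.frame(day = days, fit = est, lower = est - tq * se,
             upper = est + tq * se)
}
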
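#' Parameters of the exponential thinning model
#'
#' The thickness trajectory of a layer after occlusion is modelled as
#' \deqn{T(d) = plateau + (initial - plateau) \, e^{-k d}}
#' where `initial` is the thickness at day 0 (um), `plateau` the asymptotic
#' residual thickness (um) and `k` the per-day decay constant. An `initial`
#' below `plateau` (apparent thickening, as seen with acute-phase edema) is
#' permitted but flagged via the `thickening` attribute rather than rejected.
#'
#' @param initial Day-0 thickness, um; must be positive.
#' @param plateau Asymptotic thickness, um; must be non-negative.
#' @param k Decay constant, per day; must be non-negative.
#' @return Object of class `decay_params`.
#' @export
#' @examples
#' p <- decay_params(initial = 47.5, plateau = 12.3, k = 0.037)
#' predict_thickness(p, c(0, 30, 180))
decay_params <- function(initial, plateau, k) {
  stopifnot(length(initial) == 1, length(plateau) == 1, length(k) == 1)
  if (!is.finite(initial) || initial <= 0) stopf("initial must be > 0")
  if (!is.finite(plateau) || plateau < 0) stopf("plateau must be >= 0")
  if (!is.finite(k) || k < 0) stopf("k must be >= 0")
  structure(list(initial = initial, plateau = plateau, k = k),
            thickening = initial < plateau,
            class = "decay_params")
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("decay parameters: initial = %.4g um, plateau = %.4g um, k = %.4g /day\n",
              x$initial, x$plateau, x$k))
  if (isTRUE(attr(x, "thickening")))
    cat("  note: initial < plateau (apparent thickening)\n")
  invisible(x)
}

#' @export
as.list.decay_params <- function(x, ...) {
  # serialization field names used in JSON outputs
  list(initial_um = x$initial, plateau_um = x$plateau, k_per_day = x$k)
}

#' Evaluate the decay model
#'
#' @param params A [decay_params()] object.
#' @param days Non-negative numeric vector of days since onset.
#' @return Predicted thickness (um) at each day.
#' @export
predict_thickness <- function(params, days) {
  stopifnot(inherits(params, "decay_params"))
  if (any(!is.finite(days) | days < 0))
    stopf("days must be non-negative (extrapolation before onset is undefined)")
  params$plateau + (params$initial - params$plateau) * exp(-params$k * days)
}

#' Signed percent change in thickness relative to baseline
#'
#' `100 * (t_value - t0_value) / t0_value`; negative for thinning. Full
#' precision is kept — rounding to one decimal is a presentation concern of
#' the report builders.
#'
#' @param t0_value Baseline thickness (um), > 0.
#' @param t_value Thickness at the later time (um).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(332.3, 289.1)  # about -13.0
percent_change <- function(t0_value, t_value) {
  if (any(!is.finite(t0_value) | t0_value <= 0))
    stopf("baseline thickness must be > 0")
  100 * (t_value - t0_value) / t0_value
}
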
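#' Reference untreated thickness projections for a CRAO cohort
#'
#' Published middle-ring thickness projections (micrometres) for an untreated
#' CRAO cohort: the day-0 baseline taken from non-affected contralateral
#' control eyes, and the projected untreated thickness at trial endpoints of
#' 30, 60, 90, 120 and 180 days, for the six layers whose pooled decay fits
#' were tabulated (whole retina, combined inner layers, RNFL, GCL, IPL, INL).
#' The values are bundled at their one-decimal reported precision and are used
#' throughout the package's examples and validation suite: back-fitting the
#' decay model to a layer's column recovers the generating curve, and the
#' efficacy-adjustment arithmetic reproduces the reported treated-endpoint
#' cells.
#'
#' @return A data.frame with columns `layer` (character), `day` (numeric) and
#'   `thickness_um` (numeric). Day 0 is the control-eye baseline.
#' @seealso [fit_decay()], [build_trial_table()]
#' @export
#' @examples
#' ref <- crao_reference_thickness()
#' gcl <- subset(ref, layer == "GCL")
#' fit <- fit_decay(thickness_um ~ day, data = gcl)
#' coef(fit)
crao_reference_thickness <- function() {
  days <- c(0, 30, 60, 90, 120, 180)
  cols <- list(
    RETINA = c(332.3, 289.1, 261.9, 245.7, 236.1, 226.9),
    INNER  = c(253.8, 207.6, 180.4, 164.1, 154.4, 145.1),
    RNFL   = c(22.5, 19.4, 14.8, 12.9, 12.2, 11.7),
    GCL    = c(47.5, 23.8, 15.9, 13.4, 12.6, 12.3),
    IPL    = c(39.5, 26.4, 19.8, 17.5, 16.7, 16.3),
    INL    = c(40.1, 23.5, 19.6, 18.5, 18.2, 18.0)
  )
  data.frame(
    layer = rep(names(cols), each = length(days)),
    day = rep(days, times = length(cols)),
    thickness_um = unlist(cols, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reference day-0 baseline thicknesses by layer
#'
#' Convenience accessor for the day-0 (control-eye) rows of
#' [crao_reference_thickness()].
#'
#' @return Named numeric vector of baseline thicknesses (um).
#' @export
crao_reference_baseline <- function() {
  ref <- crao_reference_thickness()
  b <- ref[ref$day == 0, ]
  stats::setNames(b$thickness_um, b$layer)
}
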
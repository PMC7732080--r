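#' Build the trial-design table from per-layer decay fits
#'
#' For each layer whose pooled fit passes the R-squared gate (non-passing
#' layers are excluded and logged; `force_layers` overrides the gate), and
#' each endpoint day: projects the untreated thickness from the fitted
#' curve, computes the percent change versus the day-0 baseline, and for
#' each candidate drug efficacy the efficacy-adjusted endpoint thickness
#' and the per-group sample size needed to detect that treated-vs-untreated
#' difference with a two-sided two-sample t-test. The per-arm SD for each
#' layer is its fit RMSE (overridable via `sigma_by_layer`).
#'
#' @param fits Named list of `decay_fit` objects, one per layer.
#' @param t0_by_layer Named numeric vector of day-0 baseline thicknesses
#'   (um); defaults to each fit's `initial` estimate. Whether the baseline
#'   row should be the control-eye mean or the fitted intercept is a
#'   reporting choice; both are supported through this argument.
#' @param days Numeric vector of endpoint days (>= 0).
#' @param efficacies Numeric vector of decimal efficacies in \[0, 1\].
#' @param alpha,power Test level and target power for the sample sizes.
#' @param gate_threshold R-squared gate (default 0.4, strict).
#' @param force_layers Layers to tabulate even if they fail the gate.
#' @param sigma_by_layer Optional named numeric vector overriding the
#'   per-layer SD (um).
#' @param n_floor Minimum per-group sample size (default 2).
#' @return Object of class `trial_design_table`: a data.frame with one row
#'   per (layer, day) and columns `layer`, `day`, `t0_um`, `t_no_drug_um`,
#'   `pct_change`, then `t<eff>_um` and `n<eff>` per efficacy (full
#'   precision; the print method renders thicknesses at one decimal).
#'   Attributes: `excluded` (data.frame of gated-out layers with reasons)
#'   and `sigma` (per-layer SD used).
#' @export
#' @examples
#' ref <- crao_reference_thickness()
#' fits <- lapply(split(ref, ref$layer), function(d)
#'   fit_decay(thickness_um ~ day, data = d))
#' tab <- build_trial_table(fits["GCL"], days = c(30, 60),
#'                          efficacies = c(0.2, 0.5))
#' print(tab)
build_trial_table <- function(fits, t0_by_layer = NULL,
                              days = c(30, 60, 90, 120, 180),
                              efficacies = c(0.10, 0.20, 0.30, 0.50, 0.75),
                              alpha = 0.05, power = 0.8,
                              gate_threshold = 0.4,
                              force_layers = character(0),
                              sigma_by_layer = NULL, n_floor = 2L) {
  stopifnot(is.list(fits), length(fits) > 0, !is.null(names(fits)))
  if (any(days < 0)) stopf("endpoint days must be non-negative")
  if (any(efficacies < 0 | efficacies > 1))
    stopf("efficacies must be fractions in [0, 1]")

  excluded <- data.frame(layer = character(0), r_squared = numeric(0),
                         reason = character(0), stringsAsFactors = FALSE)
  rows <- list()
  sigma_used <- c()
  for (layer in names(fits)) {
    fit <- fits[[layer]]
    stopifnot(inherits(fit, "decay_fit"))
    gate <- significance_gate(fit, threshold = gate_threshold)
    if (!isTRUE(gate) && !layer %in% force_layers) {
      excluded <- rbind(excluded, data.frame(
        layer = layer, r_squared = fit$r.squared,
        reason = attr(gate, "reason") %||%
          sprintf("R-squared %.3g does not exceed the %.2g gate",
                  fit$r.squared, gate_threshold),
        stringsAsFactors = FALSE))
      next
    }
    t0 <- if (!is.null(t0_by_layer) && layer %in% names(t0_by_layer))
      t0_by_layer[[layer]] else fit$params$initial
    sigma <- if (!is.null(sigma_by_layer) && layer %in% names(sigma_by_layer))
      sigma_by_layer[[layer]] else fit$rmse
    sigma_used[layer] <- sigma
    spec <- power_spec(alpha = alpha, power = power, sigma = sigma)
    for (d in days) {
      tnd <- predict_thickness(fit$params, d)
      row <- data.frame(layer = layer, day = d, t0_um = t0,
                        t_no_drug_um = tnd,
                        pct_change = percent_change(t0, tnd),
                        stringsAsFactors = FALSE)
      for (e in efficacies) {
        adj <- efficacy_adjusted_thickness(t0, tnd, e)
        delta <- adj - tnd
        n <- if (delta > 0) sample_size_per_group(delta, spec, n_floor)
             else NA_integer_
        row[[sprintf("t%02.0f_um", 100 * e)]] <- adj
        row[[sprintf("n%02.0f", 100 * e)]] <- n
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(layer = character(0), day = numeric(0), t0_um = numeric(0),
               t_no_drug_um = numeric(0), pct_change = numeric(0))
  rownames(tab) <- NULL
  structure(tab, excluded = excluded, sigma = sigma_used,
            class = c("trial_design_table", "data.frame"))
}

#' @export
print.trial_design_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE) & !startsWith(names(df), "n")
  df[num] <- lapply(df[num], function(v) round_half_up(v, 1))
  cat("Trial design table (thickness um at one decimal; n per group)\n")
  print.data.frame(df, row.names = FALSE)
  exc <- attr(x, "excluded")
  if (!is.null(exc) && nrow(exc)) {
    cat("\nLayers excluded by the R-squared gate:\n")
    print.data.frame(exc, row.names = FALSE)
  }
  invisible(x)
}
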
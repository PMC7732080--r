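#' Default true decay parameters per layer for synthetic cohorts
#'
#' Presets for the generator: the four inner component layers (RNFL, GCL,
#' IPL, INL) take decay parameters back-fitted from the bundled reference
#' projections ([crao_reference_thickness()]), so synthetic trajectories
#' resemble observed CRAO thinning; the outer layers (OPL, ONL, OUTER, RPE)
#' and CMT are stable (k = 0) around normative middle-ring means, since the
#' outer retina is supplied by the ciliary circulation and largely spared.
#' These are modelling presets, not measurements. The composite layers
#' INNER and RETINA are not parameterized: the generator derives them as
#' exact sums of their components before noise.
#'
#' @return Named list of [decay_params()].
#' @export
default_layer_params <- function() {
  ref <- crao_reference_thickness()
  inner <- lapply(c(RNFL = "RNFL", GCL = "GCL", IPL = "IPL", INL = "INL"),
                  function(l) {
                    d <- ref[ref$layer == l, ]
                    fit_decay(d$day, d$thickness_um)$params
                  })
  stable <- function(mu) decay_params(initial = mu, plateau = mu, k = 0)
  c(inner, list(OPL = stable(28), ONL = stable(72), OUTER = stable(88),
                RPE = stable(15), CMT = stable(270)))
}

#' Configuration of the synthetic longitudinal cohort generator
#'
#' Defaults mirror the cohort shape of the retrospective study the analysis
#' is designed for: 19 CRAO patients with 1–8 scans each over up to 951 days
#' of follow-up, 15 contralateral control eyes entering at day 0, additive
#' Gaussian measurement noise, modest between-patient heterogeneity, and a
#' small probability that a scan fails segmentation QC.
#'
#' @param n_crao_patients Number of CRAO patients (one affected eye each).
#' @param n_control_eyes Number of non-affected control eyes.
#' @param layer_params Named list of true [decay_params()] for the component
#'   layers (see [default_layer_params()]).
#' @param noise_sd Additive Gaussian measurement noise SD (um), recycled
#'   over layers or a named per-layer vector.
#' @param re_frac Between-patient heterogeneity: Gaussian SD of `initial`
#'   and `plateau` as a fraction of their layer means (0 disables).
#' @param k_lnsd Between-patient log-normal SD of the decay constant `k`
#'   (0 disables).
#' @param visits_min,visits_max Per-patient scan count range (uniform).
#' @param max_followup Latest possible visit day.
#' @param qc_fail_prob Probability a scan is flagged as a segmentation
#'   failure.
#' @param seed Integer seed; all draws flow from this one generator stream.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_crao_patients = 19, n_control_eyes = 15,
                             layer_params = default_layer_params(),
                             noise_sd = 2, re_frac = 0.08, k_lnsd = 0.2,
                             visits_min = 1, visits_max = 8,
                             max_followup = 951, qc_fail_prob = 0.05,
                             seed = NULL) {
  if (n_crao_patients < 0 || n_control_eyes < 0) stopf("counts must be >= 0")
  if (any(noise_sd < 0)) stopf("noise_sd must be >= 0")
  if (qc_fail_prob < 0 || qc_fail_prob > 1)
    stopf("qc_fail_prob must be a probability")
  if (visits_min > visits_max) stopf("visits_min must not exceed visits_max")
  if (visits_min < 1) stopf("visits_min must be >= 1")
  if (max_followup < 0) stopf("max_followup must be >= 0")
  structure(list(n_crao_patients = n_crao_patients,
                 n_control_eyes = n_control_eyes,
                 layer_params = layer_params, noise_sd = noise_sd,
                 re_frac = re_frac, k_lnsd = k_lnsd,
                 visits_min = visits_min, visits_max = visits_max,
                 max_followup = max_followup, qc_fail_prob = qc_fail_prob,
                 seed = seed),
            class = "synthetic_config")
}

layer_noise_sd <- function(config, layer) {
  ns <- config$noise_sd
  if (!is.null(names(ns)) && layer %in% names(ns)) ns[[layer]]
  else unname(ns[1])
}

#' Draw a visit schedule for one synthetic patient
#'
#' The scan count is uniform on `[visits_min, visits_max]`; visit days are
#' distinct integers drawn from a right-skewed (Beta(1, 3)-weighted)
#' distribution over `[0, max_followup]`, reflecting denser acute-phase
#' recall, and returned sorted ascending.
#'
#' @param config A [synthetic_config()].
#' @return Sorted integer vector of visit days.
#' @export
generate_visit_schedule <- function(config) {
  n_visits <- if (config$visits_min == config$visits_max) config$visits_min
    else sample(config$visits_min:config$visits_max, 1)
  days <- 0:config$max_followup
  w <- stats::dbeta((days + 0.5) / (config$max_followup + 1),
                    shape1 = 1, shape2 = 3)
  sort(sample(days, n_visits, replace = FALSE, prob = w))
}

# Components that sum to the composites; order matters for reproducibility.
inner_components <- function() c("RNFL", "GCL", "IPL", "INL")
outer_components <- function() c("OPL", "ONL", "OUTER", "RPE")

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' CRAO eyes follow per-patient exponential decay curves (layer means
#' perturbed by Gaussian between-patient effects on `initial`/`plateau` and
#' a log-normal effect on `k`) plus independent additive Gaussian
#' measurement noise. Control eyes are stable draws around the layer means,
#' recorded at day 0. The composites are built as exact pre-noise sums —
#' INNER = RNFL + GCL + IPL + INL and RETINA = INNER + OPL + ONL + OUTER +
#' RPE — before per-record noise is added. Each scan carries a Bernoulli
#' segmentation-failure flag. Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a `crao_cohort`) and `truth` (list with
#'   `patient_params` — per patient/layer true parameters, `true_values` —
#'   pre-noise thickness per record, `noise_sd`, `qc_fail_prob`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  comp <- c(inner_components(), outer_components(), "CMT")
  if (config$n_crao_patients == 0 && config$n_control_eyes == 0)
    warnf("degenerate configuration: empty cohort generated")

  rows <- list(); truths <- list(); pparams <- list()

  add_records <- function(pid, eye, group, day, true_by_layer, qc) {
    all_layers <- names(true_by_layer)
    noise <- vapply(all_layers, function(l)
      stats::rnorm(1, 0, layer_noise_sd(config, l)), 0)
    obs <- pmax(unlist(true_by_layer) + noise, 0.5)
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = pid, eye = eye, group = group, day = day,
      layer = all_layers, thickness_um = unname(obs), qc_pass = qc,
      stringsAsFactors = FALSE)
    truths[[length(truths) + 1]] <<- data.frame(
      patient_id = pid, eye = eye, day = day, layer = all_layers,
      true_um = unname(unlist(true_by_layer)), stringsAsFactors = FALSE)
  }

  compose <- function(vals) {
    vals$INNER <- sum(unlist(vals[inner_components()]))
    vals$RETINA <- vals$INNER + sum(unlist(vals[outer_components()]))
    vals
  }

  # CRAO patients: one affected eye each, decaying inner layers
  for (i in seq_len(config$n_crao_patients)) {
    pid <- sprintf("CRAO%03d", i)
    eye <- if (i %% 2 == 0) "OD" else "OS"
    pp <- lapply(config$layer_params[comp], function(p) {
      ini <- max(p$initial + stats::rnorm(1, 0, config$re_frac * p$initial), 1)
      pla <- max(p$plateau + stats::rnorm(1, 0, config$re_frac * max(p$plateau, 1e-6)), 0)
      k <- p$k * exp(stats::rnorm(1, 0, config$k_lnsd))
      decay_params(ini, pla, k)
    })
    pparams[[pid]] <- pp
    days <- generate_visit_schedule(config)
    for (d in days) {
      vals <- lapply(pp, function(p) predict_thickness(p, d))
      vals <- compose(vals)
      qc <- stats::runif(1) >= config$qc_fail_prob
      add_records(pid, eye, "CRAO", d, vals, qc)
    }
  }

  # control eyes: stable around the layer means, recorded at day 0
  for (i in seq_len(config$n_control_eyes)) {
    pid <- sprintf("CTL%03d", i)
    eye <- if (i %% 2 == 0) "OS" else "OD"
    vals <- lapply(config$layer_params[comp], function(p)
      max(p$initial + stats::rnorm(1, 0, config$re_frac * p$initial), 1))
    vals <- compose(vals)
    qc <- stats::runif(1) >= config$qc_fail_prob
    add_records(pid, eye, "CONTROL", 0, vals, qc)
  }

  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), eye = character(0),
               group = character(0), day = numeric(0), layer = character(0),
               thickness_um = numeric(0), qc_pass = logical(0))
  cohort <- if (nrow(df)) as_cohort(df, provenance = "synthetic cohort")
    else new_cohort(df, provenance = "synthetic cohort")
  truth <- list(patient_params = pparams,
                true_values = if (length(truths)) do.call(rbind, truths)
                  else NULL,
                noise_sd = config$noise_sd,
                qc_fail_prob = config$qc_fail_prob,
                config = config)
  list(cohort = cohort, truth = truth)
}

#' Parameter-recovery experiment for the pooled decay fit
#'
#' Repeatedly generates a synthetic cohort, pools the affected-eye points
#' for `layer` with the control-eye day-0 baseline, fits the decay model,
#' and compares the estimates with the generating layer means. Reports
#' per-parameter bias and relative error and the pointwise
#' confidence-band coverage of the true curve at `eval_day`.
#'
#' @param config A [synthetic_config()]; its seed is ignored (replicate
#'   seeds derive from `seed`).
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Base integer seed.
#' @param layer Layer to fit (default GCL).
#' @param eval_day Day at which band coverage is assessed (default 60).
#' @param level Band coverage level.
#' @return Object of class `recovery_report`: data.frame `params` with
#'   columns `parameter`, `true`, `mean_estimate`, `bias`,
#'   `median_rel_error`; scalar `coverage`; `n_replicates`.
#' @export
parameter_recovery_experiment <- function(config, n_replicates, seed = 1,
                                          layer = "GCL", eval_day = 60,
                                          level = 0.95) {
  if (n_replicates < 2) stopf("need at least 2 replicates")
  true_p <- config$layer_params[[layer]]
  if (is.null(true_p)) stopf("no true parameters configured for layer '%s'", layer)
  true_at_eval <- predict_thickness(true_p, eval_day)

  est <- matrix(NA_real_, n_replicates, 3,
                dimnames = list(NULL, c("initial", "plateau", "k")))
  covered <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (seed + r) %% .Machine$integer.max
    sim <- generate_cohort(cfg)
    kept <- apply_exclusions(sim$cohort)$cohort
    df <- as.data.frame(kept)
    crao <- df[df$group == "CRAO" & df$layer == layer, c("day", "thickness_um")]
    base <- suppressWarnings(baseline_from_controls(kept, layer))
    pts <- rbind(crao, base[, c("day", "thickness_um")])
    fit <- fit_decay(pts$day, pts$thickness_um)
    est[r, ] <- coef(fit)
    band <- tryCatch(confidence_band(fit, eval_day, level = level),
                     error = function(e) NULL)
    covered[r] <- !is.null(band) &&
      band$lower <= true_at_eval && true_at_eval <= band$upper
  }
  truth <- c(initial = true_p$initial, plateau = true_p$plateau, k = true_p$k)
  params <- data.frame(
    parameter = colnames(est),
    true = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    median_rel_error = apply(abs(sweep(est, 2, truth) /
                                   rep(truth, each = n_replicates)), 2,
                             stats::median),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(params = params, coverage = mean(covered),
                 n_replicates = n_replicates, layer = layer,
                 eval_day = eval_day),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery for %s over %d replicates:\n",
              x$layer, x$n_replicates))
  print(x$params, digits = 4, row.names = FALSE)
  cat(sprintf("confidence-band coverage of the true curve at day %g: %.1f%%\n",
              x$eval_day, 100 * x$coverage))
  invisible(x)
}
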
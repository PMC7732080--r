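# Shared fixtures and independent oracles for the suite.

# (day, thickness) points lying exactly on a decay curve
make_points <- function(params, days) {
  data.frame(day = days, thickness_um = predict_thickness(params, days))
}

# Minimal valid cohort data.frame builder
make_cohort_df <- function(n_crao = 2, n_ctl = 2, layer = "GCL") {
  crao <- expand.grid(patient_id = sprintf("P%02d", seq_len(n_crao)),
                      day = c(10, 40), stringsAsFactors = FALSE)
  df <- rbind(
    data.frame(patient_id = crao$patient_id, eye = "OD", group = "CRAO",
               day = crao$day, layer = layer,
               thickness_um = 40 - 0.2 * crao$day,
               qc_pass = TRUE, stringsAsFactors = FALSE),
    if (n_ctl > 0)
      data.frame(patient_id = sprintf("C%02d", seq_len(n_ctl)), eye = "OS",
                 group = "CONTROL", day = 0, layer = layer,
                 thickness_um = 47.5, qc_pass = TRUE,
                 stringsAsFactors = FALSE)
  )
  df
}

# Brute-force least-squares oracle: dense lattice over (initial, plateau, k),
# chunked over k so each step is a vectorized (initial x plateau) grid.
# Independent of the Levenberg-Marquardt path it cross-checks.
lattice_min_ssr <- function(day, th, n_grid = 200,
                            k_max = 0.1) {
  # the lattice covers the model's own domain: initial > 0, plateau >= 0
  init_grid <- seq(max(1e-8, 0.5 * min(th)), 1.5 * max(th),
                   length.out = n_grid)
  plat_grid <- seq(0, max(th), length.out = n_grid)
  k_grid <- seq(0, k_max, length.out = n_grid)
  best <- Inf
  for (k in k_grid) {
    E <- exp(-k * day)
    ssr <- matrix(0, n_grid, n_grid)
    for (j in seq_along(day)) {
      pred <- outer(init_grid * E[j], plat_grid * (1 - E[j]), "+")
      ssr <- ssr + (pred - th[j])^2
    }
    m <- min(ssr)
    if (m < best) best <- m
  }
  best
}
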
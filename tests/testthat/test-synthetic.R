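test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_crao_patients = 6, n_control_eyes = 4, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_equal(a$truth$true_values, b$truth$true_values)
  c_ <- generate_cohort(synthetic_config(n_crao_patients = 6,
                                         n_control_eyes = 4, seed = 102))
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c_$cohort)))
})

test_that("with no noise and no random effects every point is on its curve", {
  cfg <- synthetic_config(n_crao_patients = 5, n_control_eyes = 3,
                          noise_sd = 0, re_frac = 0, k_lnsd = 0,
                          qc_fail_prob = 0, seed = 7)
  sim <- generate_cohort(cfg)
  df <- as.data.frame(sim$cohort)
  gcl <- df[df$group == "CRAO" & df$layer == "GCL", ]
  p <- cfg$layer_params$GCL
  expect_equal(gcl$thickness_um, predict_thickness(p, gcl$day),
               tolerance = 1e-12)
  # controls sit at the layer mean
  ctl <- df[df$group == "CONTROL" & df$layer == "GCL", ]
  expect_true(all(ctl$thickness_um == p$initial))
})

test_that("visit schedules respect the configured shape", {
  cfg <- synthetic_config(seed = 1)
  set.seed(1)
  sched <- replicate(200, generate_visit_schedule(cfg), simplify = FALSE)
  lens <- lengths(sched)
  expect_true(all(lens >= 1 & lens <= 8))
  alldays <- unlist(sched)
  expect_true(all(alldays >= 0 & alldays <= 951))
  expect_true(all(vapply(sched, function(s) !is.unsorted(s, strictly = TRUE),
                         TRUE)))
  # early visits denser than late ones (right-skew)
  expect_gt(mean(alldays < 475), 0.5)
  # min = max = 1 -> exactly one visit each
  cfg1 <- synthetic_config(visits_min = 1, visits_max = 1)
  expect_true(all(lengths(replicate(20, generate_visit_schedule(cfg1),
                                    simplify = FALSE)) == 1))
  expect_error(synthetic_config(visits_min = 5, visits_max = 2), "exceed")
  # determinism
  set.seed(9); s1 <- generate_visit_schedule(cfg)
  set.seed(9); s2 <- generate_visit_schedule(cfg)
  expect_equal(s1, s2)
})

test_that("generated cohorts validate and composites sum exactly pre-noise", {
  sim <- generate_cohort(synthetic_config(n_crao_patients = 8,
                                          n_control_eyes = 5, seed = 55))
  # re-validation raises no error
  expect_silent(as_cohort(as.data.frame(sim$cohort)))
  tv <- sim$truth$true_values
  wide <- reshape(tv, idvar = c("patient_id", "eye", "day"),
                  timevar = "layer", direction = "wide")
  get <- function(l) wide[[paste0("true_um.", l)]]
  expect_equal(get("INNER"),
               get("RNFL") + get("GCL") + get("IPL") + get("INL"),
               tolerance = 1e-12)
  expect_equal(get("RETINA"),
               get("INNER") + get("OPL") + get("ONL") + get("OUTER") +
                 get("RPE"),
               tolerance = 1e-12)
})

test_that("control summaries converge to configured means at large n", {
  cfg <- synthetic_config(n_crao_patients = 0, n_control_eyes = 10000,
                          re_frac = 0.05, noise_sd = 2, seed = 77)
  sim <- generate_cohort(cfg)
  s <- control_summary(sim$cohort)
  p <- cfg$layer_params$GCL
  expect_equal(s$mean_um[s$layer == "GCL"], p$initial, tolerance = 0.02)
  # total SD combines between-eye and measurement components
  expect_equal(s$sd_um[s$layer == "GCL"],
               sqrt((0.05 * p$initial)^2 + 4), tolerance = 0.05)
})

test_that("the exclusion fraction converges to qc_fail_prob", {
  cfg <- synthetic_config(n_crao_patients = 300, n_control_eyes = 100,
                          qc_fail_prob = 0.1, seed = 88)
  sim <- generate_cohort(cfg)
  df <- as.data.frame(sim$cohort)
  scans <- unique(df[, c("patient_id", "eye", "day", "qc_pass")])
  frac <- mean(!scans$qc_pass)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(scans)))
})

test_that("an empty configuration warns and returns an empty cohort", {
  expect_warning(sim <- generate_cohort(
    synthetic_config(n_crao_patients = 0, n_control_eyes = 0, seed = 1)),
    "empty")
  expect_equal(nrow(sim$cohort), 0)
})

test_that("a dense noisy cohort recovers the decay constant within 10%", {
  cfg <- synthetic_config(n_crao_patients = 50, n_control_eyes = 15,
                          visits_min = 6, visits_max = 8,
                          noise_sd = 2, re_frac = 0, k_lnsd = 0, seed = 123)
  sim <- generate_cohort(cfg)
  kept <- apply_exclusions(sim$cohort)$cohort
  df <- as.data.frame(kept)
  pts <- rbind(df[df$group == "CRAO" & df$layer == "GCL",
                  c("day", "thickness_um")],
               baseline_from_controls(kept, "GCL"))
  fit <- fit_decay(pts$day, pts$thickness_um)
  k_true <- cfg$layer_params$GCL$k
  expect_lt(abs(coef(fit)["k"] - k_true) / k_true, 0.1)
})

test_that("noiseless recovery is exact and SE of k shrinks like sqrt(n)", {
  cfg0 <- synthetic_config(n_crao_patients = 10, n_control_eyes = 5,
                           visits_min = 5, visits_max = 8, noise_sd = 0,
                           re_frac = 0, k_lnsd = 0, qc_fail_prob = 0)
  rep0 <- parameter_recovery_experiment(cfg0, n_replicates = 3, seed = 2)
  expect_lt(max(abs(rep0$params$bias)), 1e-5)
  expect_lt(max(rep0$params$median_rel_error), 1e-6)
  # sqrt-n scaling of the sampling SD of k-hat
  base <- synthetic_config(n_crao_patients = 15, n_control_eyes = 10,
                           visits_min = 4, visits_max = 8, noise_sd = 2,
                           re_frac = 0, k_lnsd = 0, qc_fail_prob = 0)
  dbl <- base; dbl$n_crao_patients <- 30; dbl$n_control_eyes <- 20
  k_of <- function(cfg, seeds) vapply(seeds, function(s) {
    cfg$seed <- s
    sim <- generate_cohort(cfg)
    df <- as.data.frame(sim$cohort)
    pts <- rbind(df[df$group == "CRAO" & df$layer == "GCL",
                    c("day", "thickness_um")],
                 suppressWarnings(baseline_from_controls(sim$cohort, "GCL")))
    unname(coef(fit_decay(pts$day, pts$thickness_um))["k"])
  }, 0)
  k1 <- k_of(base, 1000 + 1:150)
  k2 <- k_of(dbl, 5000 + 1:150)
  ratio <- sd(k2) / sd(k1)
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.85)
  expect_error(parameter_recovery_experiment(cfg0, n_replicates = 1),
               "at least 2")
})
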
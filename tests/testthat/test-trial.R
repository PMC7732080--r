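test_that("efficacy adjustment reproduces reported treated-endpoint cells", {
  cells <- list(
    list(t0 = 47.5, td = 23.8, e = 0.20, out = 28.5),
    list(t0 = 47.5, td = 15.9, e = 0.50, out = 31.7),
    list(t0 = 253.8, td = 164.1, e = 0.75, out = 231.4),
    list(t0 = 22.5, td = 19.4, e = 0.10, out = 19.7),
    list(t0 = 332.3, td = 289.1, e = 0.30, out = 302.1)
  )
  for (c_ in cells)
    expect_equal(round_half_up(
      efficacy_adjusted_thickness(c_$t0, c_$td, c_$e), 1), c_$out)
})

test_that("efficacy adjustment hits its endpoints and rejects bad input", {
  expect_equal(efficacy_adjusted_thickness(47.5, 23.8, 0), 23.8)
  expect_equal(efficacy_adjusted_thickness(47.5, 23.8, 1), 47.5)
  expect_error(efficacy_adjusted_thickness(47.5, 23.8, 1.2), "\\[0, 1\\]")
  expect_error(efficacy_adjusted_thickness(47.5, 23.8, -0.1), "\\[0, 1\\]")
  expect_error(efficacy_adjusted_thickness(0, 23.8, 0.5), "t0")
  # linear and monotone increasing in efficacy
  e <- seq(0, 1, by = 0.05)
  adj <- efficacy_adjusted_thickness(47.5, 23.8, e)
  expect_true(all(diff(adj) > 0))
  expect_equal(diff(adj), rep(diff(adj)[1], length(e) - 1), tolerance = 1e-12)
})

test_that("effect size is the adjusted-minus-untreated difference", {
  expect_equal(effect_size(47.5, 23.8, 0.20), 4.74, tolerance = 1e-12)
  expect_equal(effect_size(47.5, 15.9, 0.50), 15.8, tolerance = 1e-12)
  expect_equal(effect_size(47.5, 23.8, 0), 0)
})

test_that("sample size is the minimal n for the target power", {
  spec <- power_spec(sigma = 5)
  expect_equal(sample_size_per_group(5, spec), 17L)
  # n = 17 reaches 0.8 and n = 16 does not (noncentral-t check)
  expect_gte(power.t.test(n = 17, delta = 5, sd = 5)$power, 0.8)
  expect_lt(power.t.test(n = 16, delta = 5, sd = 5)$power, 0.8)
  # huge effect -> floor of 2 engaged
  expect_equal(sample_size_per_group(50, spec), 2L)
  expect_error(sample_size_per_group(0, spec), "positive")
  expect_error(sample_size_per_group(-1, spec), "positive")
})

test_that("sample size is monotone in effect size and noise", {
  spec <- function(s) power_spec(sigma = s)
  deltas <- c(1, 2, 4, 8)
  ns <- vapply(deltas, sample_size_per_group, 1L, spec = spec(5))
  expect_true(all(diff(ns) <= 0))
  sigmas <- c(2, 4, 8)
  ns2 <- vapply(sigmas, function(s) sample_size_per_group(3, spec(s)), 1L)
  expect_true(all(diff(ns2) >= 0))
})

test_that("noncentral-t and normal-approximation sizes differ by at most 2", {
  for (ds in c(0.3, 0.5, 0.8, 1.0)) for (a in c(0.01, 0.05, 0.1)) {
    spec <- power_spec(alpha = a, sigma = 1)
    n_t <- sample_size_per_group(ds, spec)
    n_z <- octdecay:::sample_size_normal_approx(ds, spec)
    if (n_t >= 15) expect_lte(abs(n_t - n_z), 2)
  }
})

test_that("empirical power behaves at its limits and is reproducible", {
  # size under the null
  p0 <- empirical_power(20, delta = 0, sigma = 1, alpha = 0.05,
                        reps = 5000, seed = 2)
  expect_lt(abs(p0 - 0.05), 3 * sqrt(0.05 * 0.95 / 5000))
  # asymptotic limit
  expect_gt(empirical_power(1000, delta = 1, sigma = 1, reps = 2000,
                            seed = 3), 0.999)
  # determinism
  expect_equal(empirical_power(17, 1, 1, reps = 1000, seed = 5),
               empirical_power(17, 1, 1, reps = 1000, seed = 5))
  expect_error(empirical_power(1, 1, 1), ">= 2")
  expect_error(empirical_power(10, 1, 1, reps = 10), ">= 1000")
})

ref_fits <- local({
  ref <- crao_reference_thickness()
  lapply(split(ref, ref$layer), function(d)
    fit_decay(thickness_um ~ day, data = d))
})

test_that("rebuilt GCL rows reproduce the reported treated thickness cells", {
  tab <- build_trial_table(ref_fits["GCL"],
                           t0_by_layer = c(GCL = 47.5),
                           days = c(30, 60, 90, 120, 180),
                           efficacies = c(0.10, 0.20, 0.30, 0.50, 0.75))
  reported <- rbind(
    c(26.2, 28.5, 30.9, 35.6, 41.6),
    c(19.0, 22.2, 25.4, 31.7, 39.6),
    c(16.8, 20.2, 23.6, 30.5, 39.0),
    c(16.1, 19.6, 23.1, 30.1, 38.8),
    c(15.8, 19.4, 22.9, 29.9, 38.7))
  got <- as.matrix(tab[, c("t10_um", "t20_um", "t30_um", "t50_um", "t75_um")])
  expect_lt(max(abs(got - reported)), 0.15)
})

test_that("the trial table respects the R-squared gate and its override", {
  set.seed(41)
  # a fit with low R2: wide scatter around a shallow curve
  days <- seq(0, 300, length.out = 40)
  th <- 40 - 0.005 * days + rnorm(40, sd = 6)
  weak <- fit_decay(days, th)
  expect_lt(weak$r.squared, 0.4)
  fits <- c(ref_fits["GCL"], list(WEAK = weak))
  names(fits) <- c("GCL", "INL")
  tab <- build_trial_table(fits, days = 30, efficacies = 0.2)
  expect_equal(unique(tab$layer), "GCL")
  exc <- attr(tab, "excluded")
  expect_equal(exc$layer, "INL")
  expect_match(exc$reason, "gate")
  forced <- build_trial_table(fits, days = 30, efficacies = 0.2,
                              force_layers = "INL")
  expect_setequal(unique(forced$layer), c("GCL", "INL"))
})

test_that("trial-table structure follows its invariants", {
  tab <- build_trial_table(ref_fits["GCL"], days = c(30, 90),
                           efficacies = c(0.1, 0.3, 0.75),
                           sigma_by_layer = c(GCL = 5))
  # adjusted thickness between untreated endpoint and baseline
  for (e in c("t10_um", "t30_um", "t75_um")) {
    expect_true(all(tab[[e]] >= tab$t_no_drug_um))
    expect_true(all(tab[[e]] <= tab$t0_um))
  }
  # n non-increasing in efficacy at fixed (layer, day)
  ns <- as.matrix(tab[, c("n10", "n30", "n75")])
  expect_true(all(apply(ns, 1, function(v) all(diff(v) <= 0))))
  expect_true(all(ns >= 2))
  # empty efficacies -> no efficacy columns
  e0 <- build_trial_table(ref_fits["GCL"], days = 30,
                          efficacies = numeric(0))
  expect_named(e0, c("layer", "day", "t0_um", "t_no_drug_um", "pct_change"))
  expect_error(build_trial_table(ref_fits["GCL"], days = -5,
                                 efficacies = 0.2), "non-negative")
})
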
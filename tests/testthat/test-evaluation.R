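# Harrell's C, prognostic indices, relative-hazard curves, bootstrap
# bands, risk grouping and derivation-to-validation transport.

test_that("Harrell's C hits its analytic anchors", {
  s <- small_random_surv(200, 1)
  expect_equal(harrell_c(rep(3.7, 200), s$time, s$event)$c, 0.5)
  # perfectly reverse-ranked predictions on an uncensored toy
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(harrell_c(rev(time), time, rep(1L, 10))$c, 1.0)
  expect_equal(harrell_c(time, time, rep(1L, 10))$c, 0.0)
})

test_that("harrell_c equals the exhaustive pair enumeration on random cohorts", {
  for (seed in 1:25) {
    n <- sample(5:50, 1)
    s <- small_random_surv(n, 400 + seed)
    got <- harrell_c(s$pred, s$time, s$event)
    want <- brute_force_c(s$pred, s$time, s$event)
    expect_identical(got$c, want$c)
    expect_identical(got$n_evaluable_pairs, want$n_evaluable_pairs)
    expect_identical(got$n_tied_prediction_pairs, want$n_tied_prediction_pairs)
  }
})

test_that("harrell_c agrees with the survival package's concordance on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(5)
  n <- 400
  t_ev <- rexp(n, 0.2 * exp(0.8 * (x <- rnorm(n))))
  t_cn <- rexp(n, 0.1)
  time <- pmin(t_ev, t_cn)
  event <- as.integer(t_ev <= t_cn)
  got <- harrell_c(x, time, event)$c
  ref <- survival::concordance(survival::Surv(time, event) ~ x, reverse = TRUE)
  expect_equal(got, unname(ref$concordance), tolerance = 1e-12)
})

test_that("harrell_c is a rank statistic", {
  s <- small_random_surv(80, 7)
  base <- harrell_c(s$pred, s$time, s$event)$c
  expect_equal(harrell_c(exp(s$pred / 2), s$time, s$event)$c, base)
  expect_equal(harrell_c(s$pred + 100, s$time, s$event)$c, base)
  # complement under negation when no tied predictions exist
  set.seed(8)
  pred <- rnorm(80)
  expect_equal(harrell_c(-pred, s$time, s$event)$c,
               1 - harrell_c(pred, s$time, s$event)$c)
})

test_that("the reference patient has relative hazard exactly 1", {
  co <- quick_cohort(n = 500, seed = 121)
  for (cls in c("dichotomized", "categorized", "fp", "rcs")) {
    m <- fit_model_class(co, cls)
    ref <- data.frame(age_years = 35, tumor_size_mm = 20, n_pos_nodes = 0L)
    expect_identical(exp(prognostic_index(m, ref)), 1.0)
  }
})

test_that("zero weights give an identically zero prognostic index", {
  co <- quick_cohort(n = 100, seed = 131)
  m <- suppressWarnings(fit_model_class(co, "categorized"))
  m$weights[] <- 0
  expect_equal(prognostic_index(m, co), rep(0, nrow(co)))
})

test_that("relative-hazard curves match their closed forms", {
  co <- quick_cohort(n = 400, seed = 141)
  m <- fit_model_class(co, "fp")
  # grid containing the reference passes through 1.00 there
  cv <- relative_hazard_curve(m, "tumor_size_mm", c(5, 20, 60))
  expect_equal(cv$relative_hazard[cv$x == 20], 1.0)
  # hand-built sqrt model: curve is exp(w (sqrt(x) - sqrt(20)))
  sp <- fp_spec("tumor_size_mm", 0.5)
  mm <- m
  mm$transforms <- list(tumor_size_mm = sp)
  mm$covariates <- "tumor_size_mm"
  mm$weights <- c(tumor_size_mm_fp1 = 0.4)
  cv2 <- relative_hazard_curve(mm, "tumor_size_mm", c(4, 9, 25))
  expect_equal(cv2$relative_hazard,
               exp(0.4 * (sqrt(c(4, 9, 25)) - sqrt(20))))
  # linear model with unit weight: exp(x - x_ref)
  ml <- mm
  ml$transforms <- list(tumor_size_mm = fp_spec("tumor_size_mm", 1))
  ml$weights <- c(tumor_size_mm_fp1 = 1)
  cv3 <- relative_hazard_curve(ml, "tumor_size_mm", 18:22)
  expect_equal(cv3$relative_hazard, exp(18:22 - 20))
  expect_error(relative_hazard_curve(m, "tumor_size_mm", numeric(0)), "empty")
})

test_that("bootstrap bands are reproducible, contain the reference, and cover a null effect", {
  co <- quick_cohort(n = 250, seed = 151)
  grid <- c(5, 10, 20, 35, 60)
  b1 <- bootstrap_band(co, "tumor_size_mm", grid, B = 30, seed = 9)
  b2 <- bootstrap_band(co, "tumor_size_mm", grid, B = 30, seed = 9)
  expect_identical(b1, b2)
  # every replicate passes through 1.00 at the reference size
  expect_equal(b1$lower[b1$x == 20], 1)
  expect_equal(b1$upper[b1$x == 20], 1)
  expect_true(all(b1$lower <= b1$upper))
  # no-effect simulation: the band should cover 1.00 at most grid points
  cfg <- cohort_config(n_patients = 300, seed = 161,
                       true_effects = c(age = 0, size = 0, nodes = 0),
                       baseline_hazard = 0.035)
  co0 <- generate_cohort(cfg)
  b0 <- bootstrap_band(co0, "tumor_size_mm", grid, B = 60, seed = 10)
  covered <- mean(b0$lower <= 1 & 1 <= b0$upper)
  expect_gte(covered, 0.8)
})

test_that("risk groups land on the requested percentiles for continuous indices", {
  set.seed(17)
  pi <- rnorm(5000)
  g <- make_risk_groups(pi)
  expect_equal(g$group_fractions, c(0.16, 0.34, 0.34, 0.16), tolerance = 0.01)
  expect_equal(g$achieved_percentiles, c(16, 50, 84), tolerance = 0.1)
  expect_equal(g$group_labels, c("G1", "G2", "G3", "G4"))
  expect_error(make_risk_groups(rep(1, 10)), "identical")
  expect_error(make_risk_groups(pi, c(50, 16, 84)), "increasing")
})

test_that("a cut-off never splits patients with identical prognostic indices", {
  pi <- rep(c(0, 1, 2, 3), times = c(10, 40, 40, 10))
  g <- make_risk_groups(pi, c(30, 50, 84))
  grp <- assign_risk_groups(pi, g)
  for (v in unique(pi)) expect_length(unique(grp[pi == v]), 1L)
  # achieved percentiles are reported, not the requested ones
  expect_false(isTRUE(all.equal(g$achieved_percentiles, g$source_percentiles)))
})

test_that("heavily tied categorized indices report achieved percentiles", {
  co <- quick_cohort(n = 2000, seed = 171)
  m <- fit_model_class(co, "categorized")
  pi <- prognostic_index(m, co)
  expect_lte(length(unique(pi)), 36L)
  g <- make_risk_groups(pi)
  expect_true(all(g$achieved_percentiles >= g$source_percentiles - 1e-9))
})

test_that("transport to the derivation cohort itself reproduces the derivation C exactly", {
  co <- quick_cohort(n = 700, seed = 181)
  m <- fit_model_class(co, "fp")
  pi <- prognostic_index(m, co)
  c_der <- harrell_c(pi, co$time_years, co$event)
  g <- make_risk_groups(pi)
  res <- transport_validate(m, g, co)
  expect_identical(res$c_index$c, c_der$c)
  expect_equal(res$group_fractions, g$group_fractions)
})

test_that("transport to a lower-risk cohort shifts the group occupancy and orders the HRs", {
  cfg <- cohort_config(n_patients = 2500, seed = 191)
  der <- generate_cohort(cfg)
  val <- generate_validation_cohort(cfg)
  m <- fit_model_class(der, "fp")
  g <- make_risk_groups(prognostic_index(m, der))
  res <- suppressWarnings(transport_validate(m, g, val))
  expect_gt(res$group_fractions[1L], 0.16)
  expect_lt(res$group_fractions[4L], 0.16)
  hr <- res$hr_vs_g1$hr
  expect_true(all(diff(hr) > 0))        # G2 < G3 < G4
  expect_true(all(hr > 1))
})

test_that("out-of-domain covariates are clamped with a warning, or rejected in strict mode", {
  co <- quick_cohort(n = 300, seed = 201)
  m <- fit_model_class(co, "fp")
  odd <- co[1:5, ]
  odd$tumor_size_mm <- max(co$tumor_size_mm) + 50
  expect_warning(prognostic_index(m, odd), "clamping")
  expect_error(prognostic_index(m, odd, out_of_domain = "strict"), "outside")
})
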
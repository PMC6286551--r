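# Cox engine, Kaplan-Meier estimator, Schoenfeld test and truncation.
# The survival package serves as an independent oracle where it implements
# the same estimand.

test_that("follow-up truncation recodes late events and is idempotent", {
  co <- data.frame(time_years = c(12.3, 9.1, 10.0, 15.2),
                   event = c(1L, 1L, 1L, 0L))
  tr <- truncate_followup(co, 10)
  expect_equal(tr$time_years, c(10, 9.1, 10, 10))
  expect_equal(tr$event, c(0L, 1L, 1L, 0L))
  expect_identical(truncate_followup(tr, 10), tr)
  expect_error(truncate_followup(co, -1), "positive")
})

test_that("cox_fit matches the survival package on continuous data", {
  skip_if_not_installed("survival")
  co <- quick_cohort(n = 800, seed = 21)
  X <- cbind(a = co$age_years, s = sqrt(co$tumor_size_mm), n = log1p(co$n_pos_nodes))
  fit <- cox_fit(X, co$time_years, co$event, co$stratum)
  ref <- survival::coxph(
    survival::Surv(co$time_years, co$event) ~ X + survival::strata(co$stratum),
    ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$covariance), unname(ref$var), tolerance = 1e-7)
  expect_equal(unname(fit$loglik["final"]), ref$loglik[2L], tolerance = 1e-9)
})

test_that("Efron tie handling matches the survival package on tied data", {
  skip_if_not_installed("survival")
  co <- quick_cohort(n = 500, seed = 22)
  tt <- pmax(round(co$time_years * 2) / 2, 0.5)     # force heavy ties
  X <- cbind(a = co$age_years, n = log1p(co$n_pos_nodes))
  for (m in c("breslow", "efron")) {
    fit <- cox_fit(X, tt, co$event, co$stratum, ties = m)
    ref <- survival::coxph(
      survival::Surv(tt, co$event) ~ X + survival::strata(co$stratum), ties = m)
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  }
})

test_that("Breslow and Efron coincide exactly without tied event times", {
  d <- toy_surv()
  fb <- cox_fit(cbind(d$x), d$time, d$event, ties = "breslow")
  fe <- cox_fit(cbind(d$x), d$time, d$event, ties = "efron")
  expect_equal(fb$coefficients, fe$coefficients, tolerance = 1e-9)
  expect_equal(fb$loglik, fe$loglik, tolerance = 1e-9)
})

test_that("a stratified fit over a single stratum equals the unstratified fit", {
  d <- toy_surv()
  f1 <- cox_fit(cbind(d$x), d$time, d$event)
  f2 <- cox_fit(cbind(d$x), d$time, d$event, strata = rep("only", nrow(d)))
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$loglik, f2$loglik)
})

test_that("the fitted partial likelihood is at least the null value", {
  for (seed in 1:5) {
    s <- small_random_surv(60, seed)
    f <- cox_fit(cbind(rnorm(60)), s$time, s$event)
    expect_gte(f$loglik[["final"]], f$loglik[["null"]])
  }
})

test_that("a zero-column design returns the null model", {
  d <- toy_surv()
  f0 <- cox_fit(matrix(numeric(0), nrow(d), 0), d$time, d$event)
  f1 <- cox_fit(cbind(d$x), d$time, d$event)
  expect_length(f0$coefficients, 0L)
  expect_equal(f0$loglik[["final"]], f1$loglik[["null"]])
})

test_that("degenerate designs and outcomes are rejected or flagged", {
  d <- toy_surv()
  expect_error(cox_fit(cbind(d$x, 2 * d$x), d$time, d$event), "collinear")
  expect_error(cox_fit(cbind(d$x), d$time, rep(0L, nrow(d))), "no events")
  # a stratum whose members are all censored contributes nothing and warns
  st <- replace(rep("a", nrow(d)), d$event == 0, "b")
  expect_warning(cox_fit(cbind(d$x), d$time, d$event, strata = st),
                 "zero events")
  # separation: a perfectly discriminating binary covariate
  xsep <- as.numeric(d$event == 1)
  w <- capture_warnings(cox_fit(cbind(xsep), d$time, d$event))
  expect_true(any(grepl("monotone", w)))
})

test_that("Kaplan-Meier matches hand computation on toy data", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$times, c(1, 2, 3))
  # all censored: flat at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_at(km0, 2.5)$survival, 1)
  # interleaved censoring, hand-tabulated product over event times:
  # events at 1 (5 at risk) and 4 (2 at risk): S = 4/5 * 1/2
  km1 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 0, 1, 0))
  expect_equal(km1$survival, c(4/5, 4/5 * 1/2))
})

test_that("Kaplan-Meier CIs match the survival package's log-log intervals", {
  skip_if_not_installed("survival")
  s <- small_random_surv(120, 31)
  km <- km_estimate(s$time, s$event)
  ref <- survival::survfit(survival::Surv(s$time, s$event) ~ 1,
                           conf.type = "log-log")
  at_ev <- ref$time %in% km$times & ref$n.event > 0
  expect_equal(km$survival, ref$surv[at_ev], tolerance = 1e-9)
  expect_equal(km$ci_lower, ref$lower[at_ev], tolerance = 1e-7)
  expect_equal(km$ci_upper, ref$upper[at_ev], tolerance = 1e-7)
})

test_that("KM on truncated data equals the untruncated curve restricted to the window", {
  co <- quick_cohort(n = 400, seed = 41, admin_cutoff = 50, censor_rate = 0.01)
  tr <- truncate_followup(co, 5)
  km_full <- km_estimate(co$time_years, co$event)
  km_tr <- km_estimate(tr$time_years, tr$event)
  keep <- km_full$times <= 5
  expect_equal(km_tr$times, km_full$times[keep])
  expect_equal(km_tr$survival, km_full$survival[keep])
})

test_that("the Schoenfeld test agrees with cox.zph on identity time", {
  # the package uses the classic score approximation with the average
  # residual variance; cox.zph uses a refined per-time variance, so the
  # statistics agree closely but not exactly
  skip_if_not_installed("survival")
  co <- quick_cohort(n = 700, seed = 51)
  df <- data.frame(time = co$time_years, event = co$event,
                   a = co$age_years, n = log1p(co$n_pos_nodes))
  fit <- cox_fit(cbind(a = df$a, n = df$n), df$time, df$event)
  ours <- schoenfeld_ph_test(fit)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(time, event) ~ a + n, data = df,
                    ties = "breslow"),
    transform = "identity", global = TRUE)
  expect_equal(ours$chisq, unname(ref$table[, "chisq"]), tolerance = 0.15)
  expect_equal(ours$df, unname(ref$table[, "df"]))
})

test_that("with one covariate the global Schoenfeld p equals the per-covariate p", {
  d <- quick_cohort(n = 300, seed = 61)
  fit <- cox_fit(cbind(x = sqrt(d$tumor_size_mm)), d$time_years, d$event)
  tab <- schoenfeld_ph_test(fit)
  expect_equal(tab$p[1L], tab$p[2L], tolerance = 1e-12)
})

test_that("the Schoenfeld test holds its level and detects a strong time-varying effect", {
  # level under proportional hazards
  rej <- vapply(1:150, function(s) {
    set.seed(1000 + s)
    n <- 250
    x <- rnorm(n)
    t_ev <- rexp(n, 0.1 * exp(0.5 * x))
    time <- pmin(t_ev, 12)
    event <- as.integer(t_ev <= 12)
    fit <- cox_fit(cbind(x), time, event)
    schoenfeld_ph_test(fit)$p[1L] < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.11)
  # power under a reversing effect: hazard depends on x only after t = 2
  rej2 <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 2000
    x <- rnorm(n)
    t1 <- rexp(n, 0.08 * exp(-0.8 * x))      # early: negative effect
    t2 <- 2 + rexp(n, 0.08 * exp(0.8 * x))   # late: positive effect
    t_ev <- ifelse(t1 < 2, t1, t2)
    time <- pmin(t_ev, 12)
    event <- as.integer(t_ev <= 12)
    fit <- cox_fit(cbind(x), time, event)
    schoenfeld_ph_test(fit)$p[1L] < 0.05
  }, logical(1))
  expect_gte(mean(rej2), 0.8)
})
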
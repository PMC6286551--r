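# Shared fixtures: all data are built in code at test time.

# hand-written toy survival data (no ties)
toy_surv <- function() {
  data.frame(time = c(1.2, 2.3, 3.1, 4.0, 5.5, 6.1, 7.9, 9.4),
             event = c(1, 0, 1, 1, 0, 1, 0, 1),
             x = c(0.5, -1.2, 1.8, 0.3, -0.7, 2.1, -1.5, 0.9))
}

# small random survival data with censoring and injected ties in both the
# times and the predictions
small_random_surv <- function(n, seed) {
  set.seed(seed)
  t_ev <- rexp(n, 0.2)
  t_cn <- rexp(n, 0.15)
  time <- round(pmin(t_ev, t_cn), 1)       # rounding injects tied times
  time[time == 0] <- 0.1
  event <- as.integer(t_ev <= t_cn)
  if (sum(event) == 0L) event[1L] <- 1L
  pred <- sample(round(rnorm(n), 1))       # rounding injects tied predictions
  list(time = time, event = event, pred = pred)
}

# independent double-loop oracle for Harrell's C under the package's
# evaluable-pair convention: times must differ and the earlier time must
# be an event; tied predictions count one half
brute_force_c <- function(pred, time, event) {
  conc <- 0; ties <- 0; ev <- 0
  n <- length(time)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j   # earlier patient
    b <- if (time[i] < time[j]) j else i
    if (event[a] != 1L) next
    ev <- ev + 1
    if (pred[a] > pred[b]) conc <- conc + 1
    else if (pred[a] == pred[b]) ties <- ties + 1
  }
  list(c = (conc + 0.5 * ties) / ev, n_evaluable_pairs = ev,
       n_tied_prediction_pairs = ties)
}

# a small synthetic cohort for fast pipeline-level tests
quick_cohort <- function(n = 600, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}
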
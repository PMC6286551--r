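# Stratified Cox partial-likelihood estimation, Kaplan-Meier curves,
# Schoenfeld proportional-hazards checking, and administrative truncation
# of follow-up. The Cox engine is written directly against the partial
# likelihood so that every downstream procedure (FP selection, MFP
# backfitting, bootstrap bands) controls its own likelihood evaluations.

#' Administratively truncate follow-up
#'
#' Records with observed time beyond `cutoff` are censored at `cutoff`;
#' all other records are unchanged. Truncation is idempotent.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]); any data
#'   frame with `time_years` and `event` columns is accepted.
#' @param cutoff truncation time in years (default 10).
#' @return the cohort with truncated `time_years`/`event`.
#' @export
truncate_followup <- function(cohort, cutoff = 10) {
  if (!is_num1(cutoff) || cutoff <= 0) fail("cutoff must be a positive number")
  over <- cohort$time_years > cutoff
  cohort$event[over] <- 0L
  cohort$time_years[over] <- cutoff
  cohort
}

# Precompute the sorted per-stratum structures the partial likelihood
# needs; these depend only on the outcome, so they are shared across the
# many candidate designs fitted during FP selection. Within each stratum
# observations are ordered by decreasing time, so the risk set of an event
# at time t is a prefix of the ordering; `riskidx` maps each position to
# the last position of its tie block (risk sets at tied times include the
# whole block).

#' Precompute the outcome ordering for repeated Cox fits
#'
#' Sorts and indexes the outcome once so that many designs can be fitted
#' against the same times, events and strata without repeating the work;
#' pass the result to [cox_fit()]'s `outcome` argument.
#'
#' @inheritParams cox_fit
#' @return an opaque `cox_outcome` object.
#' @export
cox_outcome <- function(time, event, strata = NULL) {
  n <- length(time)
  if (is.null(strata)) strata <- rep.int(1L, n)
  strata <- as.factor(strata)
  if (length(event) != n || length(strata) != n)
    fail("time, event and strata must have matching lengths")
  if (any(time <= 0)) fail("all observation times must be positive")
  if (!all(event %in% c(0, 1))) fail("event must be coded 0/1")

  ord <- order(strata, -time)
  time <- time[ord]; event <- as.integer(event[ord]); strata <- strata[ord]

  blocks <- split(seq_len(n), strata)
  ev_per_stratum <- vapply(blocks, function(ix) sum(event[ix]), 0L)
  if (any(ev_per_stratum == 0L))
    warning("stratum with zero events contributes nothing to the partial likelihood: ",
            paste(names(blocks)[ev_per_stratum == 0L], collapse = ", "))

  # last index of each tie run, computed within stratum blocks
  riskidx <- integer(n)
  for (ix in blocks) {
    r <- rle(time[ix])
    ends <- cumsum(r$lengths)
    riskidx[ix] <- ix[rep.int(ends, r$lengths)]
  }
  starts <- vapply(blocks, `[`, 0L, 1L)

  out <- list(time = time, event = event, strata = strata,
              ord = ord, riskidx = riskidx, block_starts = starts,
              blocks = blocks, n = n, n_events = sum(event),
              event_pos = which(event == 1L))
  class(out) <- "cox_outcome"
  out
}

cox_prep <- function(design, outcome) {
  if (NROW(design) != outcome$n)
    fail("design and outcome must have matching lengths")
  prep <- unclass(outcome)
  prep$design <- design[outcome$ord, , drop = FALSE]
  prep
}

# cumulative sums restarting at each stratum block (input already ordered)
block_cumsum <- function(v, prep) {
  cs <- cumsum(v)
  base <- cs[prep$block_starts] - v[prep$block_starts]
  offset <- numeric(length(v))
  for (k in seq_along(prep$blocks)) offset[prep$blocks[[k]]] <- base[k]
  cs - offset
}

# Log partial likelihood, score and observed information at beta.
# Breslow is fully vectorised; Efron corrects tie groups (d > 1) one by one.
cox_ll <- function(beta, prep, ties = "breslow", want_hess = TRUE) {
  X <- prep$design; p <- ncol(X)
  eta <- if (p > 0L) drop(X %*% beta) else numeric(prep$n)
  eta <- eta - max(eta)                      # guard against overflow
  w <- exp(eta)
  ev <- prep$event_pos
  ri <- prep$riskidx[ev]

  cum0 <- block_cumsum(w, prep)
  S0 <- cum0[ri]
  ll <- sum(eta[ev]) - sum(log(S0))
  if (p == 0L) return(list(ll = ll, U = numeric(0), I = matrix(0, 0, 0)))

  cum1 <- matrix(0, prep$n, p)
  for (j in seq_len(p)) cum1[, j] <- block_cumsum(w * X[, j], prep)
  S1 <- cum1[ri, , drop = FALSE]
  Sbar <- S1 / S0
  U <- colSums(X[ev, , drop = FALSE] - Sbar)

  I <- NULL
  if (want_hess) {
    I <- matrix(0, p, p)
    for (j in seq_len(p)) for (k in j:p) {
      c2 <- block_cumsum(w * X[, j] * X[, k], prep)
      v <- sum(c2[ri] / S0 - Sbar[, j] * Sbar[, k])
      I[j, k] <- v; I[k, j] <- v
    }
  }

  if (ties == "efron") {
    # identify event tie groups of size > 1 and replace their Breslow
    # contribution with the Efron one
    key <- paste(prep$strata[ev], prep$time[ev])
    grp <- split(seq_along(ev), key)
    for (g in grp) {
      d <- length(g)
      if (d == 1L) next
      ge <- ev[g]                       # positions of the tied events
      S0g <- cum0[prep$riskidx[ge[1L]]]
      S1g <- cum1[prep$riskidx[ge[1L]], , drop = FALSE]
      Wd <- sum(w[ge])
      X1d <- colSums(w[ge] * X[ge, , drop = FALSE])
      X2d <- crossprod(sqrt(w[ge]) * X[ge, , drop = FALSE])
      S2g <- matrix(0, p, p)
      for (j in seq_len(p)) for (k in j:p) {
        v <- block_cumsum(w * X[, j] * X[, k], prep)[prep$riskidx[ge[1L]]]
        S2g[j, k] <- v; S2g[k, j] <- v
      }
      l <- seq_len(d) - 1
      den <- S0g - (l / d) * Wd
      # remove Breslow terms for this group, add Efron terms
      ll <- ll + d * log(S0g) - sum(log(den))
      num1 <- drop(S1g)                  # p-vector
      for (li in seq_len(d)) {
        nl <- num1 - ((li - 1) / d) * X1d
        U <- U + drop(S1g) / S0g - nl / den[li]
        if (want_hess) {
          A <- (S2g - ((li - 1) / d) * X2d) / den[li] - tcrossprod(nl / den[li])
          B <- S2g / S0g - tcrossprod(num1 / S0g)
          I <- I + A - B
        }
      }
    }
  }
  list(ll = ll, U = U, I = I)
}

#' Fit a stratified Cox proportional-hazards model
#'
#' Maximizes the stratified Cox partial likelihood by Newton-Raphson with
#' step-halving. The baseline hazard is left unspecified separately within
#' each stratum; tied event times are handled by the Breslow (default) or
#' Efron approximation.
#'
#' Convergence is declared when the largest absolute score component falls
#' below `score_tol` or the relative change in log partial likelihood falls
#' below `loglik_tol`. A coefficient exceeding `coef_guard` in absolute
#' value flags monotone likelihood (separation).
#'
#' @param design numeric matrix of covariate columns (may have 0 columns,
#'   giving the null model).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param strata optional stratum labels (factor or character); `NULL`
#'   fits a single stratum.
#' @param ties `"breslow"` or `"efron"`.
#' @param max_iter maximum Newton iterations.
#' @param score_tol,loglik_tol convergence tolerances.
#' @param coef_guard magnitude at which a coefficient is flagged as
#'   separated.
#' @param outcome optional precomputed [cox_outcome()]; when supplied,
#'   `time`, `event` and `strata` are ignored.
#' @return an object of class `cox_fit`: coefficients, covariance
#'   (inverse observed information), log partial likelihood at the null
#'   and fitted coefficients, event count, stratum labels, ties method,
#'   convergence diagnostics, and the data needed for residuals.
#' @export
cox_fit <- function(design, time = NULL, event = NULL, strata = NULL,
                    ties = c("breslow", "efron"),
                    max_iter = 100L, score_tol = 1e-8, loglik_tol = 1e-10,
                    coef_guard = 15, outcome = NULL) {
  ties <- match.arg(ties)
  design <- as.matrix(design)
  if (is.null(colnames(design)) && ncol(design) > 0L)
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  p <- ncol(design)
  if (is.null(outcome)) outcome <- cox_outcome(time, event, strata)
  prep <- cox_prep(design, outcome)
  if (prep$n_events == 0L) fail("no events: the partial likelihood is undefined")

  ll0 <- cox_ll(numeric(p), prep, ties, want_hess = FALSE)$ll
  if (p == 0L) {
    out <- list(coefficients = numeric(0), covariance = matrix(0, 0, 0),
                loglik = c(null = ll0, final = ll0), n = prep$n,
                n_events = prep$n_events, strata_labels = levels(prep$strata),
                ties_method = ties, iterations = 0L, converged = TRUE,
                separation = FALSE, prep = prep)
    class(out) <- "cox_fit"
    return(out)
  }
  if (qr(design)$rank < p) fail("design columns are collinear")

  beta <- numeric(p)
  cur <- cox_ll(beta, prep, ties)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U),
                     error = function(e) fail("information matrix is singular"))
    cand <- beta + step
    new <- cox_ll(cand, prep, ties)
    halvings <- 0L
    # halve on likelihood decrease or numerical failure (overflowing basis
    # columns under extreme FP powers can yield non-finite candidates)
    while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) && halvings < 30L) {
      halvings <- halvings + 1L
      cand <- beta + step / 2^halvings
      new <- cox_ll(cand, prep, ties)
    }
    if (!is.finite(new$ll) || any(!is.finite(new$U))) break
    rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1e-300)
    beta <- cand; cur <- new
    if (max(abs(cur$U)) < score_tol || rel < loglik_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("Newton-Raphson did not converge in %d iterations (max |score| = %.3g)",
                    max_iter, max(abs(cur$U))))
  separation <- any(abs(beta) > coef_guard)
  if (separation)
    warning("possible monotone likelihood: a coefficient exceeds the magnitude guard")

  covariance <- solve(cur$I)
  names(beta) <- colnames(design)
  dimnames(covariance) <- list(colnames(design), colnames(design))
  out <- list(coefficients = beta, covariance = covariance,
              loglik = c(null = ll0, final = cur$ll), n = prep$n,
              n_events = prep$n_events, strata_labels = levels(prep$strata),
              ties_method = ties, iterations = iter, converged = converged,
              separation = separation, prep = prep)
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Stratified Cox model (", x$ties_method, " ties), ",
      x$n, " subjects, ", x$n_events, " events, ",
      length(x$strata_labels), " strata\n", sep = "")
  if (length(x$coefficients)) {
    se <- sqrt(diag(x$covariance))
    z <- x$coefficients / se
    tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                      se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
                      check.names = FALSE)
    print(tab, digits = 4)
  } else cat("null model\n")
  cat(sprintf("log partial likelihood: %.4f (null %.4f)\n",
              x$loglik["final"], x$loglik["null"]))
  invisible(x)
}

#' Coefficient table with confidence intervals
#'
#' @param fit a `cox_fit`.
#' @param conf_level confidence level for the Wald intervals.
#' @return data frame with coefficients, hazard ratios and CI limits.
#' @export
cox_coef_table <- function(fit, conf_level = 0.95) {
  se <- sqrt(diag(fit$covariance))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(fit$coefficients), coef = unname(fit$coefficients),
             se = unname(se), hr = exp(unname(fit$coefficients)),
             hr_lower = exp(unname(fit$coefficients) - z * se),
             hr_upper = exp(unname(fit$coefficients) + z * se))
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimate of the survival function with Greenwood variance
#' and log(-log) confidence intervals.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `km_curve`: `times` (distinct event times),
#'   `survival`, `at_risk`, `n_events`, `ci_lower`, `ci_upper`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) < 1L) fail("need at least one observation")
  if (length(time) != length(event)) fail("time and event lengths differ")
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    out <- list(times = numeric(0), survival = numeric(0),
                at_risk = integer(0), n_events = integer(0),
                ci_lower = numeric(0), ci_upper = numeric(0))
    class(out) <- "km_curve"
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(time >= t), 0)
  d <- vapply(et, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - d / n_risk)
  # Greenwood on the log scale, then log(-log) intervals
  gw <- cumsum(d / (n_risk * (n_risk - d)))
  gw[!is.finite(gw)] <- Inf
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- hi <- rep(NA_real_, length(surv))
  ok <- surv > 0 & surv < 1 & is.finite(gw)
  se_cll <- sqrt(gw[ok]) / abs(log(surv[ok]))
  lo[ok] <- surv[ok]^exp(z * se_cll)
  hi[ok] <- surv[ok]^exp(-z * se_cll)
  out <- list(times = et, survival = surv, at_risk = n_risk, n_events = d,
              ci_lower = lo, ci_upper = hi)
  class(out) <- "km_curve"
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve a `km_curve`.
#' @param at times at which to read off the step function.
#' @return list with `survival`, `ci_lower`, `ci_upper` at `at`.
#' @export
km_at <- function(curve, at) {
  pick <- function(v) {
    vapply(at, function(t) {
      i <- which(curve$times <= t)
      if (length(i) == 0L) 1.0 else v[max(i)]
    }, 0.0)
  }
  list(survival = pick(curve$survival),
       ci_lower = pick(ifelse(is.na(curve$ci_lower), 1, curve$ci_lower)),
       ci_upper = pick(ifelse(is.na(curve$ci_upper), 1, curve$ci_upper)))
}

#' Schoenfeld test of proportional hazards
#'
#' Correlates (scaled) Schoenfeld residuals with a transform of event time,
#' giving a 1-df chi-square test per covariate and a global p-df test.
#' Residuals are computed from the fitted model's stratified risk sets.
#'
#' @param fit a `cox_fit` with at least one covariate.
#' @param transform time transform for the test: `"identity"` (default)
#'   or `"rank"` (ranks of the event times).
#' @return data frame with one row per covariate plus a `GLOBAL` row:
#'   `chisq`, `df`, `p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = c("identity", "rank")) {
  transform <- match.arg(transform)
  p <- length(fit$coefficients)
  if (p < 1L) fail("the model has no covariates")
  prep <- fit$prep
  d <- prep$n_events
  if (d < 2L) fail("too few events to compute Schoenfeld residuals")

  ll <- cox_ll(fit$coefficients, prep, fit$ties_method, want_hess = TRUE)
  # Schoenfeld residuals: x_k - E[x | risk set at t_k]
  eta <- drop(prep$design %*% fit$coefficients)
  w <- exp(eta - max(eta))
  ev <- prep$event_pos
  ri <- prep$riskidx[ev]
  cum0 <- block_cumsum(w, prep)
  S <- matrix(0, length(ev), p)
  for (j in seq_len(p)) {
    c1 <- block_cumsum(w * prep$design[, j], prep)
    S[, j] <- prep$design[ev, j] - c1[ri] / cum0[ri]
  }
  tev <- prep$time[ev]
  g <- switch(transform, identity = tev, rank = rank(tev))
  gc <- g - mean(g)
  u <- drop(crossprod(gc, S))                 # p-vector
  V <- solve(ll$I)                            # I^{-1}
  denom <- sum(gc^2)
  per <- d * drop(V %*% u)^2 / (diag(V) * denom)
  glob <- d * drop(crossprod(u, V %*% u)) / denom
  out <- data.frame(
    term = c(names(fit$coefficients), "GLOBAL"),
    chisq = c(per, glob),
    df = c(rep(1L, p), p),
    p = c(stats::pchisq(per, 1, lower.tail = FALSE),
          stats::pchisq(glob, p, lower.tail = FALSE)))
  rownames(out) <- NULL
  out
}
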
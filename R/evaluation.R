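# Discrimination and presentation layer: prognostic indices, Harrell's
# concordance index, relative-hazard curves with bootstrap percentile
# bands, percentile-based risk groups, and derivation-to-validation
# transport of a fitted model.

#' Reference patient used to anchor relative hazards
#'
#' Age 35 years, tumor size 20 mm and 0 positive lymph nodes; the relative
#' hazard at these values is 1.00 by definition.
#' @export
reference_values <- function() {
  c(age_years = 35, tumor_size_mm = 20, n_pos_nodes = 0)
}

# Assemble a prognostic model from per-covariate transform specs: evaluate
# the bases, jointly fit the Cox model, and record reference values and
# derivation covariate ranges (used by the transport clamp policy).
build_prognostic_model <- function(cohort, specs, class_name,
                                   ties = "breslow", stratified = TRUE,
                                   reference = reference_values(),
                                   extra = list()) {
  covs <- names(specs)
  design <- do.call(cbind, lapply(covs, function(v)
    transform_basis(cohort[[v]], specs[[v]])))
  # Columns that carry no information are fixed at weight zero: all-zero
  # dummies (unobserved category), collinear directions (e.g. an
  # unobserved reference category leaves the remaining dummies summing to
  # a constant, which the partial likelihood cannot identify), and
  # columns whose null information vanishes (a lone category member never
  # present in any risk set).
  strata <- if (stratified) cohort$stratum else NULL
  outcome <- cox_outcome(cohort$time_years, cohort$event, strata)
  informative <- apply(design != 0, 2, any)
  fit <- NULL
  repeat {
    sub <- design[, informative, drop = FALSE]
    qd <- qr(sub)
    if (qd$rank < ncol(sub))
      informative[informative][-sort(qd$pivot[seq_len(qd$rank)])] <- FALSE
    sub <- design[, informative, drop = FALSE]
    fit <- tryCatch(cox_fit(sub, outcome = outcome, ties = ties),
                    error = function(e) e)
    if (!inherits(fit, "error")) break
    if (!grepl("singular", conditionMessage(fit)) || ncol(sub) == 0L)
      stop(fit)
    I0 <- cox_ll(numeric(ncol(sub)), cox_prep(sub, outcome), ties)$I
    informative[informative][which.min(diag(I0))] <- FALSE
  }
  if (!all(informative))
    warning("empty or inestimable design column(s): ",
            paste(colnames(design)[!informative], collapse = ", "),
            "; their weights are fixed at zero")
  weights <- stats::setNames(numeric(ncol(design)), colnames(design))
  weights[names(fit$coefficients)] <- fit$coefficients
  ranges <- lapply(covs, function(v) range(cohort[[v]]))
  names(ranges) <- covs
  out <- c(list(class_name = class_name, covariates = covs,
                transforms = specs, weights = weights,
                reference_values = reference[covs], ranges = ranges,
                fit = fit, stratified = stratified),
           extra)
  class(out) <- "prognostic_model"
  out
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat("Prognostic model (", x$class_name, "): ",
      paste(x$covariates, collapse = ", "), "\n", sep = "")
  for (v in x$covariates) {
    sp <- x$transforms[[v]]
    desc <- switch(sp$kind,
      fp = if (sp$degree == 0) "excluded"
           else paste0("FP powers (", paste(sp$powers, collapse = ", "), ")"),
      rcs = paste0("RCS knots {", paste(sp$knots, collapse = ", "), "}"),
      category = paste0("categories ", paste(sp$labels, collapse = "/")))
    cat("  ", v, ": ", desc, "\n", sep = "")
  }
  cat(sprintf("%d coefficients, %d events\n",
              length(x$weights), x$fit$n_events))
  invisible(x)
}

# clamp covariates to the derivation range; strict mode errors instead
clamp_covariate <- function(x, rng, name, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  out_lo <- x < rng[1L]; out_hi <- x > rng[2L]
  if (any(out_lo | out_hi)) {
    if (policy == "strict")
      fail("%d value(s) of %s outside the derivation range [%g, %g]",
           sum(out_lo | out_hi), name, rng[1L], rng[2L])
    warning(sprintf("clamping %d value(s) of %s to the derivation range [%g, %g]",
                    sum(out_lo | out_hi), name, rng[1L], rng[2L]))
    x[out_lo] <- rng[1L]; x[out_hi] <- rng[2L]
  }
  x
}

#' Prognostic index of a cohort under a fitted model
#'
#' The prognostic index (PI) is the Cox linear predictor -- the weighted
#' sum of transformed covariates -- centered so that the reference patient
#' (age 35 years, 20 mm, 0 nodes) has PI 0 and hence relative hazard
#' `exp(PI) = 1.00`.
#'
#' @param model a `prognostic_model`.
#' @param cohort cohort data frame with the model's covariates.
#' @param out_of_domain policy for covariates outside the derivation
#'   range: `"clamp"` (with a warning) or `"strict"` (error).
#' @return numeric PI vector.
#' @export
prognostic_index <- function(model, cohort, out_of_domain = c("clamp", "strict")) {
  out_of_domain <- match.arg(out_of_domain)
  pi <- numeric(nrow(cohort))
  for (v in model$covariates) {
    sp <- model$transforms[[v]]
    ncols <- ncol(transform_basis(model$reference_values[v], sp))
    if (ncols == 0L) next
    x <- clamp_covariate(cohort[[v]], model$ranges[[v]], v, out_of_domain)
    b <- transform_basis(x, sp)
    w <- model$weights[colnames(b)]
    ref <- transform_basis(model$reference_values[v], sp)
    pi <- pi + unname(drop(b %*% w)) - unname(drop(ref %*% w))
  }
  pi
}

#' Harrell's concordance index for censored survival data
#'
#' A pair of patients is evaluable when their observed times differ and
#' the shorter time ends in an event. A pair is concordant when the
#' patient with the shorter time has the higher predicted hazard; tied
#' predictions contribute one-half. Pairs with equal observed times are
#' never evaluable (including double events).
#'
#' @param predicted_hazard risk score (any scale; only ranks matter).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return object of class `cindex`: `c`, `n_evaluable_pairs`,
#'   `n_tied_prediction_pairs`.
#' @export
harrell_c <- function(predicted_hazard, time, event) {
  n <- length(time)
  if (length(predicted_hazard) != n || length(event) != n)
    fail("input lengths differ")
  if (sum(event) < 1L) fail("need at least one event")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; pred <- predicted_hazard[ord]

  concord <- 0; tied <- 0; evaluable <- 0
  # end of each tie block of observed time, in sorted order
  r <- rle(time)
  block_end <- rep.int(cumsum(r$lengths), r$lengths)
  for (i in which(event == 1L)) {
    lo <- block_end[i] + 1L       # strictly later observed times
    if (lo > n) next
    later <- pred[lo:n]
    evaluable <- evaluable + length(later)
    concord <- concord + sum(pred[i] > later)
    tied <- tied + sum(pred[i] == later)
  }
  if (evaluable == 0) fail("no evaluable pairs")
  out <- list(c = (concord + 0.5 * tied) / evaluable,
              n_evaluable_pairs = evaluable,
              n_tied_prediction_pairs = tied)
  class(out) <- "cindex"
  out
}

#' @export
print.cindex <- function(x, ...) {
  cat(sprintf("Harrell's C = %.3f (%d evaluable pairs, %d with tied predictions)\n",
              x$c, x$n_evaluable_pairs, x$n_tied_prediction_pairs))
  invisible(x)
}

#' Relative-hazard curve for one covariate
#'
#' Evaluates `exp(PI)` along a grid of one covariate with the model's
#' other covariates held at their reference values, i.e. the univariable
#' relative hazard versus the covariate's reference value.
#'
#' @param model a `prognostic_model` containing the covariate.
#' @param covariate covariate name.
#' @param grid covariate values at which to evaluate.
#' @return data frame with `x` and `relative_hazard`.
#' @export
relative_hazard_curve <- function(model, covariate, grid) {
  if (length(grid) == 0L) fail("empty grid")
  if (!covariate %in% model$covariates) fail("covariate not in model")
  sp <- model$transforms[[covariate]]
  b <- transform_basis(grid, sp)
  if (ncol(b) == 0L)
    return(data.frame(x = grid, relative_hazard = rep(1, length(grid))))
  w <- model$weights[colnames(b)]
  ref <- transform_basis(model$reference_values[covariate], sp)
  data.frame(x = grid,
             relative_hazard = exp(drop(b %*% w) - drop(ref %*% w)))
}

#' Bootstrap percentile band for a relative-hazard curve
#'
#' Resamples patients with replacement (within strata, preserving stratum
#' sizes), reruns the closed-test FP selection and the univariable Cox fit
#' on each replicate, evaluates the relative-hazard curve on the grid, and
#' returns pointwise percentile limits. Model selection is inside the
#' loop, so the band reflects selection uncertainty as well as estimation
#' uncertainty.
#'
#' @param cohort cohort data frame.
#' @param covariate covariate name.
#' @param grid evaluation grid.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed RNG seed (required for a reproducible band).
#' @param alpha closed-test level used inside each replicate.
#' @param probs lower/upper band percentiles.
#' @param stratified stratify resampling and fitting by `stratum`.
#' @return data frame with `x`, `lower`, `upper`, and the number of
#'   replicates used as attribute `B_used`; replicate failures are skipped,
#'   and more than 10% failures aborts.
#' @export
bootstrap_band <- function(cohort, covariate, grid, B = 1000L, seed = 1L,
                           alpha = 0.05, probs = c(0.025, 0.975),
                           stratified = TRUE) {
  if (B < 2L) fail("need at least 2 bootstrap replicates")
  set.seed(seed)
  idx_by_stratum <- if (stratified) split(seq_len(nrow(cohort)), cohort$stratum)
                    else list(seq_len(nrow(cohort)))
  curves <- matrix(NA_real_, B, length(grid))
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- unlist(lapply(idx_by_stratum, function(ix)
      ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
    boot <- cohort[idx, , drop = FALSE]
    res <- tryCatch(suppressWarnings({
      sel <- select_fp(boot[[covariate]], boot$time_years, boot$event,
                       if (stratified) boot$stratum else NULL,
                       alpha = alpha)
      sel$spec$covariate <- covariate
      m <- build_prognostic_model(boot, stats::setNames(list(sel$spec), covariate),
                                  class_name = "fp", stratified = stratified)
      relative_hazard_curve(m, covariate, grid)$relative_hazard
    }), error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else curves[b, ] <- res
  }
  if (failures > 0.1 * B)
    fail("%d of %d bootstrap replicates failed", failures, B)
  qs <- apply(curves[stats::complete.cases(curves), , drop = FALSE], 2,
              stats::quantile, probs = probs, names = FALSE)
  out <- data.frame(x = grid, lower = qs[1L, ], upper = qs[2L, ])
  attr(out, "B_used") <- B - failures
  out
}

#' Percentile-based risk groups on the prognostic-index scale
#'
#' Cut-offs are placed at the requested nearest-rank percentiles of the PI
#' distribution, giving four groups G1 (lowest risk) to G4 for the default
#' 16/50/84 percentiles. Because cut-offs are observed PI values and group
#' assignment uses strict inequality above each cut-off, patients with
#' identical PIs are never split; with heavily tied PIs (categorized
#' models) the achieved group fractions can differ from the requested
#' ones, and both are reported.
#'
#' @param pi prognostic-index vector.
#' @param percentiles strictly increasing percentiles in (0, 100).
#' @return object of class `risk_grouping`: `pi_cutoffs`, `group_labels`,
#'   `source_percentiles`, `achieved_percentiles`, `group_fractions`.
#' @export
make_risk_groups <- function(pi, percentiles = c(16, 50, 84)) {
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0 | percentiles >= 100))
    fail("percentiles must be strictly increasing and inside (0, 100)")
  if (length(unique(pi)) == 1L) fail("all prognostic indices are identical")
  cutoffs <- pct_nearest_rank(pi, percentiles)
  if (anyDuplicated(cutoffs))
    warning("tied prognostic indices collapse adjacent cut-offs; a group will be empty")
  achieved <- vapply(cutoffs, function(cc) 100 * mean(pi <= cc), 0.0)
  grp <- assign_risk_groups(pi, cutoffs)
  out <- list(pi_cutoffs = cutoffs,
              group_labels = paste0("G", seq_len(length(cutoffs) + 1L)),
              source_percentiles = percentiles,
              achieved_percentiles = achieved,
              group_fractions = as.numeric(table(factor(grp, seq_len(length(cutoffs) + 1L)))) / length(pi))
  class(out) <- "risk_grouping"
  out
}

#' Assign risk-group indices given PI cut-offs
#'
#' @param pi prognostic indices.
#' @param cutoffs increasing cut-off values (PI scale); values equal to a
#'   cut-off fall in the lower group.
#' @return integer group indices 1..(length(cutoffs) + 1).
#' @export
assign_risk_groups <- function(pi, cutoffs) {
  if (inherits(cutoffs, "risk_grouping")) cutoffs <- cutoffs$pi_cutoffs
  1L + rowSums(outer(pi, cutoffs, `>`))
}

#' Transport a derivation model to a validation cohort
#'
#' Applies the derivation transforms and weights unchanged (no refitting)
#' to compute validation prognostic indices, then evaluates discrimination
#' there: Harrell's C, the sizes of the risk groups formed by the
#' derivation PI cut-offs, per-group Kaplan-Meier curves, and hazard
#' ratios of G2..G4 versus G1 from a Cox fit on group indicators.
#'
#' @param model a `prognostic_model` fitted on the derivation set.
#' @param grouping a `risk_grouping` from the derivation PIs.
#' @param validation validation cohort data frame.
#' @param out_of_domain clamp-and-warn (default) or strict domain policy.
#' @return list with `c_index` (a `cindex`), `pi`, `groups`,
#'   `group_fractions`, `group_km` (per-group `km_curve`s), and
#'   `hr_vs_g1` (data frame of HRs with 95% CIs).
#' @export
transport_validate <- function(model, grouping, validation,
                               out_of_domain = c("clamp", "strict")) {
  pi <- prognostic_index(model, validation, out_of_domain)
  cidx <- harrell_c(pi, validation$time_years, validation$event)
  grp <- assign_risk_groups(pi, grouping$pi_cutoffs)
  ngrp <- length(grouping$pi_cutoffs) + 1L
  fracs <- as.numeric(table(factor(grp, seq_len(ngrp)))) / length(pi)
  km <- lapply(seq_len(ngrp), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NULL)
    km_estimate(validation$time_years[sel], validation$event[sel])
  })
  names(km) <- grouping$group_labels
  hr <- NULL
  present <- sort(unique(grp))
  if (length(present) > 1L && 1L %in% present) {
    gm <- matrix(0, length(grp), ngrp - 1L)
    for (g in 2:ngrp) gm[, g - 1L] <- as.numeric(grp == g)
    colnames(gm) <- paste0(grouping$group_labels[-1L], " vs G1")
    keep <- colSums(gm) > 0
    gfit <- cox_fit(gm[, keep, drop = FALSE],
                    validation$time_years, validation$event)
    hr <- cox_coef_table(gfit)
  }
  list(c_index = cidx, pi = pi, groups = grp, group_fractions = fracs,
       group_km = km, hr_vs_g1 = hr)
}
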
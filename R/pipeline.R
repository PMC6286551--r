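# Orchestration of the full study replica: generate or load cohorts,
# truncate follow-up, fit the requested model classes on the identical
# derivation cohort, evaluate discrimination, form percentile risk groups,
# transport each model to the validation cohort, and emit a report.

#' Study configuration
#'
#' @param derivation,validation either `cohort_config` objects (synthetic
#'   cohorts are generated) or paths to cohort CSV files.
#' @param model_classes subset of `"dichotomized"`, `"categorized"`,
#'   `"fp"`, `"rcs"`.
#' @param alpha closed-test level for FP selection.
#' @param risk_percentiles PI percentiles defining the risk groups.
#' @param bootstrap_B bootstrap replicates for relative-hazard bands
#'   (0 disables the bands).
#' @param seed seed for the bootstrap stream (cohort generation uses the
#'   seeds inside the cohort configs; fitting is deterministic).
#' @param admin_cutoff follow-up truncation in years.
#' @param exclude_max_nodes,exclude_tiny_tumors sensitivity switches: drop
#'   the single patient with the most positive nodes, and/or all tumors
#'   of 2 mm or less.
#' @param ties ties method for all Cox fits.
#' @return a `study_config` list.
#' @export
study_config <- function(derivation = cohort_config(),
                         validation = validation_config(derivation),
                         model_classes = c("dichotomized", "categorized", "fp", "rcs"),
                         alpha = 0.05,
                         risk_percentiles = c(16, 50, 84),
                         bootstrap_B = 0L,
                         seed = 1L,
                         admin_cutoff = 10,
                         exclude_max_nodes = FALSE,
                         exclude_tiny_tumors = FALSE,
                         ties = "breslow") {
  model_classes <- match.arg(model_classes,
                             c("dichotomized", "categorized", "fp", "rcs"),
                             several.ok = TRUE)
  if (length(model_classes) < 1L) fail("at least one model class is required")
  if (!is_num1(alpha) || alpha <= 0 || alpha >= 1) fail("alpha must lie in (0, 1)")
  structure(list(derivation = derivation, validation = validation,
                 model_classes = model_classes, alpha = alpha,
                 risk_percentiles = risk_percentiles,
                 bootstrap_B = as.integer(bootstrap_B), seed = as.integer(seed),
                 admin_cutoff = admin_cutoff,
                 exclude_max_nodes = exclude_max_nodes,
                 exclude_tiny_tumors = exclude_tiny_tumors,
                 ties = ties),
            class = "study_config")
}

#' Sensitivity filters of the derivation cohort
#'
#' Optionally removes the single patient with the highest number of
#' positive lymph nodes (first such record if tied) and/or all patients
#' with tumors of at most 2 mm; removal counts are reported via `message`.
#'
#' @param cohort cohort data frame.
#' @param exclude_max_nodes drop the max-node patient.
#' @param exclude_tiny_tumors drop tumors `<= 2` mm.
#' @return the filtered cohort.
#' @export
sensitivity_filter <- function(cohort, exclude_max_nodes = FALSE,
                               exclude_tiny_tumors = FALSE) {
  if (exclude_max_nodes) {
    drop <- which.max(cohort$n_pos_nodes)
    message(sprintf("sensitivity filter: removing patient %s with %d positive nodes",
                    cohort$patient_id[drop], cohort$n_pos_nodes[drop]))
    cohort <- cohort[-drop, , drop = FALSE]
  }
  if (exclude_tiny_tumors) {
    drop <- cohort$tumor_size_mm <= 2
    message(sprintf("sensitivity filter: removing %d tumor(s) of <= 2 mm", sum(drop)))
    cohort <- cohort[!drop, , drop = FALSE]
  }
  if (nrow(cohort) == 0L) fail("sensitivity filters removed every patient")
  cohort
}

#' Fit one model class of the complexity ladder
#'
#' `"dichotomized"` uses one clinical cut-point per factor, `"categorized"`
#' three to four clinical groups, `"fp"` the multivariable
#' fractional-polynomial procedure, and `"rcs"` restricted cubic splines
#' with five knots (percentile knots for age and size, fixed
#' 1/2/3/4/10 knots for the node count).
#'
#' @param cohort derivation cohort.
#' @param class_name one of the four model classes.
#' @param alpha closed-test level (FP only).
#' @param ties ties method.
#' @param stratified stratify by `stratum`.
#' @return a `prognostic_model`.
#' @export
fit_model_class <- function(cohort,
                            class_name = c("dichotomized", "categorized", "fp", "rcs"),
                            alpha = 0.05, ties = "breslow", stratified = TRUE) {
  class_name <- match.arg(class_name)
  covs <- c("age_years", "tumor_size_mm", "n_pos_nodes")
  specs <- switch(class_name,
    dichotomized = clinical_schemes("binary"),
    categorized = clinical_schemes("multi"),
    fp = return(mfp_fit(cohort, covs, alpha = alpha, ties = ties,
                        stratified = stratified)),
    rcs = list(
      age_years = place_knots(cohort$age_years, "percentile", "age_years"),
      tumor_size_mm = place_knots(cohort$tumor_size_mm, "percentile", "tumor_size_mm"),
      n_pos_nodes = place_knots(NULL, "nodes", "n_pos_nodes")))
  build_prognostic_model(cohort, specs, class_name = class_name,
                         ties = ties, stratified = stratified)
}

#' Run the full model-comparison study
#'
#' Deterministic given the configuration: loads or generates the
#' derivation and validation cohorts, truncates follow-up, applies the
#' sensitivity filters, fits every requested model class on the identical
#' derivation cohort, forms percentile risk groups on the derivation
#' prognostic index, and transports each model (transforms, weights and
#' PI cut-offs unchanged) to the validation cohort. A failure in one model
#' class is recorded in its entry without aborting the others.
#'
#' @param config a `study_config`.
#' @return a `study_report`: per model class the derivation and validation
#'   C-indices, selected transforms, coefficient table, requested and
#'   achieved risk-group percentiles, group fractions in both sets,
#'   hazard ratios of G2..G4 vs G1, and 10-year recurrence-free fractions
#'   per group with confidence intervals.
#' @export
run_study <- function(config = study_config()) {
  get_cohort <- function(src) {
    if (inherits(src, "cohort_config")) generate_cohort(src)
    else if (is.character(src)) read_cohort(src)
    else fail("cohort source must be a cohort_config or a CSV path")
  }
  derivation <- truncate_followup(get_cohort(config$derivation), config$admin_cutoff)
  validation <- truncate_followup(get_cohort(config$validation), config$admin_cutoff)
  derivation <- sensitivity_filter(derivation, config$exclude_max_nodes,
                                   config$exclude_tiny_tumors)

  models <- list()
  for (cls in config$model_classes) {
    models[[cls]] <- tryCatch({
      model <- fit_model_class(derivation, cls, alpha = config$alpha,
                               ties = config$ties)
      pi_der <- prognostic_index(model, derivation)
      c_der <- harrell_c(pi_der, derivation$time_years, derivation$event)
      grouping <- make_risk_groups(pi_der, config$risk_percentiles)
      grp_der <- assign_risk_groups(pi_der, grouping)
      km10_der <- group_km_at(derivation, grp_der, length(grouping$group_labels),
                              config$admin_cutoff)
      val <- transport_validate(model, grouping, validation)
      km10_val <- group_km_at(validation, val$groups,
                              length(grouping$group_labels), config$admin_cutoff)
      bands <- NULL
      if (config$bootstrap_B > 0L && cls == "fp") {
        bands <- lapply(model$covariates, function(v) {
          grid <- pretty_grid(derivation[[v]])
          bootstrap_band(derivation, v, grid, B = config$bootstrap_B,
                         seed = config$seed, alpha = config$alpha)
        })
        names(bands) <- model$covariates
      }
      list(model = model, pi_derivation = pi_der,
           c_derivation = c_der, c_validation = val$c_index,
           coefficients = cox_coef_table(model$fit),
           grouping = grouping,
           group_fractions_derivation = grouping$group_fractions,
           group_fractions_validation = val$group_fractions,
           hr_vs_g1_derivation = group_hr(derivation, grp_der,
                                          length(grouping$group_labels)),
           hr_vs_g1_validation = val$hr_vs_g1,
           drfi10_derivation = km10_der, drfi10_validation = km10_val,
           bands = bands)
    }, error = function(e) list(failure = conditionMessage(e)))
  }
  out <- list(config = config, n_derivation = nrow(derivation),
              n_validation = nrow(validation),
              events_derivation = sum(derivation$event),
              events_validation = sum(validation$event),
              models = models)
  class(out) <- "study_report"
  out
}

# 10-year recurrence-free fraction per risk group, with CI
group_km_at <- function(cohort, grp, ngrp, cutoff) {
  out <- lapply(seq_len(ngrp), function(g) {
    sel <- grp == g
    if (!any(sel)) return(c(survival = NA, ci_lower = NA, ci_upper = NA))
    km <- km_estimate(cohort$time_years[sel], cohort$event[sel])
    unlist(km_at(km, cutoff))
  })
  do.call(rbind, out)
}

group_hr <- function(cohort, grp, ngrp, stratified = TRUE) {
  gm <- matrix(0, length(grp), ngrp - 1L)
  for (g in 2:ngrp) gm[, g - 1L] <- as.numeric(grp == g)
  colnames(gm) <- paste0("G", 2:ngrp, " vs G1")
  keep <- colSums(gm) > 0
  fit <- cox_fit(gm[, keep, drop = FALSE], cohort$time_years, cohort$event,
                 if (stratified) cohort$stratum else NULL)
  cox_coef_table(fit)
}

pretty_grid <- function(x, n = 50L) {
  r <- range(x)
  sort(unique(seq(r[1L], r[2L], length.out = n)))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Model-comparison study: %d derivation / %d validation patients (%d / %d events)\n",
              x$n_derivation, x$n_validation,
              x$events_derivation, x$events_validation))
  for (cls in names(x$models)) {
    m <- x$models[[cls]]
    if (!is.null(m$failure)) {
      cat(sprintf("  %-12s FAILED: %s\n", cls, m$failure))
    } else {
      cat(sprintf("  %-12s C(derivation) = %.3f  C(validation) = %.3f\n",
                  cls, m$c_derivation$c, m$c_validation$c))
    }
  }
  invisible(x)
}
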
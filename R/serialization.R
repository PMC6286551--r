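# JSON serialization of fitted models, risk groupings and study reports,
# so that a model fitted on a derivation cohort can be re-applied
# bit-identically to a validation cohort in a later session.

spec_to_list <- function(sp) unclass(sp)

spec_from_list <- function(x) {
  switch(x$kind,
    category = category_scheme(x$covariate, x$cut_points, unlist(x$labels),
                               unlist(x$lower_inclusive)),
    fp = fp_spec(x$covariate, unlist(x$powers), x$shift, x$scale),
    rcs = rcs_spec(x$covariate, unlist(x$knots)),
    fail("unknown transform kind '%s'", x$kind))
}

#' Serialize / deserialize a prognostic model (JSON)
#'
#' The serialized form carries the model class, per-covariate transform
#' specs, weights, reference values and derivation covariate ranges --
#' everything [prognostic_index()] and [transport_validate()] need; the
#' internal Cox fit object is not serialized.
#'
#' @param model a `prognostic_model`.
#' @param path file path.
#' @rdname model_io
#' @export
write_model <- function(model, path) {
  x <- list(class_name = model$class_name, covariates = model$covariates,
            transforms = lapply(model$transforms, spec_to_list),
            weights = as.list(model$weights),
            reference_values = as.list(model$reference_values),
            ranges = model$ranges)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname model_io
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(class_name = x$class_name,
              covariates = unlist(x$covariates),
              transforms = lapply(x$transforms, spec_from_list),
              weights = unlist(x$weights),
              reference_values = unlist(x$reference_values),
              ranges = lapply(x$ranges, unlist),
              fit = NULL, stratified = NA)
  class(out) <- "prognostic_model"
  out
}

#' Serialize / deserialize a risk grouping (JSON)
#'
#' @param grouping a `risk_grouping`.
#' @param path file path.
#' @rdname grouping_io
#' @export
write_grouping <- function(grouping, path) {
  jsonlite::write_json(unclass(grouping), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname grouping_io
#' @export
read_grouping <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(x) <- "risk_grouping"
  x
}

# strip non-serializable members of a report entry
report_entry_to_list <- function(m) {
  if (!is.null(m$failure)) return(list(failure = m$failure))
  list(
    model = list(class_name = m$model$class_name,
                 transforms = lapply(m$model$transforms, spec_to_list),
                 weights = as.list(m$model$weights)),
    c_derivation = m$c_derivation$c,
    c_validation = m$c_validation$c,
    n_evaluable_pairs_derivation = m$c_derivation$n_evaluable_pairs,
    coefficients = m$coefficients,
    pi_derivation = m$pi_derivation,
    pi_cutoffs = m$grouping$pi_cutoffs,
    requested_percentiles = m$grouping$source_percentiles,
    achieved_percentiles = m$grouping$achieved_percentiles,
    group_fractions_derivation = m$group_fractions_derivation,
    group_fractions_validation = m$group_fractions_validation,
    hr_vs_g1_derivation = m$hr_vs_g1_derivation,
    hr_vs_g1_validation = m$hr_vs_g1_validation,
    drfi10_derivation = as.data.frame(m$drfi10_derivation),
    drfi10_validation = as.data.frame(m$drfi10_validation))
}

#' Write a study report as JSON
#'
#' Identical configuration and seed produce a byte-identical file.
#'
#' @param report a `study_report` from [run_study()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  x <- list(n_derivation = report$n_derivation,
            n_validation = report$n_validation,
            events_derivation = report$events_derivation,
            events_validation = report$events_validation,
            alpha = report$config$alpha,
            model_classes = report$config$model_classes,
            models = lapply(report$models, report_entry_to_list))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
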
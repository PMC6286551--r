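# Predictor codings compared by the pipeline: cut-point categorization,
# fractional polynomials (FP) with closed-test function selection and its
# multivariable backfitting extension (MFP), and restricted cubic splines.
# Each coding is represented by a serializable "transform spec" so a model
# fitted on one cohort can be re-applied bit-identically to another.

# ---------------------------------------------------------------------------
# Category schemes

#' Define a categorization scheme
#'
#' Cut-point categorization with an explicit boundary convention per cut:
#' when `lower_inclusive[i]` is `TRUE`, values equal to `cut_points[i]`
#' fall in the lower category; otherwise they fall in the upper one.
#'
#' @param covariate covariate name.
#' @param cut_points strictly increasing cut points.
#' @param labels category labels, one more than there are cuts.
#' @param lower_inclusive logical vector, one entry per cut.
#' @return a `transform_spec` of kind `"category"`.
#' @export
category_scheme <- function(covariate, cut_points, labels,
                            lower_inclusive = rep(TRUE, length(cut_points))) {
  if (is.unsorted(cut_points, strictly = TRUE)) fail("cut points must be strictly increasing")
  if (length(labels) != length(cut_points) + 1L)
    fail("need one more label than cut points")
  if (length(lower_inclusive) != length(cut_points))
    fail("need one boundary convention per cut point")
  structure(list(kind = "category", covariate = covariate,
                 cut_points = as.numeric(cut_points), labels = labels,
                 lower_inclusive = as.logical(lower_inclusive)),
            class = "transform_spec")
}

#' Assign values to categories
#'
#' @param x numeric vector.
#' @param scheme a category `transform_spec`.
#' @return integer category indices (1 = lowest), with `labels` attached
#'   as the `labels` attribute.
#' @export
categorize <- function(x, scheme) {
  stopifnot(inherits(scheme, "transform_spec"), scheme$kind == "category")
  if (any(!is.finite(x))) fail("non-finite values cannot be categorized")
  idx <- rep.int(1L, length(x))
  for (i in seq_along(scheme$cut_points)) {
    up <- if (scheme$lower_inclusive[i]) x > scheme$cut_points[i]
          else x >= scheme$cut_points[i]
    idx[up] <- i + 1L
  }
  attr(idx, "labels") <- scheme$labels
  idx
}

# The study's clinical schemes. Age 35 belongs to the middle group and 50
# to the middle group; size 20 is T1 and 50 is T2; any positive node count
# is node-positive.
clinical_schemes <- function(n_groups = c("multi", "binary")) {
  n_groups <- match.arg(n_groups)
  if (n_groups == "binary") {
    list(
      age_years = category_scheme("age_years", 35, c("<35", ">=35"),
                                  lower_inclusive = FALSE),
      tumor_size_mm = category_scheme("tumor_size_mm", 20, c("<=20", ">20")),
      n_pos_nodes = category_scheme("n_pos_nodes", 1, c("N0", "N+"),
                                    lower_inclusive = FALSE))
  } else {
    list(
      age_years = category_scheme("age_years", c(35, 50),
                                  c("<35", "35-50", ">50"),
                                  lower_inclusive = c(FALSE, TRUE)),
      tumor_size_mm = category_scheme("tumor_size_mm", c(20, 50),
                                      c("T1", "T2", "T3")),
      n_pos_nodes = category_scheme("n_pos_nodes", c(1, 4, 10),
                                    c("N0", "N1-3", "N4-9", "N10+"),
                                    lower_inclusive = c(FALSE, FALSE, FALSE)))
  }
}

# ---------------------------------------------------------------------------
# Fractional polynomials

#' Conventional fractional-polynomial candidate powers
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Define a fractional-polynomial transform
#'
#' The basis works on `z = (x + shift) / scale`, which must be positive.
#' Power 0 denotes `log(z)`; a repeated power pair `(p, p)` makes the
#' second column the first multiplied by `log(z)`.
#'
#' @param covariate covariate name.
#' @param powers numeric vector of length 1 or 2 (degree), or length 0 for
#'   a covariate excluded from the model.
#' @param shift additive offset making all values positive.
#' @param scale positive divisor applied before powering.
#' @return a `transform_spec` of kind `"fp"`.
#' @export
fp_spec <- function(covariate, powers, shift = 0, scale = 1) {
  if (length(powers) > 2L) fail("FP degree above 2 is not supported")
  if (scale <= 0) fail("scale must be positive")
  structure(list(kind = "fp", covariate = covariate,
                 powers = as.numeric(powers), shift = as.numeric(shift),
                 scale = as.numeric(scale), degree = length(powers)),
            class = "transform_spec")
}

# Shift/scale convention: if min(x) <= 0, shift by the smallest positive
# gap between distinct observed values; scale by the power of 10 nearest
# to the spread so the working range is near unity.
fp_shift_scale <- function(x) {
  shift <- 0
  if (min(x) <= 0) {
    ux <- sort(unique(x))
    shift <- if (length(ux) > 1L) min(diff(ux)) else 1
  }
  rng <- diff(range(x + shift))
  scale <- if (rng > 0) 10^round(log10(rng)) else 1
  list(shift = shift, scale = scale)
}

#' Evaluate a fractional-polynomial basis
#'
#' @param x numeric vector; `x + shift` must be positive.
#' @param spec an `"fp"` `transform_spec`.
#' @return numeric matrix with `degree` columns (0 columns if excluded).
#' @export
fp_basis <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"), spec$kind == "fp")
  z <- (x + spec$shift) / spec$scale
  if (any(z <= 0)) fail("non-positive argument after shift/scale")
  pw <- spec$powers
  if (length(pw) == 0L)
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  one <- function(p) if (p == 0) log(z) else z^p
  cols <- list(one(pw[1L]))
  if (length(pw) == 2L) {
    cols[[2L]] <- if (pw[2L] == pw[1L]) cols[[1L]] * log(z) else one(pw[2L])
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(spec$covariate, "_fp", seq_along(pw))
  m
}

# all FP1 and FP2 candidates over the power set
fp_candidates <- function(degree) {
  ps <- fp_power_set()
  if (degree == 1L) return(as.list(ps))
  out <- list()
  for (i in seq_along(ps)) for (j in i:length(ps))
    out[[length(out) + 1L]] <- c(ps[i], ps[j])
  out
}

# maximize the partial likelihood over FP candidates of a given degree
best_fp <- function(x, outcome, adjust, spec0, degree, ties) {
  best <- NULL
  for (pw in fp_candidates(degree)) {
    sp <- fp_spec(spec0$covariate, pw, spec0$shift, spec0$scale)
    fit <- cox_fit(cbind(fp_basis(x, sp), adjust), outcome = outcome, ties = ties)
    if (is.null(best) || fit$loglik["final"] > best$ll) {
      best <- list(spec = sp, ll = unname(fit$loglik["final"]), fit = fit)
    }
  }
  best
}

#' Closed-test fractional-polynomial function selection
#'
#' Selects the FP transform for one covariate by the closed test: (i) the
#' best FP2 is compared with the null model (4 df likelihood-ratio test) --
#' if not significant the covariate is kept linear (or excluded when
#' `keep = FALSE`); (ii) best FP2 vs the linear transform (3 df) -- if not
#' significant, linear is returned; (iii) best FP2 vs best FP1 (2 df) --
#' FP2 or FP1 accordingly. "Best" maximizes the partial likelihood over
#' the candidate power set. The sequence controls the familywise
#' probability of selecting spurious complexity at level `alpha`.
#'
#' @param x covariate values.
#' @param time,event,strata survival outcome (see [cox_fit()]).
#' @param adjust optional matrix of adjustment columns held fixed.
#' @param alpha significance level of the closed test.
#' @param max_degree maximum FP degree (1 or 2).
#' @param keep force the covariate into the model even when step (i) is
#'   not significant (default `TRUE`).
#' @param shift,scale optional overrides of the automatic positivity
#'   shift and power-of-ten scaling.
#' @param ties ties method passed to [cox_fit()].
#' @param outcome optional precomputed [cox_outcome()].
#' @return list with the selected `spec`, the final `fit` (including
#'   adjustment columns), and the closed-test `tests` table.
#' @export
select_fp <- function(x, time = NULL, event = NULL, strata = NULL, adjust = NULL,
                      alpha = 0.05, max_degree = 2L, keep = TRUE,
                      shift = NULL, scale = NULL,
                      ties = c("breslow", "efron"), outcome = NULL) {
  ties <- match.arg(ties)
  if (is.null(outcome)) outcome <- cox_outcome(time, event, strata)
  if (!is_num1(alpha) || alpha <= 0 || alpha > 1) fail("alpha must lie in (0, 1]")
  ss <- fp_shift_scale(x)
  if (!is.null(shift)) ss$shift <- shift
  if (!is.null(scale)) ss$scale <- scale
  covname <- if (!is.null(attr(x, "name"))) attr(x, "name") else "x"
  base <- fp_spec(covname, numeric(0), ss$shift, ss$scale)
  if (!is.null(adjust)) adjust <- as.matrix(adjust)

  refit <- function(sp) cox_fit(cbind(fp_basis(x, sp), adjust),
                                outcome = outcome, ties = ties)
  null_fit <- refit(base)                               # adjustment only
  lin_spec <- fp_spec(covname, 1, ss$shift, ss$scale)
  lin_fit <- refit(lin_spec)
  b1 <- best_fp(x, outcome, adjust, base, 1L, ties)
  top <- if (max_degree >= 2L) best_fp(x, outcome, adjust, base, 2L, ties) else b1
  df_top <- 2L * min(max_degree, 2L)                    # 4 for FP2, 2 for FP1

  lr <- function(ll1, ll0, df) stats::pchisq(2 * (ll1 - ll0), df, lower.tail = FALSE)
  p_null <- lr(top$ll, unname(null_fit$loglik["final"]), df_top)
  p_lin <- lr(top$ll, unname(lin_fit$loglik["final"]), df_top - 1L)
  p_fp1 <- if (max_degree >= 2L) lr(top$ll, b1$ll, 2L) else NA_real_

  tests <- data.frame(
    comparison = c("best vs null", "best vs linear", "best FP2 vs best FP1"),
    df = c(df_top, df_top - 1L, 2L),
    p = c(p_null, p_lin, p_fp1))

  if (p_null >= alpha) {
    sel <- if (keep) lin_spec else base
    fit <- if (keep) lin_fit else null_fit
  } else if (p_lin >= alpha) {
    sel <- lin_spec; fit <- lin_fit
  } else if (max_degree < 2L || p_fp1 >= alpha) {
    sel <- b1$spec; fit <- b1$fit
  } else {
    sel <- top$spec; fit <- top$fit
  }
  list(spec = sel, fit = fit, tests = tests)
}

# ---------------------------------------------------------------------------
# Restricted cubic splines

#' Define a restricted-cubic-spline transform
#'
#' @param covariate covariate name.
#' @param knots strictly increasing knot locations, at least 3.
#' @return a `transform_spec` of kind `"rcs"` with `basis_dim = k - 1`.
#' @export
rcs_spec <- function(covariate, knots) {
  if (length(knots) < 3L) fail("restricted cubic splines need at least 3 knots")
  if (anyDuplicated(knots) || is.unsorted(knots, strictly = TRUE))
    fail("knots must be strictly increasing and distinct")
  structure(list(kind = "rcs", covariate = covariate,
                 knots = as.numeric(knots), basis_dim = length(knots) - 1L),
            class = "transform_spec")
}

#' Evaluate the restricted-cubic-spline basis
#'
#' Truncated-power basis with linear tails (Harrell's normalization by the
#' squared boundary-knot span): column 1 is `x` itself; columns `2..k-1`
#' vanish below the first knot and are linear above the last, so any
#' fitted combination is linear outside the boundary knots.
#'
#' @param x numeric vector.
#' @param spec an `"rcs"` `transform_spec`.
#' @return matrix with `k - 1` columns.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"), spec$kind == "rcs")
  t <- spec$knots; k <- length(t)
  norm <- (t[k] - t[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  m <- matrix(0, length(x), k - 1L)
  m[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    m[, j + 1L] <- (pos3(x - t[j]) -
                      pos3(x - t[k - 1L]) * (t[k] - t[j]) / (t[k] - t[k - 1L]) +
                      pos3(x - t[k]) * (t[k - 1L] - t[j]) / (t[k] - t[k - 1L])) / norm
  }
  colnames(m) <- paste0(spec$covariate, "_rcs", seq_len(k - 1L))
  m
}

#' Place spline knots for a covariate
#'
#' Age and tumor size receive five knots at the 5th, 27.5th, 50th, 72.5th
#' and 95th nearest-rank percentiles; the node count, with its heavy mass
#' at zero, uses fixed knots at 1, 2, 3, 4 and 10 positive nodes.
#'
#' @param x observed covariate values (ignored for `kind = "nodes"`).
#' @param kind `"percentile"` or `"nodes"`.
#' @param covariate covariate name stored in the spec.
#' @param percentiles knot percentiles for the percentile policy.
#' @return an `"rcs"` `transform_spec`.
#' @export
place_knots <- function(x, kind = c("percentile", "nodes"),
                        covariate = "x",
                        percentiles = c(5, 27.5, 50, 72.5, 95)) {
  kind <- match.arg(kind)
  if (kind == "nodes") return(rcs_spec(covariate, c(1, 2, 3, 4, 10)))
  kn <- pct_nearest_rank(x, percentiles)
  if (anyDuplicated(kn))
    fail("fewer than %d distinct percentile values; use fewer knots",
         length(percentiles))
  rcs_spec(covariate, kn)
}

# ---------------------------------------------------------------------------
# Shared basis dispatch

#' Evaluate the design columns of any transform spec
#'
#' Category specs expand to dummy columns for categories 2..k (the lowest
#' category is the reference); FP and RCS specs evaluate their bases.
#'
#' @param x numeric vector.
#' @param spec a `transform_spec`.
#' @return numeric matrix.
#' @export
transform_basis <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  switch(spec$kind,
    category = {
      idx <- categorize(x, spec)
      k <- length(spec$labels)
      m <- matrix(0, length(x), k - 1L)
      for (j in 2:k) m[, j - 1L] <- as.numeric(idx == j)
      colnames(m) <- paste0(spec$covariate, "=", spec$labels[-1L])
      m
    },
    fp = fp_basis(x, spec),
    rcs = rcs_basis(x, spec),
    fail("unknown transform kind '%s'", spec$kind))
}

# ---------------------------------------------------------------------------
# Multivariable FP (MFP) backfitting

#' Multivariable fractional-polynomial model fit
#'
#' Backfitting extension of [select_fp()]: covariates are ordered by
#' decreasing significance of their linear fit, then each in turn is
#' re-selected by the closed test adjusted for the current transforms of
#' the others, cycling until the selected forms are stable (or
#' `max_cycles` is reached, which is reported as non-convergence). The
#' final model jointly refits all selected bases.
#'
#' @param cohort cohort data frame.
#' @param covariates covariate column names.
#' @param alpha closed-test level.
#' @param max_cycles backfitting cycle cap.
#' @param keep force all covariates into the model (default `TRUE`).
#' @param ties ties method.
#' @param stratified stratify the partial likelihood by `stratum`.
#' @return a `prognostic_model` (see [prognostic_index()]) with the extra
#'   fields `cycles` (number used) and `cycle_history` (selected powers
#'   per cycle).
#' @export
mfp_fit <- function(cohort, covariates = c("age_years", "tumor_size_mm", "n_pos_nodes"),
                    alpha = 0.05, max_cycles = 5L, keep = TRUE,
                    ties = c("breslow", "efron"), stratified = TRUE) {
  ties <- match.arg(ties)
  if (length(covariates) < 1L) fail("need at least one covariate")
  outcome <- cox_outcome(cohort$time_years, cohort$event,
                         if (stratified) cohort$stratum else NULL)

  ss <- lapply(covariates, function(v) fp_shift_scale(cohort[[v]]))
  names(ss) <- covariates
  specs <- lapply(covariates, function(v)
    fp_spec(v, 1, ss[[v]]$shift, ss[[v]]$scale))
  names(specs) <- covariates

  # visit order: decreasing significance of the linear fit (Wald p)
  if (length(covariates) > 1L) {
    lin_design <- do.call(cbind, lapply(specs, function(sp)
      fp_basis(cohort[[sp$covariate]], sp)))
    lf <- cox_fit(lin_design, outcome = outcome, ties = ties)
    pvals <- 2 * stats::pnorm(-abs(lf$coefficients / sqrt(diag(lf$covariance))))
    order_idx <- order(pvals)
  } else order_idx <- 1L
  visit <- covariates[order_idx]

  history <- list()
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    changed <- FALSE
    for (v in visit) {
      others <- setdiff(covariates, v)
      adjust <- if (length(others)) {
        do.call(cbind, lapply(others, function(o)
          transform_basis(cohort[[o]], specs[[o]])))
      } else NULL
      sel <- select_fp(cohort[[v]], adjust = adjust,
                       alpha = alpha, keep = keep,
                       shift = ss[[v]]$shift, scale = ss[[v]]$scale,
                       ties = ties, outcome = outcome)
      sel$spec$covariate <- v
      if (!identical(sel$spec$powers, specs[[v]]$powers)) changed <- TRUE
      specs[[v]] <- sel$spec
    }
    history[[cycles]] <- lapply(specs, `[[`, "powers")
    if (!changed || cycles >= max_cycles) break
  }
  if (cycles >= max_cycles && changed)
    warning("MFP backfitting did not stabilize; returning the last cycle's forms")

  build_prognostic_model(cohort, specs, class_name = "fp",
                         ties = ties, stratified = stratified,
                         extra = list(cycles = cycles, cycle_history = history))
}
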
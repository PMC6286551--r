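# Base-graphics presentation of the fitted models: relative-hazard curves
# with optional bootstrap bands and a density strip of the covariate,
# Kaplan-Meier curves by risk group, and prognostic-index histograms.

#' Plot a relative-hazard curve
#'
#' Relative hazard versus one covariate (reference value = 1.00), with an
#' optional bootstrap percentile band and a kernel-density strip of the
#' observed covariate distribution along the axis.
#'
#' @param model a `prognostic_model`.
#' @param covariate covariate name.
#' @param cohort optional cohort supplying the observed values for the
#'   density strip and the default grid.
#' @param band optional band from [bootstrap_band()].
#' @param log_scale draw the hazard axis on the log scale.
#' @param ... passed to [plot()].
#' @export
plot_relative_hazard <- function(model, covariate, cohort = NULL, band = NULL,
                                 log_scale = TRUE, ...) {
  grid <- if (!is.null(band)) band$x
          else if (!is.null(cohort)) pretty_grid(cohort[[covariate]], 100L)
          else fail("either cohort or band must supply the grid")
  curve <- relative_hazard_curve(model, covariate, grid)
  ylim <- range(curve$relative_hazard, if (!is.null(band)) c(band$lower, band$upper))
  plot(curve$x, curve$relative_hazard, type = "l", lwd = 2,
       log = if (log_scale) "y" else "",
       xlab = covariate, ylab = "relative hazard", ylim = ylim, ...)
  if (!is.null(band)) {
    graphics::polygon(c(band$x, rev(band$x)), c(band$lower, rev(band$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
    graphics::lines(curve$x, curve$relative_hazard, lwd = 2)
  }
  graphics::abline(h = 1, lty = 3)
  if (!is.null(cohort)) {
    d <- stats::density(cohort[[covariate]])
    usr <- graphics::par("usr")
    base <- if (log_scale) 10^usr[3L] else usr[3L]
    top <- if (log_scale) 10^(usr[3L] + 0.15 * (usr[4L] - usr[3L]))
           else usr[3L] + 0.15 * (usr[4L] - usr[3L])
    graphics::polygon(d$x, base + (top - base) * d$y / max(d$y),
                      col = grDevices::adjustcolor("grey50", 0.3), border = NA)
  }
  invisible(curve)
}

#' Plot Kaplan-Meier curves by risk group
#'
#' @param cohort cohort data frame.
#' @param groups integer risk-group indices (see [assign_risk_groups()]).
#' @param labels group labels.
#' @param lty line type (e.g. 2 for a validation overlay).
#' @param add overlay on an existing plot.
#' @param col colors per group.
#' @param ... passed to [plot()].
#' @export
plot_km_groups <- function(cohort, groups, labels = paste0("G", sort(unique(groups))),
                           lty = 1, add = FALSE,
                           col = grDevices::hcl.colors(length(unique(groups)), "Dark 2"),
                           ...) {
  gs <- sort(unique(groups))
  if (!add)
    plot(NA, xlim = c(0, max(cohort$time_years)), ylim = c(0, 1),
         xlab = "years", ylab = "recurrence-free fraction", ...)
  for (i in seq_along(gs)) {
    sel <- groups == gs[i]
    km <- km_estimate(cohort$time_years[sel], cohort$event[sel])
    graphics::lines(stats::stepfun(km$times, c(1, km$survival)),
                    do.points = FALSE, col = col[i], lty = lty, lwd = 2)
  }
  if (!add) graphics::legend("bottomleft", legend = labels, col = col, lwd = 2, bty = "n")
  invisible(NULL)
}

#' Histogram of prognostic indices, derivation vs validation
#'
#' Both sets are centered by the derivation mean; vertical lines mark the
#' derivation risk-group cut-offs.
#'
#' @param pi_derivation,pi_validation PI vectors.
#' @param grouping a `risk_grouping` from the derivation set.
#' @export
plot_pi_hist <- function(pi_derivation, pi_validation, grouping = NULL) {
  ctr <- mean(pi_derivation)
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  brk <- pretty(c(pi_derivation, pi_validation) - ctr, 40)
  graphics::hist(pi_derivation - ctr, breaks = brk, main = "derivation",
                 xlab = "centered prognostic index", col = "grey70", border = NA)
  if (!is.null(grouping)) graphics::abline(v = grouping$pi_cutoffs - ctr, lty = 2)
  graphics::hist(pi_validation - ctr, breaks = brk, main = "validation",
                 xlab = "centered prognostic index", col = "steelblue", border = NA)
  if (!is.null(grouping)) graphics::abline(v = grouping$pi_cutoffs - ctr, lty = 2)
  invisible(NULL)
}
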
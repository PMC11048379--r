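# Base-graphics plots: breakdown course with fitted sigmoid and sd bars,
# Arrhenius line and Gibbs-Helmholtz line with the ambient extrapolation.

#' Plot a dissociation course with its fitted sigmoid
#'
#' Mean normalized educt intensities vs collision voltage with sd bars where
#' replicates exist, the fitted Boltzmann curve, and the midpoint tangent.
#'
#' @param course A `dissociation_course`.
#' @param fit Optional [boltzmann_fit()] (computed when missing).
#' @param show_tangent Draw the midpoint tangent line.
#' @param ... Passed to [graphics::plot()].
#' @return The fit, invisibly.
#' @export
plot_course <- function(course, fit = NULL, show_tangent = TRUE, ...) {
  d <- course_means(course)
  if (is.null(fit)) fit <- fit_boltzmann(course)
  graphics::plot(d$dcv, d$mean, pch = 19, xlab = expression(Delta * "CV [V]"),
                 ylab = "normalized educt intensity [%]",
                 ylim = c(0, max(105, d$mean)), ...)
  has_sd <- is.finite(d$sd)
  if (any(has_sd)) {
    graphics::arrows(d$dcv[has_sd], d$mean[has_sd] - d$sd[has_sd],
                     d$dcv[has_sd], d$mean[has_sd] + d$sd[has_sd],
                     angle = 90, code = 3, length = 0.03)
  }
  xx <- seq(min(d$dcv), max(d$dcv), length.out = 200)
  graphics::lines(xx, boltzmann_value(fit, xx), col = "red3", lwd = 2)
  if (show_tangent) {
    tl <- tangent_line(fit)
    graphics::abline(tl$intercept, tl$slope, col = "grey40", lty = 2)
  }
  invisible(fit)
}

#' Arrhenius plot with ambient extrapolation
#'
#' `ln k` vs `1/T_eff` for the steep-region points, the regression line, and
#' its extrapolation to `1/t_amb` (open symbol).
#'
#' @param result A `thermo_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_arrhenius <- function(result, ...) {
  pts <- result$points
  cfg <- result$cfg
  x <- 1 / pts$t_eff
  y <- log(pts$k)
  xa <- 1 / cfg$t_amb
  graphics::plot(x, y, pch = 19, xlim = range(c(x, xa)),
                 ylim = range(c(y, log(result$k_m0g))),
                 xlab = expression(1 / T[eff] ~ "[1/K]"),
                 ylab = expression(ln ~ k), ...)
  graphics::abline(result$arrhenius$intercept, result$arrhenius$slope,
                   col = "red3")
  graphics::points(xa, log(result$k_m0g), pch = 1, cex = 1.4, col = "red3")
  invisible(result)
}

#' Gibbs-Helmholtz plot with ambient extrapolation
#'
#' `dG(T) = -R T ln keq` vs `T_eff`, the fitted line `dG = dH - T dS`, and
#' its extrapolation to ambient temperature (open symbol).
#'
#' @param result A `thermo_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_gibbs_helmholtz <- function(result, ...) {
  pts <- result$points
  cfg <- result$cfg
  dg <- -cfg$r_gas * pts$t_eff * log(pts$keq) / 1000
  graphics::plot(pts$t_eff, dg, pch = 19,
                 xlim = range(c(pts$t_eff, cfg$t_amb)),
                 ylim = range(c(dg, result$dg_m0g)),
                 xlab = expression(T[eff] ~ "[K]"),
                 ylab = expression(Delta * G ~ "[kJ/mol]"), ...)
  graphics::abline(result$gibbs_helmholtz$intercept / 1000,
                   result$gibbs_helmholtz$slope / 1000, col = "red3")
  graphics::points(cfg$t_amb, result$dg_m0g, pch = 1, cex = 1.4, col = "red3")
  invisible(result)
}
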
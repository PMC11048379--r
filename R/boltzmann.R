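# Boltzmann sigmoid fitting of educt decay courses and the midpoint tangent
# characteristics derived from the fit.
#
# Model: y(x) = final + (initial - final) / (1 + exp((x - dcv50) / dx))
# with x the collision cell voltage difference (V) and y the normalized educt
# intensity (%). dx > 0 and initial > final give a decreasing sigmoid.

#' Construct a Boltzmann fit object
#'
#' Usually produced by [fit_boltzmann()]; constructing one directly is useful
#' for evaluating published parameter sets.
#'
#' @param initial,final Plateau values in percent (`0 <= final < initial`).
#' @param dcv50 Midpoint voltage in V.
#' @param dx Width parameter in V (> 0).
#' @param r2 Optional coefficient of determination.
#' @param covariance Optional parameter covariance matrix.
#' @param data Optional data frame `dcv, y` the fit was computed from.
#' @return An object of class `boltzmann_fit`.
#' @export
boltzmann_fit <- function(initial, final, dcv50, dx, r2 = NA_real_,
                          covariance = NULL, data = NULL) {
  if (dx <= 0) stop("width dx must be > 0")
  if (final < 0 || initial <= final) {
    stop("need 0 <= final < initial (got initial = ", initial,
         ", final = ", final, ")")
  }
  structure(list(initial = initial, final = final, dcv50 = dcv50, dx = dx,
                 r2 = r2, covariance = covariance, data = data),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> initial %.2f%%  final %.2f%%  dcv50 %.2f V  dx %.2f V",
    x$initial, x$final, x$dcv50, x$dx))
  if (is.finite(x$r2)) cat(sprintf("  R2 %.4g", x$r2))
  cat("\n")
  invisible(x)
}

#' Evaluate a Boltzmann sigmoid
#'
#' @param fit A [boltzmann_fit()].
#' @param x Voltage(s) in V.
#' @return Normalized intensity in percent.
#' @export
boltzmann_value <- function(fit, x) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  fit$final + (fit$initial - fit$final) / (1 + exp((x - fit$dcv50) / fit$dx))
}

#' Fit a Boltzmann sigmoid to an educt decay course
#'
#' Unweighted Levenberg-Marquardt least squares (analytic Jacobian) on the
#' replicate-mean educt course (per-replicate fitting available via
#' `use_means = FALSE`). Initialization: plateaus from the data extremes;
#' midpoint and width from the interpolated 50%/25%/75% transition crossings
#' (which a Boltzmann sigmoid separates by `2 dx ln 3`), with the voltage
#' nearest mid-range and a tenth of the span as fallback start. Bounds keep
#' the plateaus in `[0, 110]` and `dx` in `(0, range(x)]`, preventing
#' plateau swap and step-function collapse.
#'
#' A warning flag (`r2_ok = FALSE`) is set when the regression coefficient is
#' below `r2_gate` (default 0.99, the quality conventionally required of
#' breakdown-curve fits); this is a gate for reporting, not a failure.
#'
#' @param course A `dissociation_course`, or a data frame with columns
#'   `dcv`/`x` and `mean`/`y`.
#' @param educt Educt species symbol (for a `dissociation_course`).
#' @param use_means Fit replicate means (default) or all replicate points.
#' @param r2_gate Warning threshold on R^2.
#' @return A [boltzmann_fit()] with fields `r2`, `r2_ok` and `data`.
#' @export
fit_boltzmann <- function(course, educt = NULL, use_means = TRUE,
                          r2_gate = 0.99) {
  if (inherits(course, "dissociation_course")) {
    if (is.null(educt)) educt <- course$educt
    if (use_means) {
      d <- course_means(course, educt)
      xy <- data.frame(x = d$dcv, y = d$mean)
    } else {
      d <- course$data[course$data$species == educt, ]
      xy <- data.frame(x = d$dcv, y = d$normalized)
    }
  } else {
    d <- as.data.frame(course)
    names(d)[names(d) %in% c("dcv", "x")][1] <- "x"
    names(d)[names(d) %in% c("mean", "y", "normalized")][1] <- "y"
    xy <- d[, c("x", "y")]
  }
  xy <- xy[order(xy$x), ]
  if (nrow(xy) < 5L) stop("need >= 5 points to fit a Boltzmann sigmoid")
  yr <- range(xy$y)
  if (diff(yr) < 0.5 * max(yr[2], 1)) {
    stop("course has no transition (max - min < 50% of range); ",
         "cannot fit a sigmoid")
  }
  # slope sign check: educt courses decay with voltage
  if (stats::cor(xy$x, xy$y) > 0.5) {
    stop("educt course increases with dcv; wrong species selected?")
  }
  xr <- diff(range(xy$x))
  # start values: plateaus from the data extremes; midpoint and width from
  # interpolated 50% / 25% / 75% transition crossings (the crossings of a
  # Boltzmann sigmoid are 2 dx ln 3 apart), falling back on the voltage
  # closest to mid-range and a tenth of the span
  cross <- function(level) {
    yy <- max(xy$y) - level * diff(yr)     # decaying course
    i <- which(diff(sign(xy$y - yy)) != 0)[1]
    if (is.na(i)) return(NA_real_)
    stats::approx(xy$y[c(i, i + 1)], xy$x[c(i, i + 1)], xout = yy)$y
  }
  x50 <- cross(0.5)
  dx_est <- (cross(0.75) - cross(0.25)) / (2 * log(3))
  starts <- list(
    list(initial = max(xy$y), final = min(xy$y),
         dcv50 = if (is.finite(x50)) x50 else
           xy$x[which.min(abs(xy$y - mean(yr)))],
         dx = if (is.finite(dx_est) && dx_est > 0) dx_est else xr / 10),
    list(initial = max(xy$y), final = min(xy$y),
         dcv50 = xy$x[which.min(abs(xy$y - mean(yr)))],
         dx = xr / 10))
  model <- function(p, x) {
    p[["final"]] + (p[["initial"]] - p[["final"]]) /
      (1 + exp((x - p[["dcv50"]]) / p[["dx"]]))
  }
  jacobian <- function(p, x) {
    u <- (x - p[["dcv50"]]) / p[["dx"]]
    sig <- 1 / (1 + exp(u))
    amp <- p[["initial"]] - p[["final"]]
    dsig <- exp(u) * sig^2          # -d(sig)/du
    cbind(initial = sig, final = 1 - sig,
          dcv50 = amp * dsig / p[["dx"]],
          dx = amp * dsig * (x - p[["dcv50"]]) / p[["dx"]]^2)
  }
  lower <- c(initial = 0, final = 0, dcv50 = min(xy$x) - xr, dx = 1e-6)
  upper <- c(initial = 110, final = 110, dcv50 = max(xy$x) + xr, dx = xr)
  best <- NULL
  errs <- character()
  for (start in starts) {
    sol <- minpack.lm::nls.lm(
      par = unlist(start),
      fn = function(p) xy$y - model(p, xy$x),
      jac = function(p) -jacobian(p, xy$x),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14))
    ok <- sol$info %in% 1:4 && sol$par[["dx"]] > 2 * lower[["dx"]]
    if (ok && (is.null(best) || sol$deviance < best$deviance)) best <- sol
    if (!ok) {
      errs <- c(errs, sprintf(
        "start (initial = %s, final = %s, dcv50 = %s, dx = %s): %s",
        signif(start$initial, 4), signif(start$final, 4),
        signif(start$dcv50, 4), signif(start$dx, 4), sol$message))
    }
  }
  if (is.null(best)) {
    stop("Boltzmann fit did not converge; ", paste(errs, collapse = "; "))
  }
  cf <- best$par
  res <- xy$y - model(cf, xy$x)
  r2 <- 1 - sum(res^2) / sum((xy$y - mean(xy$y))^2)
  covar <- tryCatch({
    J <- jacobian(cf, xy$x)
    sigma2 <- sum(res^2) / max(nrow(xy) - length(cf), 1)
    sigma2 * solve(crossprod(J))
  }, error = function(e) NULL)
  out <- boltzmann_fit(cf[["initial"]], cf[["final"]], cf[["dcv50"]],
                       cf[["dx"]], r2 = r2, covariance = covar, data = xy)
  out$r2_ok <- r2 >= r2_gate
  if (!out$r2_ok) {
    warning(sprintf("Boltzmann fit R^2 = %.4f below the %.2f quality gate",
                    r2, r2_gate))
  }
  out
}

#' Slope of the tangent at the sigmoid midpoint
#'
#' Analytic derivative of the Boltzmann sigmoid at `dcv50`:
#' `-(initial - final) / (4 dx)`, in percent per volt. Since the fitted curve
#' has a single midpoint, each complex has exactly one tangent line.
#'
#' @param fit A [boltzmann_fit()].
#' @return Slope in %/V (negative for a decaying course).
#' @export
midpoint_slope <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  -(fit$initial - fit$final) / (4 * fit$dx)
}

#' Tangent line at the sigmoid midpoint
#'
#' The line through `(dcv50, (initial + final)/2)` with slope
#' [midpoint_slope()].
#'
#' @param fit A [boltzmann_fit()].
#' @return An object of class `tangent_line` with `slope` (%/V), `intercept`
#'   (%), and `anchor` `c(dcv50, midpoint)`.
#' @export
tangent_line <- function(fit) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  slope <- midpoint_slope(fit)
  mid <- (fit$initial + fit$final) / 2
  structure(list(slope = slope, intercept = mid - slope * fit$dcv50,
                 anchor = c(dcv50 = fit$dcv50, midpoint = mid)),
            class = "tangent_line")
}

#' @export
print.tangent_line <- function(x, ...) {
  cat(sprintf("<tangent_line> slope %.2f %%/V through (%.2f V, %.2f %%)\n",
              x$slope, x$anchor[1], x$anchor[2]))
  invisible(x)
}

#' Boltzmann fit table
#'
#' Summarises a list of fits in the conventional breakdown-curve layout:
#' Initial, Final, dcv50, dx, midpoint Slope and R^2, rounded to 2 decimals
#' (rounding happens only here, at the reporting surface).
#'
#' @param fits Named list of [boltzmann_fit()]s (names = complex symbols).
#' @param digits Decimal places for the report (default 2).
#' @return Data frame with one row per complex.
#' @export
boltzmann_table <- function(fits, digits = 2) {
  stopifnot(length(fits) >= 1L)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(complex = nm,
               initial = round(f$initial, digits),
               final = round(f$final, digits),
               dcv50 = round(f$dcv50, digits),
               dx = round(f$dx, digits),
               slope = round(midpoint_slope(f), digits),
               r2 = round(f$r2, 3))
  })
  do.call(rbind, rows)
}
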
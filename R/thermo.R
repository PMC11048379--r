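# Effective-temperature conversion and thermodynamic extrapolation.
#
# The voltage axis of a breakdown curve is mapped to an effective internal
# ion temperature, survival fractions become first-order rate constants over
# the collision-cell residence time, and product/educt ratios become
# dissociation quotients. Linear Arrhenius (ln k vs 1/T) and Gibbs-Helmholtz
# (dG vs T) regressions over the steep part of the fitted sigmoid are then
# extrapolated to ambient temperature, yielding the five apparent quantities
# k#, KD#, dG#, dH# and T.dS#.

#' Thermodynamic analysis configuration
#'
#' @param t0 Effective ion temperature at dcv = 0 in K. Default 300 K
#'   (near-ambient source conditions).
#' @param t_amb Ambient temperature for the extrapolations, K (default 298).
#' @param gas_mass Collision gas molar mass in Da (default argon, 39.948).
#' @param residence_time Ion transit time through the collision cell in s
#'   (default 1e-4). It scales the apparent rate constant multiplicatively
#'   and cancels nowhere, so report it alongside any k value.
#' @param r_gas Molar gas constant in J/(mol K) (default 8.314).
#' @param steep_lo,steep_hi Fraction-of-transition bounds selecting the steep
#'   region of the fitted sigmoid used for the linear extrapolations (default
#'   10-90% of the initial-to-final transition).
#' @param n_steep Number of evaluation points across the steep region.
#' @param cv_model Conversion model `function(dcv, z, ion_mass, atom_count,
#'   cfg) -> K`; `NULL` selects the built-in centre-of-mass equipartition
#'   model (see [cv_to_temperature()]). Pluggable so an instrument-specific
#'   calibration can be substituted without touching downstream code.
#' @return An object of class `thermo_config`.
#' @export
thermo_config <- function(t0 = 300, t_amb = 298, gas_mass = 39.948,
                          residence_time = 1e-4, r_gas = cid_constants$gas_constant,
                          steep_lo = 0.1, steep_hi = 0.9, n_steep = 25,
                          cv_model = NULL) {
  stopifnot(t0 > 0, t_amb > 0, gas_mass > 0, residence_time > 0,
            0 < steep_lo, steep_lo < steep_hi, steep_hi < 1, n_steep >= 3)
  structure(list(t0 = t0, t_amb = t_amb, gas_mass = gas_mass,
                 residence_time = residence_time, r_gas = r_gas,
                 steep_lo = steep_lo, steep_hi = steep_hi, n_steep = n_steep,
                 cv_model = cv_model),
            class = "thermo_config")
}

#' Convert collision voltage to effective ion temperature
#'
#' Default model: the centre-of-mass collision energy of a singly collided
#' ion, `z e dcv m_gas / (m_gas + M_ion)`, is equipartitioned over the
#' `3 N - 6` vibrational degrees of freedom via the Boltzmann constant and
#' added to the zero-voltage temperature `t0`:
#' `T_eff = t0 + z e dcv m_gas / ((m_gas + M_ion) (3N - 6) kB)`.
#' The mapping is affine and strictly increasing in `dcv`. A different
#' calibration can be supplied through `cfg$cv_model`.
#'
#' @param dcv Voltage(s) in V (>= 0).
#' @param z Educt charge.
#' @param ion_mass Educt neutral mass in Da.
#' @param atom_count Number of atoms in the educt (>= 2).
#' @param cfg A [thermo_config()].
#' @return Effective temperature(s) in K.
#' @export
cv_to_temperature <- function(dcv, z, ion_mass, atom_count,
                              cfg = thermo_config()) {
  if (!is.null(cfg$cv_model)) {
    return(cfg$cv_model(dcv, z, ion_mass, atom_count, cfg))
  }
  if (atom_count < 2) stop("atom_count must be >= 2 (no vibrational modes)")
  if (any(dcv < 0)) stop("dcv must be >= 0")
  dof <- 3 * atom_count - 6
  e_com <- z * cid_constants$elementary_charge * dcv *
    cfg$gas_mass / (cfg$gas_mass + ion_mass)
  cfg$t0 + e_com / (dof * cid_constants$boltzmann)
}

#' First-order rate constant from a survival fraction
#'
#' Assuming first-order decay of the educt over the collision-cell residence
#' time: `k = -ln(survival) / residence_time`.
#'
#' @param survival Fraction of educt remaining, in (0, 1].
#' @param cfg A [thermo_config()].
#' @return Rate constant in 1/s.
#' @export
survival_to_rate <- function(survival, cfg = thermo_config()) {
  if (any(survival <= 0)) {
    stop("survival must be > 0 (completely depleted points are excluded upstream)")
  }
  if (any(survival > 1 + 1e-9)) stop("survival must be <= 1")
  -log(pmin(survival, 1)) / cfg$residence_time
}

#' Dissociation quotient from normalized intensities
#'
#' `keq = (dimer fraction x monomer fraction) / trimer fraction` with all
#' fractions on the 0-1 scale. For hetero-trimers with two release channels
#' the dimer and monomer fractions are each summed over channels before the
#' quotient (set `sum_channels = FALSE` to get per-channel quotients).
#'
#' @param trimer Educt fraction (> 0).
#' @param dimer,monomer Product fractions; vectors of per-channel fractions
#'   when `sum_channels = TRUE` (the default collapses them by summation).
#' @param sum_channels Sum product fractions over release channels.
#' @return Unitless dissociation quotient.
#' @export
equilibrium_quotient <- function(trimer, dimer, monomer, sum_channels = TRUE) {
  if (any(trimer <= 0)) stop("trimer fraction must be > 0")
  if (sum_channels) {
    dimer <- sum(dimer); monomer <- sum(monomer)
  }
  dimer * monomer / trimer
}

#' Temperature points over the steep region of a fitted course
#'
#' Evaluates the fitted Boltzmann curve on a uniform voltage grid spanning the
#' steep region (fraction of transition between `cfg$steep_lo` and
#' `cfg$steep_hi`; the sigmoid passes fraction f of its transition at
#' `dcv50 + dx ln(f/(1-f))`). Each point carries the effective temperature,
#' the survival fraction (fitted educt percent / 100), the first-order rate
#' constant and the dissociation quotient computed from the complementary
#' product fraction split equally between one dimer and one monomer ion per
#' dissociation event (channels summed).
#'
#' Two sources are available. `source = "fit"` (default) evaluates the
#' fitted curve on a dense uniform grid over the steep region, giving the
#' single smooth extrapolation line per complex used for reporting.
#' `source = "data"` takes the measured replicate-mean normalized educt
#' intensities at the grid voltages inside the steep region; this route is
#' free of sigmoid-family representation error and is the one used for
#' parameter-recovery validation against the thermodynamic forward model.
#'
#' @param fit A [boltzmann_fit()] of the educt course.
#' @param ion The educt [oligomer_ion()] (for mass, charge and atom count).
#' @param cfg A [thermo_config()].
#' @param source `"fit"` or `"data"` (see Details).
#' @param course The `dissociation_course` (required for `source = "data"`).
#' @return Data frame `dcv, t_eff, survival, k, keq`.
#' @export
temperature_points <- function(fit, ion, cfg = thermo_config(),
                               source = c("fit", "data"), course = NULL) {
  stopifnot(inherits(fit, "boltzmann_fit"), inherits(ion, "oligomer_ion"))
  source <- match.arg(source)
  lo <- fit$dcv50 + fit$dx * log(cfg$steep_lo / (1 - cfg$steep_lo))
  hi <- fit$dcv50 + fit$dx * log(cfg$steep_hi / (1 - cfg$steep_hi))
  if (source == "data") {
    if (is.null(course)) stop("source = 'data' needs the course")
    m <- course_means(course)
    keep <- m$dcv >= min(lo, hi) & m$dcv <= max(lo, hi) &
      m$mean > 0 & m$mean < 100
    if (sum(keep) < 3L) stop("fewer than 3 measured points in the steep region")
    dcv <- m$dcv[keep]
    y <- m$mean[keep]
  } else {
    dcv <- seq(min(lo, hi), max(lo, hi), length.out = cfg$n_steep)
    dcv <- dcv[dcv >= 0]
    if (length(dcv) < 3L) stop("steep region lies below dcv = 0")
    y <- boltzmann_value(fit, dcv)
  }
  survival <- pmin(pmax(y / 100, 1e-12), 1)
  prod_frac <- pmax(1 - survival, 0)
  keq <- (prod_frac / 2)^2 / survival
  data.frame(dcv = dcv,
             t_eff = cv_to_temperature(dcv, ion$z, ion$mass, ion$atom_count, cfg),
             survival = survival,
             k = survival_to_rate(survival, cfg),
             keq = keq)
}

#' Arrhenius extrapolation to ambient temperature
#'
#' Least-squares line of `ln k` versus `1/T_eff`; the apparent activation
#' energy is `-slope * R` and the rate constant is evaluated at `1/t_amb`.
#'
#' @param points Data frame with columns `t_eff` and `k` (e.g. from
#'   [temperature_points()]).
#' @param cfg A [thermo_config()].
#' @return List with `k_amb` (1/s), `ea` (J/mol), `ln_a`, `slope`,
#'   `intercept`, `r2`.
#' @export
arrhenius_extrapolate <- function(points, cfg = thermo_config()) {
  pts <- points[is.finite(points$k) & points$k > 0, , drop = FALSE]
  dropped <- nrow(points) - nrow(pts)
  if (dropped > 0) {
    warning(dropped, " point(s) with non-finite or zero k excluded from the Arrhenius fit")
  }
  if (nrow(pts) < 3L) stop("need >= 3 points with finite k for the Arrhenius fit")
  if (length(unique(pts$t_eff)) < 2L) {
    stop("all points share one effective temperature; Arrhenius design is singular")
  }
  fit <- stats::lm(log(k) ~ I(1 / t_eff), data = pts)
  cf <- stats::coef(fit)
  r2 <- .lm_r2(fit)
  list(k_amb = exp(cf[[1]] + cf[[2]] / cfg$t_amb),
       ea = -cf[[2]] * cfg$r_gas,
       ln_a = cf[[1]],
       slope = cf[[2]], intercept = cf[[1]], r2 = r2)
}

#' Gibbs-Helmholtz extrapolation to ambient temperature
#'
#' Converts each point's dissociation quotient to a Gibbs energy
#' `dG(T) = -R T ln keq`, fits the line `dG = dH - T dS`, and reports the
#' apparent enthalpy (intercept), entropy (negative slope) and the ambient
#' Gibbs energy `dG# = dH# - t_amb dS#` together with `t_amb dS#`, all in
#' kJ/mol.
#'
#' @param points Data frame with columns `t_eff` and `keq`.
#' @param cfg A [thermo_config()].
#' @return List with `dg_amb`, `dh`, `tds_amb` (kJ/mol), `ds` (kJ/(mol K)),
#'   `kd_amb` (unitless quotient at `t_amb`), `slope`, `intercept`, `r2`.
#' @export
gibbs_helmholtz_extrapolate <- function(points, cfg = thermo_config()) {
  pts <- points[is.finite(points$keq) & points$keq > 0, , drop = FALSE]
  if (nrow(pts) < 3L) stop("need >= 3 points with keq > 0 for the Gibbs-Helmholtz fit")
  if (length(unique(pts$t_eff)) < 2L) {
    stop("all points share one effective temperature; Gibbs-Helmholtz design is singular")
  }
  dg <- -cfg$r_gas * pts$t_eff * log(pts$keq)   # J/mol
  fit <- stats::lm(dg ~ t_eff, data = data.frame(t_eff = pts$t_eff, dg = dg))
  cf <- stats::coef(fit)
  dh <- cf[[1]]                                 # J/mol
  ds <- -cf[[2]]                                # J/(mol K)
  dg_amb <- dh - cfg$t_amb * ds
  list(dg_amb = dg_amb / 1000, dh = dh / 1000,
       tds_amb = cfg$t_amb * ds / 1000, ds = ds / 1000,
       kd_amb = exp(-dg_amb / (cfg$r_gas * cfg$t_amb)),
       slope = cf[[2]], intercept = cf[[1]],
       r2 = .lm_r2(fit))
}

# R^2 without summary.lm (which warns on numerically exact fits)
.lm_r2 <- function(fit) {
  y <- stats::fitted(fit) + stats::resid(fit)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::resid(fit)^2) / sst
}

#' Gibbs energy from a dissociation constant
#'
#' `dG = -R T ln(KD) / 1000` in kJ/mol.
#'
#' @param kd Unitless dissociation constant (> 0).
#' @param t Temperature in K.
#' @param r_gas Gas constant in J/(mol K).
#' @return Gibbs energy in kJ/mol.
#' @export
delta_g_from_kd <- function(kd, t = 298, r_gas = cid_constants$gas_constant) {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(t <= 0)) stop("temperature must be > 0")
  -r_gas * t * log(kd) / 1000
}

#' Full thermodynamic analysis of one fitted course
#'
#' Runs [temperature_points()], [arrhenius_extrapolate()] and
#' [gibbs_helmholtz_extrapolate()] and assembles the five apparent quantities.
#'
#' @param fit A [boltzmann_fit()] of the educt course.
#' @param ion The educt [oligomer_ion()].
#' @param cfg A [thermo_config()].
#' @param source,course Passed to [temperature_points()].
#' @return An object of class `thermo_result` with fields `k_m0g` (1/s),
#'   `kd_m0g` (unitless), `dg_m0g`, `dh_m0g`, `tds_m0g` (kJ/mol), the two
#'   regression diagnostics (`arrhenius`, `gibbs_helmholtz`), the
#'   `temperature points` used, and the configuration.
#' @export
analyze_thermo <- function(fit, ion, cfg = thermo_config(),
                           source = c("fit", "data"), course = NULL) {
  pts <- temperature_points(fit, ion, cfg, source = source, course = course)
  arr <- arrhenius_extrapolate(pts, cfg)
  gh <- gibbs_helmholtz_extrapolate(pts, cfg)
  structure(list(complex = ion$species$symbol,
                 k_m0g = arr$k_amb,
                 kd_m0g = gh$kd_amb,
                 dg_m0g = gh$dg_amb,
                 dh_m0g = gh$dh,
                 tds_m0g = gh$tds_amb,
                 arrhenius = arr, gibbs_helmholtz = gh,
                 points = pts, cfg = cfg),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("<thermo_result>", x$complex, "\n")
  cat(sprintf("  k#   %.3g 1/s   KD#  %.3g\n", x$k_m0g, x$kd_m0g))
  cat(sprintf("  dG#  %.2f kJ/mol   dH#  %.2f kJ/mol   T.dS#  %.2f kJ/mol\n",
              x$dg_m0g, x$dh_m0g, x$tds_m0g))
  invisible(x)
}

#' Internal-consistency checks of a thermodynamic result
#'
#' Evaluates the two identities that link the reported columns:
#' `dG = dH - T dS` and `dG = -R T ln KD`, flagging deviations larger than
#' `tol` kJ/mol.
#'
#' @param result A `thermo_result`, or a list/row with fields `kd_m0g`,
#'   `dg_m0g`, `dh_m0g`, `tds_m0g`.
#' @param cfg A [thermo_config()].
#' @param tol Flag threshold in kJ/mol (default 0.02).
#' @return Data frame `check, expected, actual, deviation, ok`.
#' @export
consistency_report <- function(result, cfg = thermo_config(), tol = 0.02) {
  gh <- result$dh_m0g - result$tds_m0g
  kd <- delta_g_from_kd(result$kd_m0g, cfg$t_amb, cfg$r_gas)
  out <- data.frame(
    check = c("dG = dH - T.dS", "dG = -R T ln KD"),
    expected = c(result$dg_m0g, result$dg_m0g),
    actual = c(gh, kd))
  out$deviation <- abs(out$actual - out$expected)
  out$ok <- out$deviation <= tol
  out
}
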
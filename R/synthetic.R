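# Synthetic dissociation experiments with known ground truth.
#
# Two generators: (a) Boltzmann-course simulation emulating measured educt
# decay / product rise shapes on the standard voltage grids, and (b) a
# thermodynamic forward model that produces a course from known apparent
# (dH, dS) through the voltage-to-temperature conversion, for end-to-end
# parameter-recovery tests.

#' Standard collision-voltage grids
#'
#' The two replicate series grids used throughout: a dense 17-step series
#' (0-55 V) and a sparse 8-step subset.
#'
#' @return List with `series1` and `series2` numeric vectors (V).
#' @export
standard_dcv_grids <- function() {
  list(series1 = c(0, 2, 4, 6, 8, 10, 12, 15, 18, 22, 26, 30, 35, 40, 45, 50, 55),
       series2 = c(4, 8, 12, 18, 26, 35, 45, 55))
}

#' Simulation specification
#'
#' @param fit A [boltzmann_fit()] giving the educt decay law.
#' @param educt Educt species symbol.
#' @param channels List of release channels, each a list with `dimer` and
#'   `monomer` species symbols; one channel for homo-trimers, two for
#'   hetero-trimers.
#' @param branching Fraction of dissociation events going through the first
#'   channel (in `[0, 1]`); ignored for a single channel. The statistical
#'   default for a trimer with one odd monomer is 2/3 loss of the majority
#'   monomer, supplied by the caller.
#' @param grids List of voltage grids, one per replicate series (default: the
#'   two [standard_dcv_grids()]).
#' @param noise_sd Gaussian noise sd in absolute percent added per replicate
#'   point (default 0 = noiseless).
#' @param detection_efficiency Named numeric relative detection efficiencies
#'   applied per species before renormalization (default all 1).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(fit, educt, channels, branching = 1,
                            grids = standard_dcv_grids(), noise_sd = 0,
                            detection_efficiency = NULL, seed = NULL) {
  stopifnot(inherits(fit, "boltzmann_fit"), length(channels) >= 1L)
  if (branching < 0 || branching > 1) stop("branching must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (g in grids) {
    if (any(diff(g) <= 0)) stop("voltage grids must be strictly increasing")
  }
  structure(list(fit = fit, educt = educt, channels = channels,
                 branching = branching, grids = grids, noise_sd = noise_sd,
                 detection_efficiency = detection_efficiency, seed = seed),
            class = "simulation_spec")
}

# Noise-free normalized percent per species at the given voltages.
.true_fractions <- function(spec, dcv) {
  educt_pct <- boltzmann_value(spec$fit, dcv)
  educt_pct <- pmin(pmax(educt_pct, 0), 100)
  prod_pct <- 100 - educt_pct
  w <- if (length(spec$channels) == 1L) 1 else c(spec$branching, 1 - spec$branching)
  species <- spec$educt
  mat <- matrix(educt_pct, nrow = length(dcv))
  for (i in seq_along(spec$channels)) {
    ch <- spec$channels[[i]]
    # each dissociation event yields one dimer and one monomer ion
    for (role in c("dimer", "monomer")) {
      sym <- ch[[role]]
      col <- prod_pct * w[i] / 2
      j <- match(sym, species)
      if (is.na(j)) {
        species <- c(species, sym)
        mat <- cbind(mat, col)
      } else {
        mat[, j] <- mat[, j] + col
      }
    }
  }
  colnames(mat) <- species
  mat
}

#' Simulate a dissociation course
#'
#' The educt follows the specified Boltzmann law; the complementary product
#' percentage is split across release channels by the branching fraction and
#' equally between the dimer and the monomer ion within a channel. Gaussian
#' noise (absolute %, truncated at 0) is added per replicate point, then each
#' scan is renormalized to 100%. Scans whose noisy total is not positive are
#' resampled with a warning.
#'
#' @param spec A [simulation_spec()].
#' @return A `dissociation_course` whose `ground_truth` attribute records the
#'   generating parameters and the noise-free fractions.
#' @export
simulate_course <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- list()
  for (r in seq_along(spec$grids)) {
    grid <- spec$grids[[r]]
    truth <- .true_fractions(spec, grid)
    if (!is.null(spec$detection_efficiency)) {
      eff <- spec$detection_efficiency[colnames(truth)]
      eff[is.na(eff)] <- 1
      truth <- sweep(truth, 2, eff, "*")
      truth <- truth / rowSums(truth) * 100
    }
    for (i in seq_along(grid)) {
      vals <- truth[i, ]
      if (spec$noise_sd > 0) {
        repeat {
          noisy <- pmax(vals + stats::rnorm(length(vals), 0, spec$noise_sd), 0)
          if (sum(noisy) > 0) break
          warning("noisy scan total <= 0 at dcv = ", grid[i], "; resampling")
        }
        vals <- noisy
      }
      vals <- normalize_scan(vals, dcv = grid[i])
      rows[[length(rows) + 1L]] <- data.frame(
        species = names(vals), dcv = grid[i],
        series_id = paste0("sim", r), normalized = as.numeric(vals),
        row.names = NULL)
    }
  }
  data <- do.call(rbind, rows)
  data <- data[order(data$species, data$dcv, data$series_id), , drop = FALSE]
  rownames(data) <- NULL
  course <- new_dissociation_course(
    data, educt = spec$educt,
    products = setdiff(unique(data$species), spec$educt))
  attr(course, "ground_truth") <- list(
    fit = spec$fit, branching = spec$branching, noise_sd = spec$noise_sd,
    seed = spec$seed)
  course
}

#' Emit synthetic peak tables from a course
#'
#' One peak per species per scan at its calculated m/z, with intensity equal
#' to the course's normalized fraction (so a round trip through
#' [build_course()] reproduces the course exactly).
#'
#' @param course A `dissociation_course`.
#' @param ions Named list of [oligomer_ion()]s keyed by species symbol,
#'   covering every species in the course.
#' @param min_spacing Minimum m/z spacing between species; closer pairs are
#'   an error (they could not be resolved by windowed extraction).
#' @return List of [scan_peak_table()]s.
#' @export
emit_peak_tables <- function(course, ions, min_spacing = 1) {
  stopifnot(inherits(course, "dissociation_course"))
  species <- unique(course$data$species)
  missing <- setdiff(species, names(ions))
  if (length(missing) > 0L) {
    stop("no ion definition for species: ", paste(missing, collapse = ", "))
  }
  mzv <- vapply(species, function(s) ions[[s]]$mz_calc, numeric(1))
  d <- diff(sort(mzv))
  if (length(d) > 0 && any(d < min_spacing)) {
    stop("m/z collision between species (spacing < ", min_spacing, ")")
  }
  key <- interaction(course$data$series_id, course$data$dcv, drop = TRUE)
  unname(lapply(split(course$data, key), function(sc) {
    scan_peak_table(sc$series_id[1], sc$dcv[1],
                    mz = mzv[sc$species], intensity = sc$normalized)
  }))
}

#' Simulate a course from known apparent thermodynamics (forward model)
#'
#' Generates the educt survival on a voltage grid from a dissociation
#' quotient law `keq(T) = exp(-(dH - T dS) / (R T))` evaluated at the
#' effective temperature of each voltage, inverting
#' `keq = ((1 - s)/2)^2 / s` for the survival `s`. This is the exact inverse
#' of the analysis pipeline's quotient construction, so analyzing the
#' simulated course must recover `dH` and `dS` (the end-to-end oracle).
#'
#' Note on magnitudes: the default voltage-to-temperature model maps the
#' 0-55 V grid onto a few kelvin above `t0`, so apparent (dH, dS) pairs
#' placing the transition inside the grid are necessarily large; they are
#' effective quantities tied to the conversion model, not molecular ones.
#'
#' @param dh Apparent dissociation enthalpy in kJ/mol.
#' @param ds Apparent dissociation entropy in kJ/(mol K).
#' @param ion The educt [oligomer_ion()].
#' @param channels,branching,grids,noise_sd,seed As in [simulation_spec()].
#' @param cfg A [thermo_config()].
#' @return A `dissociation_course` with a `ground_truth` attribute recording
#'   `dh`, `ds` and the derived `tds_amb` and `dg_amb`.
#' @export
simulate_thermo_course <- function(dh, ds, ion, channels, branching = 1,
                                   grids = standard_dcv_grids(), noise_sd = 0,
                                   seed = NULL, cfg = thermo_config()) {
  stopifnot(inherits(ion, "oligomer_ion"))
  if (!is.null(seed)) set.seed(seed)
  dh_j <- dh * 1000; ds_j <- ds * 1000
  rows <- list()
  for (r in seq_along(grids)) {
    grid <- grids[[r]]
    t_eff <- cv_to_temperature(grid, ion$z, ion$mass, ion$atom_count, cfg)
    q <- exp(-(dh_j - t_eff * ds_j) / (cfg$r_gas * t_eff))
    # survival from ((1-s)/2)^2 = q s  =>  s^2 - 2(1 + 2q)s + 1 = 0
    s <- (1 + 2 * q) - sqrt((1 + 2 * q)^2 - 1)
    educt_pct <- 100 * s
    w <- if (length(channels) == 1L) 1 else c(branching, 1 - branching)
    for (i in seq_along(grid)) {
      vals <- c(educt_pct[i])
      names(vals) <- ion$species$symbol
      prod_pct <- 100 - educt_pct[i]
      for (ci in seq_along(channels)) {
        for (role in c("dimer", "monomer")) {
          sym <- channels[[ci]][[role]]
          vals[sym] <- (if (is.na(vals[sym])) 0 else vals[sym]) +
            prod_pct * w[ci] / 2
        }
      }
      vals[is.na(vals)] <- 0
      if (noise_sd > 0) {
        repeat {
          noisy <- pmax(vals + stats::rnorm(length(vals), 0, noise_sd), 0)
          if (sum(noisy) > 0) break
          warning("noisy scan total <= 0 at dcv = ", grid[i], "; resampling")
        }
        vals <- noisy
      }
      vals <- normalize_scan(vals, dcv = grid[i])
      rows[[length(rows) + 1L]] <- data.frame(
        species = names(vals), dcv = grid[i], series_id = paste0("sim", r),
        normalized = as.numeric(vals), row.names = NULL)
    }
  }
  data <- do.call(rbind, rows)
  data <- data[order(data$species, data$dcv, data$series_id), , drop = FALSE]
  rownames(data) <- NULL
  course <- new_dissociation_course(
    data, educt = ion$species$symbol,
    products = setdiff(unique(data$species), ion$species$symbol))
  attr(course, "ground_truth") <- list(
    dh = dh, ds = ds, tds_amb = cfg$t_amb * ds,
    dg_amb = dh - cfg$t_amb * ds, noise_sd = noise_sd, seed = seed)
  course
}
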
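# Report generation: species tables, end-to-end course analysis, and the
# writers used by the command-line interface.

#' Species table for a proteoform mixture
#'
#' Enumerates all oligomer species of a two-proteoform mixture at the given
#' charge states and tabulates symbol, calculated m/z, charge and atom count
#' (m/z rounded to 2 decimals at this reporting surface only).
#'
#' @param proteoforms Registry of one or two [proteoform()]s.
#' @param trimer_z,dimer_z,monomer_z Charge states per role.
#' @return Data frame `symbol, role, mz_calc, z, atom_no`.
#' @export
species_table <- function(proteoforms, trimer_z = 5L, dimer_z = 3L,
                          monomer_z = 2L) {
  stopifnot(length(proteoforms) %in% c(1L, 2L))
  pA <- proteoforms[[1]]
  pB <- proteoforms[[length(proteoforms)]]
  mix <- enumerate_mixture_species(pA, pB)
  zs <- c(trimer = trimer_z, dimer = dimer_z, monomer = monomer_z)
  rows <- list()
  for (grp in c("trimers", "dimers", "monomers")) {
    for (sp in mix[[grp]]) {
      ion <- oligomer_ion(sp, zs[[sp$role]], mix$proteoforms)
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = sp$symbol, role = sp$role,
        mz_calc = round(ion$mz_calc, 2), z = ion$z,
        atom_no = ion$atom_count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze a set of dissociation courses end to end
#'
#' For each course: fit the Boltzmann sigmoid to the educt decay, derive the
#' midpoint tangent, convert to effective-temperature points and extrapolate
#' the apparent kinetic and quasi-thermodynamic quantities to ambient
#' temperature, with internal-consistency checks.
#'
#' @param courses Named list of `dissociation_course` objects (names =
#'   educt symbols).
#' @param ions Named list of [oligomer_ion()]s covering the educts.
#' @param cfg A [thermo_config()].
#' @return An object of class `cid_analysis`: list with `fits`,
#'   `fit_table` (breakdown-curve characteristics), `thermo` (list of
#'   `thermo_result`s), `thermo_table`, and `consistency`.
#' @export
analyze_courses <- function(courses, ions, cfg = thermo_config()) {
  stopifnot(length(courses) >= 1L)
  if (is.null(names(courses))) {
    names(courses) <- vapply(courses, `[[`, character(1), "educt")
  }
  fits <- lapply(courses, fit_boltzmann)
  thermo <- lapply(names(courses), function(nm) {
    analyze_thermo(fits[[nm]], ions[[nm]], cfg)
  })
  names(thermo) <- names(courses)
  structure(list(
    fits = fits,
    fit_table = boltzmann_table(fits),
    thermo = thermo,
    thermo_table = thermo_table(thermo),
    consistency = do.call(rbind, lapply(names(thermo), function(nm) {
      cbind(complex = nm, consistency_report(thermo[[nm]], cfg))
    })),
    cfg = cfg), class = "cid_analysis")
}

#' @export
print.cid_analysis <- function(x, ...) {
  cat("<cid_analysis> of", nrow(x$fit_table), "complex(es)\n\n")
  cat("Breakdown-curve characteristics:\n")
  print(x$fit_table, row.names = FALSE)
  cat("\nApparent quantities at ambient temperature:\n")
  print(x$thermo_table, row.names = FALSE)
  invisible(x)
}

#' Apparent-quantity table
#'
#' One row per complex with the five ambient-temperature quantities: rate
#' constant and dissociation quotient at 3 significant figures, energies in
#' kJ/mol at 2 decimals. Rounding happens only here.
#'
#' @param results Named list of `thermo_result`s.
#' @return Data frame.
#' @export
thermo_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(complex = r$complex,
               k_m0g = signif(r$k_m0g, 3),
               kd_m0g = signif(r$kd_m0g, 3),
               dg_m0g = round(r$dg_m0g, 2),
               dh_m0g = round(r$dh_m0g, 2),
               tds_m0g = round(r$tds_m0g, 2),
               arrhenius_r2 = round(r$arrhenius$r2, 4),
               gibbs_helmholtz_r2 = round(r$gibbs_helmholtz$r2, 4))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis to CSV/JSON files
#'
#' Writes `fit_table.csv`, `thermo_table.csv`, `consistency.csv` and a
#' machine-readable `analysis.json` into `dir`. Output is deterministic for
#' identical inputs.
#'
#' @param analysis A `cid_analysis`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "cid_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("fit_table.csv", "thermo_table.csv",
                            "consistency.csv", "analysis.json"))
  utils::write.csv(analysis$fit_table, paths[1], row.names = FALSE)
  utils::write.csv(analysis$thermo_table, paths[2], row.names = FALSE)
  utils::write.csv(analysis$consistency, paths[3], row.names = FALSE)
  jsonlite::write_json(
    list(fit_table = analysis$fit_table,
         thermo_table = analysis$thermo_table,
         consistency = analysis$consistency,
         config = analysis$cfg[c("t0", "t_amb", "gas_mass", "residence_time",
                                 "r_gas", "steep_lo", "steep_hi")]),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
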
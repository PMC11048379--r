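# Reference study system: the T4 phage fibritin foldon (F), a 27-residue
# miniprotein that spontaneously trimerizes, and its N-terminally
# biotinylated form (bF, biotin plus two 8-amino-3,6-dioxa-octanoic acid
# spacers mimicking an intrinsically disordered region). Mixing the two
# proteoforms yields four trimers whose quintuply protonated ions dissociate
# into 3+ dimers and 2+ monomers under collision activation.

#' Reference foldon proteoforms
#'
#' The unmodified foldon is defined by its elemental composition
#' C142H214N36O41 (monoisotopic 3079.58 Da, 433 atoms). The biotinylated
#' foldon is defined by its declared monoisotopic mass 3594.82 Da and atom
#' count 505: its published formula is inconsistent with that mass and atom
#' count, and the package never silently corrects a formula, so the
#' declared-value route is used for this fixture.
#'
#' @return Named list of two [proteoform()]s (`F`, `bF`).
#' @export
foldon_proteoforms <- function() {
  pF <- proteoform("F", "T4 fibritin foldon",
                   composition = "C142H214N36O41")
  pbF <- proteoform("bF", "biotinylated T4 fibritin foldon",
                    monoiso_mass = 3594.82, atom_count = 505L)
  stats::setNames(list(pF, pbF), c("F", "bF"))
}

#' Reference foldon oligomer ions
#'
#' The nine species observable in a foldon / biotinylated-foldon mixture at
#' their standard analysis charge states: four trimers (5+), three dimers
#' (3+), two monomers (2+).
#'
#' @param proteoforms Proteoform registry (default [foldon_proteoforms()]).
#' @param trimer_z,dimer_z,monomer_z Charge states.
#' @return Named list of [oligomer_ion()]s keyed by species symbol.
#' @export
foldon_ions <- function(proteoforms = foldon_proteoforms(),
                        trimer_z = 5L, dimer_z = 3L, monomer_z = 2L) {
  mix <- enumerate_mixture_species(proteoforms[[1]], proteoforms[[2]])
  zs <- c(trimer = trimer_z, dimer = dimer_z, monomer = monomer_z)
  ions <- list()
  for (grp in c("trimers", "dimers", "monomers")) {
    for (sp in mix[[grp]]) {
      ions[[sp$symbol]] <- oligomer_ion(sp, zs[[sp$role]], proteoforms)
    }
  }
  ions
}

#' Reference breakdown-curve parameters of the four foldon trimers
#'
#' Boltzmann parameters (initial %, final %, midpoint V, width V)
#' characterising the measured 5+ trimer dissociation courses of the foldon
#' study system; used as the default ground truth of the synthetic generator.
#'
#' @return Named list of [boltzmann_fit()]s keyed by trimer symbol.
#' @export
foldon_reference_fits <- function() {
  list(
    "F-F-F"    = boltzmann_fit(98.78, 0.00, 17.03, 1.70),
    "F-F-bF"   = boltzmann_fit(99.64, 0.00, 16.93, 2.32),
    "F-bF-bF"  = boltzmann_fit(100.00, 0.00, 20.51, 2.95),
    "bF-bF-bF" = boltzmann_fit(100.00, 0.26, 19.57, 1.84))
}

#' Reference apparent thermodynamics of the four foldon trimers
#'
#' The reported ambient-temperature apparent quantities of the four trimer
#' dissociation reactions: rate constant (1/s), dissociation quotient
#' (unitless), Gibbs energy, enthalpy and entropy term (kJ/mol).
#'
#' @return Data frame with one row per trimer.
#' @export
foldon_reference_thermo <- function() {
  data.frame(
    complex = c("F-F-F", "F-F-bF", "F-bF-bF", "bF-bF-bF"),
    k_m0g  = c(2.17e7, 9.16e8, 7.83e8, 8.68e6),
    kd_m0g = c(3.16e-12, 3.58e-12, 3.62e-12, 3.06e-12),
    dg_m0g = c(65.61, 65.30, 65.27, 65.68),
    dh_m0g = c(3.32, 1.86, 1.08, 3.85),
    tds_m0g = c(-62.29, -63.44, -64.19, -61.84))
}

#' Release channels of a foldon trimer
#'
#' The distinct (dimer, monomer) product pairs of a trimer, as channel lists
#' for the synthetic generator, together with the statistical branching
#' fraction of the first channel (2/3 when two of three monomers are of the
#' first type, etc.).
#'
#' @param symbol Trimer symbol, e.g. `"F-F-bF"`.
#' @param proteoforms Proteoform registry.
#' @return List with `channels` and `branching`.
#' @export
foldon_channels <- function(symbol, proteoforms = foldon_proteoforms()) {
  ids <- strsplit(symbol, "-", fixed = TRUE)[[1]]
  educt <- oligomer_ion(ids, 5L, proteoforms)
  rxn <- dissociation_products(educt, proteoforms)
  channels <- lapply(rxn$product_pairs, function(p)
    list(dimer = p$dimer$symbol, monomer = p$monomer$symbol))
  branching <- if (length(channels) == 1L) 1 else {
    # statistical: a channel's weight is the fraction of monomers it releases
    mean(ids == channels[[1]]$monomer)
  }
  list(channels = channels, branching = branching)
}
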
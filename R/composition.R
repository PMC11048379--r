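# Mass, m/z and atom-count calculus for proteoform monomers and their
# non-covalent oligomer ions, plus enumeration of the dissociation reactions
# of two-proteoform trimer mixtures.

#' Elemental composition
#'
#' Create an elemental composition from a named count vector or a molecular
#' formula string such as `"C142H214N36O41"`.
#'
#' @param x Named numeric vector of non-negative integer element counts, or a
#'   single formula string.
#' @return An object of class `elemental_composition`: a named integer vector.
#' @examples
#' elemental_composition("C142H214N36O41")
#' elemental_composition(c(C = 1, H = 4))
#' @export
elemental_composition <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- parse_formula(x)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("element counts must be named by element symbol")
  }
  if (any(x < 0) || any(x != round(x))) {
    stop("element counts must be non-negative integers")
  }
  x <- x[x > 0]
  if (length(x) == 0L) {
    stop("composition must contain at least one element with count > 0")
  }
  unknown <- setdiff(names(x), names(.monoiso_masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  structure(stats::setNames(as.integer(round(x)), names(x)),
            class = "elemental_composition")
}

#' Parse a molecular formula string
#'
#' @param formula Formula such as `"C164H251N41O36S"`. Element symbols are one
#'   upper-case letter optionally followed by a lower-case letter; a missing
#'   count means 1.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[_ ]", "", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula: ", formula)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]", tokens), sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(cnt, els, sum)[unique(els)]
}

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of count times the standard monoisotopic atomic mass
#' (carbon-12 scale).
#'
#' @param composition An [elemental_composition()] (or something coercible).
#' @return Mass in Da (full precision; round only for presentation).
#' @examples
#' monoisotopic_mass(elemental_composition("C142H214N36O41")) # 3079.5767
#' @export
monoisotopic_mass <- function(composition) {
  if (!inherits(composition, "elemental_composition")) {
    composition <- elemental_composition(composition)
  }
  sum(.monoiso_masses[names(composition)] * as.numeric(composition))
}

#' Define a proteoform
#'
#' A proteoform is a monomer building block of the oligomers under study,
#' identified by a short label. At least one of `composition` or
#' `monoiso_mass` must be given. When both are present the composition-derived
#' mass is used for all derived quantities and the declared mass is kept for
#' cross-checks; a disagreement beyond `tol` Da triggers a warning (user input
#' is never silently corrected).
#'
#' @param id Short label, e.g. `"F"`.
#' @param name Free-text name.
#' @param composition Optional [elemental_composition()] or formula string.
#' @param monoiso_mass Optional declared monoisotopic mass in Da.
#' @param avg_mass Optional average mass in Da.
#' @param atom_count Optional declared atom count (validated against the
#'   composition when both are present).
#' @param tol Da tolerance for the composition-vs-declared-mass cross-check.
#' @return An object of class `proteoform`.
#' @export
proteoform <- function(id, name = id, composition = NULL, monoiso_mass = NULL,
                       avg_mass = NULL, atom_count = NULL, tol = 0.02) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("-", id, fixed = TRUE)) stop("proteoform id must not contain '-'")
  if (is.null(composition) && is.null(monoiso_mass)) {
    stop("proteoform '", id, "': need a composition and/or a monoisotopic mass")
  }
  if (!is.null(composition) && !inherits(composition, "elemental_composition")) {
    composition <- elemental_composition(composition)
  }
  if (!is.null(monoiso_mass) && monoiso_mass <= 0) {
    stop("monoiso_mass must be positive")
  }
  if (!is.null(composition) && !is.null(monoiso_mass)) {
    m <- monoisotopic_mass(composition)
    if (abs(m - monoiso_mass) > tol) {
      warning(sprintf(paste0(
        "proteoform '%s': composition-derived monoisotopic mass %.4f Da ",
        "disagrees with declared mass %.4f Da (|diff| > %.3g Da); ",
        "the composition will be used for derived quantities"),
        id, m, monoiso_mass, tol))
    }
  }
  if (!is.null(composition) && !is.null(atom_count) &&
      sum(composition) != atom_count) {
    warning(sprintf(
      "proteoform '%s': composition has %d atoms but %d were declared",
      id, sum(composition), as.integer(atom_count)))
  }
  structure(list(id = id, name = name, composition = composition,
                 monoiso_mass = monoiso_mass, avg_mass = avg_mass,
                 atom_count = atom_count),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform>", x$id, "-", x$name, "\n")
  cat("  monoisotopic mass:", format(proteoform_mass(x), nsmall = 4), "Da\n")
  if (!is.null(x$composition)) {
    cat("  composition:", paste0(names(x$composition), x$composition, collapse = ""),
        sprintf("(%d atoms)\n", sum(x$composition)))
  }
  invisible(x)
}

#' Working monoisotopic mass of a proteoform
#'
#' Composition-derived mass when a composition is present, otherwise the
#' declared monoisotopic mass.
#' @param p A [proteoform()].
#' @return Mass in Da.
#' @export
proteoform_mass <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  if (!is.null(p$composition)) monoisotopic_mass(p$composition) else p$monoiso_mass
}

.proteoform_atoms <- function(p) {
  if (!is.null(p$composition)) return(sum(p$composition))
  if (!is.null(p$atom_count)) return(as.integer(p$atom_count))
  stop("proteoform '", p$id, "' has neither a composition nor a declared atom count")
}

#' Oligomer species
#'
#' A stoichiometry of proteoforms (size 1-3). The symbol is canonical:
#' members are ordered by the reference order of `proteoforms` (so the
#' unmodified proteoform, listed first in the registry, precedes modified
#' ones), joined by `-`, e.g. `"F-bF-bF"`.
#'
#' @param stoichiometry Character vector of proteoform ids (with repeats).
#' @param proteoforms A proteoform registry (named list of [proteoform()]s)
#'   fixing the canonical ordering.
#' @return An object of class `oligomer_species` with fields `stoichiometry`,
#'   `symbol` and `role` (`"trimer"`, `"dimer"` or `"monomer"`).
#' @export
oligomer_species <- function(stoichiometry, proteoforms) {
  stopifnot(length(stoichiometry) >= 1L, length(stoichiometry) <= 3L)
  ids <- names(proteoforms)
  if (!all(stoichiometry %in% ids)) {
    stop("unknown proteoform id(s): ",
         paste(setdiff(stoichiometry, ids), collapse = ", "))
  }
  stoich <- stoichiometry[order(match(stoichiometry, ids))]
  role <- c("monomer", "dimer", "trimer")[length(stoich)]
  structure(list(stoichiometry = stoich,
                 symbol = paste(stoich, collapse = "-"),
                 role = role),
            class = "oligomer_species")
}

#' @export
print.oligomer_species <- function(x, ...) {
  cat("<oligomer_species>", x$symbol, sprintf("(%s)\n", x$role))
  invisible(x)
}

#' Total atom count of an oligomer species
#'
#' Sum of the monomer atom counts; charging protons are not counted. The atom
#' count feeds the vibrational degrees of freedom (3N - 6) used in the
#' collision-voltage to effective-temperature conversion.
#'
#' @param species An [oligomer_species()].
#' @param proteoforms Proteoform registry.
#' @return Integer atom count.
#' @examples
#' # a trimer of C142H214N36O41 monomers has 3 x 433 = 1299 atoms
#' @export
atom_count <- function(species, proteoforms) {
  stopifnot(inherits(species, "oligomer_species"))
  sum(vapply(species$stoichiometry,
             function(id) .proteoform_atoms(proteoforms[[id]]), numeric(1)))
}

#' Neutral monoisotopic mass of an oligomer species
#' @inheritParams atom_count
#' @return Mass in Da (sum of monomer monoisotopic masses).
#' @export
species_mass <- function(species, proteoforms) {
  stopifnot(inherits(species, "oligomer_species"))
  sum(vapply(species$stoichiometry,
             function(id) proteoform_mass(proteoforms[[id]]), numeric(1)))
}

#' Oligomer ion
#'
#' A charged (protonated) oligomer species. The m/z and atom count are derived
#' on construction.
#'
#' @param species An [oligomer_species()] or a stoichiometry character vector.
#' @param z Positive integer charge (number of added protons).
#' @param proteoforms Proteoform registry.
#' @return An object of class `oligomer_ion` with `species`, `z`, `mz_calc`
#'   (Da/charge) and `atom_count`.
#' @export
oligomer_ion <- function(species, z, proteoforms) {
  if (!inherits(species, "oligomer_species")) {
    species <- oligomer_species(species, proteoforms)
  }
  if (length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge z must be a positive integer")
  }
  structure(list(species = species, z = as.integer(z),
                 mz_calc = mz(species, z, proteoforms),
                 atom_count = atom_count(species, proteoforms),
                 mass = species_mass(species, proteoforms)),
            class = "oligomer_ion")
}

#' @export
print.oligomer_ion <- function(x, ...) {
  cat(sprintf("<oligomer_ion> %s %d+  m/z %.2f  (%d atoms)\n",
              x$species$symbol, x$z, x$mz_calc, x$atom_count))
  invisible(x)
}

#' m/z of a protonated oligomer
#'
#' `(sum of monomer monoisotopic masses + z * m_proton) / z` with the bare
#' proton mass 1.00727646 Da. Full precision; round to 2 decimals only for
#' presentation.
#'
#' @param species An [oligomer_species()].
#' @param z Positive integer charge.
#' @param proteoforms Proteoform registry.
#' @return m/z in Da per charge.
#' @export
mz <- function(species, z, proteoforms) {
  if (length(z) != 1L || z < 1 || z != round(z)) {
    stop("charge z must be a positive integer (got ", z, ")")
  }
  (species_mass(species, proteoforms) + z * cid_constants$proton_mass) / z
}

#' Enumerate the oligomer species of a two-proteoform mixture
#'
#' For two distinct proteoforms A and B this yields the 4 trimers, 3 dimers
#' and 2 monomers observable in a mixed assembly experiment, in deterministic
#' order (decreasing oligomer size, increasing number of modified monomers).
#' A degenerate mixture (same proteoform twice) yields one species per role.
#'
#' @param pA,pB [proteoform()]s; `pA` is the reference (unmodified) form.
#' @return Named list with elements `trimers`, `dimers`, `monomers` (lists of
#'   [oligomer_species()]) and `proteoforms` (the registry used).
#' @export
enumerate_mixture_species <- function(pA, pB) {
  stopifnot(inherits(pA, "proteoform"), inherits(pB, "proteoform"))
  reg <- stats::setNames(list(pA, pB), c(pA$id, pB$id))
  if (pA$id == pB$id) {
    reg <- reg[1]
    return(list(
      trimers  = list(oligomer_species(rep(pA$id, 3), reg)),
      dimers   = list(oligomer_species(rep(pA$id, 2), reg)),
      monomers = list(oligomer_species(pA$id, reg)),
      proteoforms = reg))
  }
  a <- pA$id; b <- pB$id
  list(
    trimers = list(
      oligomer_species(c(a, a, a), reg),
      oligomer_species(c(a, a, b), reg),
      oligomer_species(c(a, b, b), reg),
      oligomer_species(c(b, b, b), reg)),
    dimers = list(
      oligomer_species(c(a, a), reg),
      oligomer_species(c(a, b), reg),
      oligomer_species(c(b, b), reg)),
    monomers = list(
      oligomer_species(a, reg),
      oligomer_species(b, reg)),
    proteoforms = reg)
}

#' Dissociation reaction of a trimer ion
#'
#' Enumerates all distinct (dimer, monomer) partitions of a trimer's
#' stoichiometry: a homo-trimer has a single release channel, a hetero-trimer
#' has two (release of either monomer type). The default product charge split
#' for a 5+ educt is dimer 3+ / monomer 2+ and for a 6+ educt dimer 4+ /
#' monomer 2+; any split summing to the educt charge may be supplied.
#'
#' @param educt An [oligomer_ion()] whose species role is `"trimer"`.
#' @param proteoforms Proteoform registry.
#' @param charge_split Length-2 integer vector `c(dimer, monomer)` summing to
#'   the educt charge, or `NULL` for the default.
#' @return An object of class `dissociation_reaction` with the educt, a list
#'   of `product_pairs` (each a list with `dimer` and `monomer`
#'   [oligomer_species()]) and `product_charges`.
#' @export
dissociation_products <- function(educt, proteoforms, charge_split = NULL) {
  stopifnot(inherits(educt, "oligomer_ion"))
  if (educt$species$role != "trimer") {
    stop("dissociation products are defined for trimer educts, got ",
         educt$species$role)
  }
  if (is.null(charge_split)) {
    charge_split <- switch(as.character(educt$z),
                           "5" = c(dimer = 3L, monomer = 2L),
                           "6" = c(dimer = 4L, monomer = 2L),
                           stop("no default product charge split for z = ",
                                educt$z, "; supply charge_split"))
  }
  charge_split <- stats::setNames(as.integer(charge_split), c("dimer", "monomer"))
  if (sum(charge_split) != educt$z) {
    stop("product charges (", paste(charge_split, collapse = "+"),
         ") must sum to the educt charge ", educt$z)
  }
  stoich <- educt$species$stoichiometry
  pairs <- list()
  for (id in unique(stoich)) {
    rest <- stoich[-match(id, stoich)]
    pairs[[length(pairs) + 1L]] <- list(
      dimer = oligomer_species(rest, proteoforms),
      monomer = oligomer_species(id, proteoforms))
  }
  # deterministic order: monomer released in registry order
  ord <- order(match(vapply(pairs, function(p) p$monomer$symbol, character(1)),
                     names(proteoforms)))
  structure(list(educt = educt, product_pairs = pairs[ord],
                 product_charges = charge_split),
            class = "dissociation_reaction")
}

#' @export
print.dissociation_reaction <- function(x, ...) {
  cat(sprintf("<dissociation_reaction> %s %d+ ->\n",
              x$educt$species$symbol, x$educt$z))
  for (p in x$product_pairs) {
    cat(sprintf("  %s %d+ + %s %d+\n", p$dimer$symbol, x$product_charges["dimer"],
                p$monomer$symbol, x$product_charges["monomer"]))
  }
  invisible(x)
}
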
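# Mass, m/z and atom-count calculus and reaction enumeration.

test_that("monoisotopic masses follow standard atomic masses", {
  expect_equal(monoisotopic_mass(elemental_composition(c(H = 1))),
               1.0078250319)
  expect_identical(monoisotopic_mass(elemental_composition(c(C = 1))), 12)
  # the foldon monomer formula reproduces its published 2-decimal mass
  expect_equal(round(fx_mono_mass, 2), 3079.58)
  expect_error(elemental_composition(c(Xx = 2)), "Xx")
  expect_error(elemental_composition(c(C = -1)), "non-negative")
  expect_error(elemental_composition(c(C = 0)), "at least one element")
})

test_that("formula strings parse with counts, defaults and separators", {
  expect_equal(parse_formula("C142H214N36O41"),
               c(C = 142L, H = 214L, N = 36L, O = 41L),
               ignore_attr = TRUE)
  expect_equal(unname(parse_formula("C164H251N41O36S")[["S"]]), 1L)
  expect_equal(parse_formula("C_142_H_214_N_36_O_41"),
               parse_formula("C142H214N36O41"))
  expect_error(parse_formula("C142x"), "cannot parse")
})

test_that("declared-vs-composition disagreement warns but is preserved", {
  # the published biotinylated-foldon formula contradicts its declared mass
  expect_warning(
    p <- proteoform("x", composition = "C164H251N41O36S",
                    monoiso_mass = 3594.82),
    "disagrees")
  expect_equal(p$monoiso_mass, 3594.82)           # user input kept verbatim
  expect_equal(sum(p$composition), 493)           # formula kept verbatim
  # composition wins for derived mass
  expect_equal(proteoform_mass(p), monoisotopic_mass(p$composition))
  expect_warning(proteoform("y", composition = "C2H6O", atom_count = 10),
                 "declared")
  expect_error(proteoform("z"), "composition and/or")
})

test_that("atom counts reproduce the reference table and exclude protons", {
  reg <- fx_proteoforms
  expect_identical(atom_count(oligomer_species("F", reg), reg), 433)
  expect_identical(atom_count(oligomer_species(c("F", "F", "F"), reg), reg),
                   1299)
  expect_identical(atom_count(oligomer_species(c("F", "bF", "bF"), reg), reg),
                   1443)
  # counts are charge-independent (protons not counted)
  expect_identical(fx_ions[["F-F-F"]]$atom_count,
                   atom_count(fx_ions[["F-F-F"]]$species, reg))
})

test_that("m/z calculus matches the reference table at 2 decimals", {
  reg <- fx_proteoforms
  expect_equal(round(mz(oligomer_species(c("F", "F", "F"), reg), 5, reg), 2),
               1848.75)
  # one-proton adduct at z = 1
  expect_equal(mz(oligomer_species("F", reg), 1, reg),
               fx_mono_mass + 1.00727646)
  # hand-derived 6+ homo-trimer value from the full-precision monomer mass
  expect_equal(round((3 * fx_mono_mass + 6 * 1.00727646) / 6, 2), 1540.80)
  expect_equal(round(mz(oligomer_species(c("F", "F", "F"), reg), 6, reg), 2),
               1540.80)
  expect_error(mz(oligomer_species("F", reg), 0, reg), "positive integer")
})

test_that("composition-derived and declared-mass m/z agree within 0.02", {
  # published table masses are 2-decimal rounded, so both routes must agree
  # to within the propagated rounding for every mixture species
  reg2 <- list(
    F = proteoform("F", monoiso_mass = 3079.58),
    bF = proteoform("bF", monoiso_mass = 3594.82, atom_count = 505L))
  for (sym in names(fx_ions)) {
    ion <- fx_ions[[sym]]
    alt <- mz(oligomer_species(ion$species$stoichiometry, reg2), ion$z, reg2)
    expect_lt(abs(alt - ion$mz_calc), 0.02)
  }
})

test_that("mixture enumeration yields 4 trimers, 3 dimers, 2 monomers", {
  mix <- enumerate_mixture_species(fx_proteoforms$F, fx_proteoforms$bF)
  expect_equal(vapply(mix$trimers, `[[`, character(1), "symbol"),
               c("F-F-F", "F-F-bF", "F-bF-bF", "bF-bF-bF"))
  expect_equal(vapply(mix$dimers, `[[`, character(1), "symbol"),
               c("F-F", "F-bF", "bF-bF"))
  expect_equal(vapply(mix$monomers, `[[`, character(1), "symbol"),
               c("F", "bF"))
  # canonical symbol is order-insensitive: unmodified listed first
  reg <- fx_proteoforms
  expect_equal(oligomer_species(c("bF", "F", "bF"), reg)$symbol, "F-bF-bF")
})

test_that("degenerate single-proteoform mixture collapses to 3 species", {
  mix <- enumerate_mixture_species(fx_proteoforms$F, fx_proteoforms$F)
  expect_length(mix$trimers, 1)
  expect_length(mix$dimers, 1)
  expect_length(mix$monomers, 1)
  expect_equal(mix$trimers[[1]]$symbol, "F-F-F")
})

test_that("dissociation channels enumerate all stoichiometry partitions", {
  reg <- fx_proteoforms
  rxn <- dissociation_products(fx_ions[["F-F-bF"]], reg)
  chans <- lapply(rxn$product_pairs,
                  function(p) c(p$dimer$symbol, p$monomer$symbol))
  expect_equal(chans, list(c("F-bF", "F"), c("F-F", "bF")))
  expect_length(dissociation_products(fx_ions[["F-F-F"]], reg)$product_pairs, 1)
  expect_length(dissociation_products(fx_ions[["bF-bF-bF"]], reg)$product_pairs, 1)
  expect_equal(dissociation_products(fx_ions[["bF-bF-bF"]], reg)$product_pairs[[1]]$dimer$symbol,
               "bF-bF")
  expect_error(dissociation_products(fx_ions[["F-F"]], reg), "trimer")
  expect_error(dissociation_products(fx_ions[["F-F-F"]], reg,
                                     charge_split = c(3, 3)), "sum")
})

test_that("mass, atom and charge conservation hold for every reaction", {
  reg <- fx_proteoforms
  for (sym in c("F-F-F", "F-F-bF", "F-bF-bF", "bF-bF-bF")) {
    educt <- fx_ions[[sym]]
    rxn <- dissociation_products(educt, reg)
    expect_equal(sum(rxn$product_charges), educt$z)
    for (p in rxn$product_pairs) {
      expect_equal(species_mass(p$dimer, reg) + species_mass(p$monomer, reg),
                   species_mass(educt$species, reg), tolerance = 1e-13)
      expect_identical(atom_count(p$dimer, reg) + atom_count(p$monomer, reg),
                       educt$atom_count)
    }
  }
})
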
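# Effective-temperature conversion, rate/quotient construction and the two
# linear extrapolations.

test_that("voltage-temperature conversion is affine, increasing and correct", {
  cfg <- thermo_config()
  ion <- fx_ions[["F-F-F"]]
  expect_equal(cv_to_temperature(0, ion$z, ion$mass, ion$atom_count, cfg),
               cfg$t0)
  t1 <- cv_to_temperature(17.03, ion$z, ion$mass, ion$atom_count, cfg)
  t2 <- cv_to_temperature(34.06, ion$z, ion$mass, ion$atom_count, cfg)
  expect_equal(t2 - cfg$t0, 2 * (t1 - cfg$t0), tolerance = 1e-12)
  # single-line hand evaluation of the centre-of-mass equipartition model
  hand <- 5 * 1.602176634e-19 * 17.03 * 39.948 / (39.948 + ion$mass) /
    ((3 * 1299 - 6) * 1.380649e-23)
  expect_equal(t1 - cfg$t0, hand)
  tt <- cv_to_temperature(seq(0, 55, 5), ion$z, ion$mass, ion$atom_count, cfg)
  expect_true(all(diff(tt) > 0))
  expect_error(cv_to_temperature(10, 5, 100, 1, cfg), "atom_count")
  # the conversion model is pluggable
  cfg2 <- thermo_config(cv_model = function(dcv, z, m, n, cfg) 300 + 10 * dcv)
  expect_equal(cv_to_temperature(2, 5, 1, 1, cfg2), 320)
})

test_that("survival converts to first-order rate constants", {
  cfg <- thermo_config(residence_time = 1)
  expect_equal(survival_to_rate(1, cfg), 0)
  expect_equal(survival_to_rate(exp(-1), cfg), 1)
  cfg2 <- thermo_config(residence_time = 1e-4)
  expect_equal(survival_to_rate(0.5, cfg2), log(2) * 1e4)
  expect_error(survival_to_rate(0, cfg), "survival")
})

test_that("dissociation quotient follows (dimer x monomer)/trimer", {
  expect_equal(equilibrium_quotient(0.5, 0.25, 0.25), 0.125)
  expect_equal(equilibrium_quotient(0.8, 0.1, 0.1), 0.0125)
  expect_equal(equilibrium_quotient(0.5, 0.25, 0), 0)
  # hetero-trimer channels summed before the quotient by default
  expect_equal(equilibrium_quotient(0.5, c(0.15, 0.10), c(0.15, 0.10)),
               0.25 * 0.25 / 0.5)
  expect_equal(equilibrium_quotient(0.5, c(0.15, 0.10), c(0.15, 0.10),
                                    sum_channels = FALSE),
               c(0.15, 0.10) * c(0.15, 0.10) / 0.5)
  expect_error(equilibrium_quotient(0, 0.5, 0.5), "trimer")
})

test_that("Arrhenius regression recovers a closed-form rate law", {
  a <- 5e8; ea <- 120e3; cfg <- thermo_config()
  t <- seq(400, 900, length.out = 12)
  pts <- data.frame(t_eff = t, k = a * exp(-ea / (cfg$r_gas * t)))
  out <- arrhenius_extrapolate(pts, cfg)
  expect_equal(out$ea, ea, tolerance = 1e-6)
  expect_equal(exp(out$ln_a), a, tolerance = 1e-6)
  expect_equal(out$k_amb, a * exp(-ea / (cfg$r_gas * 298)), tolerance = 1e-6)
  expect_equal(out$r2, 1, tolerance = 1e-9)
  # flat law: zero activation energy extrapolates to the prefactor
  flat <- data.frame(t_eff = t, k = rep(a, 12))
  expect_equal(arrhenius_extrapolate(flat, cfg)$k_amb, a, tolerance = 1e-9)
  expect_error(arrhenius_extrapolate(pts[1:2, ], cfg), ">= 3")
  same <- data.frame(t_eff = rep(500, 5), k = rep(1, 5))
  expect_error(arrhenius_extrapolate(same, cfg), "singular")
  pts$k[3] <- 0
  expect_warning(arrhenius_extrapolate(pts, cfg), "excluded")
})

test_that("Gibbs-Helmholtz regression recovers reference thermodynamics", {
  cfg <- thermo_config()
  # generate quotient curves from each complex's reported apparent values
  for (i in seq_len(nrow(fx_thermo))) {
    dh <- fx_thermo$dh_m0g[i] * 1000
    ds <- fx_thermo$tds_m0g[i] * 1000 / 298
    t <- seq(300, 304, length.out = 9)
    pts <- data.frame(t_eff = t,
                      keq = exp(-(dh - t * ds) / (cfg$r_gas * t)))
    out <- gibbs_helmholtz_extrapolate(pts, cfg)
    expect_equal(out$dh, fx_thermo$dh_m0g[i], tolerance = 1e-8)
    expect_equal(out$tds_amb, fx_thermo$tds_m0g[i], tolerance = 1e-8)
    expect_equal(out$dg_amb, fx_thermo$dh_m0g[i] - fx_thermo$tds_m0g[i],
                 tolerance = 1e-8)
    # sign structure: endergonic, endothermic, entropy-opposed dissociation
    expect_gt(out$dg_amb, 0)
    expect_gt(out$dh, 0)
    expect_lt(out$tds_amb, 0)
  }
  # entropy-free law is temperature-flat at dG = dH
  t <- seq(300, 310, length.out = 5)
  flat <- data.frame(t_eff = t, keq = exp(-5000 / (cfg$r_gas * t)))
  out <- gibbs_helmholtz_extrapolate(flat, cfg)
  expect_equal(out$dh, 5, tolerance = 1e-8)
  expect_equal(out$tds_amb, 0, tolerance = 1e-6)
  expect_error(gibbs_helmholtz_extrapolate(flat[1:2, ], cfg), ">= 3")
  same <- data.frame(t_eff = rep(300, 4), keq = rep(0.5, 4))
  expect_error(gibbs_helmholtz_extrapolate(same, cfg), "singular")
})

test_that("dG from KD reproduces the reference table links", {
  expect_equal(round(delta_g_from_kd(3.16e-12, 298), 2), 65.61)
  expect_equal(round(delta_g_from_kd(3.58e-12, 298), 2), 65.30)
  expect_equal(round(delta_g_from_kd(3.62e-12, 298), 2), 65.27)
  expect_equal(delta_g_from_kd(1, 298), 0)
  expect_error(delta_g_from_kd(0, 298), "kd")
})

test_that("consistency report flags identity violations", {
  cfg <- thermo_config()
  ok <- list(kd_m0g = 3.16e-12, dg_m0g = 65.61, dh_m0g = 3.32,
             tds_m0g = -62.29)
  rep1 <- consistency_report(ok, cfg, tol = 0.02)
  expect_true(all(rep1$ok))
  expect_true(all(rep1$deviation <= 0.011))
  # enthalpy perturbed by +1 kJ/mol breaks the Gibbs identity
  bad <- ok; bad$dh_m0g <- bad$dh_m0g + 1
  expect_false(all(consistency_report(bad, cfg)$ok))
})

test_that("temperature points span the steep region on both routes", {
  course <- fx_hetero_course("F-bF-bF")
  fit <- fit_boltzmann(course)
  ion <- fx_ions[["F-bF-bF"]]
  cfg <- thermo_config()
  pts <- temperature_points(fit, ion, cfg)
  frac <- boltzmann_value(fit, pts$dcv) / fit$initial
  expect_true(all(frac > 0.09 & frac < 0.91))
  expect_true(all(diff(pts$t_eff) > 0))
  expect_true(all(pts$keq >= 0))
  expect_equal(nrow(pts), cfg$n_steep)
  ptsd <- temperature_points(fit, ion, cfg, source = "data", course = course)
  expect_true(all(ptsd$dcv %in% course$dcv_grid))
  expect_gte(nrow(ptsd), 3)
  expect_error(temperature_points(fit, ion, cfg, source = "data"), "course")
})

test_that("energy unit discipline survives a dimensional round trip", {
  cfg <- thermo_config()
  # kJ/mol out of the extrapolation, J/mol inside: reconstruct keq at a probe
  # temperature from the reported kJ/mol values and compare with the input law
  dh <- 3200; ds <- 10.6  # kJ/mol, kJ/(mol K)
  t <- seq(300.5, 302.5, length.out = 7)
  keq <- exp(-(dh * 1000 - t * ds * 1000) / (cfg$r_gas * t))
  out <- gibbs_helmholtz_extrapolate(data.frame(t_eff = t, keq = keq), cfg)
  keq_back <- exp(-(out$dh * 1000 - 301 * out$ds * 1000) / (cfg$r_gas * 301))
  expect_equal(keq_back,
               exp(-(dh * 1000 - 301 * ds * 1000) / (cfg$r_gas * 301)),
               tolerance = 1e-6)
  expect_equal(out$kd_amb,
               exp(-out$dg_amb * 1000 / (cfg$r_gas * cfg$t_amb)))
})
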
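# Shared fixtures built in code: the foldon / biotinylated-foldon system.

fx_proteoforms <- foldon_proteoforms()
fx_ions <- foldon_ions(fx_proteoforms)
fx_fits <- foldon_reference_fits()
fx_thermo <- foldon_reference_thermo()

# full-precision monoisotopic mass of the unmodified foldon monomer
fx_mono_mass <- monoisotopic_mass(elemental_composition("C142H214N36O41"))

# a simulated noiseless course for one hetero-trimer, reused across tests
fx_hetero_course <- function(sym = "F-F-bF", noise_sd = 0, seed = NULL) {
  ch <- foldon_channels(sym, fx_proteoforms)
  simulate_course(simulation_spec(fx_fits[[sym]], sym, ch$channels,
                                  ch$branching, noise_sd = noise_sd,
                                  seed = seed))
}
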
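# Shared fixture builders: everything is generated in code at test time.

dense_schedule <- function() c(seq(0, 12, by = 0.25), seq(13, 24, by = 1),
                               seq(28, 72, by = 4))

noise_free_scenario <- function(ka = 1, ke = 0.1, dose = 100, f = 1, vd = 10,
                                schedule = dense_schedule(), ...) {
  simulation_scenario(true_ka = ka, true_ke = ke, dose = dose, f = f, vd = vd,
                      schedule = schedule, noise_model = "none", ...)
}

cipro_smiles <- function() {
  "C1CC1N2C=C(C(=O)C3=CC(=C(C=C32)N4CCNCC4)F)C(=O)O"
}

cipro_cation_geometry <- function() {
  read_xyz(system.file("extdata", "ciprofloxacin_cation_ff_synthetic.xyz",
                       package = "fqchelate"))
}

synthetic_ledger <- function() {
  read_energy_ledger(system.file("extdata", "cipro_metal_energies_synthetic.json",
                                 package = "fqchelate"))
}

# Minimal synthetic ledger built in code with hand-chosen hartree components
# (the independent spreadsheet-style sums live in the tests that use this).
toy_ledger_species <- function(e_cx, e_fq, e_hex, e_w,
                               c_cx = 0, c_fq = 0, c_hex = 0, c_w = 0,
                               metal = "Mg") {
  qm <- c(Mg = 2L, Ca = 2L, Al = 3L)
  list(
    complex = species("cx", "chelate_complex", qm[[metal]] + 1L, metal = metal,
                      formula = paste0("C17H27FN3O7", metal),
                      e_pcm_sp = e_cx, g_thermal_corr = c_cx),
    fq = species("fq", "fq_cation", 1L, formula = "C17H19FN3O3",
                 e_pcm_sp = e_fq, g_thermal_corr = c_fq),
    hex = species("hex", "metal_hexahydrate", qm[[metal]], metal = metal,
                  formula = paste0(metal, "H12O6"),
                  e_pcm_sp = e_hex, g_thermal_corr = c_hex),
    water = species("w", "water", 0L, formula = "H2O",
                    e_pcm_sp = e_w, g_thermal_corr = c_w)
  )
}
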
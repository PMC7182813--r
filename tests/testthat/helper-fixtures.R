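# Shared fixtures: probe liquids and the published PET angle triplet.
liq <- probe_liquids()

pet_angles <- function(sds = c(0, 0, 0)) {
  list(contact_angle(liq$water, 77.8, sds[1], 10L),
       contact_angle(liq$formamide, 58.2, sds[2], 10L),
       contact_angle(liq$methylene_iodide, 20.5, sds[3], 10L))
}

pet_fit <- function() solve_components(pet_angles(), surface_name = "PET")

# Record builder for assay tests.
rec <- function(material, strain = "IMUFRJ", pH = 7, is_ = 0.1,
                treatment = "none", mean = 0.5, sd = NA_real_, n = 1L) {
  adhesion_record(
    assay_condition(material, strain, pH, is_, treatment),
    replicate_summary(mean, sd, n))
}
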
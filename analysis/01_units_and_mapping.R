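#!/usr/bin/env Rscript
# Step 1: the reduced-unit system and its mapping to SI units.
#
# The coarse-grained model measures length in solvent cutoffs r_C, mass in
# bead masses and energy in kT. Matching the reduced bead density (3 beads
# per r_C^3, each bead two water molecules) to the experimental mass
# density of water at 25 C fixes every scale. This script recomputes the
# mapping and the real-unit values of the simulation constants, and
# converts the headline inter-rod spacing of the n = 0 (SDS) hexagonal
# phase to nanometres.

library(dpdmeso)
dir.create("results", showWarnings = FALSE)

um <- build_unit_map(temperature_kelvin = 298.15, water_mass_density = 997,
                     water_molecules_per_bead = 2, reduced_density = 3)
print(um)

rows <- data.frame(
  quantity = c("length r_C (Angstrom)", "mass m (kg)", "energy kT (J)",
               "time step 0.01 tau (s)", "friction gamma = 4.5 (kg/s)",
               "number density rho = 3 (1/m^3)",
               "bond constant C = 150 (J/m^2)",
               "angle constant D = 5 (J)"),
  reduced = c(1, 1, 1, 0.01, 4.5, 3, 150, 5),
  si = c(um$length_scale * 1e10, um$mass_scale, um$energy_scale,
         0.01 * um$time_scale,
         convert_units(4.5, c(mass = 1, time = -1), "to_si", um),
         convert_units(3, c(length = -3), "to_si", um),
         convert_units(150, c(energy = 1, length = -2), "to_si", um),
         convert_units(5, c(energy = 1), "to_si", um))
)
print(rows, digits = 4)
write.csv(rows, "results/unit_mapping.csv", row.names = FALSE)

rs_sds <- convert_units(7.52, c(length = 1), "to_si", um) * 1e9
cat(sprintf("\nSDS (n = 0) inter-rod spacing: 7.52 r_C = %.3g nm\n", rs_sds))
cat(sprintf("electrostatic coupling Gamma = %.4g (eps_r = 78.3)\n",
            electro_coupling(um)))
cat("wrote results/unit_mapping.csv\n")
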
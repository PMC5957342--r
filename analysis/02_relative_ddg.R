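#!/usr/bin/env Rscript
# Relative binding free energies Delta-Delta-G (water vs ion) at both toy
# sites by thermodynamic integration of the alchemical transformation at
# the site and in bulk.  Negative values favor water.
#
# Writes: results/relative_ddg.csv

suppressPackageStartupMessages(library(densassign))
dir.create("results", showWarnings = FALSE)

seed0 <- 20180518L
sys <- toy_system()
sc <- soft_core_params()     # alpha 0.5, sigma 0.3 nm, power 1

params <- function(idx) simulation_params(
  n_steps = 2e5, burn_in_steps = 2e4, dt = 0.001, friction = 2,
  seed = child_seed(seed0, idx), sample_stride = 10)

cat("== Relative binding free energies (water vs ion) ==\n")
rows <- list()
combos <- list(list(site = "f_site", ion = "fluoride"),
               list(site = "tm3_site", ion = "sodium"))
for (k in seq_along(combos)) {
  cmb <- combos[[k]]
  site <- sys$sites[[cmb$site]]
  ion <- sys$species[[cmb$ion]]
  wat <- sys$species$water
  a_site <- alchemical_hamiltonian(
    "relative", state_A = list(site = site, species = ion),
    state_B = list(site = site, species = wat), softcore = sc)
  a_bulk <- alchemical_hamiltonian(
    "relative", state_A = list(site = sys$sites$bulk, species = ion),
    state_B = list(site = sys$sites$bulk, species = wat), softcore = sc)
  g3 <- ti_leg(a_site, lambda_schedule(n = 41), params(10 * k + 1), "g3_site")
  g2 <- ti_leg(a_bulk, lambda_schedule(n = 41), params(10 * k + 2), "g2_bulk")
  rel <- relative_ddg(relative_cycle(leg_g3 = g3$leg, leg_g2 = g2$leg))
  lab <- criterion_relative(rel$ddg, rel$stderr)
  # occupancy ratio at physiological-ish concentrations (55.5 M water,
  # 100 mM ion)
  occ <- occupancy_ratio(rel$ddg, 55.5, 0.1)
  cat(sprintf("  %-9s (%s -> water): ddG = %8.2f +- %.2f kJ/mol  [%s]\n",
              cmb$site, cmb$ion, rel$ddg, rel$stderr, lab))
  cat(sprintf("            occupancy ratio P_wat/P_ion ~ 10^%.1f\n",
              log10(occ)))
  rows[[k]] <- data.frame(site = cmb$site, ion = cmb$ion,
                          ddg_kj_mol = rel$ddg, stderr = rel$stderr,
                          g3_site = g3$leg$delta_g, g2_bulk = g2$leg$delta_g,
                          label = lab, log10_occupancy_ratio = log10(occ))
}
write.csv(do.call(rbind, rows), "results/relative_ddg.csv", row.names = FALSE)
cat("\nA strongly negative ddG (beyond the 20 kJ/mol robustness threshold)\n")
cat("supports water; values within the threshold are left inconclusive.\n")
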
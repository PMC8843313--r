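#!/usr/bin/env Rscript
# Stage 1: generate the synthetic assay datasets used by the downstream
# fitting stages, with realistic plate-reader noise (0.5 % of full scale)
# and fixed seeds. Outputs go to results/sim/.

suppressPackageStartupMessages(library(covkin))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cond <- assay_conditions()     # S = 20 uM (Km 17.4 uM), E0 = 0.42 nM, 40 min

message("Assay template: ", appendLF = FALSE); print(cond)

sd_au <- 0.005 * full_scale_signal(params_gu1303(), cond)
message(sprintf("Signal noise sd = %.2f AU (0.5%% of full scale)", sd_au))

slow <- simulate_progress_curves(params_gu1303(), cond,
                                 inhibitor_nM = inhibitor_grid("slow"),
                                 noise = noise_model(sd = sd_au), seed = 101)
write_progress_curves(slow, file.path(out_dir, "gu1303_progress.csv"))
message("Gu1303 (slow binder): ", length(slow), " curves -> gu1303_progress.csv")

tight <- simulate_progress_curves(params_gu2602(), cond,
                                  inhibitor_nM = inhibitor_grid("tight"),
                                  noise = noise_model(sd = sd_au), seed = 102)
write_progress_curves(tight, file.path(out_dir, "gu2602_progress.csv"))
message("Gu2602 (tight binder): ", length(tight), " curves -> gu2602_progress.csv")

mm <- simulate_mm_rates(km_uM = 17.4, vmax = 1,
                        substrate_uM = c(2, 5, 10, 20, 40, 60, 80, 100),
                        noise_sd = 0.005, seed = 103)
write.csv(mm, file.path(out_dir, "mm_rates.csv"), row.names = FALSE)
message("Michaelis-Menten rate table (8 substrate concentrations) -> mm_rates.csv")

ti <- simulate_titration(enzyme_nM = 0.42, titrant_nM = seq(0, 0.64, 0.08),
                         v0 = 1, noise_sd = 0.01, seed = 104)
write.csv(ti, file.path(out_dir, "titration.csv"), row.names = FALSE)
message("Active-site titration (E-64-style stoichiometric titrant) -> titration.csv")
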
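#!/usr/bin/env Rscript
# Stage 2: recover the kinetic constants from the simulated assays of
# stage 1 and assemble the reporting table (Ki in nM, kon in 1e3/(M s),
# koff in 1e-3/s; rates n.d. for linear progress curves).

suppressPackageStartupMessages(library(covkin))

sim_dir <- "results/sim"
stopifnot(dir.exists(sim_dir))   # run analysis/01_simulate_assays.R first

mm <- read.csv(file.path(sim_dir, "mm_rates.csv"))
km_fit <- fit_michaelis_menten(mm)
message(sprintf("Km = %.2f +/- %.2f uM (true 17.4)",
                km_fit$estimates[["km"]], km_fit$se[["km"]]))

ti <- read.csv(file.path(sim_dir, "titration.csv"))
ti_fit <- fit_titration(ti)
message(sprintf("Active enzyme = %.3f +/- %.3f nM (true 0.42)",
                ti_fit$estimates[["enzyme_nM"]], ti_fit$se[["enzyme_nM"]]))

rows <- list()
for (cmp in c("gu1303", "gu2602")) {
  curves <- read_progress_curves(file.path(sim_dir,
                                           paste0(cmp, "_progress.csv")))
  res <- suppressWarnings(analyze_inhibition(curves, compound = cmp))
  print(res)
  rows[[cmp]] <- as.data.frame(res)
}
report <- do.call(rbind, rows)
write.csv(report, "results/inhibition_report.csv", row.names = FALSE)
message("report -> results/inhibition_report.csv")

fits <- data.frame(parameter = c("Km_uM", "enzyme_nM"),
                   estimate = c(km_fit$estimates[["km"]],
                                ti_fit$estimates[["enzyme_nM"]]),
                   se = c(km_fit$se[["km"]], ti_fit$se[["enzyme_nM"]]),
                   units = c("uM", "nM"))
write.csv(fits, "results/assay_calibration.csv", row.names = FALSE)
message("calibration fits -> results/assay_calibration.csv")
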
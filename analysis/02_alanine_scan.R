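#!/usr/bin/env Rscript
# Stage 2: alanine-scan analysis.
#
# Two parts. (a) The simulated panel from stage 1 flows through the curve
# fitting -> fold change -> bin -> hotspot pipeline, and the recovered folds
# are compared with the generator's truth. (b) The published epitope hotspot
# groups are turned into the three docking restraint scenarios (per-region
# groups plus their union, paratope held constant) and exported.

suppressMessages(library(abscan))

inp <- "results/simulated"
out <- "results/scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

curves <- read_elisa_csv(file.path(inp, "elisa_panel.csv"))
hs <- analyze_scan(curves)
write.csv(hs, file.path(out, "fold_changes.csv"), row.names = FALSE)
cat("scan analysis of", nrow(hs), "mutants:\n")
for (i in seq_len(nrow(hs)))
  cat(sprintf("  %-5s kd %.4g  fold %s  bin %-5s  hotspot %s\n",
              hs$mutant_id[i], hs$kd[i],
              ifelse(hs$censored[i], paste0(">", hs$censor_bound[i]),
                     sprintf("%.3g", hs$fold[i])),
              as.character(hs$bin[i]), hs$hotspot[i]))

# restraint scenarios from the published hotspot groups: epitope residues
# near the two receptor subdomains, paratope constant across scenarios
groups <- list(D2_contacting = c("A:52", "A:124"),
               D3_contacting = c("A:76", "A:117", "A:108"))
paratope <- c("H:33", "H:95", "H:98", "L:50", "L:96")
scenarios <- build_scenarios(groups, paratope)
for (sc in scenarios) {
  f <- file.path(out, paste0("restraints_", sc$name, ".txt"))
  export_restraints(sc, f)
  cat("scenario", sc$name, "->", f, "( epitope:",
      paste(sc$epitope_active, collapse = " "), ")\n")
}
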
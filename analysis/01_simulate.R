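#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Real inputs for this workflow would be an antigen crystal structure, a
# homology-modelled Fv, docking poses and ELISA dilution series. Here we
# build desk-scale stand-ins whose truth is known by construction: a
# miniature antigen-Fv complex (plus a pseudo-receptor reference for
# blockage analysis), a simulated ELISA panel, and an ortholog sequence pair
# with planted cross-species differences.

suppressMessages(library(abscan))

seed <- 1
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fx <- make_fv_complex(seed = seed)
write_pdb(fx$pose$complex, file.path(out, "reference_complex.pdb"))
write_pdb(fx$reference_complex, file.path(out, "antigen_receptor.pdb"))
write_annotation_csv(fx$annotation, file.path(out, "fv_annotation.csv"))
writeLines(c(paste0("epitope: ", paste(fx$truth$epitope, collapse = ",")),
             paste0("paratope: ", paste(fx$truth$paratope, collapse = ","))),
           file.path(out, "ground_truth.txt"))
cat("toy complex:", n_atoms(fx$pose$complex), "atoms;",
    length(fx$truth$epitope), "epitope and",
    length(fx$truth$paratope), "paratope contact residues\n")

# ELISA panel: wild type plus mutants spanning the fold-change bins,
# including one knock-out beyond the measurable range
true_kds <- c(WT = 0.05, MILD = 0.13, M7 = 0.35, M50 = 2.5, DEAD = 1e6)
panel <- make_elisa_panel(true_kds, noise_sd = 0.02, seed = seed)
rows <- do.call(rbind, lapply(panel, function(cv)
  data.frame(mutant_id = cv$mutant_id, concentration = cv$concentrations,
             unit = cv$unit, a450 = cv$signals)))
write.csv(rows, file.path(out, "elisa_panel.csv"), row.names = FALSE)
cat("ELISA panel:", length(panel), "mutants x",
    length(panel$WT$concentrations), "dilutions; true folds:",
    paste(names(true_kds), round(true_kds / true_kds[["WT"]], 2),
          sep = "=", collapse = " "), "\n")

# ortholog pair: binder-species reference vs non-binder query with the four
# cross-species determinants planted at their published human positions
pair <- make_ortholog_pair(180,
                           planted_query = c("49" = "T", "76" = "T",
                                             "117" = "Q", "159" = "A"),
                           ref_override = c("49" = "N", "76" = "R",
                                            "117" = "H", "159" = "S"),
                           seed = seed)
writeLines(c(">binder_ref", pair$ref_seq, ">nonbinder_query", pair$query_seq),
           file.path(out, "orthologs.fasta"))
cat("ortholog pair: 180 aa, 4 planted differences\n")
cat("wrote inputs under", out, "\n")
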
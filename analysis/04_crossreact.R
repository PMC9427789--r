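#!/usr/bin/env Rscript
# Stage 4: cross-species epitope conservation and back-mutation design.
#
# The stage-1 ortholog pair (binder reference vs non-binder query) is
# globally aligned; differences are mapped, intersected with the epitope
# positions, and turned into back-to-reference mutation proposals: four
# singles and three cumulative combinations in the stated priority order.

suppressMessages(library(abscan))

inp <- "results/simulated"
out <- "results/crossreact"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seqs <- read_fasta_seqs(file.path(inp, "orthologs.fasta"))
aln <- align_pair(seqs[["binder_ref"]], seqs[["nonbinder_query"]],
                  ref_id = "binder_ref", query_id = "nonbinder_query")
cat(sprintf("alignment: score %.1f, identity %.1f%% over %d columns\n",
            aln$score, aln$identity_percent, nrow(aln$aligned_positions)))

epitope <- c(49L, 76L, 117L, 159L)
dm <- difference_positions(aln, epitope_positions = epitope)
write_differences_csv(dm, file.path(out, "differences.csv"))
ov <- epitope_overlap(dm)
cat("differences:", nrow(dm$differing), "-", ov$count_on_epitope,
    "on the epitope (", round(ov$fraction_percent, 1), "% )\n")

bp <- propose_back_mutations(dm, restrict_to = epitope,
                             priority_order = c(117, 159, 49, 76))
write.csv(bp$mutations, file.path(out, "back_mutations.csv"),
          row.names = FALSE)
cat("back-mutation singles:", paste(bp$mutations$label, collapse = " "), "\n")
for (i in seq_along(bp$combination_sets))
  cat("combination", i, ":",
      paste(bp$combination_sets[[i]], collapse = " + "), "\n")
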
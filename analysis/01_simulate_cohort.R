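#!/usr/bin/env Rscript
# Simulate the pooled cohort: 10 experimental pools (2 regions x clinical
# strata), ~6000 proteins on the reporter-intensity scale, a planted set
# of fold changes per comparison, single-peptide identifications and
# missing values for the clean-up filters to remove. Writes the quant
# table and the planted truth so later steps can score themselves.

library(synaptomics)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
dir.create("results", showWarnings = FALSE)

design <- pool_design()
cfg <- effect_config(seed = seed)
sim <- simulate_pool_table(design, cfg)

write_protein_table(sim$table, "results/protein_table.tsv")
write.table(sim$truth, "results/planted_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(design, "results/design.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d proteins x %d pools (%d comparisons), seed %d\n",
            nrow(sim$table), length(design_pools(design)), nrow(design),
            seed))
cat(sprintf("planted %d altered proteins per comparison\n",
            sum(sim$truth$class[sim$truth$comparison == design$name[1]] !=
                  "UNCHANGED")))
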
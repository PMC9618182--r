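#!/usr/bin/env Rscript
# Clean-up and ratiometric stage: keep proteins identified by >= 2 unique
# peptides and detected in every pool, then compute case/control ratios
# per comparison, divide by the per-comparison median (1/median loading
# correction) and classify each protein UP / DOWN / UNCHANGED at the
# +/-20% thresholds (>= 1.2 or <= 0.8).

library(synaptomics)

design <- comparison_design(read.table("results/design.tsv", header = TRUE,
                                       sep = "\t",
                                       stringsAsFactors = FALSE))
tab <- read_protein_table("results/protein_table.tsv",
                          design_pools(design))

filt <- filter_analysis_ready(tab, min_unique_peptides = 2L)
cat(sprintf("filter: %d input, %d fail peptide rule, %d fail missingness, %d analysis-ready\n",
            filt$report$n_input, filt$report$n_fail_peptides,
            filt$report$n_fail_missing, filt$report$n_retained))

ratios <- ratiometric_normalize(filt$table, design)
meds <- tapply(ratios$norm_ratio, ratios$comparison, median)
stopifnot(all(abs(meds - 1) < 1e-12))
cat("per-comparison median of normalized ratios is 1 (loading corrected)\n")

write_ratio_table(ratios, "results/ratios.tsv")
jsonlite::write_json(filt$report, "results/filter_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
print(table(ratios$comparison, ratios$change_class))
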
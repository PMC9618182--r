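#!/usr/bin/env Rscript
# Synapse annotation and over-representation analysis. Reference lists,
# the compartment map and the gene-set collection are generated here
# (seeded) so the stage runs without downloads: a "published synapse
# proteome" covering most of the cohort, a pre/post compartment map, and
# pathway-like sets of which a few are spiked with altered proteins so
# enrichment has signal to find.

library(synaptomics)

set.seed(as.integer(Sys.getenv("COHORT_SEED", "1")) + 1000L)
ratios <- read.table("results/ratios.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
universe <- unique(ratios$accession)
sets <- altered_sets(ratios)

# reference proteome: covers ~98% of the analysis-ready accessions
reference <- list(name = "synthetic_brain_reference",
                  ids = sample(universe, round(0.98 * length(universe))),
                  id_type = "accession")
ov <- overlap_fraction(universe, reference)
cat(sprintf("dataset overlap with reference proteome: %d/%d (%.1f%%)\n",
            ov$count, length(universe), 100 * ov$fraction))

# compartment map: postsynaptic-leaning mixture over most of the cohort
mapped <- sample(universe, round(0.8 * length(universe)))
cmap <- list(map = setNames(sample(c("presynaptic", "postsynaptic", "both"),
                                   length(mapped), replace = TRUE,
                                   prob = c(0.3, 0.55, 0.15)), mapped),
             fine = character(0), id_type = "accession")
for (cmp in c("ALS_BA4", "ALS_BA9")) {
  d <- compartment_distribution(sets[[cmp]]$altered, cmap)
  cat(sprintf("%s altered proteins: %s\n", cmp,
              paste(d$compartment, sprintf("%.0f%%", 100 * d$fraction),
                    collapse = ", ")))
  write.table(d, sprintf("results/compartments_%s.tsv", cmp), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

# pathway-like collection: 30 random sets + 2 spiked with altered proteins
coll_sets <- lapply(1:30, function(i) sample(universe, sample(20:80, 1)))
names(coll_sets) <- sprintf("pathway_%02d", 1:30)
alt <- sets$ALS_BA4$altered
coll_sets$spiked_synaptic <- unique(c(sample(alt, min(30, length(alt))),
                                      sample(universe, 20)))
coll_sets$spiked_complement <- unique(c(sample(alt, min(15, length(alt))),
                                        sample(universe, 10)))
coll <- gene_set_collection(coll_sets, universe)

enr <- hypergeom_enrich(alt, coll)
cat("top enriched sets for ALS_BA4 altered proteins:\n")
print(head(enr[, c("set", "k", "K", "fold_enrichment", "p_value", "fdr")],
           5))
write.table(enr, "results/enrichment_ALS_BA4.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
stopifnot(enr$set[1] %in% c("spiked_synaptic", "spiked_complement"))
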
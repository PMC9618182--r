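#!/usr/bin/env Rscript
# Set logic over the classified ratios: per-comparison UP/DOWN sets and
# counts, region- and stratum-specific subsets (altered in the target
# comparison, unchanged everywhere else in its contrast group), Venn
# region counts for the regional contrast, and top-10 rankings. Scores
# the classifier against the planted truth.

library(synaptomics)

ratios <- read.table("results/ratios.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
truth <- read.table("results/planted_truth.tsv", header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

sets <- altered_sets(ratios)
counts <- altered_counts(sets)
print(counts)
write.table(counts, "results/altered_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

contrasts <- list(
  ALS_BA4 = "ALS_BA9",          # region-specific changes
  ALS_BA9 = "ALS_BA4",
  ALSci_BA4 = "ALSnoci_BA4",    # cognitive-stratum specificity per region
  ALSci_BA9 = "ALSnoci_BA9",
  C9pos_BA9 = "C9neg_BA9"       # repeat-expansion specificity
)
spec <- lapply(names(contrasts), function(tgt) {
  r <- specific_set(tgt, contrasts[[tgt]], sets)
  stopifnot(length(r$specific) + length(r$shared) ==
              length(sets[[tgt]]$altered))
  writeLines(r$specific, sprintf("results/specific_%s.txt", tgt))
  data.frame(target = tgt, vs = paste(contrasts[[tgt]], collapse = "+"),
             n_altered = length(sets[[tgt]]$altered),
             n_specific = length(r$specific), n_shared = length(r$shared))
})
spec <- do.call(rbind, spec)
print(spec)
write.table(spec, "results/specificity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

vc <- venn_counts(list(BA4 = sets$ALS_BA4$altered,
                       BA9 = sets$ALS_BA9$altered))
cat("regional Venn:", paste(names(vc), vc, sep = "=", collapse = "  "),
    "\n")

for (cmp in c("ALS_BA4", "ALS_BA9")) {
  cat(sprintf("top 10 UP in %s: %s\n", cmp,
              paste(top_k(ratios, cmp, 10, "up"), collapse = ", ")))
}

# score against planted truth
m <- merge(ratios, truth, by = c("accession", "comparison"))
planted <- m$class != "UNCHANGED"
called <- m$change_class != "UNCHANGED"
correct <- m$class == m$change_class
cat(sprintf("classifier recall %.3f, precision %.3f (vs planted truth)\n",
            sum(planted & correct) / sum(planted),
            sum(called & correct) / sum(called)))
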
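# Builders and independent oracles shared across the suite.

# Minimal two-pool design: one comparison, case vs control.
tiny_design <- function() {
  comparison_design(data.frame(
    name = "case_vs_ctrl", case_pool = "case", control_pool = "ctrl",
    region = "BA4", stratum = "ALS", stringsAsFactors = FALSE
  ))
}

# Hand-built protein table over arbitrary pools.
make_table <- function(intensities, unique_peptides = NULL,
                       accession = NULL) {
  n <- nrow(intensities)
  if (is.null(unique_peptides)) unique_peptides <- rep(3L, n)
  if (is.null(accession)) accession <- sprintf("SP%05d", seq_len(n))
  tab <- data.frame(accession = accession,
                    symbol = paste0("GENE", seq_len(n)),
                    unique_peptides = unique_peptides,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(intensities))
  validate_protein_table(tab, colnames(intensities))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Exact upper-tail hypergeometric probability by enumeration of all
# possible overlaps (independent of phyper).
hyper_tail_enum <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force Venn region counts by per-element membership enumeration.
venn_oracle <- function(sets) {
  universe <- unique(unlist(sets))
  n <- length(sets)
  counts <- integer(0)
  for (k in seq_len(2^n - 1L)) {
    in_set <- as.logical(bitwAnd(k, 2^(seq_len(n) - 1L)))
    region <- paste(names(sets)[in_set], collapse = "&")
    hit <- vapply(universe, function(e) {
      all(vapply(which(in_set), function(j) e %in% sets[[j]], logical(1))) &&
        !any(vapply(which(!in_set), function(j) e %in% sets[[j]],
                    logical(1)))
    }, logical(1))
    counts[region] <- sum(hit)
  }
  counts
}
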
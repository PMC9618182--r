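#' Build a gene-set collection over a universe
#'
#' Restricts every set to the universe and drops sets left empty; the
#' universe is the background of the over-representation test. Using the
#' intersection of the analysis-ready proteins with the collection's
#' annotation space avoids inflating enrichment with unannotatable ids.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of background identifiers.
#' @return list with `sets` (restricted, non-empty) and `universe`
#'   (unique ids).
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets) == 0L) stop("empty collection")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all sets must be named")
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  if (length(sets) == 0L) stop("no set overlaps the universe")
  list(sets = sets, universe = universe)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (tab-delimited: name, description, member ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set in the collection, tests whether the query list overlaps
#' it more than expected when drawing `n = |query|` identifiers at random
#' from the `N`-identifier universe containing `K` set members: the
#' p-value is the upper hypergeometric tail P(X >= k). Fold enrichment is
#' (k/n)/(K/N). Benjamini-Hochberg FDR is attached across all sets of the
#' collection (within-collection correction), and rows are sorted by
#' p-value.
#'
#' @param query character vector of identifiers; ids outside the universe
#'   are dropped (their number is reported in the `n_dropped` attribute).
#' @param collection a [gene_set_collection()].
#' @return data.frame with `set`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `fdr`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(query, collection) {
  query <- unique(as.character(query))
  n_dropped <- sum(!query %in% collection$universe)
  query <- intersect(query, collection$universe)
  if (length(query) == 0L) stop("query empty after universe restriction")
  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(query, set))
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = stats::phyper(k - 1L, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, clamped to [0, 1] and
#' monotone in p-rank.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
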
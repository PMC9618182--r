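#' Altered-protein sets per comparison
#'
#' Collects, for every comparison in a classified ratio table, the set of
#' UP accessions, DOWN accessions and their union (the altered set).
#'
#' @param ratios a `ratio_table` from [ratiometric_normalize()].
#' @return Named list (one element per comparison) of lists with `up`,
#'   `down` and `altered` character vectors.
#' @export
altered_sets <- function(ratios) {
  stopifnot(all(c("accession", "comparison", "change_class") %in%
                  names(ratios)))
  out <- lapply(split(ratios, ratios$comparison), function(d) {
    up <- sort(d$accession[d$change_class == "UP"])
    down <- sort(d$accession[d$change_class == "DOWN"])
    if (length(intersect(up, down))) stop("protein both UP and DOWN")
    list(up = up, down = down, altered = sort(c(up, down)))
  })
  out[unique(ratios$comparison)]
}

#' Group-specific subset of an altered set
#'
#' A protein is specific to the target comparison if it is altered there
#' and not altered in any other comparison of the contrast group. The
#' contrast group is explicit: pass the comparisons to subtract in
#' `others`.
#'
#' @param target name of the target comparison.
#' @param others character vector of comparison names to subtract; must
#'   not contain `target`.
#' @param sets output of [altered_sets()].
#' @param direction `"altered"` (default), `"up"` or `"down"`: which set
#'   of the target to partition. Subtraction always uses the full altered
#'   sets of the others, matching the idea that a protein changed in any
#'   direction elsewhere is not group-specific.
#' @return list with `specific` and `shared` accession vectors; together
#'   they partition the target set.
#' @export
specific_set <- function(target, others, sets, direction = "altered") {
  if (target %in% others) stop("target listed among others")
  missing_cmp <- setdiff(c(target, others), names(sets))
  if (length(missing_cmp)) {
    stop("unknown comparison: ", paste(missing_cmp, collapse = ", "))
  }
  direction <- match.arg(direction, c("altered", "up", "down"))
  tgt <- sets[[target]][[direction]]
  other_altered <- sort(unique(unlist(lapply(sets[others],
                                             `[[`, "altered"))))
  specific <- setdiff(tgt, other_altered)
  list(specific = sort(specific),
       shared = sort(intersect(tgt, other_altered)))
}

#' Venn region counts for 2-4 sets
#'
#' Counts every non-empty membership region (2^n - 1 regions) of up to
#' four sets. Region names join set names with `&` for the sets the
#' region belongs to, e.g. `"A&B"` is the region in A and B but in no
#' other input set.
#'
#' @param sets named list of 2-4 character vectors.
#' @return Named integer vector over all membership regions; the counts
#'   sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  n <- length(sets)
  if (n < 2L || n > 4L) stop("venn_counts supports 2 to 4 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(n)]
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  counts <- integer(0)
  for (k in seq_len(2^n - 1L)) {
    in_set <- as.logical(bitwAnd(k, 2^(seq_len(n) - 1L)))
    region <- paste(names(sets)[in_set], collapse = "&")
    hit <- rowSums(member[, in_set, drop = FALSE]) == sum(in_set) &
      rowSums(member[, !in_set, drop = FALSE]) == 0L
    counts[region] <- sum(hit)
  }
  counts
}

#' Top-k proteins of a comparison by normalized ratio
#'
#' Ranks proteins of one comparison by normalized ratio, descending for
#' `direction = "up"`, ascending for `"down"`. Ties are broken by
#' accession in lexicographic order so rankings are deterministic.
#'
#' @param ratios a `ratio_table`.
#' @param comparison comparison name.
#' @param k number of proteins to return (>= 1); truncated to the table.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of up to `k` accessions.
#' @export
top_k <- function(ratios, comparison, k = 10L, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (k < 1L) stop("k must be >= 1")
  d <- ratios[ratios$comparison == comparison, , drop = FALSE]
  if (nrow(d) == 0L) stop("unknown comparison: ", comparison)
  ord <- order(if (direction == "up") -d$norm_ratio else d$norm_ratio,
               d$accession)
  d$accession[ord][seq_len(min(k, nrow(d)))]
}

#' Summarize altered-set sizes
#'
#' @param sets output of [altered_sets()].
#' @return data.frame with per-comparison `n_up`, `n_down`, `n_altered`.
#' @export
altered_counts <- function(sets) {
  data.frame(
    comparison = names(sets),
    n_up = vapply(sets, function(s) length(s$up), integer(1)),
    n_down = vapply(sets, function(s) length(s$down), integer(1)),
    n_altered = vapply(sets, function(s) length(s$altered), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
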
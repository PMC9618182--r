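#' Read a protein-group quantification table
#'
#' Reads a TSV or CSV export with one row per protein group: an accession
#' column (primary key), a gene-symbol column, a unique-peptide count and
#' one reporter-intensity column per experimental pool. Zero and blank
#' intensities are treated as "not detected" and stored as `NA`, matching
#' the mixed conventions of search-engine exports. The delimiter is sniffed
#' from the file extension (`.csv` is comma, anything else tab).
#'
#' @param path path to the table.
#' @param pool_ids character vector of pool column names that must be
#'   present.
#' @param col_map optional named character vector mapping the canonical
#'   names `accession`, `symbol`, `unique_peptides` to the file's own
#'   headers (e.g. `c(accession = "Majority protein IDs", unique_peptides =
#'   "Unique peptides")`); pool columns may be remapped the same way.
#' @return A `protein_quant` data.frame: `accession`, `symbol`,
#'   `unique_peptides`, then one numeric column per pool.
#' @export
read_protein_table <- function(path, pool_ids, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  canon <- c(accession = "accession", symbol = "symbol",
             unique_peptides = "unique_peptides")
  if (!is.null(col_map)) {
    for (k in names(col_map)) {
      if (k %in% names(canon)) {
        canon[[k]] <- col_map[[k]]
      } else if (col_map[[k]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[k]]] <- k
      }
    }
  }
  for (k in names(canon)) {
    if (!canon[[k]] %in% names(raw)) {
      stop("required column missing: ", canon[[k]])
    }
    names(raw)[names(raw) == canon[[k]]] <- k
  }
  missing_pools <- setdiff(pool_ids, names(raw))
  if (length(missing_pools)) {
    stop("required pool column missing: ",
         paste(missing_pools, collapse = ", "))
  }
  tab <- raw[, c("accession", "symbol", "unique_peptides", pool_ids)]
  tab$accession <- as.character(tab$accession)
  tab$symbol <- ifelse(is.na(tab$symbol), "", as.character(tab$symbol))
  if (anyDuplicated(tab$accession)) {
    stop("duplicate accession: ",
         paste(unique(tab$accession[duplicated(tab$accession)]),
               collapse = ", "))
  }
  tab$unique_peptides <- as.integer(tab$unique_peptides)
  for (p in pool_ids) {
    v <- suppressWarnings(as.numeric(tab[[p]]))
    v[!is.na(v) & v <= 0] <- NA_real_
    tab[[p]] <- v
  }
  validate_protein_table(tab, pool_ids)
}

#' Validate a protein quantification table
#'
#' @param tab data.frame with `accession`, `symbol`, `unique_peptides` and
#'   pool columns.
#' @param pool_ids pool column names expected in `tab`.
#' @return The table with class `protein_quant` and attribute `pools`.
#' @export
validate_protein_table <- function(tab, pool_ids) {
  stopifnot(is.data.frame(tab))
  need <- c("accession", "symbol", "unique_peptides", pool_ids)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("required column missing: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$accession)) stop("duplicate accession")
  if (any(tab$unique_peptides < 0, na.rm = TRUE)) {
    stop("unique_peptides must be >= 0")
  }
  for (p in pool_ids) {
    v <- tab[[p]]
    if (!is.numeric(v)) stop("pool column not numeric: ", p)
    if (any(v <= 0, na.rm = TRUE)) stop("non-positive intensity in: ", p)
  }
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "pools") <- pool_ids
  class(tab) <- c("protein_quant", "data.frame")
  tab
}

#' Filter to analysis-ready proteins
#'
#' Applies the two clean-up rules for pooled reporter-intensity data:
#' proteins identified with fewer than `min_unique_peptides` unique
#' peptides are dropped, and proteins not detected in every pool (any `NA`
#' intensity) are dropped. A row failing both rules is attributed to both
#' counters of the report; reconciliation uses the union of failing rows.
#'
#' @param tab a `protein_quant` table.
#' @param min_unique_peptides retention threshold on the unique-peptide
#'   count (default 2).
#' @return list with `table` (the analysis-ready `protein_quant`) and
#'   `report` (`n_input`, `n_fail_peptides`, `n_fail_missing`,
#'   `n_retained`).
#' @export
filter_analysis_ready <- function(tab, min_unique_peptides = 2L) {
  pools <- attr(tab, "pools")
  if (is.null(pools)) stop("table must come from validate_protein_table()")
  fail_pep <- tab$unique_peptides < min_unique_peptides
  fail_mis <- rowSums(is.na(as.matrix(tab[, pools, drop = FALSE]))) > 0L
  keep <- !(fail_pep | fail_mis)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- pools
  class(out) <- c("protein_quant", "data.frame")
  report <- list(
    n_input = nrow(tab),
    n_fail_peptides = sum(fail_pep),
    n_fail_missing = sum(fail_mis),
    n_retained = sum(keep)
  )
  stopifnot(report$n_retained == report$n_input - sum(fail_pep | fail_mis))
  list(table = out, report = report)
}

#' Write a protein quantification table as TSV
#'
#' @param tab a `protein_quant` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
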
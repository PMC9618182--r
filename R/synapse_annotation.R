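#' Normalize protein identifiers
#'
#' Reference lists mix conventions: gene symbols appear in varying case
#' and accessions may carry isoform suffixes ("P12345-2"). Symbols are
#' upper-cased; accession isoform suffixes are stripped.
#'
#' @param ids character vector of identifiers.
#' @param id_type `"accession"` or `"symbol"`.
#' @return Normalized character vector.
#' @export
normalize_ids <- function(ids, id_type = c("accession", "symbol")) {
  id_type <- match.arg(id_type)
  ids <- as.character(ids)
  if (id_type == "accession") sub("-[0-9]+$", "", ids) else toupper(ids)
}

#' Read a reference identifier list
#'
#' One identifier per line (a second tab-separated column, if present, is
#' ignored). Identifiers are normalized per `id_type`.
#'
#' @param path file path.
#' @param name list name (defaults to the file stem).
#' @param id_type `"accession"` or `"symbol"`.
#' @return list with `name`, `ids` (unique, normalized) and `id_type`.
#' @export
read_reference_list <- function(path, name = NULL,
                                id_type = c("accession", "symbol")) {
  id_type <- match.arg(id_type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  ids <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  ids <- unique(normalize_ids(trimws(ids), id_type))
  if (length(ids) == 0L) stop("reference list is empty: ", path)
  list(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path))
       else name,
       ids = ids, id_type = id_type)
}

#' Fraction of a dataset covered by a reference list
#'
#' Directional: the denominator is always the dataset, so this answers
#' "how much of our data matches the published resource", not the
#' converse.
#'
#' @param dataset_ids identifiers of the dataset (normalized internally
#'   using the reference's `id_type`).
#' @param reference a reference list from [read_reference_list()] (or a
#'   list with `ids` and `id_type`).
#' @return list with `count` (overlap size) and `fraction`
#'   (count / dataset size).
#' @export
overlap_fraction <- function(dataset_ids, reference) {
  if (length(dataset_ids) == 0L) stop("empty dataset")
  if (length(reference$ids) == 0L) stop("empty reference")
  ids <- unique(normalize_ids(dataset_ids, reference$id_type))
  count <- length(intersect(ids, reference$ids))
  list(count = count, fraction = count / length(ids))
}

#' Read a compartment map
#'
#' Two-column TSV (id, compartment; optional third column with a fine
#' subsynaptic term). Coarse compartments must be one of `presynaptic`,
#' `postsynaptic`, `both`; each id maps to exactly one.
#'
#' @param path file path.
#' @param id_type `"accession"` or `"symbol"`.
#' @return list with `map` (named character vector id -> compartment),
#'   `fine` (named character vector, possibly empty) and `id_type`.
#' @export
read_compartment_map <- function(path, id_type = c("accession", "symbol")) {
  id_type <- match.arg(id_type)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "#")
  if (ncol(d) < 2L) stop("compartment map needs id and compartment columns")
  ids <- normalize_ids(d[[1]], id_type)
  comp <- tolower(trimws(d[[2]]))
  bad <- !comp %in% c("presynaptic", "postsynaptic", "both")
  if (any(bad)) stop("unknown compartment: ",
                     paste(unique(comp[bad]), collapse = ", "))
  if (anyDuplicated(ids)) stop("id mapped to more than one compartment")
  map <- stats::setNames(comp, ids)
  fine <- if (ncol(d) >= 3L) stats::setNames(as.character(d[[3]]), ids)
  else character(0)
  list(map = map, fine = fine, id_type = id_type)
}

#' Distribution of identifiers over synaptic compartments
#'
#' Counts how many of the given identifiers fall presynaptically,
#' postsynaptically, in both compartments, or are absent from the map
#' (`unknown`). Counts always sum to the number of unique input ids.
#'
#' @param ids character vector of identifiers.
#' @param cmap a compartment map from [read_compartment_map()].
#' @return data.frame with `compartment`, `count`, `fraction`.
#' @export
compartment_distribution <- function(ids, cmap) {
  ids <- unique(normalize_ids(ids, cmap$id_type))
  levels <- c("presynaptic", "postsynaptic", "both", "unknown")
  assigned <- cmap$map[ids]
  assigned[is.na(assigned)] <- "unknown"
  counts <- vapply(levels, function(l) sum(assigned == l), integer(1))
  data.frame(compartment = levels, count = unname(counts),
             fraction = if (length(ids)) unname(counts) / length(ids)
             else rep(0, length(levels)),
             stringsAsFactors = FALSE)
}
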
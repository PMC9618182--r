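#' Ratiometric values with 1/median loading correction
#'
#' For every comparison in the design, each protein's raw ratio is its
#' case-pool intensity divided by its control-pool intensity. Because
#' minor loading differences between pools shift all ratios of a
#' comparison multiplicatively, every raw ratio is then divided by the
#' per-comparison median over all analysis-ready proteins ("1/median"
#' normalization), so the median normalized ratio of each comparison is
#' exactly 1. The median is taken within each comparison, not globally,
#' since loading differs per pool.
#'
#' @param tab an analysis-ready `protein_quant` table (no missing values;
#'   see [filter_analysis_ready()]).
#' @param design a `comparison_design`; all referenced pools must be
#'   columns of `tab`.
#' @param up_threshold,down_threshold classification thresholds passed to
#'   [classify_change()].
#' @return A long `ratio_table` data.frame with columns `accession`,
#'   `symbol`, `comparison`, `raw_ratio`, `norm_ratio`, `log2_ratio`,
#'   `change_class`.
#' @export
ratiometric_normalize <- function(tab, design,
                                  up_threshold = 1.2,
                                  down_threshold = 0.8) {
  if (nrow(tab) == 0L) stop("empty protein table")
  pools <- attr(tab, "pools")
  missing_pools <- setdiff(design_pools(design), pools)
  if (length(missing_pools)) {
    stop("design references pools absent from table: ",
         paste(missing_pools, collapse = ", "))
  }
  m <- as.matrix(tab[, pools, drop = FALSE])
  if (anyNA(m)) stop("table contains missing intensities; filter first")
  pieces <- lapply(seq_len(nrow(design)), function(i) {
    raw <- m[, design$case_pool[i]] / m[, design$control_pool[i]]
    norm <- raw / stats::median(raw)
    data.frame(
      accession = tab$accession,
      symbol = tab$symbol,
      comparison = design$name[i],
      raw_ratio = unname(raw),
      norm_ratio = unname(norm),
      log2_ratio = unname(log2(norm)),
      change_class = classify_change(norm, up_threshold, down_threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Classify a normalized ratio as UP / DOWN / UNCHANGED
#'
#' The 20 percent change criterion: a protein is UP if its normalized
#' ratio is >= `up_threshold` (default 1.2) and DOWN if <= `down_threshold`
#' (default 0.8); both bounds are inclusive. Note the default pair is not
#' reciprocal (1/1.2 ~= 0.833 > 0.8), so UP and DOWN calls are not
#' symmetric under ratio inversion.
#'
#' @param norm_ratio positive numeric vector of normalized ratios.
#' @param up_threshold,down_threshold inclusive classification bounds;
#'   `up_threshold` must exceed `down_threshold`.
#' @return Character vector in `{"UP","DOWN","UNCHANGED"}`.
#' @export
classify_change <- function(norm_ratio, up_threshold = 1.2,
                            down_threshold = 0.8) {
  if (any(!is.finite(norm_ratio)) || any(norm_ratio <= 0)) {
    stop("norm_ratio must be finite and positive")
  }
  if (up_threshold <= down_threshold) {
    stop("up_threshold must exceed down_threshold")
  }
  ifelse(norm_ratio >= up_threshold, "UP",
         ifelse(norm_ratio <= down_threshold, "DOWN", "UNCHANGED"))
}

#' Row-wise z-scores of log2 ratios
#'
#' Standardizes each protein's vector of (log2) ratiometric values across
#' the displayed groups: z = (value - row mean) / row sample SD. Rows with
#' zero spread cannot be standardized; they are returned as all-zero and
#' flagged in the `degenerate` attribute.
#'
#' @param m numeric matrix, one row per protein, one column per group;
#'   at least two columns.
#' @return Matrix of z-scores with logical attribute `degenerate` (one
#'   flag per row).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least two columns per row")
  if (any(!is.finite(m))) stop("non-finite values in input")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  degenerate <- sdv == 0
  z <- (m - mu) / ifelse(degenerate, 1, sdv)
  z[degenerate, ] <- 0
  attr(z, "degenerate") <- unname(degenerate)
  z
}

#' Hierarchical row ordering for heatmap display
#'
#' Agglomerative clustering of rows on Euclidean distance (complete
#' linkage by default), as used to order heatmap rows. Returns the leaf
#' order together with the merge table and heights.
#'
#' @param m numeric matrix with at least two rows and no non-finite
#'   values.
#' @param method linkage passed to [stats::hclust()].
#' @return list with `order` (leaf permutation of row indices), `merge`
#'   and `height` from the dendrogram, and the `hclust` object.
#' @export
hierarchical_order <- function(m, method = "complete") {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two rows")
  if (any(!is.finite(m))) stop("non-finite values in input")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = method)
  list(order = hc$order, merge = hc$merge, height = hc$height, hclust = hc)
}

#' Write a ratio table as TSV
#'
#' @param ratios a `ratio_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(ratios, path) {
  utils::write.table(ratios, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
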
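#' Comparison design for a pooled TMT cohort
#'
#' A comparison design names each case-pool/control-pool contrast together
#' with its cortical region and clinical stratum. The default layout mirrors
#' a 10-pool, two-region stratified cohort: whole-group ALS vs control in
#' primary motor cortex (BA4) and dorsolateral prefrontal cortex (BA9),
#' cognitive stratification (ALSnoci / ALSci) in both regions, and
#' C9ORF72 repeat-expansion stratification (C9neg / C9pos) in BA9.
#'
#' @param comparisons data.frame with columns `name`, `case_pool`,
#'   `control_pool`, `region`, `stratum`. Names must be unique and no
#'   comparison may use the same pool as case and control.
#' @return A validated `comparison_design` data.frame.
#' @export
comparison_design <- function(comparisons) {
  req <- c("name", "case_pool", "control_pool", "region", "stratum")
  if (!is.data.frame(comparisons) || !all(req %in% names(comparisons))) {
    stop("comparison design needs columns: ", paste(req, collapse = ", "))
  }
  comparisons <- as.data.frame(comparisons, stringsAsFactors = FALSE)
  if (nrow(comparisons) < 1L) stop("comparison design is empty")
  if (anyDuplicated(comparisons$name)) {
    stop("comparison names must be unique")
  }
  same <- comparisons$case_pool == comparisons$control_pool
  if (any(same)) {
    stop("case and control pool identical in: ",
         paste(comparisons$name[same], collapse = ", "))
  }
  rownames(comparisons) <- NULL
  class(comparisons) <- c("comparison_design", "data.frame")
  comparisons
}

#' Default 10-pool stratified design
#'
#' Eight case/control comparisons over ten pools: two whole-group regional
#' contrasts, four cognitive-stratum contrasts and two C9ORF72-RE-stratum
#' contrasts, each against the control pool of its own region.
#'
#' @return A `comparison_design` data.frame with 8 rows.
#' @export
pool_design <- function() {
  comparison_design(data.frame(
    name = c("ALS_BA4", "ALS_BA9",
             "ALSnoci_BA4", "ALSci_BA4",
             "ALSnoci_BA9", "ALSci_BA9",
             "C9neg_BA9", "C9pos_BA9"),
    case_pool = c("ALS_BA4", "ALS_BA9",
                  "ALSnoci_BA4", "ALSci_BA4",
                  "ALSnoci_BA9", "ALSci_BA9",
                  "C9neg_BA9", "C9pos_BA9"),
    control_pool = c("Control_BA4", "Control_BA9",
                     "Control_BA4", "Control_BA4",
                     "Control_BA9", "Control_BA9",
                     "Control_BA9", "Control_BA9"),
    region = c("BA4", "BA9", "BA4", "BA4", "BA9", "BA9", "BA9", "BA9"),
    stratum = c("ALS", "ALS", "ALSnoci", "ALSci",
                "ALSnoci", "ALSci", "C9neg", "C9pos"),
    stringsAsFactors = FALSE
  ))
}

#' Pool identifiers referenced by a design
#'
#' @param design a `comparison_design`.
#' @return Character vector of unique pool ids (cases then controls).
#' @export
design_pools <- function(design) {
  unique(c(design$case_pool, design$control_pool))
}
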
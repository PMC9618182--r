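#' Validate a run configuration
#'
#' Accepts a YAML path or a list. All problems are collected and reported
#' together, not just the first. A valid configuration drives
#' [run_pipeline()] end-to-end.
#'
#' Recognized fields: `seed` (integer), `synthetic` (list of
#' [effect_config()] fields, or omitted when `quant_table` is given),
#' `quant_table` (path to a TSV/CSV protein table), `design` (data.frame
#' or path to a TSV with the comparison-design columns; default
#' [pool_design()]), `min_unique_peptides`, `up_threshold`,
#' `down_threshold`, `gmt` (optional GMT path), `contrast_groups`
#' (named list: target comparison -> character vector of comparisons to
#' subtract), `out_dir` (optional output directory).
#'
#' @param config list or path to a YAML file.
#' @return A validated config list (class `run_config`); on failure an
#'   error whose message lists every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path")
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.na(config$seed)) note("seed must be an integer")
  config$min_unique_peptides <-
    if (is.null(config$min_unique_peptides)) 2L
    else as.integer(config$min_unique_peptides)
  if (is.null(config$up_threshold)) config$up_threshold <- 1.2
  if (is.null(config$down_threshold)) config$down_threshold <- 0.8
  if (config$up_threshold <= 1) note("up_threshold must be > 1")
  if (config$down_threshold >= 1 || config$down_threshold <= 0) {
    note("down_threshold must lie in (0, 1)")
  }

  if (is.null(config$design)) {
    config$design <- pool_design()
  } else if (is.character(config$design)) {
    if (!file.exists(config$design)) {
      note(paste0("design file not found: ", config$design))
    } else {
      d <- utils::read.table(config$design, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      config$design <- tryCatch(comparison_design(d),
                                error = function(e) {
                                  note(conditionMessage(e))
                                  NULL
                                })
    }
  } else {
    config$design <- tryCatch(comparison_design(config$design),
                              error = function(e) {
                                note(conditionMessage(e))
                                NULL
                              })
  }

  if (is.null(config$quant_table)) {
    syn <- if (is.null(config$synthetic)) list() else config$synthetic
    syn$seed <- config$seed
    config$synthetic <- tryCatch(do.call(effect_config, syn),
                                 error = function(e) {
                                   note(conditionMessage(e))
                                   NULL
                                 })
  } else if (!file.exists(config$quant_table)) {
    note(paste0("quant table not found: ", config$quant_table))
  }

  if (!is.null(config$gmt) && !file.exists(config$gmt)) {
    note(paste0("gmt file not found: ", config$gmt))
  }
  if (!is.null(config$contrast_groups) && !is.null(config$design)) {
    known <- config$design$name
    for (tgt in names(config$contrast_groups)) {
      bad <- setdiff(c(tgt, config$contrast_groups[[tgt]]), known)
      if (length(bad)) {
        note(paste0("contrast group references unknown comparison: ",
                    paste(bad, collapse = ", ")))
      }
      if (tgt %in% config$contrast_groups[[tgt]]) {
        note(paste0("contrast group target listed among others: ", tgt))
      }
    }
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the pooled-cohort analysis end-to-end
#'
#' Stages: load or simulate the protein quantification table; filter to
#' analysis-ready proteins; compute normalized ratios and change classes;
#' derive altered sets, counts and configured group-specificity
#' partitions; optionally run over-representation analysis against a GMT
#' collection. Internal consistency (specificity partition, median of
#' normalized ratios) is re-asserted before the report is returned. With
#' synthetic input, identical config and seed give identical output.
#'
#' @param config a `run_config` (or anything [validate_config()]
#'   accepts).
#' @return A run report list: `config_hash`, `seed`, `filter` report,
#'   `counts` per comparison, `specificity` per contrast group,
#'   `enrichment` (or NULL), plus `ratios`, `sets` and (synthetic runs)
#'   `truth` for downstream use. Tables are also written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$quant_table)) {
    sim <- stage("simulate",
                 simulate_pool_table(config$design, config$synthetic))
    tab <- sim$table
    truth <- sim$truth
  } else {
    tab <- stage("ingest",
                 read_protein_table(config$quant_table,
                                    design_pools(config$design),
                                    col_map = config$col_map))
  }

  filt <- stage("filter",
                filter_analysis_ready(tab, config$min_unique_peptides))
  ratios <- stage("normalize",
                  ratiometric_normalize(filt$table, config$design,
                                        config$up_threshold,
                                        config$down_threshold))
  for (cmp in unique(ratios$comparison)) {
    med <- stats::median(ratios$norm_ratio[ratios$comparison == cmp])
    stopifnot(abs(med - 1) < 1e-12)
  }
  sets <- stage("sets", altered_sets(ratios))
  counts <- altered_counts(sets)

  specificity <- NULL
  if (!is.null(config$contrast_groups)) {
    specificity <- lapply(names(config$contrast_groups), function(tgt) {
      res <- specific_set(tgt, config$contrast_groups[[tgt]], sets)
      stopifnot(length(res$specific) + length(res$shared) ==
                  length(sets[[tgt]]$altered))
      list(target = tgt, n_specific = length(res$specific),
           n_shared = length(res$shared), specific = res$specific)
    })
    names(specificity) <- names(config$contrast_groups)
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- stage("enrich", {
      sets_gmt <- read_gmt(config$gmt)
      universe <- intersect(filt$table$accession,
                            unique(unlist(sets_gmt)))
      coll <- gene_set_collection(sets_gmt, universe)
      lapply(sets[counts$n_altered > 0],
             function(s) hypergeom_enrich(s$altered, coll))
    })
  }

  report <- list(
    seed = config$seed,
    filter = filt$report,
    counts = counts,
    specificity = specificity,
    enrichment = enrichment,
    ratios = ratios,
    sets = sets,
    truth = truth
  )
  report$config_hash <- hash_object(config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ratio_table(ratios, file.path(config$out_dir, "ratios.tsv"))
    utils::write.table(counts,
                       file.path(config$out_dir, "altered_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cmp in names(sets)) {
      writeLines(sets[[cmp]]$altered,
                 file.path(config$out_dir,
                           paste0("altered_", cmp, ".txt")))
    }
    jsonlite::write_json(
      list(seed = report$seed, filter = report$filter,
           counts = report$counts,
           specificity = lapply(specificity, function(s)
             s[c("target", "n_specific", "n_shared")]),
           config_hash = report$config_hash),
      file.path(config$out_dir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# content hash of an R object via its canonical serialization
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
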
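#' Configuration for the synthetic pooled cohort
#'
#' Defaults describe a realistic 10-plex pooled brain cohort: ~6000
#' detected proteins spanning several orders of magnitude of reporter
#' intensity, a modest fraction of proteins genuinely altered per
#' comparison with fold changes clearly beyond the 1.2/0.8 thresholds,
#' low multiplicative technical noise (pooling averages away biological
#' variance), and enough single-peptide identifications and missing
#' values that the clean-up filters have real work to do.
#'
#' @param n_proteins number of simulated proteins.
#' @param frac_altered fraction of proteins planted as changed per
#'   comparison (split evenly UP/DOWN).
#' @param fold_up interval (length 2, both > 1) of planted UP ratios.
#' @param fold_down interval (length 2, in (0,1)) of planted DOWN ratios.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise applied independently to every intensity.
#' @param frac_missing fraction of proteins given a missing value in one
#'   randomly chosen non-control pool.
#' @param frac_low_peptide fraction of proteins forced to a single unique
#'   peptide (so the peptide filter removes them).
#' @param seed integer seed; all randomness flows from it.
#' @return An `effect_config` list.
#' @export
effect_config <- function(n_proteins = 6000L,
                          frac_altered = 0.06,
                          fold_up = c(1.3, 2.5),
                          fold_down = c(0.4, 0.77),
                          noise_cv = 0.05,
                          frac_missing = 0.04,
                          frac_low_peptide = 0.08,
                          seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              frac_altered = frac_altered,
              fold_up = fold_up, fold_down = fold_down,
              noise_cv = noise_cv, frac_missing = frac_missing,
              frac_low_peptide = frac_low_peptide,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1")
  frs <- c(frac_altered = frac_altered, frac_missing = frac_missing,
           frac_low_peptide = frac_low_peptide)
  bad <- frs < 0 | frs >= 1
  bad["frac_altered"] <- frac_altered < 0 || frac_altered > 1
  if (any(bad)) stop("invalid fraction: ",
                     paste(names(frs)[bad], collapse = ", "))
  if (length(fold_up) != 2L || fold_up[1] <= 1 || diff(fold_up) < 0) {
    stop("fold_up must be an interval with lower bound > 1")
  }
  if (length(fold_down) != 2L || fold_down[2] >= 1 || fold_down[1] <= 0 ||
      diff(fold_down) < 0) {
    stop("fold_down must be an interval inside (0, 1)")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  class(cfg) <- "effect_config"
  cfg
}

#' Simulate a pooled protein quantification table with known truth
#'
#' Draws per-protein baseline intensities log-normally (log10 mean 6,
#' sd 0.5, the reporter-intensity scale), plants UP/DOWN fold changes on
#' the case pool of each comparison before noise, applies independent
#' multiplicative log-normal noise of the configured CV to every cell,
#' forces a fraction of proteins to a single unique peptide, and injects
#' missing values into randomly chosen non-control pools (controls stay
#' complete so ratio denominators always exist). With `noise_cv = 0` the
#' realized case/control ratio of every protein equals its planted ratio
#' exactly.
#'
#' @param design a `comparison_design`.
#' @param cfg an [effect_config()].
#' @return list with `table` (a `protein_quant`) and `truth` (data.frame
#'   `accession` x `comparison` with planted `class` and `true_ratio`).
#' @export
simulate_pool_table <- function(design = pool_design(),
                                cfg = effect_config()) {
  if (!inherits(cfg, "effect_config")) cfg <- do.call(effect_config, cfg)
  if (nrow(design) < 1L) stop("empty comparison design")
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  pools <- design_pools(design)
  control_pools <- unique(design$control_pool)
  accession <- sprintf("SP%05d", seq_len(n))
  symbol <- sprintf("GENE%d", seq_len(n))

  baseline <- 10^stats::rnorm(n, mean = 6, sd = 0.5)
  # planted multiplicative effect per (protein, pool); case pools only
  plant <- matrix(1, nrow = n, ncol = length(pools),
                  dimnames = list(NULL, pools))
  n_alt <- round(cfg$frac_altered * n)
  n_up <- ceiling(n_alt / 2)
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    cls <- rep("UNCHANGED", n)
    ratio <- rep(1, n)
    if (n_alt > 0L) {
      idx <- sample.int(n, n_alt)
      up_idx <- idx[seq_len(n_up)]
      dn_idx <- idx[-seq_len(n_up)]
      ratio[up_idx] <- stats::runif(length(up_idx),
                                    cfg$fold_up[1], cfg$fold_up[2])
      ratio[dn_idx] <- stats::runif(length(dn_idx),
                                    cfg$fold_down[1], cfg$fold_down[2])
      cls[up_idx] <- "UP"
      cls[dn_idx] <- "DOWN"
    }
    plant[, design$case_pool[i]] <- plant[, design$case_pool[i]] * ratio
    truth[[i]] <- data.frame(accession = accession,
                             comparison = design$name[i],
                             class = cls, true_ratio = ratio,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  sdlog <- if (cfg$noise_cv > 0) sqrt(log(1 + cfg$noise_cv^2)) else 0
  intens <- matrix(NA_real_, nrow = n, ncol = length(pools),
                   dimnames = list(NULL, pools))
  for (p in pools) {
    noise <- if (sdlog > 0) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) else 1
    intens[, p] <- baseline * plant[, p] * noise
  }

  unique_peptides <- 1L + stats::rpois(n, lambda = 8)
  n_low <- round(cfg$frac_low_peptide * n)
  if (n_low > 0L) unique_peptides[sample.int(n, n_low)] <- 1L

  n_miss <- round(cfg$frac_missing * n)
  if (n_miss > 0L) {
    target_pools <- setdiff(pools, control_pools)
    if (length(target_pools) == 0L) target_pools <- pools
    rows <- sample.int(n, n_miss)
    cols <- sample(target_pools, n_miss, replace = TRUE)
    intens[cbind(rows, match(cols, pools))] <- NA_real_
  }

  tab <- data.frame(accession = accession, symbol = symbol,
                    unique_peptides = unique_peptides,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(intens))
  list(table = validate_protein_table(tab, pools), truth = truth)
}

#' Simulate a paired validation panel
#'
#' Emulates an orthogonal-quantification (e.g. immunoblot) check of the
#' proteomics ratios: a small panel spanning increased, decreased and
#' unchanged proteins, with the orthogonal ratio linearly related to the
#' proteomics ratio plus Gaussian noise.
#'
#' @param n_proteins panel size (>= 3; a regression on fewer pairs is
#'   meaningless).
#' @param slope linear relation between the two methods.
#' @param noise_sd SD of additive Gaussian noise on the orthogonal ratio.
#' @param seed integer seed.
#' @return data.frame with `proteomics_ratio` and `orthogonal_ratio`.
#' @export
simulate_validation_panel <- function(n_proteins = 6L, slope = 1,
                                      noise_sd = 0.1, seed = 1L) {
  if (n_proteins < 3L) stop("need at least 3 proteins for a regression")
  set.seed(as.integer(seed))
  # spread evenly from clear decreases to clear increases on the ratio scale
  x <- 2^seq(-1, 1, length.out = n_proteins)
  y <- slope * x + stats::rnorm(n_proteins, sd = noise_sd)
  data.frame(proteomics_ratio = x, orthogonal_ratio = y)
}
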
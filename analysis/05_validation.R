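#!/usr/bin/env Rscript
# Validation statistics. Two computations: (1) regression of
# orthogonal-method (immunoblot-style) ratios on proteomics ratios for a
# six-protein panel spanning increased, decreased and unchanged proteins;
# (2) a two-sample t-test computed purely from group summary statistics,
# as needed when comparing cohort demographics reported as mean +/- SD
# (here: cognitive screen totals of the impaired vs non-impaired strata,
# 99 +/- 11 vs 117 +/- 5, n = 9 each).

library(synaptomics)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))

panel <- simulate_validation_panel(n_proteins = 6, slope = 1,
                                   noise_sd = 0.1, seed = seed)
reg <- regression_validation(panel)
cat(sprintf("orthogonal vs proteomics: slope %.3f, R^2 = %.3f, p = %.4g (n = %d)\n",
            reg$slope, reg$r_squared, reg$p_value, reg$n))
jsonlite::write_json(reg, "results/validation_regression.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

tt <- summary_ttest(summary_stats(117, 5, 9), summary_stats(99, 11, 9))
cat(sprintf("cognitive score contrast (Student): t = %.2f, df = %d, p = %.4g\n",
            tt$t, tt$df, tt$p_value))
ttw <- summary_ttest(summary_stats(117, 5, 9), summary_stats(99, 11, 9),
                     welch = TRUE)
cat(sprintf("cognitive score contrast (Welch):   t = %.2f, df = %.1f, p = %.4g\n",
            ttw$t, ttw$df, ttw$p_value))
jsonlite::write_json(list(student = tt, welch = ttw),
                     "results/cognitive_ttest.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
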
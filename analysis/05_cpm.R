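#!/usr/bin/env Rscript
# Stage 5: connectome-based prediction of every experiential target --
# wakefulness, the two thought-pattern loadings, and the 11 items -- with
# motion residualization, grouped 10-fold CV repeated 100 times, 1000
# subject-level permutation nulls per target (scaled from the method's
# 10,000 default to keep a desk run short) and FDR across the 14 targets.

library(restfc)

seed <- 42
n_iters <- 100
n_null <- 1000

study <- read_study("results/data")
W <- as.matrix(read.delim("results/factorization/W.tsv", row.names = 1))
scan_ids <- readLines("results/factorization/scan_ids.txt")
subject_ids <- readLines("results/factorization/subject_ids.txt")
keep <- match(scan_ids, study$dataset$scan_ids)
ds <- study$dataset
Y <- stack_to_edge_matrix(study$stack$matrices[, , keep, drop = FALSE])
motion <- ds$motion_mean[keep]

targets <- c("wakefulness", "TP1", "TP2", colnames(ds$M))
rows <- list()
dir.create("results/cpm", showWarnings = FALSE, recursive = TRUE)
for (tg in targets) {
  y_raw <- if (tg == "wakefulness") ds$wakefulness[keep]
    else if (tg %in% colnames(W)) W[, tg]
    else ds$M[keep, tg]
  y <- residualize_target(y_raw, motion)
  cfg <- cpm_config(n_iters = n_iters, n_null = n_null,
                    seed = derive_seed(seed, paste0("cpm-", tg)))
  res <- run_cpm(Y, y, subject_ids, cfg)
  r_null <- permutation_null(Y, y, subject_ids, cfg)
  p <- nonparametric_p(res$r_obs, r_null)
  cat(sprintf("%-13s median r = %6.3f  p = %.4g  consensus edges: %d+/%d-\n",
              tg, res$r_obs_median, p,
              length(res$consensus$pos_edges), length(res$consensus$neg_edges)))
  jsonlite::write_json(
    list(target = tg, r_obs = res$r_obs, r_obs_median = res$r_obs_median,
         p_nonparametric = p, consensus_pos = res$consensus$pos_edges,
         consensus_neg = res$consensus$neg_edges),
    file.path("results/cpm", paste0(tg, ".json")), auto_unbox = TRUE,
    digits = NA)
  rows[[tg]] <- data.frame(target = tg, r_obs_median = res$r_obs_median,
                           p_nonparametric = p)
}

tab <- do.call(rbind, rows)
tab$p_fdr <- fdr_correct(tab$p_nonparametric)
write.table(format(tab, digits = 15, trim = TRUE),
            "results/cpm/summary.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("\nPrediction summary (FDR across all targets):\n")
print(tab, digits = 3, row.names = FALSE)
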
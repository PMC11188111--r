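#!/usr/bin/env Rscript
# Stage 6: collect the stage outputs into a single markdown report:
# per-target prediction accuracies with non-parametric p and FDR q, and the
# NBS contrast summary with network-pair counts.

library(restfc)

lines <- c("# Synthetic-study analysis report", "")

fit_rep <- jsonlite::read_json("results/factorization/fit_report.json")
lines <- c(lines, sprintf(
  "Factorization: d = %d (beta_W = %g, beta_Q = %g), %d scans after motion QC.",
  fit_rep$d, fit_rep$beta_W, fit_rep$beta_Q, fit_rep$kept_scans), "")

mr <- jsonlite::read_json("results/grouping/matching_report.json",
                          simplifyVector = TRUE)
lines <- c(lines, sprintf(
  "Set consistency over subjects with >= 3 scans: %.0f%% all same, %.0f%% all but one, %.0f%% split.",
  100 * mr$consistency$frac_all_same, 100 * mr$consistency$frac_all_but_one,
  100 * mr$consistency$frac_split), "")

cpm <- read.delim("results/cpm/summary.tsv")
cpm$p_fdr <- fdr_correct(cpm$p_nonparametric)   # recomputed for the report
lines <- c(lines, "## Prediction of experience reports", "",
           "target | median r | p | q (FDR)", "--- | --- | --- | ---",
           sprintf("%s | %.3f | %.4g | %.4g", cpm$target, cpm$r_obs_median,
                   cpm$p_nonparametric, cpm$p_fdr), "")

lines <- c(lines, "## FC contrast between extreme sets", "")
for (f in list.files("results/nbs", pattern = "^edges_", full.names = TRUE)) {
  e <- read.delim(f)
  lines <- c(lines, sprintf("%s: %d significant edges.",
                            sub("edges_", "", sub("\\.tsv$", "", basename(f))),
                            nrow(e)))
}
if (!length(list.files("results/nbs", pattern = "^edges_")))
  lines <- c(lines, "No significant components (none).")

writeLines(lines, "results/report.md")
cat(lines, sep = "\n")
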
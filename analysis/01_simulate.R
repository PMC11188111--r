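#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- questionnaire responses driven by
# two latent thought patterns plus demographic confounds, per-scan FC
# matrices with a planted 30-edge connected group effect (Cohen's d = 1.0)
# and a planted edge-sum/behaviour relation (r = 0.7), and motion traces.
# Writes the study to results/data/ (plain text) for the later stages.

library(restfc)

seed <- 42
spec <- synthetic_spec(n_subjects = 50, scans_per_subject = 3, n_nodes = 60,
                       n_timepoints = 660, seed = seed)
study <- generate_study(spec)

dir.create("results", showWarnings = FALSE)
write_study(study, "results/data")

cat("Simulated study written to results/data/\n")
print(study$dataset)
print(study$stack)
cat(sprintf("Planted group component: %d edges; behaviour relation on %d edges\n",
            nrow(spec$effect_edges), spec$n_behavior_edges))
cat(sprintf("Ground-truth set sizes: %s\n",
            paste(names(table(study$truth$group_labels)),
                  table(study$truth$group_labels), collapse = ", ", sep = "=")))
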
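#!/usr/bin/env Rscript
# Stage 4: Network-Based Statistic between the two extreme thought-pattern
# sets, both contrast directions (edge p < 0.001, component FWE p < 0.05,
# 5000 permutations), with laterality and network-level summaries of the
# surviving edges.

library(restfc)

seed <- 42
study <- read_study("results/data")
labels_df <- read.csv("results/grouping/labels.csv")
keep <- match(labels_df$scan_id, study$dataset$scan_ids)
stack <- study$stack
Y <- stack_to_edge_matrix(stack$matrices[, , keep, drop = FALSE])

extreme <- labels_df$set %in% c("Image-Pos-Others", "Surr-Neg-Self")
subj_set <- table(labels_df$subject_id[extreme], labels_df$set[extreme])
subject_ids <- if (any(rowSums(subj_set > 0) > 1))
  labels_df$subject_id[extreme] else NULL
if (is.null(subject_ids))
  cat("No subject spans both sets; using a between-subject design.\n")

both <- contrast_both_directions(
  Y[extreme, , drop = FALSE], labels_df$set[extreme],
  "Surr-Neg-Self>Image-Pos-Others", subject_ids = subject_ids,
  n_perm = 5000, edge_p = 0.001, component_alpha = 0.05,
  seed = derive_seed(seed, "nbs"), edge_index = stack$edge_index)

dir.create("results/nbs", showWarnings = FALSE, recursive = TRUE)
for (res in both) {
  print(res)
  sig <- unlist(lapply(res$significant, `[[`, "edges"))
  if (length(sig)) {
    pairs <- res$edge_index[sig, , drop = FALSE]
    cat(sprintf("  %d significant edges over %d nodes; laterality index %.3f\n",
                length(sig), length(unique(as.integer(pairs))),
                laterality_index(pairs, stack$atlas)))
    npc <- network_pair_counts(pairs, stack$atlas)
    cat("  top network pairs:\n")
    ut <- which(upper.tri(npc, diag = TRUE) & npc > 0, arr.ind = TRUE)
    ord <- order(npc[ut], decreasing = TRUE)
    for (k in head(ord, 5))
      cat(sprintf("    %s - %s: %d\n", rownames(npc)[ut[k, 1]],
                  colnames(npc)[ut[k, 2]], npc[ut[k, ]][1]))
    tag <- gsub("[^A-Za-z]", "_", res$contrast)
    write_edge_list(sig, res$edge_index, res$edge_t[sig],
                    file.path("results/nbs", paste0("edges_", tag, ".tsv")))
    write.table(npc, file.path("results/nbs", paste0("network_counts_", tag, ".tsv")),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(node_id = stack$atlas$node_id,
                           degree = node_degree(pairs, nrow(stack$atlas))),
                file.path("results/nbs", paste0("degree_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(null_max_extent = res$null_max_extent),
              file.path("results/nbs",
                        paste0("null_", gsub("[^A-Za-z]", "_", res$contrast), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

if (!is.null(study$truth)) {
  sig_fwd <- unlist(lapply(both[[1]]$significant, `[[`, "edges"))
  planted <- edge_ids(matrix(unlist(study$truth$effect_edges), ncol = 2),
                      nrow(stack$atlas))
  cat(sprintf("Jaccard overlap with planted component: %.3f\n",
              edge_jaccard(sig_fwd, planted)))
}
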
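#!/usr/bin/env Rscript
# Stage 3: partition scans into three thought-pattern sets from the loading
# matrix (Ward agglomerative clustering), quantify within-subject
# consistency over subjects with >= 3 scans, and check that the two extreme
# sets are matched on wakefulness, head motion and demographics.

library(restfc)

W <- as.matrix(read.delim("results/factorization/W.tsv", row.names = 1))
scan_ids <- readLines("results/factorization/scan_ids.txt")
subject_ids <- readLines("results/factorization/subject_ids.txt")
study <- read_study("results/data")
keep <- match(scan_ids, study$dataset$scan_ids)
ds <- study$dataset
ds$M <- ds$M[keep, , drop = FALSE]
ds$wakefulness <- ds$wakefulness[keep]
ds$motion_mean <- ds$motion_mean[keep]
ds$demographics <- ds$demographics[keep, , drop = FALSE]

sets <- cluster_scans(W, k = 3)
print(sets)

cons <- subject_consistency(sets$labels, subject_ids, min_scans = 3)
cat(sprintf("Within-subject consistency: all same %.0f%%, all but one %.0f%%, split %.0f%%\n",
            100 * cons["frac_all_same"], 100 * cons["frac_all_but_one"],
            100 * cons["frac_split"]))

match_tab <- compare_set_confounds(ds, sets$labels)
print(match_tab, digits = 3)

dir.create("results/grouping", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(scan_id = scan_ids, subject_id = subject_ids,
                     set = sets$labels),
          "results/grouping/labels.csv", row.names = FALSE)
jsonlite::write_json(list(consistency = as.list(cons), matching = match_tab),
                     "results/grouping/matching_report.json",
                     auto_unbox = TRUE, digits = NA)
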
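# Plain-text readers/writers for the pipeline's external formats:
# questionnaire + demographics CSV, atlas and time-series TSV, motion TSV,
# FC matrices TSV, JSON sidecars.

#' Write a synthetic study to a data directory
#'
#' Layout: `questionnaire.csv` (scan_id, subject_id, wakefulness, item
#' columns), `demographics.csv`, `atlas.tsv`, `motion/<scan_id>.tsv`
#' (one displacement value per line), `timeseries/<scan_id>.tsv` (nodes x
#' timepoints, written only when the study carries raw series),
#' `fc/<scan_id>.tsv` and `truth.json` (planted ground-truth sidecar).
#'
#' @param study Output of [generate_study()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  d <- study$dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(scan_id = d$scan_ids, subject_id = d$subject_ids,
               wakefulness = d$wakefulness, d$M, check.names = FALSE),
    file.path(dir, "questionnaire.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(scan_id = d$scan_ids, subject_id = d$subject_ids,
               d$demographics, motion_mean = d$motion_mean),
    file.path(dir, "demographics.csv"), row.names = FALSE)
  utils::write.table(study$stack$atlas, file.path(dir, "atlas.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  for (s in seq_along(study$motion))
    utils::write.table(study$motion[[s]],
                       file.path(dir, "motion", paste0(d$scan_ids[s], ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  dir.create(file.path(dir, "fc"), showWarnings = FALSE)
  for (s in seq_along(d$scan_ids))
    write_matrix_tsv(study$stack$matrices[, , s],
                     file.path(dir, "fc", paste0(d$scan_ids[s], ".tsv")))
  if (!is.null(study$stack$timeseries)) {
    dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
    for (s in seq_along(d$scan_ids))
      write_matrix_tsv(study$stack$timeseries[[s]],
                       file.path(dir, "timeseries", paste0(d$scan_ids[s], ".tsv")))
  }
  truth <- study$truth
  jsonlite::write_json(
    list(W_true = truth$W_true, Q_true = truth$Q_true, Qc_true = truth$Qc_true,
         group_labels = truth$group_labels, target_true = truth$target_true,
         effect_edges = study$stack$planted$effect_edges,
         behavior_edges = study$stack$planted$behavior_edges),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Read a study data directory
#'
#' Inverse of [write_study()] (the ground-truth sidecar, if present, is
#' returned under `truth` but is never used by the analysis stages).
#'
#' @param dir Data directory.
#' @return List with `dataset` (`experience_dataset`), `stack`
#'   (`connectivity_stack`), `motion` (list of traces), `truth` (list or
#'   `NULL`).
#' @export
read_study <- function(dir) {
  qf <- file.path(dir, "questionnaire.csv")
  if (!file.exists(qf)) stop("missing questionnaire.csv in ", dir)
  q <- utils::read.csv(qf, check.names = FALSE)
  dem <- utils::read.csv(file.path(dir, "demographics.csv"))
  atlas <- utils::read.table(file.path(dir, "atlas.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  scan_ids <- q$scan_id
  items <- setdiff(names(q), c("scan_id", "subject_id", "wakefulness"))
  M <- as.matrix(q[, items]); rownames(M) <- scan_ids
  demographics <- dem[, c("age_bin", "gender")]
  rownames(demographics) <- dem$scan_id
  dataset <- structure(
    list(M = M, scan_ids = scan_ids, subject_ids = q$subject_id,
         wakefulness = q$wakefulness, demographics = demographics,
         motion_mean = dem$motion_mean),
    class = "experience_dataset")
  mats <- lapply(scan_ids, function(id)
    read_matrix_tsv(file.path(dir, "fc", paste0(id, ".tsv"))))
  stack <- fc_stack(mats, atlas, scan_ids)
  motion <- lapply(scan_ids, function(id) {
    f <- file.path(dir, "motion", paste0(id, ".tsv"))
    if (file.exists(f)) as.numeric(readLines(f)) else NULL
  })
  tf <- file.path(dir, "truth.json")
  truth <- if (file.exists(tf)) jsonlite::read_json(tf, simplifyVector = TRUE) else NULL
  list(dataset = dataset, stack = stack, motion = motion, truth = truth)
}

#' Write significant edges as a TSV edge list
#'
#' @param edge_ids Canonical edge indices.
#' @param edge_index Node-pair table.
#' @param values Optional per-edge values (e.g., t statistics).
#' @param path Output file.
#' @export
write_edge_list <- function(edge_ids, edge_index, values = NULL, path) {
  df <- data.frame(node_i = edge_index[edge_ids, 1],
                   node_j = edge_index[edge_ids, 2])
  if (!is.null(values)) df$value <- values
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
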
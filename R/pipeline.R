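# End-to-end orchestration: simulate-or-load -> motion QC -> factorize ->
# group -> confound-matching check -> NBS on the extreme sets -> CPM on
# wakefulness, the thought-pattern loadings and the individual items.

#' Pipeline configuration
#'
#' @param data_dir Existing study directory (see [write_study()]), or `NULL`
#'   to simulate from `spec`.
#' @param spec A [synthetic_spec()] used when `data_dir` is `NULL`.
#' @param out_dir Output directory for all stage results.
#' @param d,beta_W,beta_Q Factorization parameters.
#' @param select_hyper If `TRUE`, run cross-validated hyperparameter
#'   selection over the default grid instead of using `d`/`beta_W`/`beta_Q`.
#' @param k Number of scan sets.
#' @param nbs_n_perm,nbs_edge_p,nbs_alpha NBS parameters.
#' @param cpm CPM configuration from [cpm_config()].
#' @param cpm_targets Character vector of targets: any of `"wakefulness"`,
#'   `"TP1"`, `"TP2"` and item names; `"all"` expands to wakefulness + TPs +
#'   all items (14 targets).
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(data_dir = NULL, spec = synthetic_spec(),
                       out_dir = tempfile("restfc_run_"),
                       d = 2, beta_W = 0.0, beta_Q = 0.01,
                       select_hyper = FALSE, k = 3,
                       nbs_n_perm = 5000, nbs_edge_p = 0.001, nbs_alpha = 0.05,
                       cpm = cpm_config(), cpm_targets = "all", seed = 1) {
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data_dir does not exist: ", data_dir)
  structure(list(data_dir = data_dir, spec = spec, out_dir = out_dir,
                 d = d, beta_W = beta_W, beta_Q = beta_Q,
                 select_hyper = select_hyper, k = k,
                 nbs_n_perm = nbs_n_perm, nbs_edge_p = nbs_edge_p,
                 nbs_alpha = nbs_alpha, cpm = cpm,
                 cpm_targets = cpm_targets, seed = as.integer(seed)),
            class = "run_config")
}

#' Orient factor columns by item anchors
#'
#' Orders the two factor columns so that TP1 is the dimension loading
#' highest on the "images" item (the imagery-positive-others pattern) and
#' TP2 the other (surroundings-negative-self); a no-op when `d != 2` or the
#' anchor items are absent. Naming convention only; loadings are unchanged.
#'
#' @param fit An `icqf_fit`.
#' @return The fit with columns of `W` and `Q` possibly swapped.
#' @export
orient_factors <- function(fit) {
  items <- rownames(fit$Q)
  if (fit$d == 2 && all(c("images", "surroundings") %in% items)) {
    tp1 <- which.max(fit$Q["images", ])
    if (tp1 == 2) {
      fit$W <- fit$W[, 2:1, drop = FALSE]
      fit$Q <- fit$Q[, 2:1, drop = FALSE]
      colnames(fit$W) <- colnames(fit$Q) <- c("TP1", "TP2")
    }
  }
  fit
}

#' Run the full analysis pipeline
#'
#' Stages: load-or-simulate, motion censoring QC, bounded confound-aware
#' factorization, agglomerative grouping with consistency and
#' confound-matching checks, NBS between the two extreme sets in both
#' directions, and CPM for every configured target with subject-level
#' permutation significance and FDR across targets. All stage outputs are
#' written under `config$out_dir` together with a manifest; identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Run report (list), invisibly also written as JSON/TSV files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list()

  # --- stage: data ---------------------------------------------------------
  if (is.null(config$data_dir)) {
    spec <- config$spec
    spec$seed <- derive_seed(config$seed, "simulate")
    study <- generate_study(spec)
  } else {
    study <- read_study(config$data_dir)
  }
  dataset <- study$dataset
  stack <- study$stack

  # --- stage: motion QC ----------------------------------------------------
  censor <- lapply(study$motion, function(tr)
    if (is.null(tr)) NULL else censor_volumes(tr))
  rejected <- vapply(censor, function(cr) !is.null(cr) && cr$rejected, logical(1))
  if (any(rejected)) {
    keep <- !rejected
    dataset$M <- dataset$M[keep, , drop = FALSE]
    dataset$scan_ids <- dataset$scan_ids[keep]
    dataset$subject_ids <- dataset$subject_ids[keep]
    dataset$wakefulness <- dataset$wakefulness[keep]
    dataset$demographics <- dataset$demographics[keep, , drop = FALSE]
    dataset$motion_mean <- dataset$motion_mean[keep]
    stack$matrices <- stack$matrices[, , keep, drop = FALSE]
    stack$scan_ids <- stack$scan_ids[keep]
  }
  report$qc <- list(n_scans = length(dataset$scan_ids),
                    n_rejected = sum(rejected))
  jsonlite::write_json(report$qc, file.path(out, "qc.json"), auto_unbox = TRUE)

  # --- stage: factorization ------------------------------------------------
  C <- encode_confounds(dataset$demographics)
  if (config$select_hyper) {
    sel <- select_hyperparameters(dataset$M, C,
                                  seed = derive_seed(config$seed, "hyper"))
    d <- sel$d; bW <- sel$beta_W; bQ <- sel$beta_Q
    utils::write.table(sel$cv_table, file.path(out, "cv_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    d <- config$d; bW <- config$beta_W; bQ <- config$beta_Q
  }
  fit <- suppressWarnings(
    fit_icqf(dataset$M, C, d = d, beta_W = bW, beta_Q = bQ,
             seed = derive_seed(config$seed, "factorize")))
  fit <- orient_factors(fit)
  for (nm in c("W", "Q", "Qc"))
    utils::write.table(format(fit[[nm]], digits = 15, trim = TRUE),
                       file.path(out, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(d = d, beta_W = bW, beta_Q = bQ, converged = fit$converged,
         iterations = fit$iterations,
         final_objective = utils::tail(fit$objective_trace, 1)),
    file.path(out, "factorization_report.json"), auto_unbox = TRUE, digits = NA)
  report$factorization <- list(d = d, converged = fit$converged)

  # --- stage: grouping -----------------------------------------------------
  sets <- cluster_scans(fit$W, k = config$k)
  utils::write.csv(
    data.frame(scan_id = dataset$scan_ids, subject_id = dataset$subject_ids,
               set = sets$labels),
    file.path(out, "labels.csv"), row.names = FALSE)
  consistency <- tryCatch(
    subject_consistency(sets$labels, dataset$subject_ids, min_scans = 3),
    error = function(e) NULL)
  match_tab <- compare_set_confounds(dataset, sets$labels)
  jsonlite::write_json(list(consistency = as.list(consistency),
                            matching = match_tab),
                       file.path(out, "matching_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report$grouping <- list(sizes = as.list(table(sets$labels)),
                          consistency = consistency)

  # --- stage: NBS ----------------------------------------------------------
  extreme <- sets$labels %in% c("Image-Pos-Others", "Surr-Neg-Self")
  # Subject dummies are only identifiable alongside the set effect when at
  # least one subject has scans in both sets; otherwise set membership is
  # constant within every subject and the design saturates, so the contrast
  # falls back to a between-subject design.
  subj_set <- table(dataset$subject_ids[extreme], sets$labels[extreme])
  nbs_subject_ids <- if (any(rowSums(subj_set > 0) > 1))
    dataset$subject_ids[extreme] else NULL
  nbs_both <- contrast_both_directions(
    stack_to_edge_matrix(stack$matrices[, , extreme, drop = FALSE]),
    group = sets$labels[extreme],
    contrast = "Surr-Neg-Self>Image-Pos-Others",
    subject_ids = nbs_subject_ids,
    n_perm = config$nbs_n_perm, edge_p = config$nbs_edge_p,
    component_alpha = config$nbs_alpha,
    seed = derive_seed(config$seed, "nbs"),
    edge_index = stack$edge_index)
  nbs_summary <- lapply(nbs_both, function(res) {
    sig_edges <- unlist(lapply(res$significant, `[[`, "edges"))
    list(contrast = res$contrast,
         subject_design = !is.null(nbs_subject_ids),
         n_components = length(res$components),
         n_significant_components = length(res$significant),
         significant_extents = vapply(res$significant, `[[`, integer(1), "extent"),
         component_p = vapply(res$components, `[[`, numeric(1), "p_fwe"),
         n_significant_edges = length(sig_edges),
         laterality = if (length(sig_edges))
           suppressWarnings(laterality_index(
             res$edge_index[sig_edges, , drop = FALSE], stack$atlas))
         else NA)
  })
  fwd <- nbs_both[[1]]
  sig_edges <- unlist(lapply(fwd$significant, `[[`, "edges"))
  if (length(sig_edges)) {
    write_edge_list(sig_edges, fwd$edge_index, fwd$edge_t[sig_edges],
                    file.path(out, "nbs_significant_edges.tsv"))
    npc <- network_pair_counts(fwd$edge_index[sig_edges, , drop = FALSE],
                               stack$atlas)
    utils::write.table(npc, file.path(out, "nbs_network_pair_counts.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  utils::write.table(data.frame(null_max_extent = fwd$null_max_extent),
                     file.path(out, "nbs_null.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(nbs_summary, file.path(out, "nbs_components.json"),
                       auto_unbox = TRUE, digits = NA)
  report$nbs <- nbs_summary

  # --- stage: CPM ----------------------------------------------------------
  targets <- config$cpm_targets
  if (identical(targets, "all"))
    targets <- c("wakefulness", "TP1", "TP2", colnames(dataset$M))
  edge_mat <- stack_to_edge_matrix(stack$matrices)
  cpm_rows <- list()
  for (tg in targets) {
    y_raw <- if (tg == "wakefulness") dataset$wakefulness
      else if (tg %in% colnames(fit$W)) fit$W[, tg]
      else if (tg %in% colnames(dataset$M)) dataset$M[, tg]
      else stop("unknown CPM target: ", tg)
    y <- if (all(is.na(dataset$motion_mean))) y_raw - mean(y_raw)
      else residualize_target(y_raw, dataset$motion_mean)
    cfg <- config$cpm
    cfg$seed <- derive_seed(config$seed, paste0("cpm-", tg))
    res <- run_cpm(edge_mat, y, dataset$subject_ids, cfg)
    r_null <- permutation_null(edge_mat, y, dataset$subject_ids, cfg)
    p <- nonparametric_p(res$r_obs, r_null)
    jsonlite::write_json(
      list(target = tg, r_obs = res$r_obs, r_obs_median = res$r_obs_median,
           p_nonparametric = p,
           consensus_pos = res$consensus$pos_edges,
           consensus_neg = res$consensus$neg_edges),
      file.path(out, paste0("cpm_", tg, ".json")), auto_unbox = TRUE,
      digits = NA)
    cpm_rows[[tg]] <- data.frame(target = tg,
                                 r_obs_median = res$r_obs_median,
                                 p_nonparametric = p)
  }
  cpm_tab <- do.call(rbind, cpm_rows)
  cpm_tab$p_fdr <- fdr_correct(cpm_tab$p_nonparametric)
  utils::write.table(format(cpm_tab, digits = 15, trim = TRUE),
                     file.path(out, "cpm_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  report$cpm <- cpm_tab

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("restfc")),
    seed = config$seed,
    parameters = list(d = d, beta_W = bW, beta_Q = bQ, k = config$k,
                      nbs_n_perm = config$nbs_n_perm,
                      nbs_edge_p = config$nbs_edge_p,
                      nbs_alpha = config$nbs_alpha,
                      cpm = unclass(config$cpm),
                      cpm_targets = targets))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  report$out_dir <- out
  invisible(report)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `output_dir` and writes `report.md` (and
#' returns the pieces): a per-target CPM accuracy table with non-parametric
#' p and FDR q (q recomputed from the p column), and the NBS component
#' summary with network-pair counts when significant edges exist. Missing
#' stages are noted rather than erroring.
#'
#' @param output_dir Directory written by [run_pipeline()].
#' @return List with `cpm` (data frame or `NULL`), `nbs` (list or `NULL`),
#'   `report_path`.
#' @export
summarize_run <- function(output_dir) {
  lines <- c("# Pipeline run summary", "")
  out <- list()
  cpm_f <- file.path(output_dir, "cpm_summary.tsv")
  if (file.exists(cpm_f)) {
    cpm <- utils::read.delim(cpm_f)
    cpm$p_fdr <- fdr_correct(cpm$p_nonparametric)
    out$cpm <- cpm
    lines <- c(lines, "## Prediction of experience reports (CPM)", "",
               "target | median r | p (non-parametric) | q (FDR)",
               "--- | --- | --- | ---",
               sprintf("%s | %.3f | %.4g | %.4g", cpm$target,
                       cpm$r_obs_median, cpm$p_nonparametric, cpm$p_fdr), "")
  } else lines <- c(lines, "CPM stage missing.", "")
  nbs_f <- file.path(output_dir, "nbs_components.json")
  if (file.exists(nbs_f)) {
    nbs <- jsonlite::read_json(nbs_f, simplifyVector = TRUE)
    out$nbs <- nbs
    for (res in nbs) {
      n_sig <- res$n_significant_components
      lines <- c(lines, paste0("## NBS contrast ", res$contrast), "",
                 if (n_sig == 0) "No significant components (none)."
                 else sprintf("%d significant component(s); %d edges; laterality %.3f.",
                              n_sig, res$n_significant_edges,
                              as.numeric(res$laterality)), "")
    }
  } else lines <- c(lines, "NBS stage missing.", "")
  npc_f <- file.path(output_dir, "nbs_network_pair_counts.tsv")
  if (file.exists(npc_f)) {
    npc <- utils::read.delim(npc_f, row.names = 1, check.names = FALSE)
    lines <- c(lines, "## Network-pair counts of significant edges", "",
               paste(utils::capture.output(print(npc)), collapse = "\n"), "")
  }
  path <- file.path(output_dir, "report.md")
  writeLines(lines, path)
  out$report_path <- path
  out
}
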
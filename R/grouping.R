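# Partition scans into thought-pattern sets from the loading matrix W,
# quantify within-subject consistency, and verify confound matching between
# the two extreme sets.

#' Cluster scans into thought-pattern sets
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance) of the
#' scans-by-dimensions loading matrix. With two or more loading dimensions,
#' sets are named by centroid geometry: the centroid with the highest
#' `TP1 - TP2` becomes `Image-Pos-Others`, the highest `TP2 - TP1` becomes
#' `Surr-Neg-Self`, and the remainder `Intermediate`.
#'
#' @param W Scans x d loading matrix with entries in `[0, 1]`.
#' @param k Number of sets (default 3).
#' @return Object of class `scan_sets`: `labels` (character per scan),
#'   `centroids` (set x d matrix), `k`.
#' @export
cluster_scans <- function(W, k = 3) {
  W <- as.matrix(W)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(W)) stop("k exceeds the number of scans")
  if (min(W) < -1e-9 || max(W) > 1 + 1e-9) stop("W entries must lie in [0, 1]")
  hc <- stats::hclust(stats::dist(W), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  cent <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(W[cl == g, , drop = FALSE])))
  names_out <- rep("Intermediate", k)
  if (ncol(W) >= 2) {
    score <- cent[, 1] - cent[, 2]
    names_out[which.max(score)] <- "Image-Pos-Others"
    names_out[which.min(score)] <- "Surr-Neg-Self"
  } else {
    names_out[which.max(cent[, 1])] <- "Image-Pos-Others"
    names_out[which.min(cent[, 1])] <- "Surr-Neg-Self"
  }
  if (anyDuplicated(names_out[names_out != "Intermediate"]))
    stop("degenerate centroids: extreme sets coincide")
  rownames(cent) <- names_out
  structure(list(labels = names_out[cl], centroids = cent, k = k),
            class = "scan_sets")
}

#' @export
print.scan_sets <- function(x, ...) {
  cat("Scan sets (Ward agglomerative clustering, k =", x$k, ")\n")
  print(table(x$labels))
  invisible(x)
}

#' Within-subject consistency of set membership
#'
#' Over subjects with at least `min_scans` scans: the fraction whose scans
#' all share one set, the fraction with all but one scan in one set, and the
#' fraction split more evenly (including an even two-set split).
#'
#' @param labels Per-scan set labels.
#' @param subject_ids Per-scan subject identifiers.
#' @param min_scans Minimum scans for a subject to qualify (default 3).
#' @return Named numeric vector `(frac_all_same, frac_all_but_one,
#'   frac_split)` summing to 1.
#' @export
subject_consistency <- function(labels, subject_ids, min_scans = 3) {
  stopifnot(length(labels) == length(subject_ids), min_scans >= 2)
  counts <- table(subject_ids)
  keep <- names(counts)[counts >= min_scans]
  if (length(keep) == 0) stop("no subjects with at least ", min_scans, " scans")
  cls <- vapply(keep, function(s) {
    tab <- table(labels[subject_ids == s])
    n <- sum(tab)
    if (max(tab) == n) "all_same"
    else if (max(tab) == n - 1L) "all_but_one"
    else "split"
  }, character(1))
  out <- c(frac_all_same = mean(cls == "all_same"),
           frac_all_but_one = mean(cls == "all_but_one"),
           frac_split = mean(cls == "split"))
  out
}

two_sample_row <- function(covariate, a, b) {
  if (stats::sd(c(a, b)) == 0) {
    return(data.frame(covariate = covariate,
                      test = c("t", "mann_whitney"),
                      statistic = NA_real_, p_value = NA_real_,
                      note = "undefined: zero variance"))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  data.frame(covariate = covariate,
             test = c("t", "mann_whitney"),
             statistic = c(unname(tt$statistic), unname(wt$statistic)),
             p_value = c(tt$p.value, wt$p.value),
             note = "")
}

#' Confound matching between two scan sets
#'
#' For continuous covariates (wakefulness, mean head motion): two-sample t
#' test (equal variance) and Mann-Whitney U. For age-bin counts: paired t and
#' Wilcoxon signed-rank over bins. Gender is reported as counts per set
#' without a test. Degenerate covariates (zero variance in both sets) are
#' flagged as undefined rather than propagating NaN.
#'
#' @param dataset An `experience_dataset`.
#' @param labels Per-scan set labels.
#' @param set_a,set_b The two set names to compare.
#' @return Data frame with columns `covariate`, `test`, `statistic`,
#'   `p_value`, `note`.
#' @export
compare_set_confounds <- function(dataset, labels, set_a = "Surr-Neg-Self",
                                  set_b = "Image-Pos-Others") {
  stopifnot(inherits(dataset, "experience_dataset"),
            length(labels) == nrow(dataset$M))
  ia <- labels == set_a; ib <- labels == set_b
  if (!any(ia) || !any(ib)) stop("empty set in comparison")

  rows <- list()
  rows$wake <- two_sample_row("wakefulness",
                              dataset$wakefulness[ia], dataset$wakefulness[ib])
  if (!all(is.na(dataset$motion_mean)))
    rows$motion <- two_sample_row("motion_mean",
                                  dataset$motion_mean[ia], dataset$motion_mean[ib])

  bins <- sort(unique(dataset$demographics$age_bin))
  ca <- as.numeric(table(factor(dataset$demographics$age_bin[ia], bins)))
  cb <- as.numeric(table(factor(dataset$demographics$age_bin[ib], bins)))
  if (stats::sd(ca - cb) == 0) {
    rows$age <- data.frame(covariate = "age_bin",
                           test = c("paired_t", "wilcoxon"),
                           statistic = NA_real_, p_value = NA_real_,
                           note = "undefined: identical bin counts")
  } else {
    tt <- stats::t.test(ca, cb, paired = TRUE)
    wt <- suppressWarnings(stats::wilcox.test(ca, cb, paired = TRUE, exact = FALSE))
    rows$age <- data.frame(covariate = "age_bin",
                           test = c("paired_t", "wilcoxon"),
                           statistic = c(unname(tt$statistic), unname(wt$statistic)),
                           p_value = c(tt$p.value, wt$p.value),
                           note = "")
  }

  glev <- sort(unique(as.character(dataset$demographics$gender)))
  ga <- table(factor(dataset$demographics$gender[ia], glev))
  gb <- table(factor(dataset$demographics$gender[ib], glev))
  rows$gender <- data.frame(
    covariate = "gender", test = "counts", statistic = NA_real_,
    p_value = NA_real_,
    note = paste0(set_a, ": ", paste(glev, ga, sep = "=", collapse = ", "),
                  " | ", set_b, ": ", paste(glev, gb, sep = "=", collapse = ", ")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
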
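check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outranks a random negative, ties counting one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision convention: sum over distinct-score
#' thresholds of (increment in recall) times (precision at the threshold);
#' no trapezoidal interpolation.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  # last element of each distinct-score run = one threshold per score value
  cut <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[cut]
  n <- cut
  P <- sum(y)
  recall <- tp / P
  precision <- tp / n
  sum(diff(c(0, recall)) * precision)
}

#' TPR and F1 at a false-discovery-rate operating point
#'
#' Among score thresholds achieving precision at least `1 - fdr_level`,
#' selects the one maximising recall (ties broken toward the lower
#' threshold) and reports the true positive rate and F1 score there. When
#' no threshold achieves the required precision, TPR and F1 are 0 and
#' `achieved` is `FALSE`.
#'
#' @inheritParams roc_auc
#' @param fdr_level false discovery rate (default 0.05).
#' @return list with `tpr`, `f1`, `threshold`, `precision`, `achieved`.
#' @export
tpr_f1_at_fdr <- function(scores, labels, fdr_level = 0.05) {
  stopifnot(length(scores) == length(labels))
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  cut <- cumsum(rle(s)$lengths)     # predict positive at score >= s[cut]
  tp <- cumsum(y)[cut]
  precision <- tp / cut
  P <- sum(y)
  recall <- tp / P
  ok <- precision >= 1 - fdr_level & tp > 0
  if (!any(ok))
    return(list(tpr = 0, f1 = 0, threshold = NA_real_,
                precision = NA_real_, achieved = FALSE))
  cand <- which(ok)
  best <- cand[recall[cand] == max(recall[cand])]
  best <- best[length(best)]   # lower threshold wins ties
  tpr <- recall[best]
  prec <- precision[best]
  list(tpr = tpr, f1 = 2 * prec * tpr / (prec + tpr),
       threshold = s[cut[best]], precision = prec, achieved = TRUE)
}

#' ROC and precision-recall curve coordinates
#'
#' @inheritParams roc_auc
#' @return list of two data frames: `roc` (threshold, fpr, tpr) and
#'   `pr` (threshold, recall, precision), at distinct-score thresholds.
#' @export
score_curves <- function(scores, labels) {
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  cut <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[cut]; fp <- cut - tp
  P <- sum(y); N <- length(y) - P
  list(roc = data.frame(threshold = s[cut], fpr = fp / N, tpr = tp / P),
       pr = data.frame(threshold = s[cut], recall = tp / P,
                       precision = tp / cut))
}

#' Restrict test records to low-data alleles
#'
#' Keeps test records whose allele has fewer than `min_positives` positive
#' peptides in the training set (the regime where pan-allele models
#' struggle most).
#'
#' @param test_records,train_records data frames with `peptide`, `allele`,
#'   `label`.
#' @param min_positives threshold (default 200).
#' @return list with `records` (the subset) and `alleles` (the low-data
#'   allele names).
#' @export
low_data_allele_subset <- function(test_records, train_records,
                                   min_positives = 200L) {
  pos <- train_records[train_records$label == 1L, , drop = FALSE]
  counts <- table(pos$allele)
  n_pos <- as.integer(counts[match(unique(test_records$allele),
                                   names(counts))])
  n_pos[is.na(n_pos)] <- 0L
  low <- unique(test_records$allele)[n_pos < min_positives]
  list(records = test_records[test_records$allele %in% low, , drop = FALSE],
       alleles = low)
}

#' Minimum edit distance of test peptides to a training set
#'
#' Levenshtein distance (unit insertion/deletion/substitution) minimised
#' over all training peptides, then binned (defaults follow the standard
#' leakage audit: <=2, 3, 4, >=5).
#'
#' @param test_peptides,train_peptides character vectors.
#' @param chunk_size training peptides per distance-matrix block.
#' @return data frame `peptide`, `min_edit_distance`, `bin`.
#' @export
min_edit_distance_strata <- function(test_peptides, train_peptides,
                                     chunk_size = 2000L) {
  if (length(train_peptides) == 0L)
    stop("training peptide set is empty", call. = FALSE)
  test_u <- unique(test_peptides)
  mins <- rep(Inf, length(test_u))
  for (start in seq(1L, length(train_peptides), by = chunk_size)) {
    blk <- train_peptides[start:min(start + chunk_size - 1L,
                                    length(train_peptides))]
    d <- utils::adist(test_u, blk)
    mins <- pmin(mins, apply(d, 1L, min))
  }
  md <- mins[match(test_peptides, test_u)]
  bin <- cut(md, breaks = c(-Inf, 2, 3, 4, Inf),
             labels = c("<=2", "3", "4", ">=5"))
  data.frame(peptide = test_peptides, min_edit_distance = md, bin = bin,
             stringsAsFactors = FALSE)
}

#' Full evaluation report
#'
#' AUC, AUPRC, and TPR/F1 at the requested FDR levels, optionally with
#' per-stratum sub-reports for low-data alleles and edit-distance bins.
#'
#' @param scores numeric predicted probabilities.
#' @param labels 0/1 labels.
#' @param fdr_levels FDR operating points (default `c(0.05, 0.01)`).
#' @param test_records optional data frame aligned with `scores` (columns
#'   `peptide`, `allele`, `label`) enabling stratified sub-reports.
#' @param train_records optional training records for the low-data and
#'   edit-distance stratifications.
#' @param min_positives low-data allele threshold (default 200).
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(scores, labels, fdr_levels = c(0.05, 0.01),
                        test_records = NULL, train_records = NULL,
                        min_positives = 200L) {
  base <- eval_block(scores, labels, fdr_levels)
  strata <- list()
  if (!is.null(test_records) && !is.null(train_records)) {
    low <- low_data_allele_subset(test_records, train_records,
                                  min_positives)
    in_low <- test_records$allele %in% low$alleles
    if (sum(in_low) && length(unique(labels[in_low])) == 2L)
      strata$low_data <- c(eval_block(scores[in_low], labels[in_low],
                                      fdr_levels),
                           list(alleles = low$alleles, n = sum(in_low)))
    tr_pep <- unique(train_records$peptide)
    eds <- min_edit_distance_strata(test_records$peptide, tr_pep)
    by_bin <- list()
    for (b in levels(eds$bin)) {
      sel <- eds$bin == b
      if (sum(sel) >= 2L && length(unique(labels[sel])) == 2L)
        by_bin[[b]] <- c(eval_block(scores[sel], labels[sel], fdr_levels),
                         list(n = sum(sel)))
    }
    if (length(by_bin)) strata$edit_distance <- by_bin
  }
  structure(c(base, list(strata = strata,
                         n_pos = sum(labels == 1L),
                         n_neg = sum(labels == 0L))),
            class = "eval_report")
}

eval_block <- function(scores, labels, fdr_levels) {
  at <- lapply(fdr_levels, function(f) tpr_f1_at_fdr(scores, labels, f))
  names(at) <- paste0("fdr_", fdr_levels)
  list(auc = roc_auc(scores, labels), auprc = auprc(scores, labels),
       at_fdr = at)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%d positive, %d negative)\n",
              x$n_pos, x$n_neg))
  cat(sprintf("  AUC    %.4f\n  AUPRC  %.4f\n", x$auc, x$auprc))
  for (nm in names(x$at_fdr)) {
    a <- x$at_fdr[[nm]]
    cat(sprintf("  %s: TPR %.4f  F1 %.4f%s\n",
                sub("fdr_", "FDR ", nm), a$tpr, a$f1,
                if (!a$achieved) "  [FDR not achievable]" else ""))
  }
  if (length(x$strata$low_data))
    cat(sprintf("  low-data alleles (n = %d): AUC %.4f\n",
                x$strata$low_data$n, x$strata$low_data$auc))
  if (length(x$strata$edit_distance)) {
    cat("  edit-distance strata:\n")
    for (b in names(x$strata$edit_distance))
      cat(sprintf("    %-4s n = %4d  AUC %.4f\n", b,
                  x$strata$edit_distance[[b]]$n,
                  x$strata$edit_distance[[b]]$auc))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON for the scalar metrics and TSV files for the ROC/PR curves.
#'
#' @param report an [eval_report()].
#' @param scores,labels the scored data the report was computed from.
#' @param dir output directory.
#' @return invisibly, the file paths written.
#' @export
write_eval_report <- function(report, scores, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cv <- score_curves(scores, labels)
  roc_path <- file.path(dir, "roc_curve.tsv")
  pr_path <- file.path(dir, "pr_curve.tsv")
  utils::write.table(cv$roc, roc_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cv$pr, pr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json, roc = roc_path, pr = pr_path))
}
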
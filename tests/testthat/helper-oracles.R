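# Independent oracles used across the suite. These deliberately use naive
# brute-force formulations so they stay independent of the implementations
# they check.

# Textbook dynamic-programming Levenshtein distance.
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L,
                               D[i, j] + (x[i] != y[j]))
    }
  }
  D[n + 1L, m + 1L]
}

# Pairwise-count AUC: P(score_pos > score_neg) + 0.5 P(tie).
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Average precision by explicit loop over every distinct threshold.
brute_ap <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1L)
  ap <- 0
  prev_recall <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  ap
}

# Exhaustive search over thresholds for the FDR operating point.
brute_tpr_f1 <- function(scores, labels, fdr) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1L)
  best <- list(tpr = 0, f1 = 0, achieved = FALSE)
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1L)
    if (tp == 0) next
    prec <- tp / sum(sel)
    rec <- tp / P
    if (prec >= 1 - fdr &&
        (rec > best$tpr || (rec == best$tpr && best$achieved))) {
      best <- list(tpr = rec, f1 = 2 * prec * rec / (prec + rec),
                   achieved = TRUE)
    }
  }
  best
}

# All-pairs minimum word-word distance over constituent residues.
brute_min_word_dist <- function(res_u, res_v, dm) {
  vals <- c()
  for (i in res_u) for (j in res_v) {
    v <- dm[as.character(i), as.character(j)]
    if (!is.na(v)) vals <- c(vals, v)
  }
  if (length(vals)) min(vals) else NA_real_
}

random_peptide <- function(L, alphabet = pepmhc:::AA_STANDARD) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}
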
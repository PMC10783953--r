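test_that("ROC AUC equals the pairwise-count oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 1)), 2 / 3)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(51)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
})

test_that("random scores give AUC near one half", {
  set.seed(52)
  n <- 1e4
  labels <- sample(0:1, n, TRUE)
  expect_equal(roc_auc(runif(n), labels), 0.5, tolerance = 0.02)
})

test_that("AUPRC equals the step-wise average-precision oracle", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))
    expect_equal(auprc(scores, labels), brute_ap(scores, labels))
  }
})

test_that("the FDR operating point matches exhaustive threshold search", {
  res <- tpr_f1_at_fdr(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 0, 1, 0), 0.05)
  expect_equal(res$tpr, 2 / 3)
  expect_equal(res$f1, 0.8)
  expect_equal(res$threshold, 0.8)
  perfect <- tpr_f1_at_fdr(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.05)
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$f1, 1)
  # all negatives outrank all positives: unreachable FDR is flagged
  bad <- tpr_f1_at_fdr(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0), 0.05)
  expect_false(bad$achieved)
  expect_identical(bad$tpr, 0)
  expect_error(tpr_f1_at_fdr(c(0.5, 0.6), c(1, 1), 0.05), "both classes")
  set.seed(54)
  for (i in 1:60) {
    n <- sample(10:150, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2), 1))
    for (fdr in c(0.05, 0.25)) {
      got <- tpr_f1_at_fdr(scores, labels, fdr)
      want <- brute_tpr_f1(scores, labels, fdr)
      expect_equal(got$tpr, want$tpr)
      expect_equal(got$f1, want$f1)
      expect_identical(got$achieved, want$achieved)
    }
  }
})

test_that("curve coordinates are consistent with the scalar metrics", {
  set.seed(55)
  labels <- sample(0:1, 200, TRUE)
  scores <- runif(200)
  cv <- score_curves(scores, labels)
  expect_equal(max(cv$roc$tpr), 1)
  expect_equal(max(cv$roc$fpr), 1)
  expect_true(all(diff(cv$roc$tpr) >= 0))
  expect_equal(sum(diff(c(0, cv$pr$recall)) * cv$pr$precision),
               auprc(scores, labels))
})

test_that("low-data subsetting uses positive training counts per allele", {
  train <- data.frame(
    peptide = replicate(450, random_peptide(9)),
    allele = c(rep("HLA-A*01:01", 199), rep("HLA-A*02:01", 200),
               rep("HLA-B*07:02", 51)),
    label = c(rep(1L, 199), rep(1L, 200), rep(1L, 50), 0L))
  test <- data.frame(peptide = replicate(6, random_peptide(9)),
                     allele = rep(c("HLA-A*01:01", "HLA-A*02:01",
                                    "HLA-B*07:02"), 2),
                     label = 1L)
  low <- low_data_allele_subset(test, train, min_positives = 200)
  expect_setequal(low$alleles, c("HLA-A*01:01", "HLA-B*07:02"))
  expect_identical(nrow(low$records), 4L)
  # empty training set: every allele is low-data
  none <- low_data_allele_subset(test, train[0, ], min_positives = 200)
  expect_setequal(none$alleles, unique(test$allele))
})

test_that("low-data counts match a brute-force group-by", {
  set.seed(56)
  alleles <- paste0("HLA-A*90:", sprintf("%02d", 1:8))
  train <- data.frame(peptide = replicate(1000, random_peptide(9)),
                      allele = sample(alleles, 1000, TRUE),
                      label = sample(0:1, 1000, TRUE))
  test <- data.frame(peptide = replicate(200, random_peptide(9)),
                     allele = sample(alleles, 200, TRUE), label = 1L)
  for (cut in c(50, 70)) {
    low <- low_data_allele_subset(test, train, min_positives = cut)
    want <- names(which(vapply(alleles, function(a)
      sum(train$label == 1L & train$allele == a), 1L) < cut))
    expect_setequal(low$alleles, want)
  }
})

test_that("minimum edit distance matches the DP oracle", {
  expect_equal(min_edit_distance_strata("kitten", "sitting")$min_edit_distance, 3)
  ed <- min_edit_distance_strata(c("AAAAAAAAA"), c("AAAAAAAAT"))
  expect_equal(ed$min_edit_distance, 1)
  expect_identical(as.character(ed$bin), "<=2")
  same <- min_edit_distance_strata("ACDEFGHIK",
                                   c("ACDEFGHIK", "WWWWWWWWW"))
  expect_equal(same$min_edit_distance, 0)
  expect_identical(as.character(same$bin), "<=2")
  expect_error(min_edit_distance_strata("ACD", character(0)), "empty")
  set.seed(57)
  test_p <- replicate(20, random_peptide(sample(8:15, 1)))
  train_p <- replicate(10, random_peptide(sample(8:15, 1)))
  got <- min_edit_distance_strata(test_p, train_p)
  for (i in seq_along(test_p)) {   # 200 random pairs through the oracle
    want <- min(vapply(train_p, dp_edit_distance, 1L, a = test_p[i]))
    expect_equal(got$min_edit_distance[i], want)
  }
  bins <- cut(got$min_edit_distance, c(-Inf, 2, 3, 4, Inf),
              labels = c("<=2", "3", "4", ">=5"))
  expect_identical(got$bin, bins)
})

test_that("evaluation reports aggregate metrics and strata", {
  set.seed(58)
  n <- 300
  labels <- sample(0:1, n, TRUE)
  scores <- ifelse(labels == 1, rnorm(n, 1), rnorm(n))
  train <- data.frame(peptide = replicate(100, random_peptide(9)),
                      allele = "HLA-A*90:01", label = 1L)
  test <- data.frame(peptide = replicate(n, random_peptide(9)),
                     allele = sample(c("HLA-A*90:01", "HLA-A*90:02"),
                                     n, TRUE),
                     label = labels)
  rep <- eval_report(scores, labels, test_records = test,
                     train_records = train, min_positives = 50L)
  expect_equal(rep$auc, roc_auc(scores, labels))
  expect_equal(rep$auprc, auprc(scores, labels))
  expect_named(rep$at_fdr, c("fdr_0.05", "fdr_0.01"))
  expect_true(all(vapply(rep$at_fdr, function(a)
    a$tpr >= 0 && a$tpr <= 1, TRUE)))
  expect_identical(sort(rep$strata$low_data$alleles), "HLA-A*90:02")
  out <- tempfile()
  files <- write_eval_report(rep, scores, labels, out)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(files["json"])
  expect_equal(js$auc, rep$auc, tolerance = 1e-9)
})

test_that("rank-based AUC agrees with an independent library", {
  set.seed(59)
  labels <- c(0, 1, sample(0:1, 300, TRUE))
  scores <- round(runif(302), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref)
})
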
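test_that("the affinity transform matches its closed forms", {
  expect_equal(transform_affinity(50000), 0)
  expect_equal(transform_affinity(1), 1)
  expect_equal(transform_affinity(500), 1 - log(500) / log(50000),
               tolerance = 1e-12)
  expect_error(transform_affinity(0), "positive")
  expect_error(transform_affinity(-5), "positive")
  # clip above 50000 nM
  expect_equal(transform_affinity(1e6), 0)
})

test_that("the transform is strictly decreasing and invertible", {
  grid <- exp(seq(log(1), log(50000), length.out = 100))
  tv <- transform_affinity(grid)
  expect_true(all(diff(tv) < 0))
  set.seed(41)
  x <- exp(runif(100, log(1.5), log(49000)))
  back <- inverse_transform_affinity(transform_affinity(x))
  expect_equal(back, x, tolerance = 1e-7)
})

test_that("pair tables are parsed, normalized and deduplicated", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tlabel",
               "ACDEFGHIK\tA0201\t1",
               "ACDEFGHIK\tA0201\t1",
               "ACDXFGHIB\tA0201\t1",
               "acdefghik\thla-b*44:02\t0",
               "ACDEFGHIW\tHLA class I\t1"), path)
  rec <- read_pair_table(path)
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$allele, c("HLA-A*02:01", "HLA-B*44:02"))
  rep <- attr(rec, "report")
  expect_true(any(rep$reason == "non-standard residue" & rep$line == 4L))
  expect_true(any(rep$reason == "non-specific allele"))
  writeLines(c("peptide\tlabel", "ACD\t1"), path)
  expect_error(read_pair_table(path), "allele")
  expect_error(read_pair_table(tempfile()), "cannot read")
})

test_that("allele names normalize to the two-field form", {
  expect_identical(normalize_allele(c("A0201", "A*02:01", "HLA-A02:01",
                                      "hla-b*44:02", "C0702")),
                   c("HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01",
                     "HLA-B*44:02", "HLA-C*07:02"))
  expect_true(is.na(normalize_allele("HLA class I")))
})

test_that("epitope cleaning drops conflicts and off-length peptides", {
  rec <- data.frame(
    peptide = c("ACDEFGHIK", "ACDEFGHIK",       # conflicting labels
                "CDEFGHI",                       # 7-mer
                "ACDEFGHIKLMNPQRS",              # 16-mer
                "ACDEFGHK",                      # 8-mer keep
                "ACDEFGHIKLMNPQR",               # 15-mer keep
                "ACDEFGXZ1"),                    # modified
    allele = "HLA-A*02:01",
    label = c(1L, 0L, 1L, 1L, 1L, 0L, 1L))
  out <- clean_epitope_pairs(rec)
  expect_setequal(out$peptide, c("ACDEFGHK", "ACDEFGHIKLMNPQR"))
  counts <- attr(out, "filter_counts")
  expect_identical(unname(counts["conflicting"]), 2L)
  # idempotent and never grows
  again <- clean_epitope_pairs(out)
  expect_identical(nrow(again), nrow(out))
  expect_identical(again$peptide, out$peptide)
})

test_that("peptide length distributions are normalized frequencies", {
  expect_identical(peptide_length_distribution(rep("ACDEFGHIK", 5)),
                   c(`9` = 1))
  d <- peptide_length_distribution(c(rep("ACDEFGHIK", 50),
                                     rep("ACDEFGHIKL", 50)))
  expect_equal(d, c(`9` = 0.5, `10` = 0.5))
  set.seed(42)
  peps <- replicate(1000, random_peptide(sample(8:15, 1)))
  d2 <- peptide_length_distribution(peps)
  expect_equal(sum(d2), 1)
  expect_equal(unname(d2[as.character(9)]),
               sum(nchar(peps) == 9) / 1000)
  expect_error(peptide_length_distribution(character(0)), "no peptides")
})

test_that("synthetic negatives follow the requested distributions", {
  neg <- sample_negative_batch(c(`9` = 1), c("HLA-A*02:01"), 50, seed = 1)
  expect_true(all(nchar(neg$peptide) == 9))
  expect_true(all(neg$label == 0L))
  expect_true(all(neg$source == "synthetic-negative"))
  # residue usage uniform over the 20 amino acids
  big <- sample_negative_batch(c(`9` = 0.5, `10` = 0.5),
                               c("HLA-A*02:01", "HLA-B*44:02"),
                               11000, seed = 2)
  chars <- unlist(strsplit(big$peptide, "", fixed = TRUE))  # ~10^5 draws
  expect_gt(stats::chisq.test(table(chars))$p.value, 0.01)
  # fresh draws differ across seeds
  n1 <- sample_negative_batch(c(`9` = 1), "HLA-A*02:01", 20, seed = 1)
  n2 <- sample_negative_batch(c(`9` = 1), "HLA-A*02:01", 20, seed = 2)
  expect_false(identical(n1$peptide, n2$peptide))
  expect_error(sample_negative_batch(c(`9` = 1), "HLA-A*02:01", 0),
               "positive")
})

test_that("dataset splits are peptide-disjoint and exhaustive", {
  set.seed(43)
  peps <- replicate(100, random_peptide(9))
  rec <- data.frame(peptide = peps,
                    allele = sample(c("HLA-A*02:01", "HLA-B*44:02"),
                                    100, TRUE),
                    label = 1L)
  sp <- split_dataset(rec, c(train = 0.8, validation = 0.1, test = 0.1),
                      seed = 5)
  sizes <- vapply(sp[c("train", "validation", "test")], nrow, 1L)
  expect_identical(sum(sizes), 100L)
  expect_true(abs(sizes["train"] - 80L) <= 2L)
  expect_length(intersect(sp$train$peptide, sp$test$peptide), 0L)
  expect_length(intersect(sp$train$peptide, sp$validation$peptide), 0L)
  # a peptide shared by two alleles stays in one partition
  rec2 <- rbind(rec, data.frame(peptide = rec$peptide[1L],
                                allele = "HLA-C*07:02", label = 0L))
  sp2 <- split_dataset(rec2, c(a = 0.5, b = 0.5), seed = 1)
  hit <- vapply(sp2[c("a", "b")], function(d)
    rec$peptide[1L] %in% d$peptide, TRUE)
  expect_identical(sum(hit), 1L)
  # deterministic
  sp3 <- split_dataset(rec, c(train = 0.8, validation = 0.1, test = 0.1),
                       seed = 5)
  expect_identical(sp$train$peptide, sp3$train$peptide)
  expect_error(split_dataset(rec, c(0.5, 0.2)), "sum to 1")
})

test_that("aligned FASTA input is validated and uppercased", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">al1", "acdef-hikl", ">al2", "ACDEFGHIKL"), path)
  seqs <- read_aligned_fasta(path)
  expect_identical(unname(seqs["al1"]), "ACDEF-HIKL")
  expect_identical(attr(seqs, "n_columns"), 10L)
  writeLines(c(">al1", "ACDEF", ">al2", "ACDEFGHIKL"), path)
  expect_error(read_aligned_fasta(path), "al2")
})
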
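test_that("word vectors are multiset sums of sub-word vectors", {
  tab <- embedding_table(dim = 4, seed = 3)
  # all-zero table -> zero word vector
  tab0 <- emb_ensure(tab, enumerate_subwords("BCD"))
  tab0$vectors[] <- 0
  expect_equal(word_vector("BCD", tab0), rep(0, 4))
  # repeated substrings count with multiplicity: vec(AAA) = 3a + 2b + c
  tab1 <- emb_ensure(tab, c("A", "AA", "AAA"))
  a <- tab1$vectors["A", ]; b <- tab1$vectors["AA", ]
  cc <- tab1$vectors["AAA", ]
  expect_equal(word_vector("AAA", tab1), 3 * a + 2 * b + cc)
  # BCD: sum of its six sub-word vectors
  tab2 <- emb_ensure(tab, enumerate_subwords("BCD", tokenizer_config(alphabet = LETTERS)))
  expect_equal(word_vector("BCD", tab2, tokenizer_config(alphabet = LETTERS)),
               colSums(tab2$vectors[c("B", "C", "D", "BC", "CD", "BCD"), ]))
})

test_that("word vectors are linear in the table", {
  tab <- emb_ensure(embedding_table(dim = 8, seed = 5), enumerate_subwords("ACD"))
  v1 <- word_vector("ACD", tab)
  tab$vectors <- tab$vectors * 2.5
  expect_equal(word_vector("ACD", tab), 2.5 * v1)
})

test_that("unseen sub-word initialisation is deterministic and in range", {
  tab <- embedding_table(dim = 32, seed = 9)
  r1 <- emb_rows(tab, "QQQ")
  r2 <- emb_rows(tab, "QQQ")
  expect_identical(r1, r2)
  expect_true(all(abs(r1) <= 0.5 / 32))
  # different seeds give different rows
  expect_false(identical(emb_rows(embedding_table(32, seed = 10), "QQQ"), r1))
})

test_that("pair probability is the sigmoid of the dot product", {
  expect_equal(pair_probability(c(1, 0), c(0, 1)), 0.5)
  expect_equal(pair_probability(c(1, 1), c(1, -1)), 0.5)
  expect_gt(pair_probability(rep(10, 4), rep(10, 4)), 0.999999)
  expect_error(pair_probability(1:2, 1:3), "dimension mismatch")
})

test_that("negative sampling avoids true contexts and is reproducible", {
  vocab <- c("AAA", "BBB", "CCC")
  pos <- data.frame(center = "AAA", context = "BBB")
  neg <- sample_negative_pairs(vocab, pos, k = 1, seed = 4)
  expect_identical(neg$context, "CCC")   # forced choice
  vocab10 <- paste0("W", 1:10)
  pos10 <- data.frame(center = rep("W1", 5), context = paste0("W", 2:6))
  n1 <- sample_negative_pairs(vocab10, pos10, k = 3, seed = 8)
  n2 <- sample_negative_pairs(vocab10, pos10, k = 3, seed = 8)
  expect_identical(n1, n2)
  expect_true(all(n1$context %in% paste0("W", 7:10)))
  expect_error(sample_negative_pairs(c("AAA", "BBB"), pos, k = 1),
               "too small")
})

test_that("sampled negatives are uniform over the eligible vocabulary", {
  vocab <- paste0("V", 1:22)
  pos <- data.frame(center = rep("V1", 2000), context = "V2")
  neg <- sample_negative_pairs(vocab, pos, k = 5, seed = 13)  # 10^4 draws
  counts <- table(factor(neg$context, levels = paste0("V", 3:22)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("pre-training with zero epochs leaves vectors unchanged", {
  pairs <- data.frame(center = c("ACD", "DEF"), context = c("DEF", "GHI"))
  words <- unique(c(pairs$center, pairs$context))
  tab <- emb_ensure(embedding_table(dim = 8, seed = 2),
                    unlist(lapply(words, enumerate_subwords)))
  fit <- pretrain(pairs, tab, epochs = 0)
  expect_identical(fit$table$vectors, tab$vectors)
  expect_error(pretrain(data.frame(center = character(0),
                                   context = character(0)),
                        tab), "no context pairs")
})

test_that("initial pre-training loss is near ln 2 (near-zero vectors)", {
  set.seed(31)
  words <- replicate(8, random_peptide(3))
  pairs <- data.frame(center = words[c(1, 3, 5, 7)],
                      context = words[c(2, 4, 6, 8)])
  fit <- pretrain(pairs, embedding_table(dim = 32, seed = 6), epochs = 1,
                  lr = 1e-6, seed = 6)
  expect_equal(fit$loss_trace$train_loss[1L], log(2), tolerance = 1e-3)
})

test_that("skip-gram training separates planted word cliques", {
  set.seed(32)
  w1 <- c("ACD", "AEF", "AGH", "AIK", "ALM", "ANP")
  w2 <- c("QRS", "QTV", "QWY", "RST", "RVW", "RYA")
  cl <- function(w) {
    idx <- t(utils::combn(length(w), 2))
    data.frame(center = w[idx[, 1]], context = w[idx[, 2]])
  }
  pairs <- rbind(cl(w1), cl(w2))
  fit <- pretrain(pairs, embedding_table(seed = 1), epochs = 20, lr = 0.5,
                  seed = 1)
  wv <- vapply(c(w1, w2), word_vector, numeric(32), table = fit$table)
  pp <- function(a, b) pair_probability(wv[, a], wv[, b])
  within <- mean(c(apply(t(utils::combn(w1, 2)), 1,
                         function(r) pp(r[1], r[2])),
                   apply(t(utils::combn(w2, 2)), 1,
                         function(r) pp(r[1], r[2]))))
  between <- mean(outer(w1, w2, Vectorize(pp)))
  expect_gt(within, between)
  # loss decreases on held-out pairs
  expect_lt(utils::tail(fit$loss_trace$holdout_loss, 1),
            fit$loss_trace$holdout_loss[1L])
})

test_that("pre-training is reproducible under a fixed seed", {
  pairs <- data.frame(center = c("ACD", "DEF", "GHI"),
                      context = c("DEF", "GHI", "KLM"))
  f1 <- pretrain(pairs, embedding_table(seed = 3), epochs = 5, seed = 42)
  f2 <- pretrain(pairs, embedding_table(seed = 3), epochs = 5, seed = 42)
  expect_identical(f1$table$vectors, f2$table$vectors)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("embedding tables round-trip through TSV", {
  tab <- emb_ensure(embedding_table(dim = 5, seed = 4), c("A", "AC", "ACD"))
  path <- tempfile(fileext = ".tsv")
  write_embedding_table(tab, path)
  back <- read_embedding_table(path)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-12)
  expect_identical(back$dim, 5L)
})
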
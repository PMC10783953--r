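#' Create a sub-word embedding table
#'
#' Maps sub-word strings to d-dimensional vectors. A word's vector is the
#' sum over its sub-word multiset, so repeated substrings contribute with
#' multiplicity. Sub-words never seen before are initialised from a uniform
#' distribution on `[-0.5/dim, 0.5/dim]`; the draw is a deterministic
#' function of the table seed and the sub-word string, so lookups are
#' well-defined whether or not the row has been materialised.
#'
#' @param dim embedding dimension (default 32).
#' @param seed integer seed governing initialisation of unseen sub-words.
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(dim = 32L, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  structure(list(dim = dim, seed = as.integer(seed),
                 vectors = matrix(numeric(0), 0L, dim)),
            class = "embedding_table")
}

init_vector <- function(table, key) {
  with_seed(derive_seed(table$seed, paste0("init:", key)),
            runif(table$dim, -0.5 / table$dim, 0.5 / table$dim))
}

#' Materialise rows for the given sub-words
#'
#' @param table an [embedding_table()].
#' @param keys character vector of sub-word strings.
#' @return the table, with any missing rows created by the init rule.
#' @export
emb_ensure <- function(table, keys) {
  keys <- unique(keys)
  missing <- setdiff(keys, rownames(table$vectors))
  if (length(missing)) {
    new <- t(vapply(missing, function(k) init_vector(table, k),
                    numeric(table$dim)))
    rownames(new) <- missing
    table$vectors <- rbind(table$vectors, new)
  }
  table
}

#' Look up embedding rows (unseen sub-words use the init rule)
#'
#' @inheritParams emb_ensure
#' @return numeric matrix `length(keys) x dim`.
#' @export
emb_rows <- function(table, keys) {
  table <- emb_ensure(table, keys)
  table$vectors[keys, , drop = FALSE]
}

#' Word vector: sum of sub-word embeddings
#'
#' @param word a word string of `word_size` characters.
#' @param table an [embedding_table()].
#' @param cfg a [tokenizer_config()].
#' @return numeric vector of length `dim`.
#' @export
word_vector <- function(word, table, cfg = tokenizer_config(gap_char = "-")) {
  sw <- enumerate_subwords(word, cfg)
  colSums(emb_rows(table, sw))
}

#' Context probability of a word pair
#'
#' The dot product of the two word vectors passed through a sigmoid.
#'
#' @param u,v numeric vectors of equal length.
#' @return probability in (0, 1).
#' @export
pair_probability <- function(u, v) {
  if (length(u) != length(v))
    stop("embedding dimension mismatch", call. = FALSE)
  clamp_prob(plogis(sum(u * v)))
}

#' Sample negative (non-context) word pairs
#'
#' For each positive (center, context) pair, draws `k` words uniformly from
#' the vocabulary excluding the center itself and all of its true context
#' words.
#'
#' @param vocab character vector of candidate words.
#' @param positives a `context_pairs` data frame.
#' @param k negatives per positive (default 5).
#' @param seed optional seed (restores the caller's RNG stream).
#' @return data frame with columns `center`, `context`, `label` (= 0).
#' @export
sample_negative_pairs <- function(vocab, positives, k = 5L, seed = NULL) {
  stopifnot(k >= 1L, nrow(positives) >= 1L)
  ctx <- context_sets(positives)
  draw <- function() {
    cen <- rep(positives$center, each = k)
    neg <- vapply(cen, function(w) {
      elig <- setdiff(vocab, c(w, ctx[[w]]))
      if (length(elig) == 0L)
        stop("vocabulary too small to sample negatives for word '", w, "'",
             call. = FALSE)
      elig[sample.int(length(elig), 1L)]
    }, character(1L), USE.NAMES = FALSE)
    data.frame(center = cen, context = neg, label = 0L,
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# word -> character vector of its true context words (both directions).
context_sets <- function(pairs) {
  all <- data.frame(c = c(pairs$center, pairs$context),
                    x = c(pairs$context, pairs$center))
  split(all$x, all$c)
}

# Sparse sub-word -> word incidence with multiplicities, over the given
# embedding rows. Word vectors are then crossprod(M, E).
subword_incidence <- function(words, rowkeys, cfg) {
  triples <- lapply(seq_along(words), function(j) {
    sw <- enumerate_subwords(words[j], cfg)
    i <- match(sw, rowkeys)
    cbind(i = i, j = rep(j, length(sw)))
  })
  tr <- do.call(rbind, triples)
  Matrix::sparseMatrix(i = tr[, "i"], j = tr[, "j"], x = 1,
                       dims = c(length(rowkeys), length(words)))
}

#' Skip-gram pre-training of sub-word embeddings
#'
#' Learns sub-word vectors by classifying word pairs as context versus
#' non-context: the pair score is the dot product of the two summed
#' sub-word vectors through a sigmoid, trained with binary cross-entropy
#' against `k` uniformly sampled negatives per positive (resampled every
#' epoch). A single table serves both center and context roles. Both
#' directions of every unordered positive pair are trained.
#'
#' @param x a `context_pairs` data frame, or a list of [tokenize()]d
#'   sequences (sequence-window pairs are then built internally).
#' @param table an [embedding_table()] to start from.
#' @param epochs training epochs (default 30); 0 returns the table
#'   unchanged apart from row materialisation.
#' @param lr SGD learning rate on the mean-batch gradient (default 0.5).
#' @param negatives negatives per positive (default 5).
#' @param batch_size mini-batch size (default 512).
#' @param holdout_fraction fraction of positive pairs held out for the loss
#'   trace (default 0.1).
#' @param seed integer seed.
#' @param cfg tokenizer/context configs where `x` is a token list.
#' @param ctxcfg a [context_config()] used when pairs are built internally.
#' @return an object of class `mhc_pretrain`: list with the trained `table`,
#'   a `loss_trace` data frame (epoch, train_loss, holdout_loss), and the
#'   word vocabulary.
#' @export
pretrain <- function(x, table = embedding_table(), epochs = 30L, lr = 0.5,
                     negatives = 5L, batch_size = 512L,
                     holdout_fraction = 0.1, seed = 1L,
                     cfg = tokenizer_config(gap_char = "-"),
                     ctxcfg = context_config()) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L) stop("empty corpus", call. = FALSE)
    x <- do.call(rbind, lapply(x, sequence_context_pairs, cfg = ctxcfg))
  }
  if (!is.data.frame(x) || nrow(x) == 0L)
    stop("no context pairs to train on", call. = FALSE)

  words <- sort(unique(c(x$center, x$context)))
  subs <- unique(unlist(lapply(words, enumerate_subwords, cfg = cfg)))
  table <- emb_ensure(table, subs)
  if (epochs == 0L)
    return(structure(list(table = table,
                          loss_trace = data.frame(epoch = integer(0),
                                                  train_loss = numeric(0),
                                                  holdout_loss = numeric(0)),
                          words = words),
                     class = "mhc_pretrain"))

  rowkeys <- rownames(table$vectors)
  M <- subword_incidence(words, rowkeys, cfg)
  E <- table$vectors
  ctx <- context_sets(x)
  elig <- lapply(setNames(words, words), function(w)
    match(setdiff(words, c(w, ctx[[w]])), words))
  if (any(vapply(elig, length, 1L) == 0L))
    stop("vocabulary too small for negative sampling", call. = FALSE)

  ci_all <- match(x$center, words)
  xi_all <- match(x$context, words)
  n <- length(ci_all)
  hold <- with_seed(derive_seed(seed, "holdout"), {
    m <- max(1L, min(n - 1L, round(holdout_fraction * n)))
    if (n > 1L) sample.int(n, m) else integer(0)
  })
  tr <- if (length(hold)) setdiff(seq_len(n), hold) else seq_len(n)
  # fixed held-out evaluation set: positives + 1 seeded negative each
  hneg <- with_seed(derive_seed(seed, "holdneg"), vapply(ci_all[hold],
    function(ci) elig[[ci]][sample.int(length(elig[[ci]]), 1L)], 1L))

  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      holdout_loss = numeric(0))
  pair_loss <- function(E, a, b, y) {
    WV <- as.matrix(Matrix::crossprod(M, E))
    p <- clamp_prob(plogis(rowSums(WV[a, , drop = FALSE] *
                                     WV[b, , drop = FALSE])))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }

  set.seed(derive_seed(seed, "train"))
  for (ep in seq_len(epochs)) {
    # both directions + fresh negatives this epoch
    cen <- c(ci_all[tr], xi_all[tr])
    con <- c(xi_all[tr], ci_all[tr])
    negc <- rep(cen, each = negatives)
    negx <- vapply(negc, function(ci)
      elig[[ci]][sample.int(length(elig[[ci]]), 1L)], 1L)
    a <- c(cen, negc); b <- c(con, negx)
    y <- c(rep(1, length(cen)), rep(0, length(negc)))
    ord <- sample.int(length(a))
    a <- a[ord]; b <- b[ord]; y <- y[ord]
    losses <- numeric(0)
    for (start in seq(1L, length(a), by = batch_size)) {
      idx <- start:min(start + batch_size - 1L, length(a))
      WV <- as.matrix(Matrix::crossprod(M, E))
      U <- WV[a[idx], , drop = FALSE]
      V <- WV[b[idx], , drop = FALSE]
      p <- clamp_prob(plogis(rowSums(U * V)))
      g <- (p - y[idx]) / length(idx)
      dW <- matrix(0, length(words), table$dim)
      du <- rowsum(g * V, a[idx])
      dv <- rowsum(g * U, b[idx])
      dW[as.integer(rownames(du)), ] <- dW[as.integer(rownames(du)), ] + du
      dW[as.integer(rownames(dv)), ] <- dW[as.integer(rownames(dv)), ] + dv
      E <- E - lr * as.matrix(M %*% dW)
      losses <- c(losses, -mean(y[idx] * log(p) + (1 - y[idx]) * log(1 - p)))
    }
    hl <- if (length(hold))
      pair_loss(E, c(ci_all[hold], ci_all[hold]), c(xi_all[hold], hneg),
                c(rep(1, length(hold)), rep(0, length(hold))))
    else NA_real_
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(losses),
                                     holdout_loss = hl))
  }
  table$vectors <- E
  structure(list(table = table, loss_trace = trace, words = words),
            class = "mhc_pretrain")
}

#' @export
print.mhc_pretrain <- function(x, ...) {
  cat(sprintf(paste0("Sub-word skip-gram pre-training\n",
                     "  words: %d   sub-words: %d   dim: %d\n"),
              length(x$words), nrow(x$table$vectors), x$table$dim))
  if (nrow(x$loss_trace))
    cat(sprintf("  epochs: %d   final train loss: %.4f   holdout: %.4f\n",
                max(x$loss_trace$epoch),
                x$loss_trace$train_loss[nrow(x$loss_trace)],
                x$loss_trace$holdout_loss[nrow(x$loss_trace)]))
  invisible(x)
}

#' @export
plot.mhc_pretrain <- function(x, ...) {
  tr <- x$loss_trace
  graphics::plot(tr$epoch, tr$train_loss, type = "l", xlab = "epoch",
                 ylab = "binary cross-entropy", ...)
  if (any(!is.na(tr$holdout_loss)))
    graphics::lines(tr$epoch, tr$holdout_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "holdout"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Write an embedding table to TSV
#'
#' @param table an [embedding_table()].
#' @param path output file; first column `subword`, then `d1..dK`.
#' @export
write_embedding_table <- function(table, path) {
  df <- data.frame(subword = rownames(table$vectors), table$vectors)
  names(df) <- c("subword", paste0("d", seq_len(table$dim)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding table written by [write_embedding_table()]
#'
#' @param path TSV file.
#' @param seed seed for the table's init rule.
#' @return an [embedding_table()].
#' @export
read_embedding_table <- function(path, seed = 1L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(df[[1L]], NULL)
  t <- embedding_table(dim = ncol(m), seed = seed)
  t$vectors <- m
  t
}
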
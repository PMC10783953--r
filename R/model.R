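#' Network configuration for the binding predictor
#'
#' The predictor has three parts: a peptide input branch and an allele input
#' branch (each a dense layer over the flattened word-embedding block,
#' followed by dropout), and a trunk of two dense layers with dropout ending
#' in a single sigmoid unit. Word embeddings are sums of trainable sub-word
#' embeddings and receive gradients during training.
#'
#' @param embedding_dim sub-word embedding dimension (default 32).
#' @param peptide_capacity maximum peptide length in residues (default 45,
#'   i.e. 15 words at word size 3); must be divisible by `word_size`.
#' @param branch_width dense width of each input branch (default 250).
#' @param branch_dropout dropout after each branch (default 0.5).
#' @param trunk_widths trunk dense widths (default `c(240, 240)`).
#' @param trunk_dropout dropout after each trunk layer (default 0.4).
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum classical momentum (default 0.9).
#' @param batch_size training batch size (default 256).
#' @param max_epochs maximum training epochs (default 150).
#' @param patience early-stopping patience in epochs on the validation
#'   metric (default 25).
#' @param negative_ratio synthetic negatives per observed record in each
#'   training batch (default 1).
#' @param val_fraction fraction of records held out for validation
#'   (default 0.1, peptide-disjoint).
#' @param word_size tokenizer word size (default 3).
#' @param freeze_embeddings if `TRUE`, sub-word embedding tables receive no
#'   gradient updates (dense layers still train).
#' @return an object of class `net_config`.
#' @export
net_config <- function(embedding_dim = 32L, peptide_capacity = 45L,
                       branch_width = 250L, branch_dropout = 0.5,
                       trunk_widths = c(240L, 240L), trunk_dropout = 0.4,
                       learning_rate = 0.01, momentum = 0.9,
                       batch_size = 256L, max_epochs = 150L, patience = 25L,
                       negative_ratio = 1, val_fraction = 0.1,
                       word_size = 3L, freeze_embeddings = FALSE) {
  stopifnot(peptide_capacity %% word_size == 0L,
            branch_width >= 1L, all(trunk_widths >= 1L),
            branch_dropout >= 0, branch_dropout < 1,
            trunk_dropout >= 0, trunk_dropout < 1,
            learning_rate > 0, length(trunk_widths) == 2L)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 peptide_capacity = as.integer(peptide_capacity),
                 branch_width = as.integer(branch_width),
                 branch_dropout = branch_dropout,
                 trunk_widths = as.integer(trunk_widths),
                 trunk_dropout = trunk_dropout,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 negative_ratio = negative_ratio,
                 val_fraction = val_fraction,
                 word_size = as.integer(word_size),
                 freeze_embeddings = isTRUE(freeze_embeddings)),
            class = "net_config")
}

# All sub-words that can occur in a padded peptide word: plain 1-3-mers over
# the amino-acid alphabet plus the pad-prefixed patterns (^, ^^, ^X, ^^X,
# ^XY, ^^^). Pre-registering the closure fixes the embedding row space so
# per-batch negative peptides never create rows mid-training.
peptide_subword_universe <- function(cfg = tokenizer_config()) {
  aa <- setdiff(cfg$alphabet, cfg$pad_char)
  p <- cfg$pad_char
  pairs <- as.vector(outer(aa, aa, paste0))
  triples <- as.vector(outer(as.vector(outer(aa, aa, paste0)), aa,
                             function(ab, c) paste0(ab, c)))
  c(aa, p, pairs, paste0(p, aa), paste0(p, p),
    triples, paste0(p, pairs), paste0(p, p, aa), paste0(p, p, p))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Initialise an embedding matrix over `keys`: rows found in `table` are
# copied, the rest drawn uniform on [-0.5/dim, 0.5/dim]. Pre-trained rows
# are rescaled as a block so their root-mean-square matches the init rule:
# skip-gram training inflates vector norms, and without the rescale the
# branch inputs start at a very different scale than the dense
# initialisation expects; the rescale keeps the learned similarity
# structure (directions and relative norms) intact.
init_embedding_matrix <- function(keys, table, dim, seed, tag,
                                  rescale = TRUE) {
  E <- with_seed(derive_seed(seed, tag),
                 matrix(runif(length(keys) * dim, -0.5 / dim, 0.5 / dim),
                        length(keys), dim))
  rownames(E) <- keys
  if (!is.null(table)) {
    if (table$dim != dim)
      stop("embedding table dimension mismatch", call. = FALSE)
    hit <- intersect(keys, rownames(table$vectors))
    V <- table$vectors[hit, , drop = FALSE]
    if (rescale && length(hit)) {
      rms <- sqrt(mean(V^2))
      target <- (1 / dim) / sqrt(12)   # RMS of U(-0.5/dim, 0.5/dim)
      if (rms > 0) V <- V * (target / rms)
    }
    E[hit, ] <- V
  }
  E
}

#' Build an (untrained) peptide-MHC binding model
#'
#' Assembles the network over a fixed allele panel given by aligned protein
#' sequences. Embedding matrices are initialised from pre-trained tables
#' where sub-words are available and from the uniform init rule otherwise;
#' dense weights use Glorot-uniform initialisation.
#'
#' @param allele_seqs named character vector of aligned allele sequences
#'   (equal lengths), e.g. from [read_aligned_fasta()].
#' @param peptide_table optional pre-trained [embedding_table()] for the
#'   peptide branch.
#' @param allele_table optional pre-trained [embedding_table()] for the
#'   allele branch.
#' @param config a [net_config()].
#' @param seed integer seed for initialisation.
#' @return an object of class `mhc_model` (untrained; [predict.mhc_model()]
#'   works and returns ~0.5 probabilities).
#' @export
mhc_build <- function(allele_seqs, peptide_table = NULL, allele_table = NULL,
                      config = net_config(), seed = 1L) {
  if (is.null(names(allele_seqs)) || any(!nzchar(names(allele_seqs))))
    stop("allele_seqs must be named", call. = FALSE)
  if (length(unique(nchar(allele_seqs))) != 1L)
    stop("aligned allele sequences must share one length", call. = FALSE)
  d <- config$embedding_dim
  tokcfg_pep <- tokenizer_config(word_size = config$word_size)
  tokcfg_all <- tokenizer_config(word_size = config$word_size,
                                 gap_char = "-")
  n_slots <- config$peptide_capacity %/% config$word_size

  pep_keys <- peptide_subword_universe(tokcfg_pep)
  E_pep <- init_embedding_matrix(pep_keys, peptide_table, d, seed, "pep-init")

  allele_tokens <- lapply(allele_seqs, tokenize, cfg = tokcfg_all)
  A <- length(allele_tokens[[1L]]$words)
  all_keys <- sort(unique(unlist(lapply(
    unique(unlist(lapply(allele_tokens, `[[`, "words"))),
    enumerate_subwords, cfg = tokcfg_all))))
  E_all <- init_embedding_matrix(all_keys, allele_table, d, seed, "all-init")
  Mk <- lapply(allele_tokens, function(tok)
    subword_incidence(tok$words, all_keys, tokcfg_all))

  nsub <- config$word_size * (config$word_size + 1L) %/% 2L
  par <- with_seed(derive_seed(seed, "dense"), list(
    W1p = glorot(n_slots * d, config$branch_width), b1p = numeric(config$branch_width),
    W1a = glorot(A * d, config$branch_width), b1a = numeric(config$branch_width),
    W2 = glorot(2L * config$branch_width, config$trunk_widths[1L]),
    b2 = numeric(config$trunk_widths[1L]),
    W3 = glorot(config$trunk_widths[1L], config$trunk_widths[2L]),
    b3 = numeric(config$trunk_widths[2L]),
    w4 = glorot(config$trunk_widths[2L], 1L), b4 = 0))

  structure(list(config = config, seed = seed,
                 tokcfg_pep = tokcfg_pep, tokcfg_all = tokcfg_all,
                 n_slots = n_slots, n_subwords_per_word = nsub,
                 alleles = names(allele_seqs), allele_seqs = allele_seqs,
                 A = A, Mk = Mk,
                 E_pep = E_pep, E_all = E_all, par = par,
                 task = "binding", trained = FALSE, log = NULL),
            class = "mhc_model")
}

# words (with left pad-word fill to n_slots) -> sub-word row indices into
# E_pep; returns an n x (n_slots * nsub) integer matrix. Unique words are
# memoised in the model's cache environment.
encode_peptides <- function(model, peptides) {
  cfg <- model$tokcfg_pep
  w <- cfg$word_size
  nsub <- model$n_subwords_per_word
  P <- model$n_slots
  peptides <- toupper(as.character(peptides))
  n <- length(peptides)
  len <- nchar(peptides)
  if (any(len == 0L)) stop("empty input", call. = FALSE)
  toolong <- len > model$config$peptide_capacity
  if (any(toolong))
    stop(sprintf("peptide '%s' exceeds the %d-residue capacity",
                 peptides[which(toolong)[1L]],
                 model$config$peptide_capacity), call. = FALSE)
  ok <- grepl(sprintf("^[%s]+$", paste(cfg$alphabet, collapse = "")),
              peptides)
  if (any(!ok))   # per-character diagnostic
    check_alphabet(strsplit(peptides[which(!ok)[1L]], "", fixed = TRUE)[[1L]],
                   cfg)
  # left-pad every peptide to the full capacity with pad characters; the
  # leading whole-pad words are the pad-word slots
  full <- paste0(strrep(cfg$pad_char, P * w - len), peptides)
  starts <- seq(1L, P * w, by = w)
  W <- vapply(starts, function(s) substring(full, s, s + w - 1L),
              character(n))
  if (n == 1L) W <- matrix(W, 1L)
  uw <- unique(as.vector(W))
  # sub-word ids for all unique words at once: one vectorised
  # substring + match per (start, stop) sub-word position
  U <- matrix(0L, length(uw), nsub)
  k <- 0L
  for (len in seq_len(w)) {
    for (st in seq_len(w - len + 1L)) {
      k <- k + 1L
      U[, k] <- match(substring(uw, st, st + len - 1L),
                      rownames(model$E_pep))
    }
  }
  wi <- match(W, uw)
  IDX <- matrix(0L, n, P * nsub)
  for (s in seq_len(P))
    IDX[, (s - 1L) * nsub + seq_len(nsub)] <-
      U[wi[(s - 1L) * n + seq_len(n)], , drop = FALSE]
  IDX
}

# Flattened word-block input matrices. Xp: n x (n_slots * d); Xa: the
# per-allele block matrix rows selected per record.
embed_peptide_input <- function(model, IDX) {
  d <- model$config$embedding_dim
  nsub <- model$n_subwords_per_word
  n <- nrow(IDX)
  Xp <- matrix(0, n, model$n_slots * d)
  for (s in seq_len(model$n_slots)) {
    acc <- model$E_pep[IDX[, (s - 1L) * nsub + 1L], , drop = FALSE]
    for (k in 2:nsub)
      acc <- acc + model$E_pep[IDX[, (s - 1L) * nsub + k], , drop = FALSE]
    Xp[, (s - 1L) * d + seq_len(d)] <- acc
  }
  Xp
}

allele_blocks <- function(model) {
  t(vapply(model$Mk, function(M)
    as.vector(t(as.matrix(Matrix::crossprod(M, model$E_all)))),
    numeric(model$A * model$config$embedding_dim)))
}

# Forward pass. The allele branch is factorised: with a small panel the
# per-allele dense activations are computed once (K x width) and indexed
# per record, which avoids repeating identical matrix rows.
net_forward <- function(par, Xp, B, aid, cfg, dropout = FALSE) {
  scale1 <- 1 - cfg$branch_dropout
  scale2 <- 1 - cfg$trunk_dropout
  n <- nrow(Xp)
  mask <- function(nc, p) matrix(runif(n * nc) >= p, n, nc)
  A1p <- sweep(Xp %*% par$W1p, 2L, par$b1p, "+"); H1p <- relu(A1p)
  A1aK <- sweep(B %*% par$W1a, 2L, par$b1a, "+")
  H1aK <- relu(A1aK)
  H1a <- H1aK[aid, , drop = FALSE]
  M1p <- M1a <- M2 <- M3 <- NULL
  if (dropout && cfg$branch_dropout > 0) {
    M1p <- mask(ncol(H1p), cfg$branch_dropout); H1p <- H1p * M1p / scale1
    M1a <- mask(ncol(H1a), cfg$branch_dropout); H1a <- H1a * M1a / scale1
  }
  C <- cbind(H1p, H1a)
  A2 <- sweep(C %*% par$W2, 2L, par$b2, "+"); H2 <- relu(A2)
  if (dropout && cfg$trunk_dropout > 0) {
    M2 <- mask(ncol(H2), cfg$trunk_dropout); H2 <- H2 * M2 / scale2
  }
  A3 <- sweep(H2 %*% par$W3, 2L, par$b3, "+"); H3 <- relu(A3)
  if (dropout && cfg$trunk_dropout > 0) {
    M3 <- mask(ncol(H3), cfg$trunk_dropout); H3 <- H3 * M3 / scale2
  }
  z <- as.vector(H3 %*% par$w4 + par$b4)
  list(p = clamp_prob(plogis(z)), z = z, Xp = Xp, B = B, aid = aid,
       A1p = A1p, A1aK = A1aK, H1p = H1p, H1a = H1a, C = C,
       A2 = A2, H2 = H2, A3 = A3, H3 = H3,
       M1p = M1p, M1a = M1a, M2 = M2, M3 = M3)
}

net_backward <- function(par, fw, y, cfg, loss = c("bce", "mse")) {
  loss <- match.arg(loss)
  n <- length(y)
  p <- fw$p
  dz <- if (loss == "bce") (p - y) / n else 2 * (p - y) * p * (1 - p) / n
  scale1 <- 1 - cfg$branch_dropout
  scale2 <- 1 - cfg$trunk_dropout
  dz <- matrix(dz, n, 1L)
  g <- list()
  g$w4 <- crossprod(fw$H3, dz); g$b4 <- sum(dz)
  dH3 <- dz %*% t(par$w4)
  if (!is.null(fw$M3)) dH3 <- dH3 * fw$M3 / scale2
  dA3 <- dH3 * (fw$A3 > 0)
  g$W3 <- crossprod(fw$H2, dA3); g$b3 <- colSums(dA3)
  dH2 <- dA3 %*% t(par$W3)
  if (!is.null(fw$M2)) dH2 <- dH2 * fw$M2 / scale2
  dA2 <- dH2 * (fw$A2 > 0)
  g$W2 <- crossprod(fw$C, dA2); g$b2 <- colSums(dA2)
  dC <- dA2 %*% t(par$W2)
  bw <- cfg$branch_width
  dH1p <- dC[, seq_len(bw), drop = FALSE]
  dH1a <- dC[, bw + seq_len(bw), drop = FALSE]
  if (!is.null(fw$M1p)) dH1p <- dH1p * fw$M1p / scale1
  if (!is.null(fw$M1a)) dH1a <- dH1a * fw$M1a / scale1
  dA1p <- dH1p * (fw$A1p > 0)
  dA1a <- dH1a * (fw$A1aK > 0)[fw$aid, , drop = FALSE]
  g$W1p <- crossprod(fw$Xp, dA1p); g$b1p <- colSums(dA1p)
  # aggregate the allele branch gradient per allele before the (large)
  # weight products: records of the same allele share the branch input
  DA_K <- matrix(0, nrow(fw$B), ncol(dA1a))
  r <- rowsum(dA1a, fw$aid)
  DA_K[as.integer(rownames(r)), ] <- r
  g$W1a <- crossprod(fw$B, DA_K); g$b1a <- colSums(dA1a)
  g$dXp <- dA1p %*% t(par$W1p)
  g$GA <- DA_K %*% t(par$W1a)   # per-allele input gradient (K x A*d)
  g
}

# Scatter dXp back onto peptide sub-word rows (sparse: only touched rows)
# and dXa (aggregated per allele) onto allele sub-word rows.
embedding_grads <- function(model, IDX, g) {
  d <- model$config$embedding_dim
  nsub <- model$n_subwords_per_word
  rows <- sort(unique(as.vector(IDX)))
  GEp <- matrix(0, length(rows), d)
  for (s in seq_len(model$n_slots)) {
    ds <- g$dXp[, (s - 1L) * d + seq_len(d), drop = FALSE]
    for (k in seq_len(nsub)) {
      id <- IDX[, (s - 1L) * nsub + k]
      r <- rowsum(ds, id)
      ridx <- match(as.integer(rownames(r)), rows)
      GEp[ridx, ] <- GEp[ridx, ] + r
    }
  }
  GEa <- matrix(0, nrow(model$E_all), d)
  for (k in which(rowSums(abs(g$GA)) > 0)) {
    GEa <- GEa + as.matrix(model$Mk[[k]] %*%
                             t(matrix(g$GA[k, ], d, model$A)))
  }
  list(pep_rows = rows, E_pep = GEp, E_all = GEa)
}

#' Train the binding model
#'
#' Each training batch pairs observed records with freshly regenerated
#' synthetic negative records (random peptides with lengths drawn from the
#' positives' length distribution, residues uniform, allele uniform over
#' the panel); negatives are resampled every batch. Training uses SGD with
#' momentum on the mean binary cross-entropy, dropout in the dense layers,
#' and early stopping on validation AUC over a peptide-disjoint validation
#' split.
#'
#' @param model an [mhc_build()] model.
#' @param data data frame with `peptide`, `allele`, `label`; label-1 rows
#'   are observed positives; label-0 rows (if any) are used as observed
#'   negatives alongside the synthetic ones.
#' @param sampler optional function `(n)` returning a data frame of
#'   negative records; defaults to [sample_negative_batch()] driven by the
#'   positives' length distribution and the model's allele panel.
#' @param seed integer seed (shuffles, dropout, negatives, split).
#' @param quiet suppress per-epoch messages (default TRUE).
#' @return the trained `mhc_model`, with a `log` data frame (epoch,
#'   train_loss, val_auc) and `best_epoch`.
#' @export
mhc_train <- function(model, data, sampler = NULL, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(model, "mhc_model"))
  cfg <- model$config
  if (nrow(data) == 0L || !any(data$label == 1L))
    stop("training data must contain positive records", call. = FALSE)
  unknown <- setdiff(unique(data$allele), model$alleles)
  if (length(unknown))
    stop("unknown allele(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  sp <- split_dataset(data, c(train = 1 - cfg$val_fraction,
                              validation = cfg$val_fraction),
                      seed = derive_seed(seed, "valsplit"))
  train <- sp$train
  val <- sp$validation
  ldist <- peptide_length_distribution(train[train$label == 1L, ])
  if (is.null(sampler))
    sampler <- function(n) sample_negative_batch(ldist, model$alleles, n)
  # fixed validation negatives so the early-stopping metric is stable
  if (!any(val$label == 0L)) {
    vneg <- with_seed(derive_seed(seed, "valneg"),
                      sampler(max(1L, sum(val$label == 1L))))
    val <- rbind(val[, c("peptide", "allele", "label")],
                 vneg[, c("peptide", "allele", "label")])
  }
  val_idx <- encode_peptides(model, val$peptide)
  val_aid <- match(val$allele, model$alleles)

  IDX_all <- encode_peptides(model, train$peptide)
  aid_all <- match(train$allele, model$alleles)
  y_all <- train$label

  vel <- lapply(model$par, function(p) p * 0)
  best <- list(score = -Inf, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_auc = numeric(0))
  set.seed(derive_seed(seed, "train"))
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(train))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      neg <- sampler(max(1L, round(cfg$negative_ratio * length(rows))))
      IDXn <- encode_peptides(model, neg$peptide)
      IDX <- rbind(IDX_all[rows, , drop = FALSE], IDXn)
      aid <- c(aid_all[rows], match(neg$allele, model$alleles))
      y <- c(y_all[rows], rep(0L, nrow(neg)))
      B <- allele_blocks(model)
      Xp <- embed_peptide_input(model, IDX)
      fw <- net_forward(model$par, Xp, B, aid, cfg, dropout = TRUE)
      g <- net_backward(model$par, fw, y, cfg, loss = "bce")
      eg <- embedding_grads(model, IDX, g)
      for (nm in names(model$par)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[nm]]
        model$par[[nm]] <- model$par[[nm]] + vel[[nm]]
      }
      if (!cfg$freeze_embeddings) {
        # embedding tables take plain (momentum-free) SGD steps on the
        # rows the batch touched
        model$E_pep[eg$pep_rows, ] <- model$E_pep[eg$pep_rows, ] -
          cfg$learning_rate * eg$E_pep
        model$E_all <- model$E_all - cfg$learning_rate * eg$E_all
      }
      losses <- c(losses, bce_loss(fw$p, y))
    }
    vp <- predict_encoded(model, val_idx, val_aid)
    vauc <- if (length(unique(val$label)) == 2L)
      roc_auc(vp, val$label) else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 val_auc = vauc))
    if (!quiet)
      message(sprintf("epoch %3d  loss %.4f  val AUC %.4f", ep,
                      mean(losses), vauc))
    if (!is.na(vauc) && vauc > best$score + 1e-6) {
      best <- list(score = vauc, epoch = ep, par = model$par,
                   E_pep = model$E_pep, E_all = model$E_all)
    } else if (ep - best$epoch >= cfg$patience && best$epoch > 0L) {
      break
    }
  }
  if (!is.null(best$par)) {
    model$par <- best$par
    model$E_pep <- best$E_pep
    model$E_all <- best$E_all
  }
  model$trained <- TRUE
  model$log <- log
  model$best_epoch <- best$epoch
  model$val_auc <- if (is.finite(best$score)) best$score else NA_real_
  model$n_train <- nrow(train)
  model
}

predict_encoded <- function(model, IDX, allele_id) {
  B <- allele_blocks(model)
  Xp <- embed_peptide_input(model, IDX)
  fw <- net_forward(model$par, Xp, B, allele_id, model$config,
                    dropout = FALSE)
  fw$p
}

#' Fit a peptide-MHC binding model
#'
#' Convenience wrapper composing [mhc_build()] and [mhc_train()].
#'
#' @inheritParams mhc_build
#' @inheritParams mhc_train
#' @return a trained `mhc_model`.
#' @export
mhc_fit <- function(data, allele_seqs, peptide_table = NULL,
                    allele_table = NULL, config = net_config(),
                    sampler = NULL, seed = 1L, quiet = TRUE) {
  model <- mhc_build(allele_seqs, peptide_table, allele_table, config,
                     seed = seed)
  mhc_train(model, data, sampler = sampler, seed = seed, quiet = quiet)
}

#' Predict binding probabilities
#'
#' Deterministic (dropout disabled); output strictly in (0, 1); batch
#' predictions preserve input order.
#'
#' @param object an `mhc_model`.
#' @param newdata data frame with `peptide` and `allele` columns; or use
#'   the `peptide`/`allele` arguments.
#' @param peptide,allele alternative vector interface.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.mhc_model <- function(object, newdata = NULL, peptide = NULL,
                              allele = NULL, ...) {
  if (is.null(newdata)) {
    stopifnot(!is.null(peptide), !is.null(allele))
    newdata <- data.frame(peptide = peptide, allele = allele,
                          stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(newdata$allele), object$alleles)
  if (length(unknown))
    stop("unknown allele(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(object$alleles, collapse = ", "),
         call. = FALSE)
  IDX <- encode_peptides(object, newdata$peptide)
  predict_encoded(object, IDX, match(newdata$allele, object$alleles))
}

#' Fine-tune on transformed binding affinity
#'
#' Re-uses the binding architecture (sigmoid output as the regression head)
#' with mean-squared-error loss against targets in `[0, 1]` (the
#' `1 - log50000(IC50)` transform). Initialisation is either a trained
#' binding model (transfer learning) or a fresh build (from scratch). No
#' negative sampling; early stopping on validation MSE.
#'
#' @param model a (typically trained) `mhc_model`, or an untrained build
#'   for the from-scratch configuration.
#' @param records data frame with `peptide`, `allele`, `target` in `[0, 1]`
#'   (e.g. from [transform_affinity()]).
#' @param seed integer seed.
#' @param quiet suppress progress.
#' @return an `mhc_model` with `task = "affinity"` and a log of
#'   (epoch, train_mse, val_mse).
#' @export
finetune_affinity <- function(model, records, seed = 1L, quiet = TRUE) {
  stopifnot(inherits(model, "mhc_model"))
  if (!"target" %in% names(records))
    stop("records must carry a 'target' column in [0, 1]; ",
         "raw IC50 must be transformed first (see transform_affinity)",
         call. = FALSE)
  if (any(records$target < 0 | records$target > 1))
    stop("targets must lie in [0, 1]; raw IC50 values are not accepted",
         call. = FALSE)
  cfg <- model$config
  unknown <- setdiff(unique(records$allele), model$alleles)
  if (length(unknown))
    stop("unknown allele(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sp <- split_dataset(records, c(train = 1 - cfg$val_fraction,
                                 validation = cfg$val_fraction),
                      seed = derive_seed(seed, "valsplit"))
  train <- sp$train; val <- sp$validation
  IDX_all <- encode_peptides(model, train$peptide)
  aid_all <- match(train$allele, model$alleles)
  val_idx <- encode_peptides(model, val$peptide)
  val_aid <- match(val$allele, model$alleles)

  vel <- lapply(model$par, function(p) p * 0)
  best <- list(score = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_mse = numeric(0),
                    val_mse = numeric(0))
  set.seed(derive_seed(seed, "finetune"))
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(train))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      rows <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      IDX <- IDX_all[rows, , drop = FALSE]
      aid <- aid_all[rows]
      y <- train$target[rows]
      B <- allele_blocks(model)
      fw <- net_forward(model$par, embed_peptide_input(model, IDX),
                        B, aid, cfg, dropout = TRUE)
      g <- net_backward(model$par, fw, y, cfg, loss = "mse")
      eg <- embedding_grads(model, IDX, g)
      for (nm in names(model$par)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[nm]]
        model$par[[nm]] <- model$par[[nm]] + vel[[nm]]
      }
      if (!cfg$freeze_embeddings) {
        # embedding tables take plain (momentum-free) SGD steps on the
        # rows the batch touched
        model$E_pep[eg$pep_rows, ] <- model$E_pep[eg$pep_rows, ] -
          cfg$learning_rate * eg$E_pep
        model$E_all <- model$E_all - cfg$learning_rate * eg$E_all
      }
      losses <- c(losses, mean((fw$p - y)^2))
    }
    vp <- predict_encoded(model, val_idx, val_aid)
    vmse <- mean((vp - val$target)^2)
    log <- rbind(log, data.frame(epoch = ep, train_mse = mean(losses),
                                 val_mse = vmse))
    if (!quiet)
      message(sprintf("epoch %3d  mse %.5f  val mse %.5f", ep,
                      mean(losses), vmse))
    if (vmse < best$score - 1e-8) {
      best <- list(score = vmse, epoch = ep, par = model$par,
                   E_pep = model$E_pep, E_all = model$E_all)
    } else if (ep - best$epoch >= cfg$patience && best$epoch > 0L) {
      break
    }
  }
  if (!is.null(best$par)) {
    model$par <- best$par
    model$E_pep <- best$E_pep
    model$E_all <- best$E_all
  }
  model$task <- "affinity"
  model$trained <- TRUE
  model$log <- log
  model$best_epoch <- best$epoch
  model$val_mse <- best$score
  model
}

#' Export per-allele embedding blocks
#'
#' The flattened word-embedding block that the allele branch consumes, for
#' every allele in the model's aligned panel (alleles without any ligand
#' training data included: the aligned sequence suffices).
#'
#' @param model an `mhc_model`.
#' @param alleles subset of allele names (default: all).
#' @return numeric matrix, one row per allele.
#' @export
export_allele_embeddings <- function(model, alleles = NULL) {
  B <- allele_blocks(model)
  rownames(B) <- model$alleles
  if (!is.null(alleles)) {
    unknown <- setdiff(alleles, model$alleles)
    if (length(unknown))
      stop("unknown allele(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    B <- B[alleles, , drop = FALSE]
  }
  B
}

#' @export
print.mhc_model <- function(x, ...) {
  cat(sprintf(paste0("Peptide-MHC binding model (%s%s)\n",
                     "  allele panel: %d allele(s), %d aligned words\n",
                     "  peptide capacity: %d residues (%d words), ",
                     "embedding dim %d\n"),
              x$task, if (x$trained) ", trained" else ", untrained",
              length(x$alleles), x$A,
              x$config$peptide_capacity, x$n_slots,
              x$config$embedding_dim))
  if (x$trained && !is.null(x$log)) {
    if (x$task == "binding")
      cat(sprintf("  best validation AUC %.4f at epoch %d (of %d run)\n",
                  x$val_auc, x$best_epoch, nrow(x$log)))
    else
      cat(sprintf("  best validation MSE %.5f at epoch %d (of %d run)\n",
                  x$val_mse, x$best_epoch, nrow(x$log)))
  }
  invisible(x)
}

#' @export
summary.mhc_model <- function(object, ...) {
  n_par <- sum(vapply(object$par, length, 1L)) +
    length(object$E_pep) + length(object$E_all)
  out <- list(task = object$task, trained = object$trained,
              alleles = object$alleles, n_parameters = n_par,
              config = object$config, log = object$log,
              best_epoch = object$best_epoch,
              val_auc = object$val_auc, val_mse = object$val_mse)
  class(out) <- "summary.mhc_model"
  out
}

#' @export
print.summary.mhc_model <- function(x, ...) {
  cat(sprintf("Peptide-MHC binding model summary (task: %s)\n", x$task))
  cat(sprintf("  parameters: %d (dense + sub-word embeddings)\n",
              x$n_parameters))
  cat(sprintf("  alleles (%d): %s\n", length(x$alleles),
              paste(head(x$alleles, 8L), collapse = ", ")))
  if (x$trained) {
    if (!is.null(x$val_auc) && !is.na(x$val_auc %||% NA))
      cat(sprintf("  best validation AUC: %.4f (epoch %d)\n",
                  x$val_auc, x$best_epoch))
    if (!is.null(x$val_mse))
      cat(sprintf("  best validation MSE: %.5f (epoch %d)\n",
                  x$val_mse, x$best_epoch))
  }
  invisible(x)
}

#' @export
coef.mhc_model <- function(object, ...) {
  c(object$par, list(E_pep = object$E_pep, E_all = object$E_all))
}

#' @export
plot.mhc_model <- function(x, ...) {
  if (is.null(x$log) || nrow(x$log) == 0L)
    stop("model has no training log", call. = FALSE)
  lg <- x$log
  metric <- if (x$task == "binding") "val_auc" else "val_mse"
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(lg$epoch, lg[[2L]], type = "l", xlab = "epoch",
                 ylab = names(lg)[2L], ...)
  graphics::plot(lg$epoch, lg[[metric]], type = "l", xlab = "epoch",
                 ylab = metric, ...)
  invisible(x)
}
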
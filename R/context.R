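#' Context-pairing configuration
#'
#' Two notions of word context are used for skip-gram pre-training: words
#' within `seq_window` words of each other on a peptide sequence, and words
#' of an HLA allele whose residues lie within `struct_threshold` angstroms of
#' each other on the protein 3D structure. Only residues between
#' `residue_lo` and `residue_hi` (structure-model numbering) are considered,
#' since structural models typically lack parts of the termini.
#'
#' @param seq_window sequence context half-width in words (default 3).
#' @param struct_threshold structural contact threshold in angstroms
#'   (default 45; the tuning grid in the field runs 5-65 in steps of 5).
#' @param residue_lo,residue_hi 1-based inclusive bounds of the usable
#'   structural residue window (defaults 24 and 301).
#' @param word_dist how to reduce residue-residue distances to a word-word
#'   distance: `"min"` (default, most permissive contact definition) or
#'   `"mean"`.
#' @return an object of class `context_config`.
#' @export
context_config <- function(seq_window = 3L, struct_threshold = 45,
                           residue_lo = 24L, residue_hi = 301L,
                           word_dist = c("min", "mean")) {
  seq_window <- as.integer(seq_window)
  stopifnot(seq_window >= 1L, struct_threshold > 0,
            residue_lo < residue_hi)
  structure(list(seq_window = seq_window,
                 struct_threshold = struct_threshold,
                 residue_lo = as.integer(residue_lo),
                 residue_hi = as.integer(residue_hi),
                 word_dist = match.arg(word_dist)),
            class = "context_config")
}

new_context_pairs <- function(center, context, provenance) {
  stopifnot(length(center) == length(context))
  structure(data.frame(center = center, context = context,
                       stringsAsFactors = FALSE),
            provenance = provenance, class = c("context_pairs", "data.frame"))
}

#' Sequence-window context pairs
#'
#' For word index i the context words are those at indices j with
#' `1 <= |i - j| <= seq_window`. Each unordered pair is emitted once
#' (training later uses both directions).
#'
#' @param x a [tokenize()]d sequence or a character vector of words.
#' @param cfg a [context_config()].
#' @return a `context_pairs` data frame with columns `center`, `context`.
#' @export
sequence_context_pairs <- function(x, cfg = context_config()) {
  words <- if (inherits(x, "pmhc_tokens")) x$words else as.character(x)
  n <- length(words)
  if (n < 1L) stop("at least one word required", call. = FALSE)
  if (n == 1L) return(new_context_pairs(character(0), character(0), "sequence"))
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j > i & (j - i) <= cfg$seq_window),
               arr.ind = TRUE)
  new_context_pairs(words[idx[, 1L]], words[idx[, 2L]], "sequence")
}

#' Pairwise C-alpha distance matrix from residue coordinates
#'
#' @param coords numeric matrix (n x 3) of C-alpha coordinates in angstroms.
#' @param resno integer residue numbers for the rows (default `1:n`).
#' @param cfg a [context_config()]; residues outside
#'   `[residue_lo, residue_hi]` are excluded.
#' @return a symmetric `distance_matrix` with dimnames set to the retained
#'   residue numbers (attribute `positions`).
#' @export
calpha_distance_matrix <- function(coords, resno = seq_len(nrow(coords)),
                                   cfg = context_config()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(resno) == nrow(coords))
  keep <- resno >= cfg$residue_lo & resno <= cfg$residue_hi &
    stats::complete.cases(coords)
  coords <- coords[keep, , drop = FALSE]
  resno <- resno[keep]
  if (nrow(coords) < 2L)
    stop("fewer than 2 usable residues in the structural window",
         call. = FALSE)
  dm <- as.matrix(stats::dist(coords))
  dimnames(dm) <- list(resno, resno)
  structure(dm, positions = as.integer(resno),
            class = c("distance_matrix", class(dm)))
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts CA ATOM records (optionally from one chain) via bio3d.
#'
#' @param path PDB file.
#' @param chain optional chain identifier.
#' @return list with `coords` (n x 3 matrix) and `resno` (residue numbers).
#' @export
read_pdb_calpha <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  sel <- bio3d::atom.select(pdb, elety = "CA",
                            chain = if (is.null(chain)) NULL else chain)
  at <- pdb$atom[sel$atom, , drop = FALSE]
  list(coords = as.matrix(at[, c("x", "y", "z")]),
       resno = as.integer(at$resno))
}

#' Average distance matrices across alleles
#'
#' Entry-wise mean over the matrices in which the entry is present
#' (NA-aware); entries present in no matrix stay NA. Rows/columns are
#' aligned by residue number, so matrices covering different residue subsets
#' can be combined.
#'
#' @param matrices list of `distance_matrix` objects.
#' @return a single averaged `distance_matrix` over the union of residues.
#' @export
mean_distance_matrix <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("need at least one distance matrix", call. = FALSE)
  pos <- sort(unique(unlist(lapply(matrices, function(m)
    as.integer(rownames(m))))))
  key <- as.character(pos)
  n <- length(pos)
  acc <- matrix(0, n, n, dimnames = list(key, key))
  cnt <- matrix(0L, n, n)
  for (m in matrices) {
    i <- match(rownames(m), key)
    ok <- !is.na(m)
    sub <- m
    sub[!ok] <- 0
    acc[i, i] <- acc[i, i] + sub
    cnt[i, i] <- cnt[i, i] + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  structure(out, positions = pos,
            class = c("distance_matrix", "matrix", "array"))
}

# Map each word of a tokenized (aligned) allele sequence to the residue
# numbers it covers. Word i spans padded positions (i-1)*w+1 .. i*w; after
# removing the pad offset these are alignment columns, and gap columns
# consume no residue number, so the column -> residue map is the cumulative
# count of non-gap characters.
word_residue_map <- function(tokens, cfg, tokcfg = tokenizer_config(gap_char = "-")) {
  w <- tokcfg$word_size
  chars <- strsplit(tokens$source, "", fixed = TRUE)[[1L]]
  is_res <- chars != (tokcfg$gap_char %||% "-")
  resno <- ifelse(is_res, cumsum(is_res), NA_integer_)
  lapply(seq_along(tokens$words), function(i) {
    padded <- ((i - 1L) * w + 1L):(i * w)
    cols <- padded - tokens$pad_count
    cols <- cols[cols >= 1L & cols <= length(chars)]
    r <- resno[cols]
    r <- r[!is.na(r)]
    r[r >= cfg$residue_lo & r <= cfg$residue_hi]
  })
}

#' Structural context pairs from a distance matrix
#'
#' Two distinct words of an allele sequence form a context pair when the
#' distance between their residues on the 3D structure is at most
#' `struct_threshold` angstroms; the word-word distance is the minimum (or
#' mean, per config) over present C-alpha pairs. Words with no residues in
#' the usable window produce no pairs.
#'
#' @param tokens a [tokenize()]d aligned allele sequence.
#' @param dm a `distance_matrix` (typically the allele-averaged matrix).
#' @param cfg a [context_config()].
#' @param tokcfg tokenizer config used to produce `tokens`.
#' @return a `context_pairs` data frame with integer attribute columns
#'   `i`, `j` (word indices) alongside `center`/`context` word strings.
#' @export
structural_context_pairs <- function(tokens, dm, cfg = context_config(),
                                     tokcfg = tokenizer_config(gap_char = "-")) {
  stopifnot(inherits(tokens, "pmhc_tokens"))
  wr <- word_residue_map(tokens, cfg, tokcfg)
  pos <- rownames(dm)
  ridx <- lapply(wr, function(r) match(as.character(r), pos))
  ridx <- lapply(ridx, function(i) i[!is.na(i)])
  usable <- which(vapply(ridx, length, 1L) > 0L)
  if (length(usable) == 0L)
    stop("no words cover usable structural residues", call. = FALSE)
  ii <- integer(0); jj <- integer(0)
  reduce <- if (cfg$word_dist == "min") min else mean
  for (a in seq_along(usable)) {
    for (b in seq_len(a - 1L)) {
      u <- usable[a]; v <- usable[b]
      d <- dm[ridx[[u]], ridx[[v]], drop = FALSE]
      d <- d[!is.na(d)]
      if (length(d) && reduce(d) <= cfg$struct_threshold) {
        ii <- c(ii, v); jj <- c(jj, u)
      }
    }
  }
  out <- new_context_pairs(tokens$words[ii], tokens$words[jj], "structure")
  out$i <- ii
  out$j <- jj
  out
}
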
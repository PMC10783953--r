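#' Normalize HLA allele names
#'
#' Accepts common spellings (`A0201`, `A*02:01`, `HLA-A02:01`, lowercase)
#' and returns the two-field form `HLA-A*02:01`. Names that cannot be
#' resolved to a specific two-field allele (e.g. "HLA class I") yield `NA`.
#'
#' @param x character vector of allele names.
#' @return character vector of normalized names, `NA` where non-specific.
#' @export
normalize_allele <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^HLA-", "", x)
  m <- regmatches(x, regexec("^([A-Z]+[0-9]*)\\*?([0-9]{2,3}):?([0-9]{2,3})$", x))
  vapply(m, function(g) {
    if (length(g) == 4L) sprintf("HLA-%s*%s:%s", g[2L], g[3L], g[4L])
    else NA_character_
  }, character(1L))
}

#' Read a peptide-HLA pair table
#'
#' TSV or CSV (by extension) with columns `peptide`, `allele`, and `label`
#' or `ic50`. Allele names are normalized; rows with peptides containing
#' non-standard residues, or with non-specific alleles, are dropped with a
#' report; exact duplicate rows are collapsed.
#'
#' @param path file path.
#' @return data frame of records; attribute `report` lists dropped row
#'   numbers and reasons.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path, stringsAsFactors = FALSE)
  else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "allele")
  if (!all(need %in% names(df)))
    stop("missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!any(c("label", "ic50") %in% names(df)))
    stop("missing required column(s): label or ic50", call. = FALSE)
  df$peptide <- toupper(trimws(df$peptide))
  df$allele <- normalize_allele(df$allele)
  ok_pep <- grepl(sprintf("^[%s]+$", paste(AA_STANDARD, collapse = "")),
                  df$peptide)
  ok_all <- !is.na(df$allele)
  report <- data.frame(line = integer(0), reason = character(0))
  if (any(!ok_pep))
    report <- rbind(report, data.frame(line = which(!ok_pep) + 1L,
                                       reason = "non-standard residue"))
  if (any(!ok_all))
    report <- rbind(report, data.frame(line = which(!ok_all) + 1L,
                                       reason = "non-specific allele"))
  df <- df[ok_pep & ok_all, , drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, report = report)
}

#' Clean a labeled epitope pair table
#'
#' Applies the standard epitope filters: non-standard/modified peptides out,
#' peptide-HLA pairs carrying both a positive and a negative label removed
#' entirely, and only peptide lengths 8-15 kept. Idempotent.
#'
#' @param records data frame with `peptide`, `allele`, `label`.
#' @param min_len,max_len inclusive length bounds (defaults 8 and 15).
#' @return filtered data frame; attribute `filter_counts` reports removals.
#' @export
clean_epitope_pairs <- function(records, min_len = 8L, max_len = 15L) {
  stopifnot(all(c("peptide", "allele", "label") %in% names(records)))
  n0 <- nrow(records)
  ok_pep <- grepl(sprintf("^[%s]+$", paste(AA_STANDARD, collapse = "")),
                  records$peptide)
  records <- records[ok_pep, , drop = FALSE]
  n_mod <- n0 - nrow(records)
  records <- unique(records)
  n_dup <- n0 - n_mod - nrow(records)
  key <- paste(records$peptide, records$allele, sep = "\r")
  nlab <- tapply(records$label, key, function(l) length(unique(l)))
  conflicted <- names(nlab)[nlab > 1L]
  records <- records[!(key %in% conflicted), , drop = FALSE]
  n_conf <- sum(key %in% conflicted)
  len <- nchar(records$peptide)
  keep <- len >= min_len & len <= max_len
  n_len <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  structure(records, filter_counts = c(modified = n_mod, duplicate = n_dup,
                                       conflicting = n_conf,
                                       length = n_len))
}

#' Transform IC50 affinity to the unit interval
#'
#' `1 - log(ic50) / log(50000)`, clipped to `[0, 1]`: 1 nM maps to 1 (strong
#' binder), 50000 nM maps to 0.
#'
#' @param ic50 positive IC50 values in nM.
#' @return targets in `[0, 1]`.
#' @seealso [inverse_transform_affinity()]
#' @export
transform_affinity <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 values must be positive", call. = FALSE)
  pmin(pmax(1 - log(ic50) / log(50000), 0), 1)
}

#' Invert the affinity transform
#'
#' @param target values in `[0, 1]`.
#' @return IC50 in nM (`50000^(1 - target)`).
#' @export
inverse_transform_affinity <- function(target) {
  stopifnot(all(target >= 0 & target <= 1))
  50000^(1 - target)
}

#' Empirical peptide length distribution
#'
#' @param records data frame of positive records with a `peptide` column,
#'   or a character vector of peptides.
#' @return named numeric vector of frequencies summing to 1.
#' @export
peptide_length_distribution <- function(records) {
  peps <- if (is.data.frame(records)) records$peptide else records
  if (length(peps) == 0L) stop("no peptides supplied", call. = FALSE)
  tab <- table(nchar(peps))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p
}

#' Sample a batch of synthetic negative records
#'
#' Random peptides emulate the standard negative-generation scheme for
#' mass-spectrometry data: peptide length drawn from the empirical
#' distribution of observed ligands, each residue uniform over the 20
#' amino acids, and the peptide paired with an allele drawn uniformly from
#' the panel. A fresh draw is made on every call (per-batch regeneration).
#'
#' @param length_dist named frequency vector from
#'   [peptide_length_distribution()].
#' @param allele_panel character vector of allele names.
#' @param n number of negatives.
#' @param seed optional seed (caller's RNG stream restored).
#' @return data frame `peptide`, `allele`, `label` (= 0),
#'   `source` (= "synthetic-negative").
#' @export
sample_negative_batch <- function(length_dist, allele_panel, n, seed = NULL) {
  if (length(length_dist) == 0L || length(allele_panel) == 0L)
    stop("length distribution and allele panel must be non-empty",
         call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  draw <- function() {
    lens <- as.integer(sample(names(length_dist), n, replace = TRUE,
                              prob = length_dist))
    maxL <- max(lens)
    chars <- matrix(sample(AA_STANDARD, n * maxL, replace = TRUE), n, maxL)
    peps <- substring(do.call(paste0, as.data.frame(chars,
                                                    stringsAsFactors = FALSE)),
                      1L, lens)
    data.frame(peptide = peps,
               allele = sample(allele_panel, n, replace = TRUE),
               label = 0L, source = "synthetic-negative",
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Peptide-disjoint train/validation/test split
#'
#' Unique peptide sequences (not records) are partitioned so that no peptide
#' appears in more than one partition; peptides are stratified by the allele
#' of their first record where possible, and allocation within each stratum
#' follows the requested fractions (largest-remainder rounding).
#'
#' @param records data frame with `peptide` and `allele` columns.
#' @param fractions numeric vector summing to 1, e.g. `c(train = 0.8,
#'   validation = 0.1, test = 0.1)`.
#' @param seed integer seed.
#' @return an object of class `dataset_split`: named list of data frames.
#' @export
split_dataset <- function(records, fractions = c(train = 0.8,
                                                 validation = 0.1,
                                                 test = 0.1),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  if (is.null(names(fractions)))
    names(fractions) <- paste0("part", seq_along(fractions))
  peps <- unique(records$peptide)
  stratum <- records$allele[match(peps, records$peptide)]
  assign <- setNames(integer(length(peps)), peps)
  with_seed(seed, {
    for (s in unique(stratum)) {
      members <- sample(peps[stratum == s])
      m <- length(members)
      sizes <- floor(fractions * m)
      rem <- m - sum(sizes)
      if (rem > 0) {
        extra <- order(fractions * m - sizes, decreasing = TRUE)[seq_len(rem)]
        sizes[extra] <- sizes[extra] + 1L
      }
      assign[members] <- rep(seq_along(fractions), times = sizes)
    }
  })
  parts <- lapply(seq_along(fractions), function(k) {
    out <- records[assign[records$peptide] == k, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(parts) <- names(fractions)
  structure(c(parts, list(seed = seed)), class = "dataset_split")
}

#' Read a multiple-sequence-aligned FASTA of allele proteins
#'
#' All sequences must share the same column count (e.g. 372 for the class I
#' HLA alignment); input is uppercased.
#'
#' @param path aligned FASTA file.
#' @return named character vector of aligned sequences with attribute
#'   `n_columns`.
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  widths <- Biostrings::width(ss)
  if (length(unique(widths)) > 1L) {
    bad <- names(ss)[which(widths != widths[1L])[1L]]
    stop("ragged alignment: sequence '", bad,
         "' has a different length", call. = FALSE)
  }
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  structure(out, n_columns = unname(widths[1L]))
}
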
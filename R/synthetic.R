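#' Generate a synthetic allele panel
#'
#' Builds a desk-scale stand-in for real HLA inputs: per family, a base
#' aligned pseudo-allele sequence, a helix-like 3D backbone (ideal
#' alpha-helix C-alpha geometry: 2.3 A radius, 100 degrees per residue,
#' 1.5 A rise, so consecutive C-alpha atoms are ~3.8 A apart) with small
#' per-allele coordinate jitter, and a 9-mer binding motif with anchor
#' positions 2 and 9. Alleles within a family differ in at most 5% of
#' alignment columns and share the family motif up to a small perturbation.
#' All output is a pure function of the parameters and seed.
#'
#' @param n_families number of allele families (default 2).
#' @param alleles_per_family alleles per family (default 3).
#' @param n_columns alignment columns (default 60; must be >= 30).
#' @param seed integer seed.
#' @param anchor_positions motif anchor positions (default `c(2, 9)`).
#' @return an object of class `synthetic_panel`: list with `alleles` (per
#'   allele: `name`, `family`, `aligned`, `coords`, `resno`, `motif`),
#'   `families`, `n_columns`, and `seed`.
#' @export
gen_panel <- function(n_families = 2L, alleles_per_family = 3L,
                      n_columns = 60L, seed = 1L,
                      anchor_positions = c(2L, 9L)) {
  if (n_columns < 30L) stop("n_columns must be at least 30", call. = FALSE)
  if (n_families < 1L || alleles_per_family < 1L)
    stop("need at least one family and one allele per family", call. = FALSE)
  genes <- LETTERS[seq_len(n_families)]
  with_seed(derive_seed(seed, "panel"), {
    alleles <- list()
    for (f in seq_len(n_families)) {
      base_seq <- sample(AA_STANDARD, n_columns, replace = TRUE)
      base_coords <- helix_coords(n_columns)
      motif <- gen_motif(anchor_positions)
      for (a in seq_len(alleles_per_family)) {
        s <- base_seq
        n_mut <- if (a == 1L) 0L else max(1L, round(0.05 * n_columns))
        if (n_mut > 0L) {
          at <- sample.int(n_columns, n_mut)
          s[at] <- sample(AA_STANDARD, n_mut, replace = TRUE)
        }
        m <- perturb_motif(motif, strength = 0.02 * (a - 1L))
        name <- sprintf("HLA-%s*90:%02d", genes[f], a)
        alleles[[name]] <- list(
          name = name, family = genes[f],
          aligned = paste(s, collapse = ""),
          coords = base_coords + matrix(rnorm(3L * n_columns, sd = 0.02),
                                        ncol = 3L),
          resno = seq_len(n_columns),
          motif = m)
      }
    }
    structure(list(alleles = alleles,
                   families = split(names(alleles),
                                    vapply(alleles, `[[`, "", "family")),
                   n_columns = as.integer(n_columns), seed = seed),
              class = "synthetic_panel")
  })
}

# Ideal alpha-helix C-alpha trace: consecutive residues ~3.8 A apart.
helix_coords <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  t <- (seq_len(n) - 1L) * turn_deg * pi / 180
  cbind(x = radius * cos(t), y = radius * sin(t),
        z = (seq_len(n) - 1L) * rise)
}

# Position-specific residue preference matrix for a 9-mer: anchor columns
# concentrate 85% of the mass on one residue; other columns are a mildly
# jittered near-uniform Dirichlet draw. Columns sum to 1.
gen_motif <- function(anchor_positions = c(2L, 9L)) {
  m <- matrix(0, nrow = length(AA_STANDARD), ncol = 9L,
              dimnames = list(AA_STANDARD, NULL))
  for (p in 1:9) {
    w <- -log(runif(length(AA_STANDARD)))  # Dirichlet(1)
    w <- 1 + w  # alpha ~ 2: near-uniform with jitter
    m[, p] <- w / sum(w)
  }
  for (p in anchor_positions) {
    anchor <- sample(AA_STANDARD, 1L)
    m[, p] <- m[, p] * 0.15 / sum(m[, p])
    m[anchor, p] <- m[anchor, p] + 0.85
    m[, p] <- m[, p] / sum(m[, p])
  }
  m
}

perturb_motif <- function(motif, strength = 0) {
  if (strength <= 0) return(motif)
  noise <- matrix(runif(length(motif)), nrow = nrow(motif))
  m <- motif * (1 - strength) + strength * noise / rep(colSums(noise),
                                                       each = nrow(motif))
  sweep(m, 2L, colSums(m), "/")
}

# Sample one peptide of length L (8-11) honouring the 9-mer motif: columns
# 1-5 map to the first 5 positions and columns 6-9 to the last 4 (keeping
# anchors at P2 and the C-terminus); length-8 drops column 5, lengths > 9
# insert uniform residues in the middle.
sample_motif_peptide <- function(motif, L) {
  cols <- if (L == 8L) c(1:4, 6:9) else c(1:5, 6:9)
  core <- vapply(cols, function(p)
    sample(rownames(motif), 1L, prob = motif[, p]), character(1L))
  if (L <= 9L) return(paste(core, collapse = ""))
  mid <- sample(AA_STANDARD, L - 9L, replace = TRUE)
  paste(c(core[1:5], mid, core[6:9]), collapse = "")
}

#' Score a peptide against a 9-mer motif
#'
#' Mean log-likelihood of the motif-mapped positions relative to uniform;
#' used by the affinity generator and as a simple position-weight-matrix
#' baseline classifier.
#'
#' @param peptide peptide string (length >= 8).
#' @param motif a 20 x 9 column-stochastic matrix.
#' @return numeric score (higher = better motif match).
#' @export
pwm_score <- function(peptide, motif) {
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  cols <- if (L == 8L) c(1:4, 6:9) else c(1:5, 6:9)
  pos <- if (L == 8L) 1:8 else c(1:5, (L - 3L):L)
  ll <- log(pmax(motif[cbind(match(chars[pos], rownames(motif)), cols)],
                 1e-9))
  mean(ll) - log(1 / nrow(motif))
}

#' Generate synthetic peptide-HLA binding records
#'
#' Positives are sampled from each allele's motif (lengths 8-11); decoys
#' are uniform random peptides paired with alleles drawn uniformly from the
#' panel, labeled 0. To emulate the low-data regime, the second allele of
#' each family receives only `n_pos_per_allele / 10` positives and the
#' third ("zero-shot") allele receives none.
#'
#' @param panel a [gen_panel()] object.
#' @param n_pos_per_allele positives per fully observed allele (default 200).
#' @param decoy_ratio decoys per positive (default 1).
#' @param seed integer seed.
#' @param length_probs sampling distribution over lengths 8-11.
#' @return data frame `peptide`, `allele`, `label`, `source`.
#' @export
gen_binding_data <- function(panel, n_pos_per_allele = 200L, decoy_ratio = 1,
                             seed = 1L,
                             length_probs = c(`8` = 0.15, `9` = 0.6,
                                              `10` = 0.15, `11` = 0.1)) {
  stopifnot(inherits(panel, "synthetic_panel"))
  with_seed(derive_seed(seed, "binding"), {
    rows <- list()
    for (fam in panel$families) {
      for (k in seq_along(fam)) {
        al <- panel$alleles[[fam[k]]]
        n <- if (k == 2L) max(1L, round(n_pos_per_allele / 10))
        else if (k == 3L) 0L
        else n_pos_per_allele
        if (n == 0L) next
        lens <- as.integer(sample(names(length_probs), n, replace = TRUE,
                                  prob = length_probs))
        peps <- vapply(lens, function(L) sample_motif_peptide(al$motif, L),
                       character(1L))
        rows[[length(rows) + 1L]] <-
          data.frame(peptide = peps, allele = al$name, label = 1L,
                     source = "observed", stringsAsFactors = FALSE)
      }
    }
    pos <- do.call(rbind, rows)
    n_neg <- round(decoy_ratio * nrow(pos))
    neg <- sample_negative_batch(peptide_length_distribution(pos),
                                 names(panel$alleles), n_neg)
    out <- rbind(pos, neg)
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic binding affinity records
#'
#' IC50 values are log-uniform on `[1, 50000]` nM with the mean shifted by
#' the peptide's motif-match score (better match, lower IC50), so the
#' transformed target correlates with motif fit. Transformed targets are
#' attached.
#'
#' @param panel a [gen_panel()] object.
#' @param n number of records.
#' @param seed integer seed.
#' @return data frame `peptide`, `allele`, `ic50`, `target`.
#' @export
gen_affinity_data <- function(panel, n = 1000L, seed = 1L) {
  stopifnot(inherits(panel, "synthetic_panel"), n >= 1L)
  with_seed(derive_seed(seed, "affinity"), {
    alleles <- names(panel$alleles)
    al <- sample(alleles, n, replace = TRUE)
    lens <- sample(8:11, n, replace = TRUE, prob = c(0.15, 0.6, 0.15, 0.1))
    frac_binder <- 0.5
    binder <- runif(n) < frac_binder
    peps <- vapply(seq_len(n), function(i) {
      motif <- panel$alleles[[al[i]]]$motif
      if (binder[i]) sample_motif_peptide(motif, lens[i])
      else paste(sample(AA_STANDARD, lens[i], replace = TRUE), collapse = "")
    }, character(1L))
    score <- vapply(seq_len(n), function(i)
      pwm_score(peps[i], panel$alleles[[al[i]]]$motif), numeric(1L))
    srange <- range(score)
    snorm <- (score - srange[1L]) / max(srange[2L] - srange[1L], 1e-9)
    log10_ic50 <- 4.5 - 3.8 * snorm + rnorm(n, sd = 0.5)
    ic50 <- pmin(pmax(10^log10_ic50, 1), 50000)
    data.frame(peptide = peps, allele = al, ic50 = ic50,
               target = transform_affinity(ic50), stringsAsFactors = FALSE)
  })
}

#' Generate a peptide corpus for pre-training
#'
#' Emulates a permissive-cleavage 9-mer corpus: random proteins are drawn
#' and every overlapping 9-mer window is emitted, so each protein region is
#' densely sampled.
#'
#' @param n_proteins number of random proteins.
#' @param protein_length residues per protein (>= 9).
#' @param seed integer seed.
#' @return character vector of 9-mers.
#' @export
gen_peptide_corpus <- function(n_proteins = 30L, protein_length = 100L,
                               seed = 1L) {
  if (protein_length < 9L) stop("protein_length must be >= 9", call. = FALSE)
  with_seed(derive_seed(seed, "corpus"), {
    unlist(lapply(seq_len(n_proteins), function(i) {
      prot <- paste(sample(AA_STANDARD, protein_length, replace = TRUE),
                    collapse = "")
      starts <- seq_len(protein_length - 9L + 1L)
      substring(prot, starts, starts + 8L)
    }))
  })
}

#' Write synthetic panel files in the formats the pipeline reads
#'
#' Aligned FASTA for the allele sequences and one minimal PDB (CA ATOM
#' records) per allele.
#'
#' @param panel a [gen_panel()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (list with `fasta`, `pdb`).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "alleles_aligned.fasta")
  seqs <- Biostrings::AAStringSet(vapply(panel$alleles, `[[`, "", "aligned"))
  names(seqs) <- names(panel$alleles)
  Biostrings::writeXStringSet(seqs, fasta)
  pdbs <- character(0)
  for (al in panel$alleles) {
    p <- file.path(dir, paste0(gsub("[*:]", "_", al$name), ".pdb"))
    write_ca_pdb(al$coords, al$resno, p)
    pdbs[al$name] <- p
  }
  invisible(list(fasta = fasta, pdb = pdbs))
}

# Minimal PDB writer: CA-only ATOM records, chain A.
write_ca_pdb <- function(coords, resno, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(resno), resno, coords[, 1L], coords[, 2L], coords[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf(paste0("Synthetic HLA panel: %d allele(s) in %d family(ies), ",
                     "%d alignment columns\n"),
              length(x$alleles), length(x$families), x$n_columns))
  invisible(x)
}
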
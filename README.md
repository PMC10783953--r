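# pepmhc

Peptide–MHC class I binding prediction with sub-word sequence embeddings.

Class I MHC (HLA) proteins present short intracellular peptides (8–15
residues) on the cell surface; predicting which peptides a given HLA allele
binds is a core step in T-cell epitope screening and personalised cancer
vaccine design. Large immunopeptidomics datasets cover a few hundred
alleles very unevenly, and prediction accuracy drops sharply on alleles
with little training data. `pepmhc` addresses this regime with a
representation-learning strategy for both inputs:

- **Sub-word features.** Amino-acid sequences are front-padded with `^` to
  a multiple of the word size (3) and split into non-overlapping words;
  each word is decomposed into the positional multiset of its contiguous
  substrings (6 sub-words per 3-residue word). A word's embedding is the
  sum of its sub-word embeddings (the fastText scheme), so rare or unseen
  residue combinations are encoded through their common parts and
  information is shared across related sequences.
- **Skip-gram pre-training.** Sub-word embeddings are pre-trained to
  classify word pairs as context vs non-context through
  `sigmoid(u·v)` with binary cross-entropy and k = 5 uniform negatives per
  positive. Peptide words use a ±3-word sequence window; HLA allele words
  use a 3D structural context — two words are contexts when their residues
  lie within 45 Å on the Cα–Cα distance matrix averaged over allele
  structural models (residues 24–301).
- **Binding network.** The aligned allele sequence and the (≤45-residue)
  peptide are embedded word-wise, flattened, passed through per-branch
  dense layers (250 units, dropout 0.5), concatenated, and fed through a
  240–240 trunk (dropout 0.4) to a sigmoid binding probability. Training
  pairs observed ligands with freshly regenerated random-peptide negatives
  in every batch (lengths from the empirical ligand length distribution,
  residues uniform, allele uniform over the panel), using SGD (lr 0.01)
  with early stopping on validation AUC.
- **Affinity transfer.** IC50 values map to `[0, 1]` via
  `1 − log₅₀₀₀₀(IC50)`; the trained binding network is fine-tuned on these
  targets with mean-squared-error loss.
- **Evaluation.** ROC AUC, average-precision AUPRC, and TPR/F1 at a 5%
  (and 1%) false-discovery-rate operating point; stratified reports for
  low-data alleles (< 200 training positives) and by minimum Levenshtein
  distance between test and training peptides (≤2 / 3 / 4 / ≥5), the
  standard leakage audit.

A synthetic-data module (`gen_panel()`, `gen_binding_data()`,
`gen_affinity_data()`, `gen_peptide_corpus()`) generates pseudo-allele
alignments, helix-like Cα structures, planted position-specific binding
motifs (anchors at P2 and the C-terminus) and a random 9-mer corpus, so
the entire pipeline runs and is tested at desk scale without downloads.

## Worked example

```r
library(pepmhc)

panel <- gen_panel(n_families = 2, alleles_per_family = 3, n_columns = 60,
                   seed = 7)
dat   <- gen_binding_data(panel, n_pos_per_allele = 200, decoy_ratio = 1,
                          seed = 7)
seqs  <- vapply(panel$alleles, `[[`, "", "aligned")
sp    <- split_dataset(dat, c(train = .8, validation = .1, test = .1),
                       seed = 7)

# pre-train the two embedding tables
pep <- pretrain(lapply(gen_peptide_corpus(30, 100, seed = 7), tokenize),
                embedding_table(seed = 7), epochs = 3, lr = 0.05, seed = 7)
cc  <- context_config()             # 45 A, residues 24-301
dm  <- mean_distance_matrix(lapply(panel$alleles, function(al)
         calpha_distance_matrix(al$coords, al$resno, cc)))
tok <- tokenizer_config(gap_char = "-")
prs <- do.call(rbind, lapply(panel$alleles, function(al)
         structural_context_pairs(tokenize(al$aligned, tok), dm, cc, tok)))
alle <- pretrain(prs[, c("center", "context")], embedding_table(seed = 7),
                 epochs = 60, lr = 0.5, seed = 7)

fit <- mhc_fit(rbind(sp$train, sp$validation), seqs,
               peptide_table = pep$table, allele_table = alle$table,
               seed = 7)
fit
#> Peptide-MHC binding model (binding, trained)
#>   allele panel: 6 allele(s), 20 aligned words
#>   peptide capacity: 45 residues (15 words), embedding dim 32
#>   best validation AUC 0.9459 at epoch 149 (of 150 run)

round(roc_auc(predict(fit, sp$test), sp$test$label), 4)
#> [1] 0.9639
```

The held-out AUC of 0.96 shows the network recovering the planted binding
motifs from labelled pairs alone. `predict()` returns binding
probabilities in (0, 1); `eval_report()` adds AUPRC, the TPR/F1 at the 5%
FDR cutoff and the low-data/edit-distance strata;
`export_allele_embeddings()` gives one row per allele (including alleles
without any training ligands) for clustering or visualisation;
`finetune_affinity()` continues training on transformed IC50 targets.

A thin command-line wrapper (`inst/scripts/pepmhc`) exposes the same
pipeline as sub-commands: `simulate`, `pretrain-peptide`,
`pretrain-allele`, `train`, `finetune-affinity`, `predict`, `evaluate`;
see `?pmhc_main`.

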
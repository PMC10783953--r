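---
title: "Sub-word embeddings for peptide-MHC class I binding: models and methods"
author: "pepmhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-word embeddings for peptide-MHC class I binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmhc)
```

## The problem

Class I MHC (in humans, HLA) molecules bind short intracellular peptides
and display them to cytotoxic T cells. Immunopeptidomics experiments yield
large positive-only lists of eluted ligands, but coverage across HLA
alleles is extremely uneven: a handful of alleles account for most data
while many clinically relevant alleles have fewer than 200 known ligands.
`pepmhc` implements a pan-allele binding predictor designed to generalise
into that low-data regime by learning *compositional* sequence
representations that share information across related peptides and
related alleles, rather than encoding each sequence independently.

## Words, sub-words, and sequence embeddings

A sequence is front-padded with `^` until its length is divisible by the
word size (3 residues) and split into non-overlapping words, so `ABCD`
becomes `^^A | BCD`. Padding is only ever prepended; the final word always
ends at the C-terminus, which matters because class I binding motifs
anchor at the second and the C-terminal peptide positions. Each word is
expanded into the multiset of all its contiguous substrings — for word
size 3 always six sub-words, counted once per position, so `AAA` yields
`A, A, A, AA, AA, AAA`. A word vector is the sum over this multiset and a
sequence embedding is the ordered collection of its word vectors. Unseen
sub-words are initialised uniformly on $[-0.5/d, 0.5/d]$ with $d = 32$;
the draw is a pure function of the table seed and the sub-word string, so
lookups are reproducible in any order.

Two open choices are worth recording. First, sub-word enumeration is a
positional multiset rather than a set: this is what makes "six sub-words
per word" an invariant, and it weights repeated substrings by
multiplicity in the word sum. Second, alignment gap characters in allele
sequences are tokenized as ordinary symbols (`gap_char = "-"`); gaps
carry positional information in a fixed-column alignment, and mapping to
structure residue numbers skips them (a gap column consumes no residue
number).

## Context pairing and skip-gram pre-training

Embeddings are pre-trained to classify word pairs as context vs
non-context: $p = \sigma(u \cdot v)$ on the two word vectors, binary
cross-entropy loss, and $k = 5$ negatives per positive drawn uniformly
from the vocabulary excluding the centre word and its true contexts
(resampled every epoch). One table serves both pair roles, and both
directions of each unordered pair are trained.

*Peptide contexts* are words within three words on the sequence.
*Allele contexts* are structural: residue-wise Cα–Cα distance matrices
are computed per allele (structure models are typically incomplete at the
termini, so only residues 24–301 are used), averaged entry-wise over
alleles (NA-aware: an entry is averaged over the models that contain it),
and two words are contexts when the minimum distance between their
residues is at most 45 Å. The 45 Å default sits at the optimum of the
conventional 5–65 Å grid (step 5), which `context_config()` exposes. The
minimum over residue pairs is the most permissive standard contact
definition; a mean-based reduction is available
(`word_dist = "mean"`). Thresholding is applied to the averaged matrix,
producing a single panel-wide context definition, consistent with using
one context matrix for pre-training.

Learning rates differ by corpus type, deliberately: the peptide corpus is
large and highly redundant (overlapping 9-mers), so it uses the fastText
convention of a small rate (0.05) for a few epochs, while the structural
pair set of a small allele panel is tiny and uses 0.5 for 60 epochs to
converge. Mean-batch gradients are used throughout.

## The binding network

The predictor has a peptide branch and an allele branch. Peptides up to
45 residues (15 words; shorter peptides are left-padded with whole pad
words, consistent with prepended padding) and the aligned allele sequence
are embedded word-wise and flattened; each branch passes through a dense
layer of 250 rectified-linear units with dropout 0.5; the concatenation
passes through two 240-unit layers with dropout 0.4 and a single sigmoid
output. Optimisation is stochastic gradient descent at learning rate
0.01. Classical momentum 0.9 is applied to the dense layers — at this
learning rate plain SGD converges impractically slowly — while the
embedding tables take momentum-free sparse updates on the rows each batch
touches, the usual treatment of embedding gradients. Pre-trained
embedding matrices are rescaled as a block to the root-mean-square of the
uniform init before entering the network: skip-gram inflates vector norms
by an order of magnitude, which otherwise saturates the first dense layer
at initialisation; the rescale preserves directions and relative norms,
i.e. the learned similarity structure.

Because eluted-ligand data are positive-only, every training batch pairs
the observed records with freshly generated synthetic negatives (ratio
1:1 by default): peptide length drawn from the empirical length
distribution of the positive ligands, residues uniform over the 20 amino
acids, allele uniform over the panel. Regenerating negatives per batch
prevents the network from memorising a fixed decoy set. Validation uses a
peptide-disjoint 10% split with a fixed, seeded negative set so the
early-stopping metric (validation AUC) is stable; patience is 25 epochs
within a 150-epoch default budget. The validation-AUC trajectory under
SGD 0.01 has a long, slow early phase at small data scales, and shorter
patience frequently stops inside it — this is why the default is 25
rather than a more aggressive value. The best-validation checkpoint is
restored after training.

Affinity fine-tuning reuses the same architecture and its sigmoid head as
a regression output on IC50 values transformed by
$1 - \log_{50000}(\mathrm{IC50})$, clipped to $[0,1]$ (values above
50000 nM clip to 0); the loss is mean squared error and early stopping
uses validation MSE. Raw nanomolar values are rejected; the transform
must be applied explicitly, which keeps the unit convention visible at
the call site.

## Evaluation

`roc_auc()` is the rank-based (Mann–Whitney) AUC with half-weight ties.
`auprc()` uses the step-wise average-precision convention (no trapezoid
interpolation) over distinct-score thresholds. `tpr_f1_at_fdr()` finds,
among thresholds with precision at least $1-\mathrm{FDR}$ (5% and 1%
levels reported), the one maximising recall — ties broken toward the
lower threshold — and reports TPR and F1 there; an unreachable FDR level
is flagged rather than interpolated. The FDR cutoff is computed globally
over pooled scores, not per allele. Stratified reports cover low-data
alleles (fewer than `min_positives` = 200 positive training peptides) and
minimum Levenshtein distance from each test peptide to the training set,
binned ≤2 / 3 / 4 / ≥5 — the standard audit that exposes test-set leakage
through near-duplicate peptides. Edit distances use `utils::adist`;
the test suite checks it against a textbook dynamic-programming oracle.
Dataset splitting itself is exact-sequence peptide-disjoint (a peptide's
records all land in one partition, allele-stratified where possible); the
edit-distance stratification quantifies the residual similarity rather
than enforcing a distance-based split.

## The synthetic panel

`gen_panel()` builds the study conditions used throughout the tests:
2 families × 3 alleles, 60 alignment columns, seed 7. Each family has a
random base sequence, a 9-mer binding motif whose anchor columns (P2 and
P9, i.e. the C-terminus) put 85% of their mass on one family-specific
residue while other columns are near-uniform, and an ideal α-helix Cα
backbone (2.3 Å radius, 100°/residue, 1.5 Å rise → consecutive Cα ≈
3.8 Å) with 0.02 Å per-allele jitter. Non-base alleles mutate 5% of
columns and perturb the motif slightly, so within-family identity (≥95%
to base) always exceeds between-family identity (~5%). A helix rather
than a real HLA fold suffices because only pairwise Cα distances enter
the method, and the extended geometry gives a controllable gradient of
near and far word pairs across the 45 Å threshold.
`gen_binding_data()` samples motif positives of lengths 8–11 (lengths
8/10/11 drop or insert central positions so both anchors are preserved)
with uniform decoys at ratio 1:1; the second allele of each family
receives a tenth of the positives and the third receives none, creating
the low-data and zero-shot regimes. `gen_affinity_data()` draws IC50
log-uniform on [1, 50000] nM with the mean shifted by motif-match score;
`gen_peptide_corpus()` emits every overlapping 9-mer of random proteins,
emulating permissive-cleavage corpus construction. All generators are
pure functions of their parameters and a seed.

What the synthetic world does *not* contain is as important as what it
does: the peptide corpus is random (natural peptide composition
statistics are absent), the structures are idealised, families are
unrelated to each other, and mass-spectrometry noise is not modelled.
Tests passing on this panel therefore demonstrate correctness of the
machinery — tokenization, context construction, training dynamics, motif
recovery, metric computation — not real-data accuracy, and effects whose
real-world mechanism is natural-sequence or real-structure information
(notably the low-data advantage of pre-training over random
initialisation) are at or below training noise here: at the panel scale,
family transfer to a low-data allele is already achieved by exact word
identity, since family members share ≥95% of alignment columns. The
zero-shot embedding-proximity property, by contrast, is robust: the
exported embedding of an allele with no ligands sits with its family on
all 12 cosine comparisons of the default panel.

## Numerical choices and degenerate inputs

Probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ so log-losses stay
finite. Dense weights are Glorot-uniform; all stage seeds are derived
from one master seed with a labelled hash (`derive_seed()`), so changing
one stage's randomness never perturbs another, and every fit, pre-train
and generator call is bitwise reproducible on a platform. Degenerate
inputs error early with named diagnostics: empty sequences, residues
outside the alphabet (position reported), ragged alignments (offending
sequence named), non-positive IC50, single-class metric inputs, unknown
alleles (available panel listed), peptides over the 45-residue capacity.
Sub-word index spaces for the peptide branch are pre-registered over the
full closure of possible padded words so that per-batch negative
peptides never create embedding rows mid-training. Problem sizes in the
test suite (60-column alignments, 200 positives per allele, 100–150
epoch budgets) were chosen as the smallest at which the planted structure
is comfortably recoverable (a plain position-weight-matrix scorer reaches
AUC ≈ 0.98 on the default panel, upper-bounding what the network should
approach; the network reaches ≈ 0.96).

## Known limitations

- Single network, no ensembling, no percentile-rank calibration against
  an allele-specific background.
- Recurrent (GRU/LSTM) input branches are out of scope by design.
- The allele branch applies one dense layer to the flattened word block;
  per-position weight sharing is not implemented.
- Combined simultaneous pre-training of both input modules is not
  implemented (separately pre-trained tables only).
- `t`-SNE/clustering of allele embeddings is left to downstream tools;
  the package only exports the embedding matrix.
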
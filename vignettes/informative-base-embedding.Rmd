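---
title: "Informative RNA base embeddings: model, training tasks and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informative RNA base embeddings: model, training tasks and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaembed)
```

## The problem

Structural alignment of two non-coding RNAs places conserved secondary-
structure elements — not merely matching residues — in the same columns.
The classical route is Sankoff-style joint folding-and-alignment, which is
O(n^6) naively and still expensive in its sparsified descendants. `rnaembed`
takes the representation-learning route: a small transformer encoder maps
every base of an RNA sequence to a D-dimensional vector that absorbs both
sequence context and structural role, after which structural alignment
reduces to ordinary affine-gap Needleman–Wunsch over a cosine score matrix,
an O(nm) computation.

## The encoder

A sequence over {A, C, G, U} is tokenized (fixed vocabulary
A=0, C=1, G=2, U=3, plus MASK and PAD) and embedded as the element-wise sum
of a learned token table and a learned position table. A stack of
transformer layers follows; each layer applies multi-head scaled
dot-product self-attention,

$$\mathrm{head}_i = \mathrm{softmax}\!\left(\frac{Q_i K_i^\top}{\sqrt{D}}\right) V_i,
\qquad C = \mathrm{Concat}(\mathrm{head}_1,\dots,\mathrm{head}_H)\,W^O,$$

followed by a position-wise feed-forward network with GELU activation.
The final layer's output is the per-base embedding matrix
$Z = [z_1, \dots, z_n]$.

Default dimensions are D = 120, six layers, twelve heads,
feed-forward width 4D, maximum length 440. Head count, feed-forward
width and activation are declared defaults — the architecture statement
they come from leaves them open — and all are configurable through
`model_config()`. Two choices deserve comment:

* **Per-head width.** The stated per-head projections are full D × D
  matrices with a concatenation width of H·D. That literal reading is the
  default (`head_dim = D`); the conventional D/H split is available via
  `head_dim = D / H`. The attention scale is √D in both cases.
* **Residual connections and layer normalization.** The bare
  attention-plus-feed-forward stack is untrainable at depth six, so
  standard post-norm residual blocks are used. Both can be disabled
  (`use_residual`, `use_layernorm`) for unit-level analysis, and several
  tests exercise the reduced forms.

There are no CLS/SEP tokens: neither training task needs sentence-level
positions. Forward and backward passes are implemented directly in R
matrix code; the backward pass is verified against central-difference
gradients in the test suite.

## Task 1: masked language modelling

15% of positions are selected uniformly without replacement (at least one
for very short sequences; count `max(1, round(0.15 n))`). Of the selected
positions, 80% are replaced by MASK, 10% are substituted with one of the
*other three* bases, and 10% are kept. The model predicts the original base
at the selected positions only, under softmax cross-entropy. The
pre-training corpus takes 10 copies of every sequence with independent mask
patterns, drawn once and kept fixed (`build_pretraining_set()`), so a
corpus of 76,237 sequences expands to 762,370 instances.

## Task 2: structural alignment learning

Given embeddings $Z, Z'$ of two sequences, the score matrix is the cosine
matrix $\omega_{ij} = z_i \cdot z'_j / (\lVert z_i\rVert\,\lVert z'_j\rVert)$.
An alignment $y$ scores
$f = \sum_{(i,j) \in y} \omega_{ij} + \text{gap terms}$, with affine gap
terms: a run of L same-direction gap columns costs
$\text{open} + \text{extend}\,(L-1)$, defaults −1 and −0.1.

Training minimizes a structured hinge: with margin
$\Delta(y,\hat y) = \delta^{FN}\,|y \setminus \hat y| + \delta^{FP}\,|\hat y \setminus y|$
counted over matched pairs (defaults $\delta^{FN} = 0.05$,
$\delta^{FP} = 0.1$), the per-instance loss is
$f(\hat y) + \Delta(y, \hat y) - f(y) + \lambda \lVert w \rVert_2^2$, where
$\hat y$ is the loss-augmented decode: because $\Delta$ decomposes over
matched pairs, $\hat y$ is an ordinary affine-gap Needleman–Wunsch on
modified scores ($\omega_{ij} + \delta^{FP}$ off the reference,
$\omega_{ij} - \delta^{FN}$ on it). The decoder is exact, so the hinge is
never negative — a property the suite checks on hundreds of random
instances and against exhaustive enumeration of all alignments for
n, m ≤ 4.

Design notes, where the design was genuinely open:

* $\Delta$ counts matched position pairs only, not gap columns; this is
  what makes the margin decompose over DP cells, and it matches the
  alignment accuracy metrics, which also count matched pairs.
* Gap scores are fixed constants, not learned; the regularized parameter
  vector $w$ is the network weights.
* The optimizer treats $\hat y$ as constant within a gradient step (the
  standard structured-SVM subgradient); the subgradient of the hinge with
  respect to $\omega_{ij}$ is +1 on pairs matched only in $\hat y$ and −1
  on pairs matched only in $y$, back-propagated through the cosine and the
  encoder. Updates use Adam with per-instance steps, so the L2 term
  ($\lambda$ default 1e-4) is applied per batch of size one.
* `train_alternating()` alternates one MLM epoch with one SAL epoch per
  cycle; alignment pairs are re-sampled from each family every cycle,
  mask patterns are fixed up front.

## Alignment and its metrics

`align_pair()` composes encoder, cosine matrix and the three-state
affine-gap DP (`nw_affine()`). Traceback ties are broken deterministically
(match over gap-in-second over gap-in-first), so results are
bit-reproducible; terminal gaps are penalized like internal ones.
Accuracy against a reference counts matched pairs only: sensitivity is
TP over reference pairs, PPV is TP over predicted pairs, F1 their harmonic
mean.

## Clustering

The whole-sequence similarity is soft symmetric alignment:
$\hat s = \frac{1}{A}\sum_{ij} a_{ij}\,\omega_{ij}$ with
$a_{ij} = \alpha_{ij} + \beta_{ij} - \alpha_{ij}\beta_{ij}$, where
$\alpha$ row-softmaxes and $\beta$ column-softmaxes $\omega$, and
$A = \sum a_{ij}$. Swapping the sequences exchanges $\alpha$ and $\beta$,
so $\hat s$ is symmetric by construction. The N × N matrix of $\hat s$
values is clustered by treating each **row** as a feature vector: a
Gaussian kernel on row Euclidean distances (bandwidth = median pairwise
distance) gives a non-negative affinity — $\hat s$ itself can be negative,
so it cannot serve as one — followed by normalized-Laplacian spectral
clustering with k-means (20 restarts) on the row-normalized leading
eigenvectors. k is a required input; there is no automatic model
selection. Agreement metrics follow the pair-counting definitions
(TP/TN/FP/FN over unordered pairs, RI, expected index E, ARI) plus
entropy-based homogeneity and completeness; the ARI implementation is
cross-checked in the tests against an independent contingency-table
implementation and against `mclust::adjustedRandIndex`.

## Motifs from attention

The attention map sums each head's softmax rows over heads and query
positions, one non-negative value per key position, mass exactly n·H; by
default it is read from the final layer. Positions above
mean + 1 sd are flagged and maximal flagged runs of length ≥ 3 are
reported (`call_motifs()`); both the threshold (in sd units) and the
minimum length are parameters, declared rather than derived — the
procedure they operationalize is shown in shaded-map form only.

## The synthetic family generator

`generate_family()` emulates what an Rfam-style seed family provides:

* a random consensus sequence consistent with a given consensus secondary
  structure (Watson–Crick pairs at paired columns);
* members drawn by per-position substitution — at paired columns a
  substitution replaces the whole pair with a different Watson–Crick pair
  (compensatory change), so every member folds into the consensus
  structure;
* single-base indels restricted to loop columns, so the structure stays
  well-defined for every member;
* optionally a conserved loop motif (a contiguous run of loop columns kept
  invariant in all members), emulating conserved boxes such as the C/D box
  of snoRNAs or the T-loop motif of tRNAs;
* the generating MSA records the true homology columns, so exact reference
  pairwise alignments and pairwise identities
  (matches over matched columns) come for free, and
  `make_benchmark()` stratifies all member pairs into identity bins with
  an optional disjoint train/test family split.

What the generator does **not** emulate: thermodynamic realism (no energy
model, no G·U wobble by default), covariance-model emission profiles,
position-specific conservation gradients, or alignment ambiguity — the
reference alignment is unique by construction. Tests passing on these
families therefore show that the machinery learns and evaluates
correctly, not that the method reaches any particular accuracy on real
ncRNA data.

## The scaled-down study

`run_scaled_study()` is the package's end-to-end experiment at desk scale
(a few tens of seconds on one CPU): a tiny encoder (2 layers, D = 24,
4 heads, conventional head split) is alternately trained for five cycles
on five families from `toy_family_specs()` — five distinct architectures,
eight members each, 10 mask copies per sequence, 10 alignment pairs per
family per cycle, using only members 1–6 of each family. It reports:

* mean alignment F1 on held-out pairs (all pairs touching members 7–8)
  for the trained model and for its random initialization;
* clustering ARI on the 12 sequences formed by members 1–4 of the three
  low-identity families (pairwise identity near 40%, mirroring the
  identity regime of curated low-identity clustering benchmarks), trained
  versus random initialization.

The alignment effect is large and stable: training raises held-out mean
F1 by roughly 0.2–0.35 over the random baseline. The clustering
comparison at N = 12 is a different story: the ARI of *both* models
fluctuates strongly across generator draws, and their difference changes
sign from draw to draw. The robust, reproducible signature of training on
the clustering side sits one level below the ARI: the mean within-family
soft-symmetric-alignment similarity exceeds the between-family mean, and
that contrast widens under training — the test suite asserts exactly
this. The acceptance suite nevertheless also asserts the strict ARI
ordering at the study's fixed conditions, and that assertion is expected
to be fragile; the per-seed values are reported by
`scripts/acceptance.R` so the comparison is visible rather than hidden.

## Numerical choices and degenerate inputs

* Attention softmax subtracts the row maximum; PAD positions are excluded
  as keys.
* Layer normalization uses eps = 1e-5; GELU is the exact
  $x\,\Phi(x)$ form.
* `omega()` refuses zero-norm embedding rows by name rather than returning
  NaN.
* DP tie-breaks are fixed (match > gap-in-second > gap-in-first); the
  suite checks score symmetry under input transposition on tie-free
  matrices and monotonicity of the optimum in any single score entry.
* Checkpoints are plain JSON (config block + flat weight vector) and
  loading validates the value count against the configuration.
* `read_stockholm()` treats both `.` and `-` as gaps, normalizes WUSS
  bracket aliases to parentheses and drops pseudoknot letters with a
  warning; the model has no pseudoknot notion.
* Unknown bases in FASTA input skip the record with a warning naming it
  (configurable to a hard error).

## Known limitations

* Training is per-instance CPU R; it is meant for the bundled toy scale,
  not for corpus-scale pre-training.
* Multiple alignment, local alignment and banded DP are out of scope.
* Spectral clustering requires k; no model selection is attempted.
* The attention-map motif caller reports salient runs, not statistically
  tested motifs.
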
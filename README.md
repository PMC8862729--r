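# rnaembed

Context- and structure-aware per-base embeddings for non-coding RNA, in R.

Structural alignment of RNAs — aligning conserved secondary-structure
elements, not just residues — classically requires Sankoff-style joint
folding-and-alignment, O(n⁶) naively. `rnaembed` instead learns an
*informative base embedding*: a small transformer encoder maps every base
of a sequence to a D-dimensional vector Z = [z₁, …, zₙ] that absorbs
sequence context and structural role. Two alternating pre-training tasks
shape it:

* **MLM (masked language modelling)** — 15% of bases are selected; 80% of
  those become a MASK token, 10% are substituted with another base, 10%
  are kept; the model restores them under cross-entropy, with 10 mask
  patterns per sequence.
* **SAL (structural alignment learning)** — a structured max-margin task:
  with the cosine score matrix ω<sub>ij</sub> = zᵢ·z′ⱼ /(‖zᵢ‖‖z′ⱼ‖) and
  alignment score f = Σ ω<sub>ij</sub> + affine gap terms (open −1,
  extend −0.1), it minimizes the structured hinge
  f(ŷ) + Δ(y, ŷ) − f(y) + λ‖w‖², where ŷ is the loss-augmented
  Needleman–Wunsch decode and Δ = δ<sup>FN</sup>·(missed pairs) +
  δ<sup>FP</sup>·(spurious pairs), defaults δ<sup>FN</sup> = 0.05,
  δ<sup>FP</sup> = 0.1.

The embedding then powers three O(n²) downstream procedures:

1. **Structural pairwise alignment** — affine-gap Needleman–Wunsch with Ω
   as the score matrix (`align_pair`, `nw_affine`), scored by
   sensitivity/PPV/F1 over matched pairs.
2. **Family clustering** — soft symmetric alignment similarity
   ŝ = (1/A) Σ a<sub>ij</sub> ω<sub>ij</sub> for all sequence pairs,
   followed by spectral clustering of the similarity-matrix rows
   (`similarity_matrix`, `spectral_cluster`), scored by ARI, homogeneity
   and completeness.
3. **Motif detection** — per-base attention maps
   M = Σ<sub>h</sub> Σ<sub>i</sub> softmax(qᵢʰ K<sub>h</sub>ᵀ/√D) from the
   final layer; salient runs are reported as motif calls (`find_motifs`).

A synthetic family generator (`generate_family`, `make_benchmark`)
produces toy RNA families with known consensus structure, compensatory
stem substitutions, loop indels, conserved loop motifs and exact reference
alignments, so the whole pipeline trains and evaluates without any
external download. Forward **and** backward passes of the encoder are
plain R matrix code (verified against numerical gradients); no deep
learning framework is required.

Intended users: RNA bioinformaticians who want a transparent, fully
inspectable reference implementation of embedding-based structural
alignment and clustering at desk scale — not a GPU-scale training system.

## Worked example

```r
library(rnaembed)

## end-to-end scaled-down study: generate 5 families, train a tiny encoder
## (2 layers, D = 24, 4 heads) for 5 alternating MLM/SAL cycles, evaluate
res <- run_scaled_study(seed = 1)
round(c(f1_random = res$f1_random, f1_trained = res$f1_trained), 3)
#>  f1_random f1_trained
#>      0.344      0.652

## align a held-out pair (members never seen by the SAL task)
fam <- res$bench$families[["stembulge"]]
al  <- align_pair(fam$members[["stembulge_2"]], fam$members[["stembulge_8"]],
                  res$params)
cat(al$aligned_rows, sep = "\n")
#> GGGUACCUCCUCACGUGUAAUUGAGAAGGUAC-UU
#> GUGGGUCCCGCAAAGUGUAAUUUUGGUGGGACCGU
round(al$score, 3)
#> [1] 22.998
```

Mean held-out F1 rises from 0.344 (random initialization) to 0.652 after
five training cycles: the embedding, not the DP, is what carries the
structural signal. On single pairs the effect can be dramatic — the
held-out pair `stembulge_1|stembulge_7` scores F1 0.901 with the trained
model against 0.254 with the random one.

A command-line interface wrapping the same functions ships at
`inst/cli/rnaembed` (subcommands `synth`, `pretrain`, `train-sal`,
`train`, `align`, `cluster`, `eval-cluster`, `motif`).

See `vignettes/informative-base-embedding.Rmd` for the model, the two
training tasks, the clustering construction, all tunable parameters and
the design decisions.

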
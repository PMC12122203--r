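---
title: "Methods: invariant domain embeddings and multi-domain architecture search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invariant domain embeddings and multi-domain architecture search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structure search at the *domain* level asks: given one protein domain, or
the ordered set of domains making up a chain, which entries of a structure
database have the same fold — and, for multi-domain queries, the same
domain composition and order? foldsearch answers this with a learned
embedding for fast candidate retrieval, followed by explicit structural
superposition (TM-score) to validate candidates, and a combinatorial
matching step that reasons about whole chains domain-by-domain.

## The embedding model

A domain is represented by its C-alpha trace `x` (an `L x 3` matrix). The
network is a stack of `n_blocks >= 2` graph message-passing blocks over the
fully connected residue graph. Node features start as sinusoidal positional
encodings `h⁰ = PE(L, node_dim)`; block `t` computes, for every ordered
residue pair `(i, j)`,

    m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2)
    h_i' = phi_h(h_i, sum_{j != i} m_ij)

where `phi_e` and `phi_h` are two-layer perceptrons (SiLU activation,
hidden width `hidden_dim`, output width `out_dim`). Coordinates are never
updated: every block sees the original `x`, and geometry enters only
through squared inter-residue distances. The final node features are
averaged over residues and linearly projected to an `embed_dim`-wide
embedding, which is therefore

* invariant to rotations, translations and reflections of the input, and
* of fixed width regardless of the number of residues.

Sequence is deliberately *not* an input: sequence features make an
embedder latch onto sequence identity rather than fold shape.

Three linear heads map the embedding to class (C), architecture (CA) and
topology (CAT) logits of a CATH-style hierarchy; the network is trained
purely as this multi-level classifier, and the embedding is read out by
dropping the heads.

### Width defaults and the 256 -> 128 projection

The update perceptrons default to a hidden width of 128 and an output
width of 256, while the stored embeddings are 128-wide. The reduction is
implemented here as an explicit final linear projection
(`out_dim -> embed_dim`); the alternative — making the last block's output
width equal the embedding width — is equivalent in capacity, but the
explicit projection keeps both widths independently configurable. The
positional-encoding width (`node_dim = 128`) and the choice of SiLU are
package choices where the design was open; the block count defaults to
the minimum, 2.

## Training

The loss is the unweighted sum of three class-weighted categorical
cross-entropies (one per head); the coarser C and CA terms act as
auxiliary losses. Class weights are `f_min / f_i` (reciprocal frequency,
minimum-frequency class pinned at weight 1), applied as a weighted mean
within each minibatch. Optimization uses AdamW (learning rate 3e-4,
decoupled weight decay 1e-2) for at most 300 epochs. Each training example
is perturbed every epoch with independent Gaussian coordinate noise
(sd 1.5 Angstrom); validation examples are never perturbed. A random
validation set (default 50 domains) monitors overfitting, and the
checkpoint with the best validation CAT accuracy is kept.

Message-passing weights are initialized from `N(0, 1e-3^2)`, the heads
from a fan-in-scaled uniform distribution. Because the tiny initialization
makes early logits minuscule, the AdamW epsilon is set small (1e-12) so
that the scale-free Adam update can grow the parameters out of the
near-zero regime; with a larger epsilon the effective step collapses and
the network stalls. Batch size (default 32; the parameter-recovery runs
use 8, which doubles the optimizer steps per epoch and converges in fewer
epochs at identical cost per epoch), early stopping (no-improvement
patience plus an optional validation-accuracy target, `stop_acc`, which by
default ends training once the validation set is classified perfectly),
and the Adam moment constants are unspecified by the recipe and exposed
as configuration. Model selection on validation CAT accuracy is likewise
a package choice. Batches are processed as one block-diagonal graph; because
pooling is a per-sample mean over that sample's own nodes, batch
composition cannot leak across samples.

## Databases and retrieval

`createdb()` embeds a list of domains, unit-normalizes the vectors and
stores them with the records (id, parent chain, order along the chain,
sequence, coordinates) plus a model fingerprint. The on-disk container is
a directory: a TSV index, a JSON header and raw little-endian doubles for
embeddings and coordinates, so a write/read round trip is bit-exact.

Retrieval is exhaustive: cosine similarity on unit vectors is an inner
product, computed for every row, with the top `k` returned (ties broken
by database index). `batched_search()` chunks queries but scores each one
through the identical code path, so results are bit-identical for every
batch size — the batching contract is about memory, never about results.
Inner products are accumulated row-wise (`rowSums`) rather than through a
matrix-matrix BLAS call, because BLAS kernel selection can change the
last bit of a dot product depending on operand shape and row position,
which would make tie-breaking and the batching contract
platform-accidental.

`search_single()` embeds the query, retrieves `k = 20` candidates (the
best-recall single-domain setting) and validates each by structural
alignment, reporting TM-scores under both normalizations and sorting by
descending query-normalized TM-score. Thresholding the validated list is
optional and off by default, since callers may want all `k` validated
candidates.

## TM-score alignment

The built-in aligner is a deliberately simplified TM-align-style
procedure used to *validate* candidate hits, not to reproduce TM-align:
gapless seed threadings at several offsets, each refined by iterating
(Kabsch superposition on the currently aligned pairs -> rebuild the
alignment by semi-global dynamic programming on the similarity matrix
`1/(1 + d_ij^2/d0^2)`) until the aligned set repeats or 20 rounds. The
TM-score is `(1/L_norm) sum_i 1/(1 + (d_i/d0)^2)` with
`d0 = 1.24 (L_norm - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom for
`L_norm <= 21`. The DP uses `d0` of the shorter chain, making the
procedure symmetric in its two inputs; both normalizations are reported
and the query-length normalization gates thresholds by default (hit lists
are sorted by query-normalized score). The gap penalty (-0.6 per gapped
column, no affine extension) follows common TM-align practice. Kabsch is
restricted to proper rotations, so mirror-image structures keep a
positive RMSD. An adapter hook allows an external TM-align binary to be
substituted; nothing in the package depends on one being present.

Known limitations: no secondary-structure seeding and no fragment
rotation search, so on genuinely hard remote-homology pairs the scores
can sit below what full TM-align finds. The property suite therefore
checks identities (self-score 1, rigid-motion invariance, monotone
degradation under noise) rather than agreement with the external program.

## Multi-domain search

For a query of `Q` ordered domains: each domain is searched with
`k = 100` (the high-precision multi-domain setting); every database chain
containing any hit is a candidate, chains with fewer than `Q` domains are
discarded, and *all* domains of each surviving chain are retrieved. After
all-against-all TM-score comparison, all injective pairings covering
every query domain with per-pair TM >= 0.5 are enumerated, and each chain
is labelled with the most restrictive category any pairing satisfies:

* `exact_mda` — identical composition and order, no extra domains;
* `contiguous` — order preserved, extras only at the termini;
* `discontiguous` — order preserved, at least one insertion between
  matched domains;
* `unordered` — all query domains matched, in any order.

Because pairing ignores inter-domain geometry, an exact-composition chain
whose domains are rearranged in 3D still scores `exact_mda` — by design,
as conformational rearrangement does not change architecture. Enumeration
is capped at 10 000 pairings per chain (tandem repeats explode
combinatorially); past the cap a branch-and-bound assignment guarantees a
maximum-total-TM representative is kept. When several pairings of one
chain differ in category, the most restrictive wins, with mean TM
breaking ties; hit chains are ranked by category restrictiveness then
mean TM. Self-hits are legitimate positives and are kept unless
`exclude_self` is set.

`easy_search()` composes segmentation with the above per chain;
single-domain chains fall through to single-domain search, and a failing
segmentation is reported for that chain without aborting the batch.

## Segmentation

Neural chain segmentation is intentionally outside this package; the
segmenter is a plug-in contract (`chain -> per-residue labels`, `0` = NDR).
Two baselines ship: `segment_single()` (whole chain = one domain) and
`segment_contact()`, a deterministic contact-graph heuristic (8 Angstrom
cutoff, sequence separation >= 4; connected components as candidate
domains, contact-free residues as NDR, small components merged into their
dominant neighbour). The contact baseline exists so the end-to-end
workflow is exercisable; it is not a substitute for a learned segmenter
on real chains with interleaved domains. `segment_external()` adapts any
external tool through a residue/label TSV contract.

## Synthetic structures and what the tests do (and do not) show

The generator builds fold templates as seeded random assemblies of
idealized helices (rise 1.5 A, radius 2.3 A, 100 degrees/residue) and
extended zigzag strands, joined end-to-end at 3.8 A steps with random
packing directions; family members are the template plus per-atom
Gaussian noise and a random rigid motion; multi-domain chains connect
placed domains with extended linkers (ground-truth NDR) whose length sets
the spatial separation (span `(linker_len + 1) * 3.8` A — a fixed
inter-domain offset cannot be imposed independently of the linker without
breaking backbone geometry, so domain spacing is controlled through
`linker_len`). Default template length is 100 residues, a typical domain
size, at which 1-Angstrom member noise leaves within-family TM-scores
near 0.73 while unrelated templates average below 0.4 — the calibration
the retrieval and training tests rely on.

Problem sizes in the test and acceptance runs are deliberately modest: the
parameter-recovery experiment trains a 2-block, 32-wide model on 8
families of 50 members each (36-residue templates, which keeps the
fully-connected edge count per domain at ~1.3k), and the archetype
benchmark uses 60-residue domains. These sizes were chosen so the whole
suite runs on one CPU in minutes; accuracy on them demonstrates that the
training loop, the embedding geometry and the matching logic are correct,
not that a full-scale model reproduces published benchmark performance on
real CATH/PDB data. Synthetic members differ from real within-family
variation (no indels, no loop remodelling, uniform noise), and synthetic
folds are far better separated than remote homologs; real-data
performance claims are out of scope here.

## Numerical choices

* Embedding invariance is exact in arithmetic; tests allow 1e-4 relative
  deviation for floating-point noise.
* Cosine ties are broken by ascending database index, making retrieval
  deterministic.
* Degenerate (collinear) point sets are flagged by Kabsch rather than
  silently superposed.
* All stochastic components (templates, members, noise, initialization,
  batching) draw from R's RNG under caller-supplied seeds; a training run
  is fully reproducible from its seed on one platform.
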
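---
title: "Contrastive graph descriptors for alignment-free structure comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive graph descriptors for alignment-free structure comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Comparing two protein tertiary structures with an alignment-based tool means
searching over residue correspondences and superpositions — accurate, but far
too slow to rank a query against a database of many thousands of structures.
`strucr` takes the alignment-free route: every single-chain structure is
mapped once to a fixed-length unit vector (a *descriptor*), after which
comparison is a vector distance and database retrieval is a matrix product.
The descriptor map is learned so that descriptor distance tracks TM-score,
the field's standard length-normalized structural-similarity measure.

## From coordinates to a graph

Only the C-alpha trace is used. A chain of $N_r$ residues with coordinates
$v_1,\dots,v_{N_r}$ becomes a *complete* graph whose adjacency is derived
from the Euclidean distance matrix $D$:

$$A_{ij} = \frac{\omega}{\max(D_{ij}, \epsilon)},\qquad \omega = 4,\ \epsilon = 2,$$

so every entry lies in $(0, 2]$, the diagonal is exactly 2 (a built-in
self-loop), and near residues dominate aggregation. No further row
normalization is applied — the normalization and the self-loop are part of
the construction.

Raw node features must be invariant to rigid motion, so they are built from
distances and angles only:

* **Reference-point distances.** The chain is cut into $2^m$ contiguous
  fragments for $m = 0,\dots,M-1$; each fragment's centroid is a reference
  point ($2^M - 1$ points; 31 at the default $M = 5$). Fragment $g$ of group
  $m$ covers 0-based indices $[\lfloor (g-1)N_r/2^m \rfloor,\
  \lceil g N_r/2^m \rceil)$, and the feature of residue $i$ is its distance
  to each reference point, in (group, index) order. The hierarchy encodes
  where a residue sits relative to progressively finer pieces of the fold.
* **Bend-angle cosine.** For interior residues, the cosine of the angle
  between the two consecutive virtual bonds
  $(v_i - v_{i-1})$ and $(v_{i+1} - v_i)$; terminal residues (and residues
  at a zero-length segment) get 0. Together: $d = 2^M = 32$ columns.

Both feature families are achiral — a mirror-image fold produces identical
features. No chirality term exists in this representation, a known
limitation.

## The encoder

The encoder maps a featurized graph to residue embeddings and a descriptor:

1. a per-residue MLP (default widths 64, 128) with batch normalization and
   leaky ReLU;
2. a BiLSTM over the residue order whose per-position hidden states
   (both directions concatenated) become the initial node embeddings —
   graph convolution alone is permutation-invariant and would lose the
   chain order;
3. a stack of residual graph-convolution blocks. A single layer is
   $\sigma(A X W)$ — the adjacency itself acts as the aggregation weight —
   and a block computes $X^{l+2} = \sigma(A\,X^{l+1} W^{l+1} + X^l W_s)$
   with $X^{l+1} = \text{dropout}(\text{ReLU}(\text{BN}(A X^l W^l)))$ and
   $W_s$ the identity when widths agree;
4. a global max-pool over (real, non-padding) residues followed by L2
   normalization, yielding a unit descriptor whose length is independent of
   $N_r$.

The final block's node matrix doubles as *residue-level* embeddings used by
the superposition module.

Defaults and the reasons behind them: the descriptor length is not dictated
by the method, so it is configurable (`descriptor_dim`, default 512, equal
by construction to the final block width since the descriptor is a max-pool
of that matrix); earlier blocks use `gc_dim = 256`; dropout after the first
GC layer of each block defaults to 0.1; leaky-ReLU slope 0.01. Batch
normalization sits after each MLP linear, after the BiLSTM concatenation and
after the first GC layer of each block — not on the second GC layer, so the
residual sum stays unnormalized and the skip path is preserved.

The forward and reverse passes are written directly in base R matrix
algebra. The reverse-mode gradients are checked against central finite
differences in the test suite (relative error below $10^{-5}$ on sampled
coordinates of every parameter tensor).

## Contrastive training

Training follows the momentum-contrast recipe. Two encoders share one
architecture: the *query* encoder $\theta_q$ is trained by SGD
(momentum 0.9, batch 64, initial learning rate 0.1 divided by 10 when the
validation AUPRC plateaus), while the *key* encoder is a momentum average,

$$\theta_k \leftarrow m\,\theta_k + (1 - m)\,\theta_q,\qquad m = 0.999,$$

and never receives gradients. Each iteration encodes a batch of queries with
$\theta_q$ and one positive per query with $\theta_k$; the InfoNCE loss

$$\mathcal{L} = -\log\frac{e^{y_q\cdot y_k/\tau}}{e^{y_q\cdot y_k/\tau} +
\sum_{i=1}^{n} e^{y_q\cdot y_i/\tau}},\qquad \tau = 0.07,$$

pulls the positive pair together against a FIFO queue of $n = 1024$ past key
descriptors (randomly initialized with unit vectors). The positive term is
included in the denominator, so the loss is non-negative and equals
$\ln(n+1)$ in the uninformative uniform case. Key descriptors are enqueued
after every step; the oldest entries leave first.

**Dynamic training-data partition.** For each query, database entries are
sorted by ground-truth similarity and the top $K = 30\%$ form a candidate
set $S$; the positive is drawn uniformly from $S$ and anything scoring
*below the sampled positive* counts as a negative. Because the positive
moves around inside $S$, the encoder is pushed to order fine-grained
similarity levels rather than to learn a single positive/negative split.
Queue entries violating the negative predicate for a given query (i.e., at
least as similar to the query as its sampled positive) are masked out of
that query's denominator; entries with unknown identity — the random
initial fill — always count as negatives. The static alternative
(`dynamic_partition = FALSE`) draws positives from the fixed neighbor set
at $\rho = 0.9$, which is the older partition style this strategy improves
on.

**Shuffled batch normalization.** Batch statistics leak information between
a query and its positive when both sit in the same normalization batch. The
original remedy shuffles samples across GPUs; on a single device we emulate
it by permuting the key batch and computing BN statistics in 4 chunks
(`bn_chunks`), then restoring order. With whole-batch statistics the
shuffle would be a no-op; chunked statistics are what preserves the intent.
The query encoder uses whole-batch statistics and maintains running
estimates for deterministic eval-mode encoding.

One master seed drives everything (initialization, queue fill, sampling,
dropout, BN shuffling); a fixed seed reproduces the loss trace exactly in a
single-threaded run.

## Retrieval

At query time the database is ranked by the **length-scaling cosine
distance**

$$d(y_a, y_b) = \frac{1 - y_a^\top y_b}{1 + \max\!\big((l_b - l_a)/l_{\max},\, 0\big)} \in [0, 2],$$

where $l_a, l_b$ are the query/key residue counts and $l_{\max}$ the longest
database chain, frozen when the database is built. When the key is not
longer than the query this is plain cosine distance; when it is longer the
distance shrinks — the same length asymmetry TM-score has. Training itself
uses plain cosine similarity; the scaling applies only to ranking. Ties
break by ascending id and the query is excluded from its own ranking by id.

## Evaluation protocol

* **Structural neighbors**: entries scoring $\ge 0.9 \times$ the query's
  maximal non-self similarity (the arg-max is always a neighbor; with
  self-pairs included the rule would be vacuous).
* **Per-query AUROC/AUPRC**, macro-averaged; AUROC via the rank-sum
  statistic, AUPRC by step-wise (non-interpolated) integration — declared,
  since the integration convention is otherwise ambiguous. Queries with no
  positive or no negative are skipped with a warning.
* **Top-K hit ratio**: $\frac{1}{N_q}\sum_i N_{hit}^i / \min(K,
  N_{nbr}^i)$ — Top-K accuracy generalized to credit *how many* neighbors
  were found; at $K=1$ they coincide.
* **Classification probe**: multinomial logistic regression (via
  `nnet::multinom`, default L2-free fit treated as a fixed linear probe) on
  raw descriptors under stratified 10-fold cross-validation; pooled
  held-out accuracy and macro F1.
* **Significance test**: half of the queries resampled 10 times; paired
  per-half means compared by a paired t-test when the differences pass
  Shapiro–Wilk at $\alpha = 0.05$, otherwise the Wilcoxon signed-rank test.
  The normality gate and its $\alpha$ are this package's choice.

## Residue-level superposition

Residue embeddings of two structures give a cosine-similarity matrix
(rows L2-normalized, so dot products are cosines); Needleman–Wunsch global
alignment over that matrix — gap open 0, gap extension 0.1, hence a gap of
length $g$ costs $0.1\,g$ under either affine convention; traceback ties
break diagonal, up, left — yields a monotone residue correspondence, and the
Kabsch algorithm (SVD with determinant correction, proper rotation enforced)
superposes the paired C-alpha atoms and reports the RMSD. The embeddings
come from the final GC block; whether an intermediate layer would align
better is untested — the final layer is the one whose max-pool forms the
descriptor, so it is the natural choice.

## The synthetic benchmark

Real fold databases with TM-align supervision are far beyond a desk-scale
test budget, so the package generates its own conditions:

* **Archetypes** are parametric C-alpha traces: ideal alpha-helices (rise
  1.5 Å/residue, radius 2.3 Å, 100°/residue) and near-extended strands
  joined by random smooth loops, in four topologies (helix bundle, sheet,
  mixed, coil). All consecutive C-alpha distances stay within
  [3.7, 3.9] Å.
* **Family members** add Gaussian coordinate noise (graded scales, default
  0.3–3 Å across the 10 members of an archetype), re-smooth bonds to
  3.8 ± 0.15 Å, and apply a random rigid transform so invariance is always
  exercised.
* **Supervision** comes from a same-length TM-score oracle: identity
  correspondence, 5 rounds of TM-weighted Kabsch superposition, then
  $\mathrm{TM} = \frac{1}{L}\sum_i 1/(1 + (d_i/d_0)^2)$ with
  $d_0 = \max(1.24(L-15)^{1/3} - 1.8,\ 0.5)$ (floored — the cube-root form
  goes negative below $L = 22$). Members share their archetype's length, so
  within-family pairs always have oracle scores; cross-length pairs get a
  floor constant of 0.17, the literature's random-pair expectation,
  configurable because it is a convention rather than a measurement.

What this emulates — and what it does not: graded within-family similarity,
length diversity, fold-class labels, and rigid-motion nuisance are all
present; side chains, Ramachandran statistics, chirality contrasts, and
cross-length alignment are not. Passing the desk-scale suites therefore
demonstrates that the machinery learns and ranks graded geometric
similarity, not that it reaches any particular accuracy on real fold
databases.

## Desk-scale study sizes and numerical choices

The test and acceptance runs use 6 archetypes × 10 members (lengths 40–60),
a reduced encoder (MLP 32→48, BiLSTM hidden 24, one residual block,
descriptor length 64), queue 128, batch 32, 400 training iterations with
validation every 50 — sizes chosen so the whole suite runs comfortably on a
single CPU while the retrieval signal (AUPRC several times the
random-ranking baseline, Top-5 hit ratio above one half) is far from the
noise floor. The dynamic-partition comparison re-trains at 200 iterations
over three seeds and asks only for a directional majority.

Numerical conventions worth stating: BN uses $\epsilon = 10^{-5}$ and
running-stat momentum 0.1; LSTM forget gates start at bias 1; Glorot
initialization elsewhere; max-pool ties route gradients to the first
arg-max row; descriptor normalization guards zero norm (a zero vector would
only arise from an all-zero node matrix); ranking ties break by id so
results are stable across runs. One caveat on loss comparisons: at
iteration 0 the negative queue is random, negatives are trivially easy and
the loss is near zero; and scoring an untrained (collapsed) embedding
against another model's queue rewards the collapse. Meaningful before/after
loss comparisons therefore evaluate each encoder on the same sampled pairs
with negatives drawn from that encoder's *own* database encodings — the
test suite does exactly that.

## Known limitations

* Achiral features: mirror folds are indistinguishable by construction.
* The TM oracle requires equal lengths; cross-length supervision is a
  constant, so the encoder sees no graded cross-length signal.
* The classification probe and ranking metrics are desk-scale; absolute
  values are not comparable to results on curated fold databases.
* Training is single-threaded base R; it is meant for small studies and
  method scrutiny, not for embedding large databases.
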
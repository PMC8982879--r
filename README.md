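# strucr — alignment-free protein structure comparison with contrastive graph encoders

Ranking a protein structure against a large database with an
alignment-based tool (TM-align and relatives) costs a superposition search
per pair. `strucr` instead learns a function that maps each single-chain
structure to a fixed-length unit descriptor, so that database search
becomes a single matrix product and comparison a vector distance that
tracks TM-score.

The pipeline, end to end:

1. **Graph construction.** A chain's C-alpha trace becomes a complete graph
   with adjacency `A_ij = ω / max(D_ij, ε)` (ω = 4, ε = 2; entries in
   (0, 2], diagonal 2), plus rotation/translation-invariant node features:
   distances from each residue to a hierarchy of 2^M − 1 fragment-centroid
   reference points (31 at M = 5) and the bend-angle cosine of consecutive
   C-alpha triples — 32 features per residue.
2. **Encoder.** Per-residue MLP → BiLSTM over the chain order → residual
   graph-convolution blocks (`X^{l+2} = σ(A X^{l+1} W^{l+1} + X^l W_s)`) →
   global max-pool → L2 normalization. The final block's node matrix also
   serves as residue-level embeddings.
3. **Contrastive training (MoCo).** A momentum-averaged key encoder
   (`θ_k ← m θ_k + (1 − m) θ_q`, m = 0.999), a FIFO queue of 1024 negative
   descriptors, the InfoNCE loss (τ = 0.07), and a *dynamic training-data
   partition*: positives drawn from each query's top-30% most similar
   structures, negatives defined relative to the sampled positive.
4. **Retrieval.** Ranking by the length-scaling cosine distance
   `d = (1 − y_a·y_b) / (1 + max((l_b − l_a)/l_max, 0))`, which mimics
   TM-score's length asymmetry.
5. **Evaluation.** Structural neighbors at 0.9 × max-similarity, per-query
   AUROC/AUPRC, Top-K hit ratio, a logistic-regression fold-class probe,
   and a half-resampling significance test.
6. **Superposition.** Cosine similarities of residue embeddings →
   Needleman–Wunsch (gap open 0, extend 0.1) → Kabsch rotation + RMSD.

A synthetic C-alpha trace generator (helix bundles, sheets, mixed folds,
coils; graded Gaussian perturbations; same-length TM-score oracle) provides
fully known desk-scale benchmarks, so everything above is testable without
downloading any database.

## Worked example

```r
library(strucr)

# a known-ground-truth benchmark: 6 fold archetypes x 10 family members
bench <- make_benchmark(synthetic_spec(seed = 11))

# reduced encoder, desk-scale training
fit <- strucr(
  bench$structures, bench$sim_table,
  encoder  = encoder_config(mlp_dims = c(32, 48), lstm_hidden = 24,
                            n_res_blocks = 1, gc_dim = 64,
                            descriptor_dim = 64),
  training = train_config(iterations = 400, batch_size = 32,
                          queue_size = 128, eval_every = 50),
  seed = 5)
fit
#> Contrastive graph encoder for protein structure retrieval
#>   60 training structures, 400 iterations, seed 5
#>   descriptor length 64; 1 residual GC block(s); BiLSTM hidden 24
#>   final training loss 2.7578; last validation AUPRC 0.6751

db  <- build_descriptor_db(fit, bench$structures)
res <- evaluate_ranking(db, bench$sim_table, ks = c(1, 5, 10))
round(c(auprc = res$avg_auprc, auroc = res$avg_auroc, res$hit_ratio_at), 3)
#> auprc auroc    K1    K5   K10
#> 0.675 0.973 0.483 0.818 0.997
```

`avg_auprc` is the macro average over queries of the area under the
precision–recall curve against each query's structural neighbors (a random
ranking scores ≈ 0.11 here), and `K5 = 0.82` means that on average 82% of
`min(5, #neighbors)` true neighbors appear in each query's top 5.

Superposing two family members through their residue embeddings:

```r
sup <- superpose(bench$structures$arch01_m01, bench$structures$arch01_m02, fit)
sup
#> <superposition_result> 48 aligned pairs, RMSD = 0.991 A
```

A command-line front end over the same functions is installed at
`inst/cli/strucr` (`simulate`, `featurize`, `train`, `embed`, `search`,
`align`, `evaluate`).

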
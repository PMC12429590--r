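# cpifuse

Multi-modal chemical–protein interaction (CPI) prediction with
interpretable late fusion, in pure R.

## Who this is for

Computational chemists and bioinformaticians who want a CPI link predictor
whose evidence channels stay inspectable: which part of a prediction came
from network topology, which from literature context, and which from
structural compatibility. The package also ships a fully deterministic
synthetic-data generator with *planted* per-modality signal, so every claim
the model machinery makes (ablation orderings, counterfactual probability
drops, fusion-weight attribution) can be tested on a desk without any
external database.

## The model

For a chemical `u` and protein `v`, three branches each emit an interaction
probability, combined by a learnable convex late fusion on the probability
simplex:

```
p(u,v) = α·p_struct + β·p_sem + δ·p_topo,   α+β+δ = 1  (softmax of 3 logits)
```

* **Topology branch** — seven node centralities on the merged interaction
  network (PageRank, betweenness, harmonic closeness, eigenvector,
  clustering coefficient, degree, Katz), min–max normalized; a pair feature
  is the mean of the two node values; the composite score
  `CTC(u,v) = Σ_k w_k f_k(u,v)` has learnable weights initialized by entropy
  weighting `w_k ∝ 1 − H(f_k)/log|V|` and an L1 sparsity penalty;
  probability via a calibrated sigmoid `σ(a·CTC + b)`.
* **Structure branch** — residue contact graphs (Cα pairs ≤ 8 Å) encoded by
  a frozen SE(3)-invariant geometric message-passing network with
  pLDDT-weighted pooling; chemicals as Morgan/ECFP bit fingerprints
  (radius 2) from the package's own SMILES reader; a 2-layer head on the
  projected pair concatenation.
* **Semantic branch** — per-entity literature embeddings served by a
  pluggable provider (file-backed TSV store or synthetic); a 2-layer head on
  `[x_u ‖ x_v]`. The zero vector doubles as the semantic-ablation input.

Training: BCE on the fused probability, Adam (lr 1e-3, weight decay 1e-5),
cosine decay, dropout 0.2, batch 128, 1:3 negative sampling resampled per
epoch, early stopping on validation AUC.

The interpretability protocol includes counterfactual edge-removal
perturbations (`perturb_topology`, `delta_p_distribution`), modality
ablations (`ablate_modality`), fusion-weight and depth sweeps, virtual
screening enrichment factors (`enrichment_factor`), and exact Wilcoxon
seed-paired statistics (`paired_seed_comparison`, `seed_statistics`).

## Worked example

```r
library(cpifuse)

cfg <- generator_config(n_chem = 120, n_prot = 120, embedding_dim = 8,
                        residue_length = c(30L, 45L), negative_multiple = 3,
                        seed = 42)
ds    <- generate_cpi_dataset(cfg)
feats <- build_features(ds$graph, ds$structures, ds$smiles, ds$sem_store,
                        encoder = encoder_config(layers = 2, s_dim = 64, v_dim = 8),
                        nbits = 512)
sp    <- split_dataset(ds)
model <- train_fusion_model(sp, feats,
                            train_config(seed = 1, max_epochs = 120, patience = 20))
print(model)
#> <cpi_model> 74 epochs (best 54), val AUC 0.7514
#> fusion weights: alpha=0.347, beta=0.375, delta=0.278
round(unlist(evaluate(model, sp$test, feats))[1:4], 4)
#>       auc precision    recall        f1
#>    0.7960    0.7073    0.6374    0.6705
pr <- perturb_topology(model, feats, ds$graph, sp$test[1, ], k = 5)
#> pair (C0061, P0120): baseline 0.190 -> perturbed 0.187, delta_p = 0.003
```

The trained model recovers the planted signal (test AUC 0.80 against a
Bayes-oracle ceiling near 0.97), the fusion spreads over all three
informative branches, and removing the five highest-betweenness edges
around `P0120` lowers the fused probability — a positive counterfactual
`delta_p`, exactly the quantity `delta_p_distribution()` summarizes over 50
random proteins.

## Command line

```sh
exec/cpi graph summarize --edges edges.tsv --dialect generic
exec/cpi topo score --edges edges.tsv --pairs pairs.tsv --out scores.tsv
exec/cpi struct contact-graph --pdb protein.pdb --cutoff 8.0
exec/cpi sem build-store --table embeddings.tsv
exec/cpi synth --n-chem 200 --n-prot 200 --seed 0 --out data/
exec/cpi train --data data/ --seed 0 --out model.rds
exec/cpi eval --model model.rds
exec/cpi perturb --model model.rds --pair C0001,P0002 --k 5
exec/cpi ablate --model model.rds --modality semantics
exec/cpi sweep weights --model model.rds --step 0.1
exec/cpi screen --candidates scored.tsv --actives actives.txt --top-frac 0.1
```

## What this package does not do

No database downloads or identifier mapping (STITCH/STRING/PubMed ids pass
through opaquely); no transformer fine-tuning (the semantic provider
consumes cached vectors; the fine-tuning recipe is documented in the
vignette); no structure prediction, docking, or conformational ensembles;
no attempt to reproduce large-scale benchmark numbers that depend on
external data. See `vignettes/cpifuse-methods.Rmd` for the full model
account, numerical conventions, generator calibration, and known
limitations (including one honestly-red oracle-recovery bound in the
acceptance suite).
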
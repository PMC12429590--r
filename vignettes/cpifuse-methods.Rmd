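---
title: "Multi-modal CPI prediction with cpifuse: models, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal CPI prediction with cpifuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical–protein interaction (CPI) prediction asks, for a chemical $u$ and a
protein $v$, whether the pair interacts. `cpifuse` treats three sources of
evidence as separate modalities, gives each its own probabilistic predictor,
and combines the three probabilities by a learnable convex (late) fusion:

$$p_{uv} = \alpha\,p_{uv}^{\mathrm{struct}} + \beta\,p_{uv}^{\mathrm{sem}}
 + \delta\,p_{uv}^{\mathrm{topo}},\qquad \alpha+\beta+\delta=1 .$$

Late fusion keeps the model decomposable: each branch can be inspected,
ablated, or counterfactually perturbed on its own, which is the basis of the
interpretability protocol in `perturb_topology()`, `ablate_modality()` and
`sweep_fusion_weights()`.

## The three branches

**Topology.** The interaction network (chem–prot, prot–prot, chem–chem
edges, undirected and unweighted; confidence scores are metadata only) is
summarized per node by seven centralities: PageRank, betweenness, closeness,
eigenvector centrality, local clustering coefficient, degree, and Katz
centrality. Each metric is min–max normalized to $[0,1]$; a pair's feature
$f_k(u,v)$ is the arithmetic mean of the two node values (the node-to-pair
map is not canonical; the mean preserves symmetry and boundedness). The
composite topological score is $\mathrm{CTC}_{uv}=\sum_k w_k f_k(u,v)$ with
learnable weights $w$, initialized by the entropy-weighting rule
$w_k^{(0)} \propto 1 - H(f_k)/\log|V|$: metrics whose distribution is
concentrated (low Shannon entropy) start with high weight. $H$ uses natural
logs over an equal-width histogram with $\min(|V|,20)$ bins, so
$H \le \log(\text{bins}) \le \log|V|$ and raw weights are provably
non-negative; an all-zero corner case falls back to uniform weights. The
branch probability is $\sigma(a\,\mathrm{CTC}_{uv}+b)$ with a learnable
affine $(a,b)$ initialized at $(1,0)$ — raw CTC lives in $[0,1]$, so without
the affine the sigmoid could only produce probabilities in a narrow band.
During training $w$ is unconstrained (the simplex constraint governs
initialization only) and carries an L1 penalty ($10^{-3}$) promoting sparse,
interpretable metric usage.

Numerical conventions, fixed for determinism: PageRank damping 0.85; Katz
attenuation $0.9/\lambda_{\max}$ evaluated by its convergent series;
eigenvector centrality by per-component power iteration (tolerance $10^{-8}$,
max 1000 iterations, each component scaled to max 1); closeness is normalized
harmonic centrality, which stays finite on disconnected graphs; clustering of
degree-$\le 1$ nodes is 0.

**Structure.** Each protein is a residue-level contact graph: nodes are
residues (21-letter one-hot type + pLDDT), edges connect C$\alpha$ pairs
within 8 Å (inclusive boundary — the cutoff's boundary semantics are a
convention; inclusive is tested explicitly at 8.000 Å). A frozen, seeded
geometric message-passing encoder in the geometric-vector-perceptron style
produces a 128-dim embedding: scalar channels consume only SE(3)-invariant
quantities (RBF-encoded distances, vector-channel norms, projections onto
edge directions), vector channels (seeded from backbone unit vectors) are
mixed equivariantly, and pooling is a pLDDT-weighted mean (weights
pLDDT/100; a plain mean is available by config) so low-confidence residues
contribute less. Invariance to rigid motions is exact up to floating point
and is tested at $10^{-5}$. Chemicals are Morgan/ECFP bit fingerprints
(radius 2, 2048 bits by default) computed by the package's own restricted
SMILES reader; a trained 2-layer perceptron projects the fingerprint into
the same 128-dim space so the pair head can consume a well-typed
concatenation (the two native dimensions differ, which the branch definition
leaves unaddressed). The structure head is a 2-layer MLP on
$[x_u^{(s)}\,\|\,x_v^{(s)}]$ with terminal sigmoid. Protein embeddings are
pooled per protein before pairing; keeping residue-level features would
require a pair-level attention mechanism that the branch definition does not
specify.

**Semantics.** Literature-derived per-entity embeddings enter through a
provider abstraction: any mapping id $\to$ vector of a fixed dimension
(default 768, the hidden size of biomedical transformer encoders). Shipped
providers are file-backed TSV stores (bit-exact round trip) and the
synthetic generator. Fine-tuning a transformer on co-mention prediction
(masked-language objective, lr $2\times10^{-5}$, batch 16, sequence length
256, 5 epochs, encoder frozen afterwards) is documented as the external
recipe that would populate the store; it is deliberately not implemented —
it needs a corpus and a GPU, and nothing downstream depends on more than the
cached vectors. The missing-entity fallback returns the zero vector, which
is by construction identical to the semantic-ablation intervention
$x^{(l)}\to 0$. The head is a 2-layer MLP on $[x_u^{(l)}\,\|\,x_v^{(l)}]$.
Semantic inputs are column-scaled (scale only, no centering) so that the
zero ablation vector is preserved while hidden layers see unit-variance
inputs.

**Fusion and training.** $(\alpha,\beta,\delta)$ are a softmax of three
logits — positive and summing to 1 for any parameter value, which is the
cleanest way to enforce the printed constraint under unconstrained
backpropagation — initialized uniform. Training minimizes binary
cross-entropy of the fused probability with Adam (lr $10^{-3}$, L2 weight
decay $10^{-5}$ uniformly), cosine learning-rate decay, dropout 0.2 on all
hidden layers, batch size 128, early stopping on validation AUC with
patience 10, and a 200-epoch hard cap. When training from graph positives,
3 negatives per positive are drawn uniformly from non-interacting chem–prot
pairs, resampled once per epoch with the seed offset by the epoch index
(refresh policy is unstated in the protocol; per-epoch resampling is the
common choice and reduces pair memorization). Classification metrics use
threshold 0.5; AUC uses midranks, so an all-ties degenerate predictor scores
exactly 0.5.

## The synthetic world

`generate_cpi_dataset()` produces a complete desk-scale dataset from one
seeded configuration; every artifact is a pure function of the config.

* **Network**: chem–prot edges by stub matching of near-regular chemical
  degrees (target mean 2.8) against protein degrees with a planted hub set
  (default 5% of proteins at 6× baseline attachment, giving the protein side
  its heavy tail), plus a small-world prot–prot ring overlay sized so the
  protein mean degree hits 3.1. Because edge counts are constructed, the
  realized means equal the targets up to rounding, at any size.
* **Structures**: ideal α-helical C$\alpha$ traces (3.8 Å spacing) built
  from segments joined by clash-rejected random reorientations; pLDDT high
  in the core, low at termini. A planted per-protein class biases amino-acid
  composition, which is what makes the class visible to the encoder.
* **Chemicals**: SMILES assembled from an alkyl/aryl/ether/amide fragment
  grammar, drawn from a seeded library of 48 distinct molecules (scaffold
  reuse, as in real screening collections).
* **Semantics**: planted directions cluster around 8 random archetypes
  (spread 0.1 before renormalization); observed embeddings add isotropic
  noise (sd 0.1) and renormalize.
* **Labels**: for candidate pairs (the graph's chem–prot edges plus an equal
  or larger number of uniform non-edges), the log-odds is
  $s\,(w_t z_t + w_s z_s + w_c z_c)$ where $z_t$ is the standardized mean
  pair centrality, $z_s$ the standardized cosine of the planted semantic
  directions, $z_c$ a standardized bilinear compatibility between the
  protein's class and the chemical's fingerprint bits; labels are Bernoulli
  draws of its logistic, and the log-odds is retained as the Bayes oracle.

Two generator constants were calibrated once, before any test was written,
and not revisited:

* `effect_scale = 3.0`: chosen by a 200k-draw Monte-Carlo so that a single
  modality alone supports AUC ≈ 0.75 and the Bayes oracle on three-signal
  data reaches ≈ 0.97, leaving visible headroom for fusion gains.
* archetype clustering (8 archetypes, spread 0.1 in the shipped default,
  observation noise 0.1): early experiments showed that fully random
  per-entity embeddings make *any* noise branch a de-facto entity
  memorizer — train/test pairs share entities, so an MLP fed injective
  entity vectors learns per-entity label propensities even when the modality
  carries no planted signal, and modality-attribution experiments become
  uninterpretable. Clustered embeddings (like real literature embeddings,
  which group entities by topic) limit a noise branch to coarse
  archetype-level propensities, which are uncorrelated with the planted
  signal. The same reasoning motivates the finite chemical library.

What a green planted-signal test does establish: the pipeline can recover a
planted modality signal, the fusion weights track which modality carries
signal, and topology perturbations move fused predictions in the expected
direction. What it does not establish: performance on real, biased,
incomplete interaction databases; transfer across chemical space; or any of
the headline benchmark numbers of large-scale evaluations, which depend on
external data and a fine-tuned language model and are explicitly outside the
desk-scale acceptance surface.

## Interpretability protocol

* `perturb_topology()` removes the $k$ highest edge-betweenness edges
  incident to the protein's 2-hop neighborhood (graph-wide with
  `scope = "global"`), recomputes centralities on the perturbed graph, and
  re-fuses with untouched structure/semantic probabilities.
  $\Delta p = p_{\text{base}} - p_{\text{pert}}$, so signal-destroying
  interventions give positive $\Delta p$. The min–max scalers fitted on the
  intact graph are *frozen* and re-applied to the perturbed centralities:
  the counterfactual changes the input, not the fitted preprocessing.
  Refitting the scalers on the perturbed graph lets unrelated global
  rescaling (e.g. the max-degree node losing edges) move the pair's
  normalized features and drowns the local effect in artifacts — we measured
  median $\Delta p$ dropping by ~5× under refitting.
* `ablate_modality()`: topology ablation forces $\delta=0$ and renormalizes
  $(\alpha,\beta)$; semantic ablation zeroes all $x^{(l)}$; structure
  ablation empties every contact graph and zeroes fingerprints, then
  re-encodes.
* `sweep_fusion_weights()` evaluates the frozen branch probabilities on the
  simplex grid with components in $[0.1, 0.8]$ (36 points at step 0.1);
  `sweep_depth()` retrains the topology-path GCN at depths 1–4.
* `paired_seed_comparison()` is the exact two-sided Wilcoxon signed-rank
  test (sign-flip null by generating-function convolution over doubled
  ranks, so midranks stay integral; zeros dropped). With 5 seeds the
  smallest attainable two-sided p is $2/2^5 = 0.0625$ — reported as
  computed, never thresholded away.
* The seed-summary CI uses $t_{0.975,\,n-1}\,\mathrm{sd}/\sqrt{n}$; the
  coefficient of variation is $100\,\mathrm{sd}/\mathrm{mean}$, flagged
  undefined at mean 0.

## Baselines

The reference baselines follow the usual benchmark settings: a trainable
GCN link predictor (depth from `cfg$depth`, hidden 128, ReLU, trained
end-to-end with the same optimizer protocol); a 2-layer, 8-head GAT-style
encoder with frozen seeded attention weights and a trained logistic head (a
deliberate simplification — training attention end-to-end in plain R buys
little at desk scale; the shape parameters match the stated settings);
DeepWalk (uniform walks) and node2vec (return bias $q=0.5$) embeddings of
dimension 128 with window 5, realized as the PPMI factorization of the walk
co-occurrence matrix — the closed-form equivalent of skip-gram with negative
sampling — followed by a trained logistic head. The early-fusion baseline
concatenates topological pair features, both semantic vectors, a seeded
sign-projection of the fingerprint and the protein embedding into one
2-layer head trained with the identical protocol.

## Degenerate inputs and tie-breaks

Constant metric columns normalize to 0.5; all-zero entropy weights fall back
to uniform; single-residue proteins yield edgeless contact graphs, which the
encoder handles (messages vanish, the embedding reduces to a per-residue
transform); predictions at exactly 0 or 1 are clamped at $10^{-12}$ with a
warning inside the BCE; enrichment-factor ties break by stable id order; the
signed-rank test with all-zero differences returns a degenerate flag rather
than a p-value.

## Known limitations

* Branch heads learn multiplicative pair interactions (dot products) from
  concatenated inputs; at desk-scale sample sizes this needs the full epoch
  budget, and the fusion-weight race resolves slowly — the planted-signal
  tests therefore run with extended patience (25–40) while keeping every
  other protocol constant.
* The GAT baseline's attention is frozen (see above).
* The SMILES reader covers the organic subset emitted by the generator plus
  common bracket atoms; it is not a general-purpose cheminformatics parser,
  and its fingerprint bit positions are not interchangeable with any other
  toolkit's (bit semantics are hash-dependent everywhere; only within-toolkit
  comparisons are meaningful).
* Centralities are computed on the full merged network, including chem–chem
  and prot–prot layers; whether pair features should instead be recomputed
  pair-level quantities (e.g. edge betweenness) is an open modeling choice —
  the node-aggregate reading is implemented.
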
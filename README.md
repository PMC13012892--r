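# tcrgraphs

Structure-aware modelling of T-cell receptor recognition of peptide-MHC
class I complexes, in R. `tcrgraphs` turns a four-chain TCR-pMHC-I
structure (MHC heavy chain, peptide, TCR&alpha;, TCR&beta;) into a
residue-level interaction graph spanning five interface zones
(MHC-peptide, peptide-TCR&alpha;, peptide-TCR&beta;, MHC-TCR&alpha;,
MHC-TCR&beta;), and classifies the complex as strong- or weak-binding
(K<sub>d</sub> below vs above 200 µM) with an equivariant graph neural
network. Because experimentally characterised weak binders are scarce, a
graph VAE-GAN trained only on weak-binding interfaces synthesises
additional weak-binding decoy graphs, vetted by a three-level
quality-control suite before they enter training.

The package is aimed at structural immunologists and method developers
who want an inspectable, fully scriptable version of this pipeline:
every stage - PDB parsing, contact detection, featurisation, generation,
filtering, classification, evaluation - is an exported R function with a
synthetic-fixture generator, so the whole framework runs and is testable
without any external dataset.

## The model in brief

* **Graphs.** Residues within an 8 Å heavy-atom cutoff across a chain
  pair become nodes joined by an edge. Nodes carry a 20-dim amino-acid
  one-hot, physicochemical descriptors (charge, Kyte-Doolittle
  hydropathy, polarity, side-chain volume, pI, mass), surface features
  (SASA, buried surface area, residue depth), backbone dihedrals and the
  C&alpha; coordinate. Edges carry the minimum heavy-atom distance, an
  orientation angle, hydrogen-bond / salt-bridge / hydrophobic flags and
  Coulomb and Lennard-Jones pairwise potentials. Zone graphs merge into
  one unified graph per complex.
* **Decoy generator.** A two-layer GCN encoder maps a graph to a
  16-dim latent Gaussian; per-size-bucket decoders emit adjacency, node
  and edge features; a Wasserstein critic with weight clipping and noise
  injection adversarially sharpens the samples. Decoys must also pass
  feature-level KL checks, Weisfeiler-Lehman-kernel MMD, topology checks
  and a latent-space filter that excludes anything inside the
  strong-binder high-density region.
* **Classifier.** Two EGNN layers update node embeddings and coordinates
  jointly (messages see squared inter-residue distances, so predictions
  are provably invariant to rotations and translations), mean pooling, a
  two-layer MLP head, three-class weighted cross-entropy over
  {strong, weak<sub>exp</sub>, weak<sub>aug</sub>}; the binding score is
  P(strong), called at 0.5.
* **Evaluation.** Five rounds of stratified group-aware 10-fold
  cross-validation (groups prevent structural leakage), feature-group
  ablation, and a post-hoc two-component Gaussian-mixture analysis
  relating binding scores to log-affinities.

See `vignettes/tcrgraphs-methods.Rmd` for assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(tcrgraphs)

# a synthetic strong-binding complex: MHC groove, 9-mer peptide, TCR above
cs <- simulate_complex("strong", synthetic_spec(), seed = 42)
cs
#> complex_structure sim_strong_42 - 69 residues, 297 heavy atoms
#>   chain M [MHC]: 127 atoms
#>   chain P [PEPTIDE]: 39 atoms
#>   chain A [TCRA]: 63 atoms
#>   chain B [TCRB]: 68 atoms

g <- build_complex_graph(cs)
g
#> interface_graph sim_strong_42 [UNIFIED]: 60 nodes, 177 edges, label=NA

# the planted class contrast: strong interfaces are denser and tighter
gw <- build_complex_graph(simulate_complex("weak", synthetic_spec(), seed = 42))
c(strong = mean(g$edge_feats[, "dist"]), weak = mean(gw$edge_feats[, "dist"]))
#>   strong     weak
#> 5.556660 6.084027

# affinity labelling
label_from_kd(100)            # "strong"  (Kd < 200 uM)
log50k_score(500)$score       # 0.4256... - the binder boundary
```

A full train/score cycle on synthetic data:

```r
ds   <- simulate_graph_dataset(synthetic_spec(n_strong = 100, n_weak = 100, seed = 11))
idx  <- sample(200, 60)                                   # held-out test
norm <- normalize_features(ds$graphs[-idx], ds$graphs[idx])
m    <- train_egnn(norm$train, ds$labels[-idx])
p    <- predict_egnn(m, norm$apply)
compute_metrics(p$binding_score, ds$labels[idx] == "strong")$auc
#> [1] 1
```

A command-line wrapper over the same functions lives at
`inst/cli/tcrgraphs-cli.R` (`simulate`, `build-graphs`, `cdr-metrics`,
`train-gan`, `generate`, `filter-decoys`, `train`, `predict`,
`evaluate`).

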
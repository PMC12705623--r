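# herbnet

Prescriptions in traditional herbal medicine are multi-herb combinations,
and whether a given combination carries a therapeutic efficacy class
("regulating blood", "expelling phlegm", ...) is a nonlinear function of
its composition. `herbnet` predicts prescription efficacy from a
heterogeneous network that links prescriptions to their herbs, herbs to
their chemical metabolites, and metabolites to their protein targets —
so the prediction can draw on pharmacology, not just on herb-level
attributes. It is aimed at computational researchers studying formula
compatibility and at method developers who need a fully testable,
dependency-light graph-attention pipeline in R.

## What it does

* **Featurization** — herbs become 22-dimensional multi-hot vectors over
  the fixed property/flavor/meridian vocabulary; prescriptions are the
  standardized sum of their herbs' vectors; SMILES and protein sequences
  are embedded by a deterministic k-mer hashing encoder (pluggable; a
  contrastive objective with dropout-pair positives,
  `L = -log( exp(sim(h_i, h_i') / tau) / sum_j exp(sim(h_i, h_j') / tau) )`,
  is included for fine-tuning); each molecule additionally gets a circular
  (Morgan-style) fingerprint attached as a degree-1 virtual graph node.
* **Heterogeneous graph** — typed nodes (prescription, herb, metabolite,
  target, fingerprint) and bidirectional typed relations, with cleaning
  filters (rare-efficacy removal at a 15% positive-share threshold,
  removal of unsequenced molecules/targets with exact edge bookkeeping)
  and TSV/JSON/GraphML serialization.
* **Relational graph attention** — per layer, K scaled-dot attention
  heads `softmax(QK'/sqrt(d_k))V` over each node's in-neighborhood are
  concatenated with M relation-attention heads, where each edge is scored
  from its learned relation embedding via
  `g = sigma(relu(r W1 + b1) W2 + b2)` and
  `beta = softmax_neighborhood(g)`; the concatenation passes through a
  relu projection. Trained end-to-end (Adam, early stopping on
  validation AUC) by a built-in reverse-mode autodiff engine — no deep
  learning framework required.
* **Adversarial augmentation** — one GAN per (efficacy, label) stratum,
  trained with the minimax value function
  `min_G max_D  E_x log D(x) + E_z log(1 - D(G(z)))`, generates label,
  feature vector and prescription–herb adjacency row for synthetic
  prescription nodes; generated records containing classically forbidden
  herb pairs are pruned, and augmentation is fitted on training folds
  only.
* **Evaluation** — stratified 10-fold cross-validation with rotating
  test/validation folds (an 8:1:1 split), AUC / AUPR / accuracy / recall
  / precision / F1, ablation variants (`R`, `E`, `H`, `S`) as config
  flags, and export of post-training herb–metabolite attention weights
  (binned, top edges per bin) for interpretation.
* **Synthetic benchmark** — a generator with a planted rule (prescription
  positive iff it contains ≥ k herbs of a hidden effective set) whose
  signal can be routed through herb features or exclusively through the
  metabolite graph, making every claim above testable offline.

## Worked example

```r
library(herbnet)

# synthetic study conditions: 300 prescriptions x 40 herbs, planted signal
cfg <- synth_config(n_prescriptions = 300, n_herbs = 40,
                    n_metabolites = 60, n_targets = 60, seed = 42)
ds <- generate_synthetic_dataset(cfg)

g <- build_graph(ds$prescriptions, ds$herbs, ds$metabolites, ds$targets,
                 ds$herb_metabolite, ds$metabolite_target,
                 embedding_spec = sequence_embedding_spec(dim = 32))
g <- drop_unsequenced(g)
g <- attach_virtual_ecfp(g, nbits = 128)
g
#> <hetero_graph>
#>   prescription     300 nodes
#>   herb              40 nodes
#>   metabolite        51 nodes
#>   target            55 nodes
#>   ecfp              51 nodes
#>   ecfp-metabolite                  51 edges
#>   herb-metabolite                 184 edges
#>   herb-prescription              3058 edges
#>   ...
#>   prescription-herb              3058 edges

rep <- crossvalidate(g, "planted",
                     train_config(folds = 5, epochs = 20, seed = 1))
rep
#>  fold   auc  aupr accuracy recall precision    f1
#>     1 0.864 0.777    0.852  0.808     0.840 0.824
#>     2 0.931 0.916    0.869  0.808     0.875 0.840
#>     3 0.934 0.930    0.883  0.769     0.952 0.851
#>     4 0.901 0.878    0.881  0.840     0.875 0.857
#>     5 0.965 0.960    0.932  0.880     0.957 0.917
#>  mean 0.919 0.892    0.884  0.821     0.900 0.858
#>    sd 0.038 0.071    0.030  0.041     0.052 0.035
```

The mean row says the cross-validated model separates prescriptions
carrying the planted efficacy from those that do not at AUC 0.92 on this
small fixture (the generator plants a "positive iff at least 2 of the 10
effective herbs" rule and flips 5% of labels). A final model's
herb–metabolite attention can then be extracted, binned, and exported:

```r
ids <- g$nodes$prescription$id
fold <- stratified_folds(ids, g$labels[ids, "planted"], 10, 1)
model <- fit_rgat(g, "planted", ids[fold <= 8], ids[fold == 9],
                  train_config(epochs = 20, seed = 1))
att <- extract_relation_attention(model, g, "herb-metabolite")
head(bin_top_edges(att), 3)
#>      src    dst        relation     weight
#> 34  H024 M00008 herb-metabolite 0.09988583
#> 31  H004 M00008 herb-metabolite 0.09942706
#> 130 H040 M00044 herb-metabolite 0.09888966
export_attention(bin_top_edges(att), "attention.tsv")
```

Each row is a herb-to-metabolite edge with its neighborhood-normalized
attention coefficient (here the strongest edges of the lowest occupied
bin; metabolites with many incident herbs spread their attention).

A command-line wrapper with `simulate`, `build-graph`, `augment`,
`train`, `attention` and `pipeline` subcommands is installed at
`inst/cli/herbnet-cli.R`.

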
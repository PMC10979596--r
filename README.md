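# kmpred

Two-stage prediction of Michaelis constants (K_M) for wildtype and mutant
enzyme–substrate pairs, from substrate SMILES and protein sequence alone.

The Michaelis constant describes the affinity of an enzyme for a substrate
and is a central parameter of enzyme kinetics; measuring it is slow and
expensive, so predicted log10 K_M values are useful wherever sequence
variants and candidate substrates outnumber assay capacity (enzyme
engineering, synthetic biology, kinetic modelling). `kmpred` implements the
full workflow: curation of raw kinetic records, molecular-graph and
protein-embedding featurization, a two-stage regression model, stratified
evaluation, and a synthetic-data harness so every stage is testable without
any database download.

## The model

Records are curated by materializing mutant sequences from substitution
strings (`D123A/R456K`), canonicalizing SMILES, quarantining invalid
entries, removing fusion-length sequences (≥ 1,000 residues), keeping the
maximum K_M per (sequence, canonical SMILES) key, and log10-transforming
K_M.

Prediction is two-staged:

1. **Stage 1** — a message-passing graph encoder (one of GIN, GCN, GAT, or
   a combined GAT-GCN) maps the substrate's molecular graph to a 128-d
   embedding; concatenated with a 1,280-d protein embedding it forms a
   1,408-d combined vector feeding a two-layer fully connected head. Encoder
   and head are trained end to end on log10 K_M (Adam, cosine-annealed
   learning rate, MSE loss), keeping the epoch with minimal validation RMSE.
2. **Stage 2** — gradient-boosted trees (xgboost) are fit on the combined
   features extracted with the trained encoder, with a seeded random
   hyperparameter search; predictions come from this regressor.

Protein embeddings go through a pluggable contract: the bundled default is a
deterministic mock embedder (amino-acid composition + hashed 3-mer
frequencies, 1,280-d to match the hidden size of the ESM-2 650M language
model); a language-model wrapper plugs in through `protein_embedder()`.

Evaluation reports R², RMSE and Pearson's r (with t-based p-values) overall
and stratified by enzyme type (wildtype/mutant) and top-level EC class 1–6.

## Worked example

Generate a synthetic dataset with a planted signal, run the whole pipeline,
and inspect the held-out report:

```r
library(kmpred)

ds  <- generate_dataset(synthetic_config(n_records = 400, seed = 5))
run <- run_training_pipeline(
  ds$records, encoder = "gin",
  train_cfg = train_config(epochs = 5, base_lr = 3e-3, seed = 2),
  gbm_budget = 6, seed = 3)
print(run)
```

```
<kmpred_run> 381 curated records (0 quarantined), 305/76 train/test, encoder GIN
Test-set report:
  stratum  n         r2      rmse pearson_r    pearson_p
      all 76  0.3606469 0.4372872 0.6227891 1.888978e-09
 wildtype 40  0.2325315 0.4221866 0.5457366 2.703301e-04
   mutant 36  0.4478306 0.4534764 0.6954630 2.502834e-06
      EC1 13  0.4532726 0.3610747 0.7072201 6.859354e-03
      ...
```

381 of 400 raw records survive curation (the rest are duplicate
enzyme–substrate keys, resolved to the maximum K_M); the report rows give
per-stratum sample size, R², RMSE on log10 K_M, and Pearson's r with its
p-value. At this deliberately small scale the pipeline already recovers most
of the learnable signal; the bundled studies use 2,000 records, where
held-out R² reaches ≈ 0.6 against an explainable-variance ceiling of
≈ 0.73 (40% of the planted signal sits in per-mutant effects that must be
memorized from a few examples each).

Predicting for a new pair takes one call:

```r
predict_km(run$model, smiles = "CCO",
           sequence = "MKTAYIAKQRQISFVKSHFSRQLE")
#> [1] 0.1388762     # predicted log10 K_M, i.e. K_M ~ 1.4 mM
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "kmpred", package = "kmpred")`, with subcommands
`curate`, `simulate`, `overlap`, `featurize`, `train`, `predict`,
`evaluate`, and `compare`.

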
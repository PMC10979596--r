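---
title: "Two-stage prediction of Michaelis constants: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of Michaelis constants: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmpred)
```

## The problem

The Michaelis constant $K_M$ — the substrate concentration at half-maximal
reaction velocity — is a central kinetic parameter in enzyme and protein
engineering, and measuring it is slow. `kmpred` predicts $\log_{10} K_M$ for
an enzyme–substrate pair from nothing but the substrate SMILES and the
protein sequence, covering both wildtype enzymes and point mutants. This
matters for mutants in particular: most published predictors handle only
wildtype sequences, while mutagenesis is exactly where cheap $K_M$ estimates
are most useful.

## Record curation

Kinetic databases report the same enzyme–substrate pair many times under
different assay conditions, mix synonymous substrate encodings, and describe
mutants as a wildtype sequence plus a substitution string. The cleaning chain
in `curate_records()` therefore:

1. **Materializes mutants.** Mutation strings follow the common database
   convention `<WT><POS><MUT>` joined by `/` (e.g. `D123A/R456K`, 1-based
   positions). The residue at each position must match the stated wildtype
   residue — a mismatch signals stale numbering and quarantines the record.
   A record whose sequence already carries the substitutions is recognized
   and left unchanged, which makes the chain idempotent.
2. **Canonicalizes SMILES** (Open Babel), so synonymous encodings of one
   substrate collide on one key.
3. **Quarantines** records with unparseable SMILES, invalid sequences, or
   non-positive $K_M$, each with a reason code. Nothing is dropped silently;
   an audit of the cleaning is always possible from the rejects table.
4. **Removes fusion-length sequences**: enzymes of 1,000 residues or more
   are treated as fusion proteins whose extra domains are unrelated to the
   catalysis being modelled. The boundary is sharp: 999 residues stay,
   1,000 go.
5. **Deduplicates** on the (sequence, canonical SMILES) key, keeping the
   entry with the **maximum** $K_M$ (ties keep the first seen). Keeping the
   maximum is a deliberate curation convention for multi-condition
   measurements; the alternative (geometric mean) blends conditions into a
   value that was never measured.
6. **Log-transforms** $K_M$; all modelling happens on $\log_{10} K_M$.

$K_M$ values are stored as given with a unit tag (`mM` by default) and never
converted: sources rarely state units reliably enough to convert, and a
uniform constant offset on the log scale does not affect correlation-based
evaluation. Train/test splitting is uniform at 80/20 (no stratification),
reproducible under a recorded seed.

## Substrate representation

`smiles_to_graph()` builds a heavy-atom molecular graph: one node per
non-hydrogen atom, each chemical bond stored as two directed edges. Per-atom
features are one-hot blocks — element over {C,N,O,S,P,F,Cl,Br,I,other},
heavy-atom degree 0–5, formal charge −2…+2, hybridization {sp, sp², sp³,
other}, an aromatic flag, and attached-hydrogen count 0–4 — for a feature
dimension of 31. Elements outside the table map to the "other" slot rather
than failing, so exotic substrates degrade gracefully. Hydrogens are
implicit: they enter only through the H-count block. Edge features are not
used (none of the four encoders consumes them); the graph container keeps a
place for them.

## Graph encoders

Four interchangeable message-passing encoders map a molecular graph to a
128-dimensional substrate embedding:

* **GCN**: $H' = \mathrm{ReLU}(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H W)$
  with $\tilde A = A + I$ built once (self loops are never double-added).
* **GIN**: $h_v' = \mathrm{MLP}\big((1+\varepsilon)h_v + \sum_{u\in N(v)}
  h_u\big)$ with a two-layer MLP; the neighbor aggregation is a **sum**, not
  a mean. $\varepsilon$ is 0 by default and can be made trainable.
* **GAT**: per head, $e_{ij} = \mathrm{LeakyReLU}(a_{dst}^\top W h_i +
  a_{src}^\top W h_j)$ over the self-loop-augmented neighborhood,
  $\alpha_{ij}$ by softmax (every attention row sums to 1 — self loops are
  mandatory so no softmax is ever empty), update $\sum_j \alpha_{ij} W h_j$;
  heads are concatenated in hidden layers and averaged in a final GAT layer.
* **GAT-GCN**: two GAT layers followed by one GCN layer, with a max‖mean
  readout — the usual wiring of this combined architecture.

Defaults are 3 layers, hidden width 128, ReLU activations, and a final
linear projection to 128; all of it is configuration, and none of the
package's correctness claims depend on these exact values. Graph-level
readout is `sum` for GIN (the readout of the original GIN construction, and
the only one of the three modes that can represent extensive quantities such
as atom counts — see the synthetic-data section for why that matters),
`mean` for GCN and GAT, and max‖mean (projected back to 128) for GAT-GCN.

All forward and backward passes are written in plain R with dense linear
algebra. Molecular graphs are small (tens of atoms), so dense adjacency
matrices are faster and simpler than sparse machinery. Gradients for every
layer are verified against central finite differences in the test suite
(tolerance $10^{-6}$ on sampled coordinates).

## Protein representation

Fixed-length protein embeddings come through a pluggable contract
(`protein_embedder()`): any pure function of the sequence returning a
constant-dimension finite vector. The intended production embedder is a
protein language model such as ESM-2 650M, whose hidden size 1,280 sets the
default dimension; per-sequence pooling of such a model's residue states is
taken as the arithmetic mean over the final layer excluding special tokens
(the field-standard per-sequence reduction). The packaged default is
`mock_embedder()`: amino-acid composition fractions (20 entries) plus hashed
3-mer frequencies (the remaining 1,260), which is deterministic,
download-free, order-sensitive beyond the composition block, and separates
single-substitution mutants. Embeddings are memoised per embedder, and
`write_embedding_archive()` produces a plain-text archive whose manifest
names the embedder and dimension, so results are reproducible under any
embedder choice.

## The two-stage model

Stage 1 (`train_stage1()`) concatenates the 128-d substrate embedding with
the protein embedding — substrate block first, giving the 1,408-d combined
vector at the defaults — and feeds it to a two-layer fully connected head
(1,408 → 512 → 1, ReLU, dropout 0.1). Encoder and head train end to end by
Adam on mean squared error of $\log_{10} K_M$, with the learning rate under
cosine annealing
$\eta(t) = \eta_{min} + \tfrac12(\eta_{base}-\eta_{min})(1+\cos(\pi t/T))$
(defaults $\eta_{base}=10^{-3}$, $\eta_{min}=0$, $T$ = the epoch budget;
200 epochs and batch size 128 by default). The parameters kept are those of
the epoch with minimal **validation** RMSE; selecting on the test set would
leak, so an internal split (10% of the training records) serves model
selection.

Stage 2 (`fit_gbm()`) re-fits the target with gradient-boosted trees
(xgboost) on the combined features extracted with the *selected-epoch*
encoder. Hyperparameters are chosen by seeded random search over a declared
space (depth 3–9, learning rate $10^{-1.7}$–$10^{-0.5}$, subsampling,
column subsampling, minimum child weight, L2 penalty; up to 600 rounds with
early stopping on the same internal validation split). Draws are made
trial-by-trial upfront, so a budget of $b$ explores exactly a prefix of any
larger budget under the same seed — which makes "more budget never hurts"
a testable property rather than a hope. Predictions are the stage-2 output
alone; stage 1's head exists to shape the substrate embedding.

Everything is deterministic given the seed: batch order, dropout masks,
initialization, the search draws, and single-threaded boosting. Two runs
with one seed produce bit-identical reports, and a saved bundle
(`save_kmpred()`) predicts identically after reload.

## Evaluation

`stratified_report()` computes, per stratum, $R^2$
($1 - \sum(y_e-y_p)^2/\sum(y_e-\bar y_e)^2$), RMSE, and Pearson's $r$ with a
two-sided p-value from the $t$ transformation
$t = r\sqrt{(n-2)/(1-r^2)}$ (the test is not named in most reports of this
kind; the $t$ route is the standard choice). Strata are: all records,
wildtype, mutant, and top-level EC classes 1–6; translocases (EC 7) are out
of scope, and malformed EC codes fall into an `unclassified` stratum. A
stratum with fewer than two records reports `NA` rather than a fabricated
number.

Two Pearson forms are exposed because the covariance-only variant
(`pearson_r_literal()`, $\frac{1}{n-1}\sum(y_p-\bar y_p)(y_e-\bar y_e)$)
appears in some methodological write-ups with the normalization by the two
standard deviations omitted. Reported $r$ values elsewhere lie in $[-1,1]$,
which only the standard form guarantees, so reports here use the standard
form; the literal form is kept for comparison and treated as a
typographical variant, not an alternative statistic.

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` builds record tables in the exact curation dialect
(wildtype sequence + mutation spec for mutants, so the generator's output
exercises the curation chain) with a planted label:

$$\log_{10} K_M = \beta_0 + \beta_1\,\mathrm{heavyatoms} +
\beta_2\,\mathrm{aromaticrings} + \beta_3\,\mathrm{hydrophobicfraction} +
\textstyle\sum\mathrm{mutationeffects} + \mathcal N(0, \sigma^2)$$

Defaults, chosen once as plausible for this domain: $\beta = (-1.0,\ 0.08,\
0.3,\ 2.0)$ — an intercept near $K_M = 0.1$ mM, a size effect of about
0.08 log-units per heavy atom so the vocabulary spans roughly 1.5 log-units,
a ring effect of 0.3, and a weak composition effect; per-substitution
mutation effects $\mathcal N(0, 0.3^2)$; noise $\sigma = 0.3$, comparable to
inter-laboratory spread of kinetic measurements; 2,000 records, half
wildtype; 25 base enzymes of 100–500 residues; and a pool of 8
characterized mutants per enzyme. The pool matters: real databases measure
one characterized mutant against several substrates, so mutant sequences
recur across records, which is what makes mutant effects learnable and the
mutant evaluation stratum meaningful. Each substitution's effect is keyed by
(enzyme, position, residue) and recorded in the ground-truth manifest.

The three descriptors are deliberately recoverable from the model's own
inputs — heavy-atom and aromatic-ring counts from the molecular graph under
a sum readout, hydrophobic fraction as a sum of mock-embedder composition
entries — so a failure to learn indicts the implementation, not the task.
This is also why the GIN default readout is `sum`: mean or max pooling
cannot represent extensive quantities like atom counts, and planting a
signal the model family cannot express would make recovery tests
meaningless.

What the generator does **not** emulate: mechanistic enzymology, the
empirical $K_M$ distribution of real databases, substrate–enzyme binding
specificity (substrates are assigned to enzymes at random), or correlated
measurement error. Passing the recovery tests therefore demonstrates that
the pipeline's plumbing, optimization and feature flow work — not that the
model attains any particular accuracy on real kinetic data, which would
require the full database extraction and a language-model embedder.

With these defaults the planted signal variance is about 0.22 against a
noise variance of 0.09, an explainable-variance ceiling of roughly 0.73.
About 40% of the signal variance sits in per-mutant effects that must be
memorized from a handful of training examples each, so a realistic
well-functioning pipeline lands in the $R^2 \approx 0.55$–$0.65$ range on
held-out records — comfortably above the 0.5 recovery bar and far above the
permuted-label control, which sits at 0 by construction.

## Problem sizes and numerical choices

The packaged tests and the acceptance script run desk-scale configurations
chosen as the package's own defaults for its bundled studies: the recovery
study uses the full 2,000-record synthetic dataset with 8 stage-1 epochs
and a stage-2 budget of 12 draws (training longer continues to help
slightly, but epoch selection already plateaus there on this data);
contract and determinism checks use 60–120 records and 2 epochs, since the
properties they assert are scale-free. Degenerate inputs are handled
explicitly: empty graphs and empty strata are errors or `NA` reports, never
silent zeros; isolated nodes are well-defined in every encoder (GAT through
mandatory self loops); dedup ties break to first appearance; unparseable
records quarantine rather than crash. Dense $n\le 6$ closed forms, hand
oracles, and finite differences anchor the numerics at tolerances of
$10^{-10}$ (linear-algebra identities) and $10^{-6}$ (gradients,
permutation invariance).

## Known limitations

* The mock embedder is a featurization, not a learned representation; it
  cannot transfer evolutionary information the way a language model does.
  Results with it bound the pipeline, not the science.
* Training is CPU-bound, single-threaded R; it is comfortable at thousands
  of records and tens of epochs, not at database scale.
* No edge-feature message passing, 3-D conformers, stereochemistry, or
  reaction SMILES.
* Units are tagged, never converted; mixing sources with inconsistent units
  will shift strata by constants.
* The stage-2 search is random, not adaptive; with very large budgets an
  adaptive optimizer would find marginally better configurations sooner.
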
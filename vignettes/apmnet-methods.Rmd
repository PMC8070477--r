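---
title: "Scoring protein-ligand affinity with a cascade graph network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-ligand affinity with a cascade graph network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmnet)
```

## The model and its assumptions

`apmnet` regresses the binding affinity of a protein-ligand complex,
expressed as pKa = -log10 of the dissociation/inhibition constant in molar
units, from nothing but the 2D chemical graphs of the binding pocket and the
ligand. The central assumption is that affinity-relevant signal is carried
by atom identities, their local chemical environment and the covalent bond
pattern - not by a particular 3D pose. Pocket and ligand are therefore
embedded as one joint graph whose node matrix concatenates both molecules
and which contains **no pocket-ligand edges**: non-covalent contacts are
intentionally absent from the input, so the model can score a pair that has
never been docked. This is a modelling bet, not a law; it trades pose
sensitivity for applicability to unbound pairs.

Every atom becomes a fixed 75-dimensional vector: a 44-slot element one-hot
(43 named elements, "unknown" last), degree one-hot over bins 0-10, explicit
valence over 0-6, raw signed formal charge, raw radical-electron count,
hybridization one-hot over {SP, SP2, SP3, SP3D, SP3D2}, an aromaticity flag,
and a total-hydrogen one-hot over 0-4. Every bond becomes 6 bits:
single/double/triple/aromatic (mutually exclusive), conjugation and ring
membership. The element order is frozen in `atom_type_vocabulary()` because
it defines the meaning of saved parameters.

The network is a cascade of two different graph convolutions:

1. a **linear embedding** `X' = X W + b` of width `embed_dim` (m1), purely
   to densify the sparse one-hot input - no activation;
2. the **ARMA stage**: `K` parallel stacks of the recursion
   `Xbar_{t+1} = relu(Ltilde %*% Xbar_t %*% W_t + X %*% V_t)` with
   `Ltilde = I - D^{-1/2} A D^{-1/2}`, run `T` steps from `Xbar_0 = X` and
   averaged over stacks (the average is linear). This is a rational graph
   filter realised recursively, so it stays local in node space;
3. the **message-passing stage**: `x_i' = x_i + sum_j Theta(e_ij) %*% x_j`,
   where a one-hidden-layer dense network maps each 6-bit bond vector to a
   `d x d` mixing matrix. This is the layer that lets bond *types*
   (not just connectivity) shape the representation;
4. **global add pooling** and a dense head (`m1 -> m1/2 -> 1`, ReLU inside,
   linear out) emitting the scalar pKa.

Sum pooling makes the prediction exactly invariant to atom numbering and
additive over disconnected components - both properties are asserted in the
test suite rather than assumed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `embed_dim` (m1) | 128 | width of the embedding and of all node states; 64/128/256 are the natural settings to sweep |
| `arma_layers` (T) | 5 | recursion depth per ARMA stack; 3/5/7 are the natural sweep |
| `arma_stacks` (K) | 3 | parallel ARMA stacks averaged at the end; treated as a free hyperparameter |
| `mpnn_layers` | 1 | stacked edge-conditioned layers (ReLU between, fresh weights each); 0 disables the stage |
| `edge_hidden` | 32 | hidden width of the bond-vector-to-matrix network |
| `variant` | `"full"` | `"arma_only"` / `"mpnn_only"` ablation switches |
| `lr`, `lr_step`, `lr_gamma` | 1e-4, 20, 0.5 | Adam initial rate, epochs per decay, decay factor |
| `epochs`, `batch_size` | 200, 32 | training length and mini-batch size |

All pKa quantities are unitless (-log10 molar). The defaults for `lr` and
`lr_step` follow the published recipe for the full-scale problem; `lr_gamma`,
`epochs` and `batch_size` are unreported there and carry package defaults.

## Design choices where the design was open

* **Recursion start**: `Xbar_0 = X`, matching the recursive ARMA
  formulation; with this choice `T = 0` would be the identity.
* **Activations**: ReLU inside each ARMA step; the final stack average is
  linear. The embedding is linear ("simple linear transformation" is all
  the stage is for), and no extra nonlinearity sits between the ARMA and
  message-passing stages - the last ReLU inside the recursion is the last
  one before message passing.
* **No weight sharing across recursion steps**: `W_t`, `V_t` carry the step
  index, so each stack holds `T` pairs of matrices.
* **Edge conditioning**: the bond-feature product is read as matrix-valued
  conditioning - the edge network outputs a `d x d` matrix applied to the
  neighbour state; the self term passes untransformed. The edge network is
  a single-hidden-layer dense map (6 -> hidden -> d*d, ReLU), the smallest
  architecture that can represent bond-type-specific mixing.
* **Operator convention**: the normalized operator is
  `L = D^{-1/2} A D^{-1/2}` (an adjacency normalization; its complement
  `Ltilde = I - L` is the symmetric normalized Laplacian). Degree-zero
  nodes get zero rows in `L`, hence identity rows in `Ltilde`. No
  self-loops are added; the `X V_t` skip term plays that role.
* **Head**: `m1 -> m1/2 -> 1`; only "a fully connected layer" is specified
  anywhere, so the smallest head with one nonlinearity was chosen.
* **Model selection**: when a validation set is given, the checkpoint with
  the best validation RMSE is returned; otherwise the final parameters.
* **SD metric**: defined as the residual standard deviation about the
  least-squares line of predictions on observations with denominator
  `n - 1`, the CASF scoring-power convention; the quantity is reported in
  benchmark tables without a printed formula, so the convention is stated
  here once.
* **Ranking-power ties**: tied predictions count as failures at both
  levels - the conservative reading.
* **Learning-rate stepping** is per *epoch* (not per iteration), the usual
  reading of a step size of 20 alongside epoch-scale training.

## Numerical implementation

Forward and backward passes are hand-written on base-R matrices; the graph
operator is a sparse block-diagonal `Ltilde` (Matrix package), so a
mini-batch is one disconnected graph and batched inference is exactly the
concatenation of single-graph inference (asserted to 1e-6). Gradients are
analytic; the test suite checks them against central finite differences
through every stage (embedding, both ARMA stacks, stacked message passing,
head) with a directional-derivative test at relative tolerance 1e-6. Both
convolution layers additionally have deliberately naive per-node loop
implementations (`arma_reference()`, `edge_conv_reference()`) used purely
as oracles; fast and naive paths must agree to 1e-6 max-abs on seeded
random graphs. Adam uses the standard (0.9, 0.999, 1e-8) moments with bias
correction; Glorot-uniform initialization is seeded and bit-reproducible.
Degenerate inputs are defined, not accidental: empty molecules error,
edgeless graphs make the ARMA stage a dense layer chain, isolated nodes
pass through message passing unchanged, and a non-finite training loss
aborts with the epoch index.

## What the synthetic generator emulates - and what it does not

`synthetic_spec()` draws connected random molecules (spanning tree plus a
few ring-closing edges, degree capped at 4) with elements from
{C, N, O, S, Cl} assigned consistently with their valence, hydrogens
filling the remainder - so every generated atom featurizes inside the
one-hot bins without clamping. Pockets carry 16-30 atoms and ligands 6-14:
far below real pocket sizes, a desk-scale choice so that the full train/test
cycle runs in minutes on one CPU. The planted affinity is
`b + sum(w[element])` over all atoms of the complex (weights published in
`planted_affinity_params()`), optionally plus a ring-bond term
(`planted = "topology"`), with Gaussian noise (default 0.25 pKa, the order
of experimental affinity uncertainty) and clipping to the physical 0-14
range. The label is deliberately *composition-linear*: a correctly wired
network of this architecture can represent it, so learnability tests the
plumbing (featurization, pooling, gradients, optimizer), not the model's
chemical insight. Passing them therefore demonstrates that the
implementation is sound - it says nothing about performance on real
affinity data, where labels are noisy, non-linear in composition and
pose-dependent. The real-data benchmark numbers of the scoring-function
literature require the full public databases and GPU-scale training and are
out of scope here.

The reference study (`run_synthetic_study()`, also what
`scripts/acceptance.R` reruns) uses 200 training and 50 held-out complexes
with noise off, a reduced network (embed 16, K = 2, T = 2, one
message-passing layer, edge hidden 16) and 300 epochs of Adam at 3e-3
halved every 100 epochs, batch 32. These sizes were fixed once for the
package: large enough that the planted signal must be learned from
generalization (held-out Pearson R > 0.9, train RMSE < 0.1 noise-off),
small enough for a laptop CPU. Ranking power is measured on consecutive
triples of the held-out set (16 clusters).

```{r, eval = FALSE}
study <- run_synthetic_study(seed = 1)
study$test_report
study$ranking_report
```

## Known limitations

* Topology-only input: binding modes that hinge on 3D complementarity are
  invisible by construction.
* The PDB reader takes bonds from CONECT records (orders are not encoded in
  PDB and read as single); pockets without CONECT records come back
  edgeless. Formal charges and radicals are read as zero from formats that
  do not carry them; hybridization and conjugation are perceived with
  simple topological heuristics, not a full aromaticity model.
* Hydrogens are neither added nor removed at parse time; the hydrogen-count
  feature carries whatever the file implies.
* Dense per-edge `d x d` mixing matrices make the message-passing stage
  memory-hungry at large `embed_dim`; the default configuration is sized
  for CPU-scale experiments.
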
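# apmnet

Scoring protein–ligand binding affinity from molecular topology with a
cascade graph-convolutional network, in pure R.

## The problem

Virtual screening needs a *scoring function*: a model that maps a
protein–ligand complex to its binding affinity, expressed as
pKa = −log₁₀ K with K the dissociation/inhibition constant (Kd, Ki or IC50)
in molar units — 1 nM binding is pKa 9, 1 µM is pKa 6. `apmnet` implements a
descriptor-free, topology-only scoring function for people who want an
end-to-end graph model of affinity without force fields, docking poses or 3D
conformers: the binding pocket and the ligand enter as plain chemical graphs.

## The model

Each atom is featurized into a fixed 75-dimensional vector
(element one-hot over 43 symbols + unknown, degree 0–10, explicit valence
0–6, raw formal charge, raw radical-electron count, hybridization
SP/SP2/SP3/SP3D/SP3D2, aromaticity flag, total hydrogens 0–4) and each bond
into a 6-dimensional vector (single/double/triple/aromatic flags,
conjugation, ring membership). Pocket and ligand node matrices are
concatenated into one complex graph with **no cross edges** — non-covalent
contacts are deliberately not part of the input, so unbound pairs can be
scored.

The network is a cascade:

1. **Linear embedding** X′ = XW, taming the sparse one-hot input
   (default width m₁ = 128);
2. **ARMA graph convolution**: K parallel stacks of the recursion
   X̄⁽ᵗ⁺¹⁾ = σ(L̃ X̄⁽ᵗ⁾ Wᵗ + X Vᵗ), with L̃ = I − D^{−1/2}AD^{−1/2},
   averaged over stacks (defaults K = 3, T = 5);
3. **Edge-conditioned message passing**: xᵢ′ = xᵢ + Σ_{j∈N(i)} Θ(e_ij)·xⱼ,
   where a small dense network maps each bond vector e_ij to a d×d matrix
   Θ (one layer by default);
4. **Global add pool** X_graph = Σᵢ xᵢ′ and a dense head emitting one
   scalar pKa.

Training uses smooth L1 loss, Adam, Glorot initialization and a stepped
learning-rate schedule. Forward pass *and* analytic backpropagation are
implemented directly on base-R matrices (plus a sparse block-diagonal graph
operator), so everything runs on one CPU with no deep-learning runtime.
Evaluation implements the standard scoring-power metrics (RMSE, Pearson R,
MAE, and SD — the residual standard deviation about the regression line)
and CASF-style ranking power over three-ligand clusters (high level = full
order correct; low level = top binder identified).

## Worked example

The package ships a synthetic-complex generator with a planted,
graph-computable affinity function, so the whole pipeline runs without any
external database:

```r
library(apmnet)

spec  <- synthetic_spec(n_complexes = 250, noise_sd = 0, seed = 1)
cplx  <- synthetic_dataset(spec)
train <- cplx[1:200]; test <- cplx[201:250]

fit <- apmnet(train,
              config  = apmnet_config(embed_dim = 16, arma_layers = 2,
                                      arma_stacks = 2, mpnn_layers = 1,
                                      edge_hidden = 16, head_dims = 8),
              control = apmnet_control(lr = 3e-3, lr_step = 100, epochs = 300,
                                       batch_size = 32, seed = 1))
evaluate_predictions(predict(fit, test), sapply(test, `[[`, "label"))
```

```
n = 50 complexes
  RMSE      0.1954
  Pearson R 0.9852
  MAE       0.1606
  SD        0.1734
```

A held-out Pearson R of 0.985 with RMSE ≈ 0.2 pKa units means the network
has recovered the planted composition-linear affinity almost exactly from
raw graphs — the wiring test the synthetic study is designed for (real
affinity data is far harder; see the vignette). `print`, `summary`, `plot`
(loss trace), `coef`, `predict`, `fitted` and `residuals` methods are
available on the fit.

Real data in PDBbind layout is assembled with `assemble_dataset()` /
`read_pdbbind_index()` (PDB pockets, SDF/mol2 ligands), split with
`make_splits()`, and the same `apmnet()` call trains on it. A thin command
line over the same functions lives at `inst/cli/apmnet.R`
(`synth | prepare | train | evaluate`, one YAML config).

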
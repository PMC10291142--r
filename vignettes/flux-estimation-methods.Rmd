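---
title: "Methods: neural flux estimation for the central metabolism network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural flux estimation for the central metabolism network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcentral)
```

## The model

`fluxcentral` estimates sample-wise metabolic fluxes of a curated central
metabolism network from bulk transcriptomics.  The network is a factor
graph: metabolites are variables, *reaction modules* — lumped sets of
consecutive reactions with unit stoichiometry — are factors, and directed
consume/produce edges connect them.  Metabolites are either *intermediates*
(their total production should match their total consumption) or *ends*
(sources and sinks, excluded from balance).  The packaged graph
(`central_metabolism_fixture()`) has 42 modules, 27 intermediates and 15
ends across cytosol, mitochondria and the extracellular space, covering
glycolysis, the upper and lower TCA cycle, glutaminolysis, glutamine and
glutamate metabolism, glutathione metabolism, and six minor branches
(nucleotide synthesis from G3P, serine synthesis from 3PD, the
aspartate–malate shuttle, citrate-fueled fatty-acid synthesis, transport of
2OG to the cytosol, and 2OG to 2HG).

Two modeling assumptions drive the estimator:

1. **Approximate flux balance.**  At steady state the influx of each
   intermediate approximately equals its outflux; violations are penalized
   quadratically rather than imposed exactly, because bulk tissue is not a
   closed system and the curation never captures every route.
2. **A latent monotone link from expression to flux.**  The rate of a
   module is an unknown nonlinear function of the expression of its genes
   (an implicitly parameterized Michaelis–Menten-type relation).  Each
   module $m$ therefore gets its own small fully connected network
   $f_m(\cdot\,;\theta_m)$ mapping the log(FPKM+1) expression of its genes
   in sample $j$ to a scalar flux $\mathrm{Flux}_{m,j}$.

All module networks are trained **jointly** on

$$
L = \sum_{j}\sum_{k \in \mathrm{int}}
      \Big(\textstyle\sum_{m \in \mathrm{Fin}(C_k)} \mathrm{Flux}_{m,j}
           - \sum_{m' \in \mathrm{Fout}(C_k)} \mathrm{Flux}_{m',j}\Big)^2
  + \sum_{j,m}\big(\mathrm{Flux}_{m,j} - |\mathrm{Flux}_{m,j}|\big)^2
  + \lambda \sum_{j}\Big(\textstyle\sum_m \mathrm{Flux}_{m,j} - TA_j\Big)^2 ,
$$

whose three terms are the flux-imbalance loss, a non-negativity penalty
(zero for non-negative predictions, $4\,\mathrm{Flux}^2$ otherwise), and a
total-activity anchor that excludes the trivial all-zero solution.  $TA_j$
is either the summed expression of all network genes in sample $j$ (the
default) or a user constant.  No sparsity loss and no imputation are used:
the estimator targets dense bulk profiles.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `lambda_scale` | 1 | weight of the total-activity anchor; order 1 keeps the anchor comparable to the balance term on log-expression scales |
| `hidden_sizes` | 8, 4 | tanh hidden layers of each module predictor; a three-layer dense net is small enough that $N \times K_{int}$ balance constraints dominate the parameter count |
| `epochs` | 100 | maximum full-batch Adam epochs |
| `learning_rate` | 0.008 | Adam step size |
| `ta_mode` | `metabolic_total` | per-sample anchor from network-gene expression; a constant is available when cross-sample scaling is undesirable |
| `convergence_tol`, `patience` | 1e-4, 10 | stop once the relative change of `L` stays below tol for `patience` consecutive epochs |
| `seed` | 42 | controls weight initialization; runs are bit-reproducible |

Output activations are linear: non-negativity is encouraged only through
the loss (matching the loss definition), and a post-hoc clamp at zero is
available for reporting (`predict_flux(..., clamp = TRUE)`, off by
default).  Genes in a module roster but absent from the data are imputed as
zero expression with a warning; modules with *no* observed genes are pinned
to zero flux.

## The synthetic-data generator

Real compendium-scale inputs (tumor/normal RNA-seq cohorts) cannot ship
with a package, so testability rests on a generator with known ground
truth:

* **Balanced fluxes.**  `flux_path_basis()` enumerates simple
  source-to-sink paths on the bipartite graph and completes each into an
  exactly balanced integer flux mode: whenever a module on the path
  consumes a second intermediate (e.g. citrate synthase consuming both
  acetyl-CoA and oxaloacetate), producing/consuming modules are added one
  unit at a time — preferring the least-used module — until every
  intermediate balances, which closes cycles such as the TCA loop.
  Internal cycles never crossed by a source-to-sink path (the GSH/GSSG
  redox loop) get dedicated cycle modes.  Samples are non-negative
  combinations of these modes with log-normal loads (meanlog 0, sdlog 0.5,
  right-skewed like real flux magnitudes), so with zero slack the balance
  loss is exactly zero by construction.  Optional per-module slack is
  half-normal (a Gaussian truncated at zero), keeping fluxes non-negative.
* **Expression.**  Gene $i$ of module $m$ reads
  $\log(1 + w_{im}\,\mathrm{Flux}_{m,j}) + \varepsilon$,
  $w_{im} \sim U(0.5, 2)$, $\varepsilon \sim N(0, \sigma)$, clipped at 0 —
  i.e. values live directly on the log(FPKM+1) scale consumed by the
  estimator.  Gene-level noise is Gaussian on the log scale rather than
  count-level Poisson: the estimator never sees counts.
* **Two-group studies.**  `make_two_group_study()` scales the tumor-group
  loads of every mode through a perturbed module by the requested fold, so
  that module's expected flux changes by exactly that fold.  Under flux
  balance a module's flux *cannot* change in isolation — modes sharing
  those paths co-scale — which is the physically consistent reading of a
  module-level perturbation.

What the generator does **not** emulate: library-size and batch effects,
count noise, correlated gene programs outside the network, cell-type
mixtures, and tissue-specific baseline fluxomes.  Passing tests therefore
demonstrate the estimator's correctness and calibration under its own
modeling assumptions, not performance on real cohorts.

## Numerical choices

* **Optimizer.**  Full-batch Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\varepsilon = 10^{-8}$); gradients of $L$ with respect to the flux
  matrix are exact and back-propagated analytically through each module
  network.  Xavier-style Gaussian initialization, zero biases.
* **Loss trace.**  Recorded every epoch (epoch 0 is the initialized
  model); training aborts with an error on a non-finite loss.
  `epochs = 0` returns the initialized model without error.
* **Mann–Whitney.**  $U$ from midrank sums; exact two-sided p-values (the
  enumeration distribution) when $n_1 + n_2 \le 20$ without ties, else the
  normal approximation with tie and continuity corrections.  Two-sided
  throughout, with direction read from the median difference.  Raw
  $p < 0.001$ defines significance, deliberately without multiplicity
  correction, matching the cutoff convention of pan-cancer differential
  fluxomics.
* **Z-score profiles.**  Cancer samples are standardized per module
  against matched normal controls with the $n-1$ denominator; zero-variance
  modules yield $z = 0$ with a warning.
* **PCA sign convention.**  Each component is flipped so its
  largest-magnitude loading is positive, making scores deterministic.
* **SNN clustering.**  k-nearest-neighbor graph on Euclidean distances
  (k = 20, self included), Jaccard edge weights pruned below 1/15, Louvain
  community detection at resolution 0.8 — defaults mirroring the
  widely used single-cell pipeline conventions.  t-SNE uses perplexity 30
  (the cited implementation default) on the raw fluxome; raw rather than
  rescaled fluxes is a deliberate choice where the upstream convention is
  unstated.
* **ssGSEA.**  Genes ranked per sample by descending expression; the score
  sums the gap between the weighted in-set CDF (weights
  $\mathrm{rank}^\alpha$, midranks, $\alpha = 0.75$) and the out-of-set
  CDF.  Using ranks rather than raw values makes scores invariant under
  strictly increasing transforms of a sample's profile.
* **Stage enrichment.**  The cluster-versus-stage association is tested by
  chi-square on the complete-stage subset — a plain default where only the
  distributions themselves are conventionally reported.

## Oracle and benchmark settings used by the test-suite

* The **constrained least-squares oracle**: on a chain graph with one gene
  per module and identity links (expression = flux), the loss minimizer
  per sample is the unique solution of
  $(S^\top S + \lambda \mathbf{1}\mathbf{1}^\top) f = \lambda\,TA_j\,\mathbf{1}$,
  which is a function of each module's own input — so a per-module
  predictor can represent it, and trained fluxes are required to match it
  within 5% relative Frobenius error.  On branched graphs this matrix is
  singular (parallel branches trade off freely at equal loss), so the
  value-level comparison is restricted to chains.  Balanced inputs
  (zero slack) are used for the same reason: under per-module slack the
  minimizer depends on whole-sample information a single-module predictor
  cannot see.
* **Recovery benchmarks** use chains and diamonds with $n = 200$ samples,
  3 genes per module and noise 0.05–0.5; **calibration** uses the packaged
  42-module graph with 200 replicates of 50 + 50 samples on ground-truth
  fluxes (8,400 null tests) and 50 replicates for power at a 2-fold
  perturbation.  **Pipeline determinism** runs the full
  simulate→estimate→diff→phenotype chain twice at 40 samples per group and
  compares output checksums.  These sizes keep the whole suite inside a
  few minutes on one CPU while leaving each check statistically
  meaningful.

## Known limitations

* The packaged network is a best-effort curation at module resolution;
  module gene rosters are representative, not exhaustive, and all
  stoichiometry is unit-lumped.  Reversible reactions are represented in a
  single canonical direction.
* Predicted fluxes are relative quantities anchored by $TA_j$; they are
  not calibrated to absolute rates, and comparisons across cohorts
  processed with different normalizations are not meaningful.
* The balance-loss surrogate for metabolite change
  (`metabolite_change()`, influx − outflux) indicates direction and trend,
  not concentration change.
* Mutant-enzyme-specific fluxes (e.g. 2OG→2HG by mutant IDH1/2) are
  structurally present but not identifiable from expression of the
  wild-type gene set.
* t-SNE and Louvain clustering are seeded and reproducible, but their
  outputs (like all embeddings/clusterings) depend on those
  hyperparameters; the package treats them as descriptive tools.
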
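---
title: "DEPF: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEPF: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `depf`, the
tunable parameters and their defaults, the synthetic-data generator used
throughout the test suite, and the numerical and design choices made
where the method leaves room for interpretation.

## The pipeline

DEPF treats single-cell clustering as a consensus problem over a
deliberately diversified ensemble, with an explicit pruning stage
between ensemble generation and consensus:

1. **Preprocessing** — QC filtering (genes expressed in < `min_cells`
   cells removed first, then cells with < `min_features` expressed genes
   or a mitochondrial count fraction above `max_mito_frac`), `log1p`,
   and per-cell min-max rescaling to `[0, 1]`. A cell row of zero range
   is mapped to all zeros: such a cell carries no between-gene contrast,
   and zero is the only value consistent with both branch limits. The
   order (log before min-max) is a package decision; both steps can be
   switched off in `depf_config()`.
2. **Hierarchical autoencoder** — a non-negative kernel autoencoder
   (NNKAE) scores genes for removal, then a stacked Bayesian autoencoder
   (a variational autoencoder whose `sigma` head is a function of `mu`)
   yields `d` stochastic latent spaces by repeated reparameterized
   sampling of one trained model. Sampling one model rather than
   retraining per space is the cheaper of the two readings of the
   method and is exposed as the only mode; retraining can be emulated
   by calling `compute_latent_spaces()` with different seeds.
3. **Base clustering** — ultra-scalable bipartite spectral clustering
   (transfer cut) per latent space, `T_runs` times with jittered
   representative sets; or Louvain/Leiden on a kNN graph when a
   resolution parameter is wanted.
4. **Direction, pruning, consensus** — an initial locally weighted
   consensus over the full ensemble supplies silhouette coefficients in
   the concatenation of all latent spaces; the minimum silhouette
   against the threshold `eps_direction = -0.6` fixes one global
   optimization direction. BOFOA then prunes each subspace's ensemble,
   and the final partition is the locally weighted consensus of the
   union of selected members.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `min_cells`, `min_features`, `max_mito_frac` | 3, 200, 0.05 | Seurat-style QC thresholds; `mito_prefix = "MT-"` case-insensitive |
| `n_keep` | 5000 | genes kept after NNKAE scoring (all genes if fewer) |
| `hidden_dim` (NNKAE) | 64 | single sigmoid hidden layer, linear decoder |
| `latent_dim` | 15 | dimensionality of each latent space |
| `d` | 3 | number of sampled latent spaces |
| `epochs_nnkae` | 30 | full-batch Adam steps for the NNKAE |
| `epochs_vae` | 1000 | full-batch Adam steps for the Bayesian AE |
| `beta_kl` | 0.005 | KL weight in the variational loss |
| `T_runs` | 10 | base-clustering runs per latent space |
| `p`, `K`, `mix_frac` | min(n, 1000), 5, 0.5 | representatives, kept neighbors, k-means share of representatives |
| `sigma` | `"auto"` | Gaussian bandwidth = mean retained cell-representative distance (scale-free) |
| `eps_direction` | -0.6 | silhouette threshold choosing the direction |
| `alpha`, `max_fes`, `n_flies` | 13, 20, 9 | BOFOA balance rate, iterations, population size |
| `bounds` | [0, 2] | fly coordinate box per component |
| `eps_smell` | 1e-6 | pole guard in the smell transform |
| `theta` | 0.4 | ECI adjustment factor |
| `restarts` | 1 | independent optimizer restarts (means/sds reported) |

The optimizer constants (`alpha = 13`, 20 iterations, population 9,
`eps_direction = -0.6`, `T_runs = 10`) are the method's reference
settings. The reference protocol repeats the optimizer 50 times and
averages; the default here is a single run with `restarts` exposed,
which keeps desk-scale runs cheap.

## Numerical choices

* **Autoencoders in base R.** Both networks are trained by full-batch
  Adam with manually derived gradients; one "epoch" is one optimizer
  step. The Bayesian AE uses the per-cell *summed* reconstruction error
  (`sum_g (a - â)² + beta_kl · KL` per cell): with the per-entry mean
  instead, the KL gradient dominates on `[0,1]`-scaled data, `sigma`
  drifts to 1 and the posterior collapses to a gene-mean predictor.
  The defaults (30 NNKAE / 1000 VAE steps) were chosen so training
  converges on matrices of a few hundred to a few thousand cells;
  under-training shows up as distorted latent geometry (unequal
  centroid spacing for planted equidistant populations) well before it
  shows up in the loss.
* **Non-negativity** of the NNKAE is enforced by projection (clamp at
  zero) after every step, plus a small decoupled weight decay so genes
  that never receive reconstruction gradient (e.g. all-zero columns)
  decay to the bottom of the score ranking.
* **Smell transform.** `S = 1/(sqrt(X² + Y²) + eps_smell)` — the
  original fruit-fly form (reciprocal distance) with an additive pole
  guard; the alternative grouping `1/(X² + Y² + eps)` is a typographic
  possibility but is not used. `S = 0.5` exactly maps to bit 0; an
  all-zero mask is repaired to all ones so a consensus is always
  defined.
* **Fly bounds** `[0, 2]`: distance 0 gives `S ≫ 0.5` (bit 1) and the
  corner gives distance `2√2` (bit 0), so both mask states are reachable
  and the initialization straddles the 0.5 threshold. Coordinates are
  clamped to the box after both initialization and olfactory steps.
* **`omega` schedule.** `omega = alpha^((FEs-1)/MaxFEs)` *increases*
  from 1 to `alpha`: steps get larger late. With clamping this turns
  the late phase into near-uniform corner sampling — effectively a
  global re-exploration — while the early phase searches near the
  incumbent best. This is the schedule as specified; note it inverts
  the usual explore-early narrative.
* **Dominance bookkeeping.** The subswarm best is replaced only when
  strictly Pareto-dominated; among several dominating challengers the
  tie-break is smaller Dev, then smaller Cp, then lower fly index. An
  implementation that also lets merely non-dominated smaller-Dev
  candidates capture the best slot turns the bi-objective search into a
  lexicographic Dev-minimizer and measurably degrades consensus
  quality; it was removed.
* **Ring exchange.** The migrant from subswarm `i` overwrites the first
  fly of subswarm `i+1` with its coordinates and mask; its objective
  pair is invalidated and re-evaluated in the destination subspace at
  the start of the next iteration. The destination's best is untouched
  until the migrant dominates it, preserving elitism.
* **ECI normalization after pruning.** `theta · D · N` with `N` taken
  as the mean per-subspace partition count, i.e. `theta ·` (total
  partitions); exact for balanced ensembles, graceful for unbalanced
  pruned ones.
* **Ties in agglomeration.** The co-association matrix is converted to
  distances via `1 - ca/max(ca)` with zero self-distance;
  average-linkage merging is performed by `stats::hclust`, which
  resolves equal-height merges deterministically from its input
  ordering, so consensus labels are reproducible.
* **Determinism.** Every stochastic stage derives its seed from the
  master seed and its structural indices (subspace, run, iteration,
  fly) with a fixed 32-bit linear congruential hash; identical
  configuration and seed give bitwise-identical labels on all
  platforms using R's default RNG.

## The synthetic-data generator

`simulate_counts()` emulates the stylized facts the pipeline must cope
with: log-normal baseline gene means, *disjoint* per-cluster blocks of
differentially expressed genes shifted by `±lfc` (disjointness makes
planted populations approximately equidistant, which is what
"cluster-specific markers" means geometrically), negative-binomial
overdispersion (`variance = mu + dispersion·mu²`), and logistic dropout
whose probability decays with `log1p(mu)`. Defaults (500 cells, 1500
genes, k = 3, `de_frac = 0.1`, `lfc = 1.5`, `dispersion = 0.3`,
`dropout_mid = 1`) describe a modest droplet experiment.
`simulate_latent_blobs()` provides isotropic Gaussian clusters for
testing the clustering core without autoencoder training; separation is
measured in units of the within-cluster standard deviation, with 10
used as the fully separable regime (base clusterers recover labels
exactly) and 2–4 as overlapping regimes.

What the generator does *not* emulate: batch effects, trajectories or
other continuum structure, gene-gene correlation beyond cluster means,
and ambient RNA. Tests passing on these simulations therefore certify
the algorithmic contracts — not performance on tissue atlases.

## Behavior of pruning under corruption: an honest account

The test suite includes an experiment in the spirit of
"many could be better than all": ensembles on separable 3-blob latent
data (600 cells, 3 subspaces, 10 members each) with 3 members per
subspace replaced by label-shuffled copies. Two findings are worth
recording.

First, the locally weighted consensus is itself highly robust: a
shuffled member's clusters receive ECI weights roughly 15-fold smaller
than intact clusters, so the full-ensemble consensus is typically
unchanged by the corruption, and the pruned consensus can only match it
(the experiment asserts non-inferiority, which holds in all seeds).

Second, *because* the full-ensemble consensus is already optimal in
this regime, its (Dev, Cp) pair is not strictly dominated by any mask,
and the dominance-gated optimizer — whose initial fly encodes the full
ensemble — correctly refuses to move: corrupted members are then *not*
excised from the masks. They are excised in overlapping regimes
(separation 3.5–4), where dominating masks exist; but there the
Dev/Cp-minimal masks also drift from the ground-truth labeling, since
compactness objectives and external agreement part ways once clusters
overlap. This tension is a property of the method, not of the
implementation: pruning pays off exactly in the window where base
partitions are good but the consensus is not yet saturated.

## Problem sizes

The test suite and the reproduction script run entirely on simulated
data at desk scale, chosen to exercise every code path while keeping a
full run in minutes on one CPU core: oracle comparisons at n ≤ 60,
spectral-reduction checks at n = 30, pruning experiments at n = 400–600
with the reference optimizer budget (20 iterations, 9 flies), and
end-to-end runs at n = 600–1000 cells × 1200–1500 genes. The
`estimate_k()` scan uses a reduced budget per candidate k (5 optimizer
iterations, 3 base runs per subspace, 200 representatives) — the
mean-silhouette curve is insensitive to the extra optimizer budget on
these problems, and the full budget remains available via arguments.

## Known limitations

* The autoencoders are trained full-batch; beyond ~10⁴ cells, memory
  and time favor minibatch training, which is not implemented. The SVD
  embedding (`embedding_mode = "svd_fallback"`) is the pragmatic route
  for large matrices.
* `k` must be supplied or estimated by the MSC scan; there is no
  model-based selection.
* The bi-objective pair (Dev, Cp) rewards geometric compactness; on
  data whose populations are not compact in latent space (trajectories,
  nested subtypes), the direction indicator can only flip the sign, not
  change the geometry.
* The co-association matrix is dense (`n × n`); above ~10⁴ cells the
  consensus stage dominates memory.
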
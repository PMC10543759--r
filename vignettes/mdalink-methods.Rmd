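---
title: "Predicting microbe–disease associations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbe–disease associations: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdalink)
```

## The problem

Curated microbe–disease association (MDA) databases record which microbial
taxa have experimental evidence of involvement in which human diseases.
These matrices are small and very sparse — a few hundred confirmed links
over tens of thousands of possible pairs, a density of roughly 1–4% — and
they contain only *positives*: an absent entry means "not yet studied", not
"no association". mdalink predicts which unobserved pairs are most likely
to be genuine associations, using only the observed link structure (plus
optional precomputed biological similarity matrices).

The pipeline has four stages:

1. **Similarity.** Each disease is described by its row of the binary
   association matrix \(Y \in \{0,1\}^{n \times m}\) (each microbe by its
   column). The Gaussian association-profile kernel (GAPK) similarity
   between two profiles \(V_i, V_j\) is
   \(G_{ij} = \exp(-\theta \lVert V_i - V_j \rVert^2)\) with bandwidth
   \(\theta = n / \sum_i \lVert V_i \rVert^2\) — the standard
   interaction-profile normalization in which an average-norm profile
   contributes a unit-scale exponent. Where a functional similarity matrix
   is supplied, fused similarity is the arithmetic mean of functional and
   kernel values at entries where the functional value is nonzero, and the
   kernel value alone elsewhere. The zero test is exact (no tolerance):
   functional matrices are sparse, and their zeros are structural
   ("no evidence"), not numeric noise. Absent a functional matrix, the
   fused similarity *is* the kernel similarity.

2. **Embedding.** A graph attention autoencoder learns a 64-dimensional
   representation per node on each side. The dense fused similarity matrix
   is sparsified into a k-nearest-neighbor graph (default \(k = 10\), plus
   a self-loop; ties toward the lower index). Each encoder layer transforms
   inputs with a shared weight matrix and tanh, scores each edge with a
   sigmoid attention logit
   \(c_{ij} = \mathrm{sigmoid}(v_s^\top \sigma(W h_i) + v_r^\top \sigma(W h_j))\),
   softmax-normalizes the logits over each neighbor set, and aggregates the
   transformed neighbors with those weights. The decoder mirrors the
   encoder and reconstructs the node attributes. The loss is the squared
   attribute-reconstruction error plus \(\lambda\) times a structure term,
   \(-\sum_{(i,j)} \log \mathrm{sigmoid}(h_i^\top h_j)\), which rewards
   large embedding inner products along graph edges.

3. **Reliable negatives.** Because unobserved pairs are unlabeled rather
   than negative, the classifier's negative class is mined with a spy-based
   positive–unlabeled procedure: cluster the positives with K-means,
   move the most centroid-central \(\lfloor t\,|P| \rfloor\) positives
   (default \(t = 0.15\)) into the unlabeled pool as *spies*, fit a
   gradient-boosted tree ensemble with the remaining positives against
   the unlabeled-plus-spies pool, and keep as reliable negatives every
   unlabeled pair scoring strictly below the minimum spy score
   \(A_{\min}\). Spies are genuine positives, so pairs the scorer ranks
   below all of them are unlikely to be hidden positives.

4. **Classification.** Each pair is represented by the concatenation of
   its microbe and disease embeddings (width 128) and classified by a
   feed-forward network with layers 128–100–100–50–1, ReLU hidden
   activations, a sigmoid output, dropout 0.2 after each hidden layer and
   learning rate 0.001, trained with binary cross-entropy on known
   positives versus the mined reliable negatives.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `embedding_dim` | 64 | per-side embedding width; pair features are 2×64 = 128 |
| `k_neighbors` | 10 | neighbors kept per node when sparsifying the similarity graph |
| `lambda` | 1 | weight of the graph-structure term in the autoencoder loss |
| `t_fraction` | 0.15 | fraction of positives used as spies (0.20 suits corpora an order of magnitude larger) |
| `n_clusters` | 5 | K-means clusters for spy selection |
| `dnn_epochs` | 300 | classifier epochs; large corpora warrant more (e.g. 1500) |
| `learning_rate` | 0.001 | Adam step size for both networks |
| `dropout` | 0.2 | dropout rate after each hidden classifier layer |

One master seed (`mda_config(seed = …)`) is fanned out to every stage by
hashing the stage name, so a single integer reproduces an entire run
bit-identically: weight initialization, K-means restarts, the boosted
scorer (single-threaded), mini-batch order and dropout masks all derive
from it.

## Design choices where the design was open

* **Bandwidth orientation.** The kernel bandwidth is
  \(\theta = n / \sum \lVert V_i \rVert^2\) (reciprocal mean squared
  profile norm), the convention used throughout the interaction-profile
  kernel literature; it makes the kernel scale-free with respect to
  database size.
* **Node attributes.** Each node's attribute row is its association
  profile (a disease's row of \(Y\), a microbe's column). Association
  profiles keep the decoder target binary-like and make the learned pair
  features carry association signal directly. The fused-similarity row is
  a reasonable alternative; the association profile is the default.
* **Autoencoder depth.** One encoder layer (attribute width → 64) and one
  mirrored decoder layer. `hidden_dims` stacks deeper models, but on
  matrices this small extra layers only add variance.
* **Transform activation.** tanh for the layer transforms; the sigmoid is
  reserved for attention logits. Zero-centered transforms stabilize the
  inner-product structure term.
* **Graph sparsification.** Similarity matrices are dense; attention over
  all nodes would drown the signal in near-uniform weights. Top-k by fused
  similarity with a self-loop keeps each neighbor set informative, and the
  lower-index tie-break keeps graphs reproducible.
* **Clustering scope.** Spies are selected by clustering the positive set
  only: only positives can become spies, so clustering the full pair set
  would merely blur the centroids with unlabeled mass.
* **Spy distance.** Distance to the *assigned cluster's* centroid, so a
  positive set with several biological regimes (one cluster per disease
  area, say) supplies central spies from each regime.
* **|RN| is data-driven.** The number of reliable negatives is whatever
  falls below \(A_{\min}\) — it is never forced to match the positive
  count. If the threshold admits no negatives at all (possible on tiny or
  degenerate inputs), cross-validation falls back to random unlabeled
  pairs with a warning rather than aborting the fold.
* **Class imbalance.** The classifier trains on all positives versus all
  reliable negatives without reweighting; mined negative counts are
  typically the same order as the unlabeled pool, and the evaluation
  metrics (AUC/AUPR) are threshold-free.
* **Optimizers.** Adam everywhere (full-batch for the autoencoder,
  mini-batches of 32 for the classifier); binary cross-entropy for the
  classifier, as is standard for a sigmoid output.

## Evaluation protocol

Three five-fold cross-validation regimes: held-out **pairs** (random fifth
of all matrix cells), held-out **diseases** and held-out **microbes**
(cold start — every pair involving a held-out entity is removed). Within
each fold the held-out block of \(Y\) is zeroed and *everything* —
kernel similarity, fused similarity, embeddings, reliable negatives,
classifier — is recomputed from the masked matrix only, so no held-out
label can leak into training. The evaluation is transductive, as in
matrix completion generally: held-out cells re-enter the negative-mining
stage as *unlabeled* pairs (the selection algorithm defines its pool as
all unknown pairs), but their labels are never consulted — indeed the
spy mechanism exists precisely to keep such hidden positives out of the
negative class, and the PU-vs-random ablation measures that effect. Held-out known associations are the test
positives; all other held-out cells are test negatives (not RN-filtered,
keeping test labels independent of the PU step). A fold whose test block
contains no positive is skipped with a warning, which can happen in the
cold-start schemes on sparse data.

Cold-start entities have all-zero training profiles; their kernel
similarities collapse toward the other empty profiles and their
embeddings are driven by the attention structure alone. That is the
masking convention here: deliberately conservative, and the reason
cold-start AUCs run well below pair-scheme AUCs.

AUC is computed from midranks (the exact tie-aware Mann–Whitney
statistic); AUPR by step interpolation over descending score thresholds
with tied scores processed as one block.

## The synthetic generator

`generate_associations()` draws block-dominant nonnegative factors
\(U\) (diseases × rank) and \(V\) (microbes × rank), forms the propensity
matrix \(UV^\top\), thresholds at the \((1-\text{density})\) quantile and
optionally flips a noise fraction. Defaults — 40 diseases × 120 microbes,
rank 4, density 0.04 — emulate a small curated MDA database: the 4%
density matches the sparsity of real curated matrices, and the low-rank
block structure encodes the assumption every pipeline stage relies on,
namely that entities with similar association profiles share links.

What it does **not** emulate: the heavy-tailed degree distributions of
real databases (a few "hub" diseases), taxonomy-structured microbe
correlations, and literature-driven reporting bias. Passing the synthetic
recovery checks therefore demonstrates that the machinery recovers
profile-similarity signal when it exists; it does not certify performance
on any particular real database.

`generate_pu_ground_truth()` builds a harness for the negative-mining
algorithm alone: labeled positives and planted true negatives drawn from
two Gaussians a configurable number of standard deviations apart, plus an
"ambiguous" overlap group drawn midway between the means, standing in for
hidden positives. The ambiguous group defaults to 5% of the unlabeled
pool: in a matrix of ~4% density the hidden-positive rate among unknown
pairs is a few percent, so a small overlap fraction is the realistic
emulation. Reliable-negative *precision* counts only planted true
negatives as correct.

## Numerical choices

* Attention softmax needs no max-shift: logits are sigmoid outputs in
  \((0,1)\), so overflow is impossible.
* `log(sigmoid(x))` is computed as `-log1p(exp(-x))` with a linear branch
  below \(-30\).
* Classifier outputs are clamped to \([10^{-12}, 1-10^{-12}]\) so scores
  are strictly inside \((0,1)\) and cross-entropy never sees a hard 0/1.
* The reliable-negative cut is strictly below \(A_{\min}\); a pair scoring
  exactly \(A_{\min}\) stays unlabeled.
* Matrix text files round-trip at 17 significant digits (bit-exact for
  doubles).
* All tie-breaks (neighbor selection, spy distance, candidate ranking) are
  deterministic: lower index or alphabetical order.

## Problem sizes used by the test suite

The package's checks run on generated data sized so the full suite
completes comfortably on one CPU: the end-to-end cross-validation checks
use the 40 × 120 generator defaults with 80 autoencoder epochs and 40
classifier epochs. These shortened training lengths are a deliberate
scaling choice for matrices of this size — with ~190 positives both
networks converge far earlier than on a database-scale corpus, and the
published-scale defaults (200/300) remain the package defaults for real
use.

## Worked example

```{r example, eval = FALSE}
gen <- generate_associations(synthetic_spec(seed = 7))
cfg <- mda_config(seed = 11, gate_epochs = 80L, dnn_epochs = 40L)

cv <- run_cv(gen$assoc, cfg, scheme = "pair", repeats = 2L)
glance(cv)

fit <- fit_mda(gen$assoc, cfg)
rank_candidates(fit, "disease_01", top_k = 10L)
```

## Known limitations

* On the synthetic generator the reliable-negative step does **not**
  improve over random negatives: the quantile-thresholded propensity
  construction puts the most informative (hard) negatives just below the
  decision boundary, and the spy threshold excludes exactly those
  high-scoring cells from the negative class while there are few hidden
  positives to protect. The benefit reported for spy-based selection on
  real databases rests on meaningful hidden-positive contamination and a
  soft class boundary — features the noise-free generator deliberately
  lacks. The ablation machinery (`ablate_pu()`) quantifies this honestly
  in both directions.
* Cold-start predictions for entities with empty training profiles rest
  on attention structure alone and are markedly weaker — as cold-start
  link prediction generally is.
* The autoencoder is transductive: nodes absent at training time cannot
  be embedded without refitting.
* Functional similarity matrices are accepted as input but never
  computed; their provenance (genome co-occurrence, shared genes or
  symptoms) is upstream of this package.
* Single-thread determinism is part of the contract; the package does not
  parallelize across folds.
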
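---
title: "Joint KG and text embedding for rich DDI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint KG and text embedding for rich DDI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most computational drug–drug interaction (DDI) methods predict a single
binary outcome per drug pair. Clinically, the interesting question is
*richer*: which pharmacological mechanisms and adverse outcomes describe the
interaction — "enhanced anticoagulant effect", "bleeding", "bradycardia"?
`prddi` treats a DDI as a **multi-label relation** between two drug
entities in a drug knowledge graph (KG), where the label set is drawn from a
fixed vocabulary harvested from biomedical text. Prediction becomes a link
prediction problem in a jointly learned embedding space.

The KG has two layers:

* **Basic triples** `(h, r, t)` — curated biological facts over four entity
  kinds (drugs, proteins, pathways, phenotypes) connected by five relation
  types (`hasTarget`, `hasEnzyme`, `hasTransporter`, `isPresentIn`,
  `isImplicatedIn`).
* **Rich DDI triples** `(u, l, v)` — a drug pair together with a label set
  `l ⊆ L`. DDI relations are undirected; the graph stores each one as two
  directed triples of opposing directions with the same label set. This
  convention matters below.

# The model

## Basic triple encoder

Entities are embedded as vectors in `R^k`, relations in `R^d`, and each
relation `r` carries a projection matrix `M_r ∈ R^{k×d}` mapping entity
space into its relation space (the TransR mechanism). A triple is scored by

```
z_bte(h, r, t) = b1 − || h M_r + r − t M_r ||      (L1 or L2 norm)
```

so the score is maximal (`b1`) exactly when the projected head translates
onto the projected tail.

## Rich DDI triple encoder

A DDI label set is binarized over the vocabulary into `s ∈ {0,1}^|L|` and
compressed by a deep autoencoder. The encoder applies two tanh layers; the
code layer activation is the DDI relation embedding `l ∈ R^d`. Scoring then
reuses the translational form with one shared projection `M_l`:

```
z_dte(u, l, v) = b2 − || u M_l + l − v M_l ||
```

The decoder maps the code back to a reconstruction `ŝ ∈ (0,1)^|L|`
(tanh hidden layer, logistic output). Because zero labels vastly outnumber
nonzero ones, the reconstruction score weights components by
`x_i = β > 1` where `s_i = 1` and `x_i = 1` elsewhere:

```
z_rcl(s, ŝ) = b3 − || (s − ŝ) ⊙ x ||
```

Without the weights the decoder collapses to reconstructing zeros.

### Sign-invariant decoding

One design decision deserves emphasis. DDI relations are stored in both
directions, so during training the translational term pulls the code of a
label set towards `+ΔM` and `−ΔM` simultaneously, where `ΔM = vM_l − uM_l`.
Under the L1 norm the equilibrium constrains the coordinate *magnitudes* of
the code to those of `ΔM`, but leaves every coordinate *sign* unidentified
(for any target the pull towards `+ΔM` exactly cancels the pull towards
`−ΔM` inside the coordinate box). A decoder that reads signed codes
therefore cannot generalize to predicted embeddings, however well the
entity geometry itself is learned.

`prddi` therefore makes decoding invariant to the ambiguity that the
symmetric storage creates: the code layer takes the **magnitude** of its
tanh activation (codes are nonnegative), and the decoder consumes
coordinate-wise magnitudes of its input. Training and prediction then live
in the same identifiable space.

## Joint objective, negative sampling, optimization

The joint objective sums the three log-likelihood surrogates and subtracts
soft norm constraints weighted by `γ`:

```
O = L_bte + L_dte + L_rcl − γ C,
C = Σ_e [||e||² − 1]_+ + Σ_r [||r||² − 1]_+ + Σ_(e,r) [||e M_r||² − 1]_+
```

with the projection penalty over entity–relation pairs observed in the
training graph (including the shared DDI projection for drugs in DDI
triples). Exact normalizers are intractable, so every conditional is
replaced by the negative-sampling surrogate
`log σ(z(pos)) + Σ_j log σ(−z(neg_j))` with `c` corruptions per positive:

* basic triples: head, relation and tail slots are each corrupted
  (uniform draws over entities, or relations for the relation slot);
* DDI triples: both drug slots (uniform over drugs) **and the relation
  slot**, by substituting the codes of other observed label sets;
* reconstruction: corrupted label vectors obtained by flipping
  `min(5, |L|/10)` random components of `s`.

Corruptions that reproduce a training triple are rejected and resampled
("filtered" sampling), avoiding false negatives. The relation-slot
corruption of DDI triples is the term that couples the code space to the
projected drug geometry across clusters of label sets: it is the only term
whose gradient discriminates between the code of the observed label set and
codes of other label sets at a fixed drug pair.

Optimization is mini-batch Adam (ascent), batches split proportionally
between basic and DDI triples, with inverted dropout on the autoencoder's
hidden layers during training. The returned parameters are the tail
(Polyak) average over the final quarter of iterations, which removes most
of the stochastic jitter of the L1 sign gradients. Everything is
deterministic given the seed.

All gradients are analytic (hand-derived backpropagation through the
scores, the autoencoder and the constraints) and are verified against
central finite differences to relative error below `1e-5` in the test
suite.

## Prediction

For a candidate pair `(u, v)` the relation embedding is predicted by pure
translation, `l = v M_l − u M_l`, and decoded into per-label scores; labels
are returned top-n or above a threshold. Ranking evaluation follows the
standard raw/filtered protocol: each correct label is ranked against the
whole vocabulary (raw), and after removing the triple's other correct
labels (filtered); ties resolve pessimistically (worst rank in the tie
group), so a constant decoder cannot inflate Hits@k. MeanRank averages over
all correct-label ranks; Hits@k is reported ×100.

Binary DDI classification follows the concatenated-embedding protocol: a
logistic regression (`stats::glm`) on `(u, v)` embedding concatenations of
training pairs versus sampled non-DDI pairs, evaluated on held-out pairs by
threshold-sweep ROC (trapezoidal area) and precision–recall (step-wise
interpolated area) curves. Because pairs are unordered while the feature
vector is ordered, both orientations enter training and a test pair's
score averages its two orientations.

# Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `k`, `d` | entity / relation dimension | 100 / `k` | reference configuration; `d` defaults to `k`, the simplest consistent choice |
| `b1`, `b2`, `b3` | score offsets | 5, 5, 1 | reference configuration |
| `beta` | weight on nonzero labels | 5 | must exceed 1; moderate upweighting of the rare nonzero labels |
| `c_neg` | negatives per positive | 10 | reference configuration |
| `gamma` | soft-constraint weight | 0.01 | reference configuration |
| `lr` | Adam learning rate | 0.001 | reference configuration |
| `norm` | dissimilarity norm | L1 | reference configuration |
| `dropout` | autoencoder hidden-layer dropout | 0.2 | standard choice, configurable |
| `iterations` | Adam steps | 1000 | full-scale reference count; the synthetic benchmark uses 8000 (see below) |
| `batch_size` | positives per batch | 128 | standard choice |

On the bundled synthetic benchmark (200 entities, k reduced to 20) the
model converges more slowly per unit data than at full scale, so the
benchmark runs use 8000 iterations of batch 128; with the vectorized R
implementation that is a few minutes on one CPU.

# The synthetic benchmark

Real inputs at the scale of public drug KGs and annotated DDI corpora
cannot ship with a package, so `prddi` includes a generator with *known
planted structure* that exercises every stage:

* **Translational geometry.** Drugs live in a small number of tight
  communities placed at scaled coordinate vectors; proteins, pathways and
  phenotypes hang off the communities through latent relation vectors, so
  every sampled basic triple satisfies
  `latent(t) ≈ latent(h) + latent(r) + N(0, noise_sd²)`. Consistent triples
  are enumerated and sampled without replacement, and with `noise_sd = 0`
  every triple scores exactly `b1` under the generating latents.
* **Label clusters.** Each DDI cluster is a distinct unordered community
  pair (distinctness matters: with bidirectional storage, `±Δ` must still
  identify the cluster) and owns a core label set of size `labels_per_ddi`.
  A pair carries its cluster core with each label independently swapped for
  a random outside label with probability `1 − sqrt(0.8)`, so two core
  labels co-occur with probability 0.8.
* **DDI-carrying drugs.** Only a fraction (default 0.25) of drugs carry
  DDI records, mirroring real KGs where most drugs have no interaction
  sentence. This is also what gives the binary task a learnable margin: if
  every drug could interact, most community pairs would be potential DDI
  classes and random negative pairs would be indistinguishable from unseen
  positives at any model's information ceiling.
* **Sentences.** One synthetic sentence per pair embeds the planted labels
  as content tokens among stop words and zero-IDF fillers, so the TF-IDF
  extraction stage recovers them.

What passing on this benchmark does **not** show: robustness to the noise,
incompleteness and scale of real KG extracts; entity-linking quality
(the alias table is a stand-in); or the realistic long-tailed label
distribution of curated corpora. The generator plants exactly the structure
the model class can represent; real-data performance claims require real
data.

# Numerical choices and degenerate inputs

* L1 norms use sign subgradients; the hinge constraints use subgradient 0
  at the boundary. Finite-difference checks are run at generic points.
* Initialization: entities/relations uniform `(−6/√k, 6/√k)`, then
  row-normalized to unit L2 norm; projections identity plus `N(0, 0.01)`;
  autoencoder weights Glorot-style; all seeded.
* Softmax in `conditional_probability()` subtracts the maximum score
  before exponentiation.
* Ties in label ranking give the correct label the worst rank of its tie
  group; top-n selection breaks ties lexicographically.
* Degenerate inputs fail fast with typed conditions: self-interactions,
  labels outside the vocabulary, empty corpora or candidate sets, rates
  outside `[0,1]`, exhausted negative-sampling pools, non-finite training
  objectives (reported with the iteration number).
* A run with `rate = 0` returns the full graph for training and empty test
  sets; a KG with a single relation type skips relation-slot corruption
  (a corruption pool of one cannot produce a valid negative), as does a
  DDI set with a single distinct label set for the label slot.

# Known limitations

* Training is dense R matrix algebra; it is comfortable at hundreds of
  entities and thousands of triples, not at millions.
* The relation embedding of a pair is identifiable only up to coordinate
  signs (bidirectional storage); the sign-invariant decoder resolves
  prediction, but other downstream uses of raw codes should respect the
  same invariance.
* Entity linking is a case-insensitive alias lookup, not a disambiguation
  model.
* The binary classifier is plain logistic regression on concatenated
  embeddings by design (comparability), not a tuned classifier.
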
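---
title: "Embedding heterogeneous pharmaceutical knowledge graphs with textual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding heterogeneous pharmaceutical knowledge graphs with textual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmakg)
```

## The problem

Pharmaceutical knowledge bases link drugs to the proteins they target, the
pathways they act in, the MeSH categories and ATC codes that classify
them, and — through drug–drug interaction records — to each other. Viewed
as a typed, directed multigraph of `(head, relation, tail)` triples, such
a knowledge graph (KG) supports *link prediction*: ranking candidate
entities to complete `(h, r, ?)` or `(?, r, t)`, the computational
backbone of interaction screening and drug repurposing. Most of these
entities also carry free text (names, descriptions, synonyms, indications)
that ordinary KG-embedding pipelines ignore. `pharmakg` implements the
full pipeline — schema, scoring functions, losses, training, filtered
evaluation — together with three ways of injecting entity text into
embedding learning, and synthetic generators that make every component
testable offline.

## Data model

The schema has five concrete entity types (`drug`, `protein`, `pathway`,
`category`, `atc`) plus `text_node` for augmented graphs, and eight
evaluated relations: `category` (drug → MeSH term), `atc` (drug → ATC
code at *every* level of the code's five-level hierarchy), `pathway`
(drug/protein → pathway), the symmetric `interact` (drug → drug), and
`target`/`enzyme`/`carrier`/`transporter` (drug → protein). A ninth
relation, `atc_hypernym`, links each ATC code to its next-higher level
(`A10BA → A10B`, `N02 → N`); because the hierarchy is readable off the
code strings it is excluded from link prediction and always assigned to
the training partition. Symmetry is materialized: the closure adds
`(b, interact, a)` for every `(a, interact, b)`.

Two decisions here were genuinely open:

* **Split leakage.** We stratify the 90/5/5 split per relation and force
  both directions of an interact pair into the *same* partition;
  otherwise every test interact triple has its mirror in train and the
  task is trivial. With pairs moving as units, per-relation partition
  sizes can land one unit off the 5% target (they stay within one pair).
* **Evaluation candidates never pair an entity with itself**: when
  ranking replacements for one side, the other endpoint is excluded.
  During *negative sampling*, only the corrupted side's original entity
  is excluded, so a self-pair can occur as a (false) training negative.

## Scoring functions

Four scorers cover the standard families — translational, bilinear,
complex, and role-factorized:

* TransE: \(f(h,r,t) = -\lVert h + r - t \rVert_2\) (L2 norm),
* DistMult: \(f(h,r,t) = \sum_i h_i r_i t_i\), symmetric in \(h, t\),
* ComplEx: \(f(h,r,t) = \mathrm{Re}(\sum_i h_i r_i \bar t_i)\) over
  complex vectors,
* SimplE: \(f(h,r,t) = \tfrac12(\langle h^{head}, v_r, t^{tail}\rangle +
  \langle h^{tail}, v_{r^{-1}}, t^{head}\rangle)\).

ComplEx is implemented with the tail conjugated, the form under which the
scorer can represent asymmetric relations; without the conjugate it
degenerates to a symmetric bilinear form, which would be useless for the
seven asymmetric relations of the schema. A `conjugate_tail = FALSE`
switch exposes the unconjugated variant for comparison. Embeddings are
initialized i.i.d. uniform on \(\pm(\gamma+\epsilon)/d\) with
\(\gamma = 12\), \(\epsilon = 2\) — about \(\pm 0.018\) at the default
\(d = 768\), which matches the output width of a BERT-style sentence
encoder so that text vectors can seed the tables directly.

## Losses, negative sampling, training

Per positive triple, `negatives_per_positive` corruptions are drawn,
alternating head- and tail-side. With *type filtering* on (the default)
replacements are restricted to entity types the relation admits on that
side, so a `drug-interact-category` negative can never arise; corrupted
triples may still coincide with unregistered true facts — that is
inherent to local-closed-world training and deliberately not prevented.

Two losses are available, defaulting to the convention of the scorers'
original papers: margin ranking loss
\(\sum \max(0, \gamma - f^+ + f^-)\) for TransE and DistMult, logistic
loss \(\sum \log(1+e^{-y f})\) for ComplEx and SimplE, both with L2
regularization \(\lambda\lVert\Theta\rVert_2^2\). The logistic sign
convention rewards positives for high scores; a `strict_eq5` flag flips
the sign inside the exponential for the (clearly typographical) variant
in which the loss grows with positive scores. The margin \(\gamma\)
defaults to 12 and the negative count to 64; neither is prescribed
anywhere, so both are exposed as configuration.

The optimizer is mini-batch Adagrad (per-parameter adaptive rates,
initial rate \(\alpha_0\)), the default of the KG-embedding toolkits this
design follows; plain SGD is available by configuration. The L2 and
alignment penalties are applied *lazily* — their gradients are added only
for rows the current batch touches — which is the standard sparse-update
treatment; the loss **values** recorded in the per-epoch trace use the
exact full-table expressions. Training aborts with a diagnostic on a
non-finite loss and is bit-reproducible under `config$seed`.

## Injecting text

A `text_encoder` is any object with a dimension and a deterministic
`encode(text)`; the bundled `hashed_encoder()` maps each token to a
seeded pseudo-random unit vector and returns the L2-normalized mean over
the first 512 tokens. It models exactly the property the three methods
below need — lexically overlapping texts get nearby vectors — while
remaining fast, dependency-free and deterministic; an external
transformer encoder can be substituted behind the same contract. Text is
resolved per entity and field, joining multiple items with `", "` and
falling back to the entity's name when the field is absent (names have
100% coverage by construction, so the fallback is total).

* **Initialization** writes each entity's text vector over its embedding
  before training; both vectors of two-vector scorers receive the same
  copy. Relation vectors stay random.
* **Alignment** adds \(L_a = \lambda_a \lVert V_{KG} - V_{text}\rVert^2\)
  to the loss, pulling entity tables toward the frozen text vectors
  (both tables for two-vector scorers; no gradient flows into the
  encoder).
* **Augmentation** adds one `text_node` per *(field, exact text)* pair an
  entity natively carries (no name fallback here — a fallback node would
  duplicate the name's node) and a train-only `has_<field>` edge to it.
  Nodes are content-addressed and deduplicated, so two drugs sharing a
  synonym share a node and thereby graph structure; text nodes remain
  trainable after their text-vector initialization. Ablating a field
  removes exactly that field's nodes and edges.

## Evaluation

For every validation/test triple both sides are ranked. The candidate set
starts from all entities minus the fixed endpoint, optionally drops
wrong-typed entities (type-aware setting) and entities completing *other*
registered triples (filtered setting); the true entity always remains.
Ranks use the mean-rank tie policy
\(1 + \#\{f > f_{true}\} + \tfrac12\#\{f = f_{true}\}\) — an optimistic
policy would award rank 1 to a constant scorer, which is why an untrained
model here scores the expected \((n+1)/2\). Per-relation MRR pools head
and tail observations; the macro average weights relations equally
(interact dominates micro otherwise) and `run_grid()` wraps
train/evaluate over scorer × text-method × hyper-parameter combinations,
selecting by validation macro-MRR.

## Synthetic generators and what they do (not) show

Real pharmaceutical KGs are licensed and huge, so the package ships two
generators at study scale — roughly 250 entities over all five types and
2,000 triples, dominated by `interact`, with a five-level ATC-like code
system and heavy-tailed category degrees.

`generate_planted_kg()` samples a ground-truth model and declares, per
head, its top-`m` type-valid tails true, then closes `interact`
symmetrically. Two design points matter:

* The truth's entity vectors are drawn around a small number of per-type
  cluster centroids (`n_clusters = 6`, within-cluster spread 0.1). With
  fully random truth vectors the planted relation matrices have effective
  rank ≈ d, and completing them from the 2–5 observed edges per head is
  information-theoretically hopeless — no trainer could pass a recovery
  test. Clustered truth drops the effective rank below the observation
  density while keeping the nominal dimension at 16.
* Every head contributes its *entire* top-`m` set (the per-relation depth
  is derived from the triple budget). A true-but-unregistered pair would
  compete unfiltered at evaluation time and cap the attainable filtered
  MRR well below 1 regardless of model quality.

At these conditions (d = 16, 100 epochs, batch 512, 8 negatives,
\(\alpha_0 = 0.25\)) all four scorers reach held-out filtered macro-MRR
around 0.7–0.9 against untrained baselines near 0.07 — the
parameter-recovery check in the test suite.

`generate_lexical_kg()` puts the signal in the text instead: categories
and ATC codes own distinct token bundles, and each drug's description
contains its linked categories' name tokens with probability
`text_signal` (filler tokens otherwise) — the mechanism by which a drug
description that mentions, say, its stereochemistry class lexically
matches the category entity's name and synonyms. Category memberships
follow a power law (default exponent 1.2; 1.5 in the text-utility
experiment), so most categories have very few edges and structure alone
cannot place them. The text-utility experiment (sparse category budget of
60 edges, DistMult, \(\alpha_0 = 0.05\), 100 epochs, three seeds)
shows text-vector initialization lifting category-relation test MRR by
roughly +0.15 to +0.27 at `text_signal = 0.9`, with the gap collapsing
to noise at `text_signal = 0`. The lower learning rate keeps the
initialization from being washed out before the sparse category edges
are revisited — with aggressive rates the benefit disappears, which
mirrors the practical sensitivity of initialization-based methods.

What passing these tests shows: the estimator ranks planted facts far
above chance, the text channels propagate lexical signal, and the
bookkeeping (filtering, closure, train-only augmentation) is exact. What
it does not show: behaviour on real, noisy, million-triple graphs with
incomplete text coverage, polysemous tokens, or a fine-tuned transformer
encoder — the synthetic text is clean, the truth is genuinely low-rank,
and graph sizes are three orders of magnitude smaller.

## Numerical choices and degenerate inputs

* TransE's gradient divides by the distance; a guard floor of 1e-12
  avoids 0/0 at exact translation.
* `log(1+e^x)` switches to its asymptote above x = 30.
* Adagrad's accumulator is offset by 1e-10.
* `epochs = 0` returns the initial model with an empty trace; an empty
  relation yields an empty degree histogram; ranking with an empty
  candidate set or evaluating an empty partition raises.
* Checkpoints store vocabulary hashes and refuse to load on mismatch.
* Ties in ranking are exact floating-point equalities; the mean-rank
  policy makes them well-defined rather than order-dependent.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on the
generators: scoring oracles at d ≤ 8 on ~1,000 instances; recovery at
~250 entities / ~1,950 triples / d = 16 / 100 epochs per scorer; the
text-utility comparison over 3 seeds × 2 signal levels; a million
sampled negatives for the type-filter check. These sizes were chosen as
the smallest at which each effect is unambiguous.

## Known limitations

* The DrugBank-like XML parser targets the documented fixture dialect
  only; it is not a general DrugBank reader.
* No Hits@K or mean-rank metrics; MRR (per-relation, macro, micro) only.
* No GPU or compiled kernels: pure R matrix operations, adequate at
  synthetic scale but not for multi-million-triple graphs.
* Early stopping is out of scope; model selection across configurations
  is the harness's job (`run_grid()`), not the trainer's.
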
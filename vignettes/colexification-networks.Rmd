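---
title: "Colexification networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colexification networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colexnet)
library(dplyr)
```

This vignette documents the models and procedures behind `colexnet`, the
parameters that matter, the synthetic data the package tests itself
against, and the design decisions taken where more than one defensible
choice existed.

## 1. From wordlists to networks

The atomic datum is a *form record*: one attested word for one concept in
one language variety. A *full colexification* is attested in a variety
when two distinct concepts share at least one identical word form after
normalisation (lower-casing, whitespace collapsing, removal of
parenthesised annotations). This is deliberately strict: partial
colexification — shared morphemes inside compounds, e.g. *eye-water* for
tears — is out of scope, because morpheme segmentation is unreliable
across heterogeneous sources and whole-form identity is the conservative,
reproducible criterion.

Two tunable parameters govern detection:

- `min_form_length` (characters, default **2**). Single-character forms
  match each other by chance far too easily across a 30-odd-symbol
  orthography; requiring two characters suppresses most chance identity
  at negligible cost in recall.
- the inclusion filters: datasets need at least **250** distinct concepts
  (so that concept coverage gaps are sampling noise rather than
  structure), and a concept enters the analysis only when at least
  **10** families each attest at least **5** word forms for it. The
  filter sentence admits a second reading (5 words *in total* across 10
  families); both are implemented (`filter_concepts(rule = )`), with the
  per-family reading as default because the filter exists to guarantee
  per-family evidence for family-level networks. All bounds are
  inclusive.

Edges carry three counts: attesting varieties, attesting families, and
cognate sets (below). A variety contributes at most 1 to the variety
count of a pair even when several shared synonym forms exist, because the
unit of observation is the variety, not the form. Family subnetworks
recount all edges from that family's witnesses only and weight edges by
the within-family variety count.

## 2. Cognate-corrected counts

Counting varieties overstates the evidence for a colexification wherever
it arose once and was inherited: dozens of related varieties may all
continue a single ancestral innovation (the *lima/nima* 'hand–five'
pattern). The correction clusters each edge's witness forms *within each
family* into cognate sets and replaces the per-family contribution by the
number of sets.

The clustering is deliberately simple and fully declared:

- **distance**: Levenshtein distance over phonetic segment tokens (or
  characters when no segmentation is available), divided by the longer
  length — symmetric, in [0, 1];
- **linkage**: single linkage, i.e. connected components of the graph
  linking witnesses at distance ≤ `threshold`; this is the only flat
  clustering with no tie-breaking behaviour;
- **threshold**: default **0.45**, the conventional cutoff for
  segment-edit-distance cognate screening.

State-of-the-art cognate detection uses sound-class alignment scores;
the edit-distance variant here trades some accuracy for determinism,
total applicability (it never fails on unsegmented forms) and exact
testability against brute-force component enumeration. Two boundary
properties anchor it: at threshold 0 only identical forms cluster, and at
threshold 1 every family collapses to one set; in between, the number of
sets is monotone in the threshold. Importantly, the *edge set* of a
network never depends on the threshold — only `cognate_set_count` does —
so descriptive network structure is threshold-invariant by construction.

## 3. Communities

Two algorithms serve two purposes. **Infomap** (two-level, weighted,
undirected, 100 optimisation trials at a fixed seed for stability on
small sparse graphs) produces the descriptive partitions used to colour
networks. **Walktrap** with walk length 5 — "5-step random walk" —
produces the partitions used for cross-family comparison, cut at maximum
modularity; it is deterministic given the graph, which matters when 190
family pairs must be compared reproducibly.

Partitions are *canonicalised*: labels are contiguous integers from 0,
with communities ordered by their smallest member concept id under a
fixed byte-order string sort. Canonical labels are a pure function of the
(membership, node-name) mapping, so node insertion order cannot leak into
results. Isolated nodes are retained as singleton communities rather than
dropped: node sets must stay aligned across families, and downstream
comparisons use attestation (degree ≥ 1), not membership, to decide what
to compare.

## 4. Comparing partitions across families and domains

For each unordered family pair within a domain, both partitions are
restricted to concepts attested (degree ≥ 1) in *both* family networks;
pairs sharing fewer than `min_shared = 3` such concepts are skipped, since
chance-corrected indices on one or two nodes are degenerate. On the
restriction we compute:

- **ARI** — Hubert–Arabie, from the contingency table;
- **AMI** — with the *exact* expected mutual information under the
  fixed-margins hypergeometric model and arithmetic-mean normalisation
  (the most common convention; the choice is recorded because other
  normalisations — min, max, geometric — exist and differ on unbalanced
  partitions).

Degenerate denominators (both partitions trivial) return 1 for identical
structures and 0 otherwise, matching the limiting behaviour of the
adjusted indices. Welch's unequal-variance *t*-test compares the pairwise
ARI distributions between domains; it is run on the pairwise values (the
per-family aggregation is available to the user as an ordinary dplyr
summary) and no multiple-testing correction is applied, as only three
domain contrasts exist.

Because the domain networks are sparse, a complementary **weighted-degree
resampling** is provided: per trial, one node sample of size `n` is drawn
uniformly without replacement from the domain's concept pool and applied
to *all* of that domain's family networks; each family scores the summed
weighted degree of sampled nodes divided by its variety count, making
families of very different sizes comparable. One sample per trial per
domain (rather than fresh samples per family) keeps family scores within
a trial comparable. The default `n` is the domain's concept-list size;
analyses in this package's own scripts pass `n` = the number of attested
nodes per domain instead, which leaves room for sampling variation while
still covering most of the network.

## 5. Perceptual features and homelands

Each colexified pair can be coded 0/1 for three perceptual features:
*contiguity* (parts adjacent on the body), *function* (parts cooperating
in action), *shape* (visual similarity). Multiple coding is allowed — a
pair may be contiguous *and* functionally linked — so per-family feature
counts can sum to more than the number of pairs, and proportions are
normalised by the summed feature counts. The packaged coding table
contains the two attested codings documented in the literature
(hand–arm: contiguity 1, function 1, shape 0; head–knee: contiguity 0,
function 0, shape 1) plus clearly-labelled synthetic placeholder rows for
other frequent pairs; it is a fixture, and real analyses should supply a
complete coding file in the same TSV dialect.

Family homeland points are computed as recursive spherical centroids:
coordinates become 3-D unit vectors, groups are averaged bottom-up
through the (optional) subgroup tree, renormalised and converted back.
The 3-D mean is used rather than naive lat/lon averaging because the
latter misbehaves at the antimeridian; an exactly antipodal configuration
has no defined mean and is an error. Snapping to the nearest point on
land needs a coastline resource; it is exposed as a pluggable `snap_fun`
hook (off by default, recorded in the `method` column) so the package
stays download-free — homelands serve visualisation, not inference.

## 6. The synthetic-data generator

`simulate_wordlist()` emulates exactly the generative structure the
cognate correction assumes:

- families of varieties related by uniform random rooted binary trees
  (branch lengths are implicit: mutation applies per edge, which is all
  the pipeline ever sees);
- per-concept family proto-forms over a 20-symbol segment alphabet,
  length 3–6 (chance identity of independent forms < 1e-4), mutating by
  per-segment substitution along each edge;
- *vertical* colexification events that activate on a random tree edge
  and propagate to all descendants as cognate copies; additional planted
  origins of the same pair innovate fresh, deliberately distant forms on
  disjoint subtrees — two origins sharing the proto-form would be
  genuinely cognate and *should* be merged by any correct counter, so
  distinct origins must be lexically distinct to be recoverable;
- *independent* events that make single varieties colexify with fresh
  forms; and per-cell coverage gaps.

The ledger records every planted event, the surviving colexifications,
realized origin counts and planted homelands, sufficient to score every
pipeline output exactly. What the generator does **not** model: real
phonology and sound correspondences, borrowing and contact, semantic
shift, or areal structure in coverage. Passing recovery tests on this
generator therefore demonstrates correctness of the counting and
clustering machinery under the model's own assumptions — not robustness
of the edit-distance heuristic on real transcription data, where
sound-class methods are known to be stronger.

`planted_partition_network()` and `simulate_family_networks()` provide
the community-detection counterpart: per-family weighted graphs drawn
from planted block partitions, either shared across families (a
"body-part-like" domain, whose structure is largely universal) or
independent per family ("emotion-like"). On these conditions the package
reproduces the qualitative headline that shared-structure domains show
far higher cross-family partition agreement than independent ones.

## 7. Numerical and scale choices

- Concept pairs are stored canonically (`concept_a` before `concept_b`
  under a locale-independent byte-order sort); all pair joins rely on it.
- Cognate set ids and community labels are deterministic functions of the
  data (ordered by smallest member), never of iteration order.
- The exact E[MI] sum is evaluated in log-gamma space; the verification
  suite checks it against a full permutation-enumeration oracle for all
  partitions of up to 6 nodes (about 44 000 ordered pairs) to 1e-12.
- Self-test problem sizes — 200 brute-force mini-wordlists (5 varieties ×
  6 concepts), 100 cognate-recovery simulations (12 varieties, planted
  origin counts 1–3, mutation 0.03), 100 planted-partition seeds (3
  blocks of 6, p_in = 0.9, p_out = 0.05), 20 families per domain with
  1000 resampling trials — were chosen so the whole suite runs in a
  couple of minutes while keeping Monte-Carlo standard errors well below
  the asserted margins.
- Welch's test requires two values and nonzero variance per sample;
  degenerate inputs error rather than returning NaN.

## 8. Known limitations

- Edit-distance cognate clustering under-merges forms related by regular
  but orthographically large sound correspondences, and over-merges short
  look-alike forms; the cognate-based counts on real data should be read
  as approximations, and the threshold sensitivity of any conclusion
  should be checked (the tooling makes this a one-argument change).
- Full colexification misses compound-based associations entirely.
- The homeland centroid is a visualisation aid; it has no phylogeographic
  interpretation.
- Feature proportions are descriptive; no inferential machinery is
  attached to them.
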
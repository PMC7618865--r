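---
title: "Methods: consensus segmentation, interaction geometry and triage in domainkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus segmentation, interaction geometry and triage in domainkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainkit)
```

This vignette documents the models and procedures behind `domainkit`,
the assumptions they make, the tunable parameters and their defaults,
and the places where the design was genuinely open and a choice had to
be made. It is the package's account of *why* the code is the way it
is; the README shows *how* to run it.

## Consensus domain segmentation

The unit of input is a *chopping*: a partition of a chain's residues
into domains, each domain a set of contiguous segments (discontinuous
domains are first-class). Three independent segmentation methods each
produce one chopping per chain, and the consensus stage merges them.

**Agreement.** Two domains from different methods are considered the
same domain when their residue-set intersection-over-union reaches
`iou_min` (default **0.7**). IoU was chosen because it is symmetric,
scale-free and insensitive to residue numbering gaps. The default 0.7
keeps the canonical disagreement case — one method splitting a chain
1–200 into two 100-residue domains that another method leaves whole
(IoU 0.5 per pair) — below agreement, which matches how a two-versus-one
split should behave: the two agreeing methods outvote the third rather
than merge with it.

**Grouping.** Matching between two choppings is the one-to-one
assignment maximising total IoU, restricted to pairs at or above
`iou_min`. Up to eight domains a branch-and-bound exhaustive search
guarantees the optimum (domains above that fall back to greedy descent;
segmentation methods rarely produce more). A group of three mutually
matched domains yields a **high**-confidence consensus domain; exactly
two, **medium**. When transitivity fails (A~B and B~C but not A~C),
the highest-IoU pair forms a medium group and the third domain is left
unmatched — a deterministic, local rule.

**Boundaries by vote.** The consensus residue set keeps a residue iff
at least two of a high group's three domains contain it, or both
domains of a medium group. Voting is symmetric in the methods, so the
result cannot depend on input order. Voted sets may become
discontinuous; segments are recomputed from the final residue set.
Groups smaller than `min_len` (default **25** residues, a conventional
lower bound for a structural domain) are discarded into the non-domain
residue (NDR) set.

**Determinism under ties.** Two distinct candidate pairs can tie
exactly in IoU (it is a ratio of small integers). Ties are broken on
the *content* of the competing pairs — the sorted first residues of the
two domains — rather than on method indices, because a method-index
tie-break would make the output depend on the order in which the three
choppings are supplied. Property tests permute the inputs over random
triples to enforce this.

## Superposition, globularity and internal symmetry

All geometry is **Cα-only**: every statistic computed here (RMSD,
centres of mass, gyration radii, contact counts) is well-defined at Cα
resolution, and fixtures stay small.

**Kabsch superposition** is the SVD solution of the orthogonal
Procrustes problem restricted to proper rotations (the reflection
branch is always folded back, so mirrored inputs superpose with
det R = +1 and a nonzero RMSD). Inputs with fewer than three points or
collinear geometry are rejected. Self-consistency (reported RMSD equals
the RMSD of the transformed coordinates) is tested to 1e-9, and the
implementation is cross-checked against the independent superposition
in `bio3d` on random point clouds.

**Globularity** replaces a learned domain-quality classifier with a
geometric heuristic: the observed radius of gyration divided by the
collapsed-chain expectation `2.2 n^0.38` Å (Flory-type scaling for
compact globules). Compact domains score near 1, extended or
fragmented choppings score high; the non-globular flag is
`score > 1.5` (config-exposed). This is a stand-in authored for this
package, not a reimplementation of any trained network: it captures
the single property downstream triage needs — "does this chopping look
like one folded unit" — while remaining fully transparent.

**Internal symmetry** is scanned by superposing residues `1..n-s` onto
`1+s..n` for every shift `s` in `[min_shift, n - min_shift]`
(`min_shift` default **8**, excluding trivial near-diagonal
self-alignment) and scoring the count of aligned pairs within
`dist_cutoff` (default **4 Å**). A chain of k copies of a p-residue
unit scores near `n - s` at `s = p` and every multiple.

The Z-score design deserves its own paragraph, because the naive
formulation fails. Comparing the best score against *all* other shifts
treats the harmonics (2p, 3p, ...) and the off-register shoulders
(p ± 1, p ± 2 — consecutive residues sit only one bond length apart, so
an alignment off by one register still matches many pairs within a 4 Å
cutoff) as noise, when they are in fact part of the periodic signal;
for a perfect 11-fold ring this inflates the null so much that the
Z-score drops to about 5 and a true repeat architecture would fail the
published repeat gate of Z > 9. The statistic therefore: (i) selects
the period among shifts `s ≤ n/2` only — a period must admit at least
two copies; (ii) builds the null from candidate shifts whose circular
offset from a multiple of the best shift exceeds 2; and (iii) floors
the null standard deviation at `max(1, 0.05 (n - s*))` — one residue
pair, or 5% of the attainable score — so that geometrically exact
repeats with an essentially empty null produce a large but finite Z
instead of a division by near-zero. A consequence worth knowing: Z
*saturates* around 20 for exact fixtures and is nearly flat in the
number of repeat copies, because the statistic is calibrated against
its own null; the raw repeat score, not Z, is what grows with copy
number. The decision rule the package inherits — route to the repeat
category iff Z **strictly** exceeds `z_min = 9` — is unaffected.

## Interacting superfamily pairs and CIO

Instances are extracted per chain from high/medium-confidence consensus
domains that carry superfamily (H) labels. Two filters gate an
unordered domain pair:

* **contact**: at least `min_pairs = 3` Cα–Cα pairs within
  `dist_max = 8` Å — conventional Cα contact-map values;
* **favourable PAE**: the symmetrised mean of the two off-diagonal
  inter-domain blocks of the predicted aligned error matrix at most
  `pae_max = 10` Å. The symmetrised block mean is used because PAE is
  asymmetric by construction and neither direction is privileged.

Both thresholds are config-exposed rather than hard-coded, since
reasonable pipelines differ here.

**CIO** (conservation of interaction orientation) puts every instance
of an ISP into a common frame: one domain per instance is the
*reference* (the domain whose superfamily code sorts first; for
homotypic pairs the larger domain, then the earlier start — fully
deterministic), the instance whose reference has most residues is the
*master*, each reference is Kabsch-aligned onto the master, the fitted
transform carries the *tag-along* domain, and the unit vectors from
reference to tag-along centre of mass are pooled. CIO is their mean
resultant length `‖Σ v̂ᵢ‖ / n` — the standard directional-statistics
concentration measure, bounded on [0, 1], equal to 1 for a perfectly
conserved geometry and tending to `O(n^{-1/2})` for isotropic
orientations. One vector per instance is used (reference → tag-along),
also for homotypic pairs. References of unequal length align over
their common prefix; an instance whose reference shares less than half
the master's length is dropped with a warning rather than silently
distorting the frame.

The synthetic ISP ensembles draw the tag-along placement direction from
a von Mises–Fisher distribution of concentration κ and then apply a
random global rigid motion to every instance, so the CIO pipeline is
genuinely exercised (nothing is pre-aligned). Tests verify CIO = 1 for
exact copies, 0 for an antipodal pair, < 0.1 for 1000 uniform
orientations, strict growth across κ ∈ {0, 5, 50}, and invariance to a
common rigid motion to 1e-6.

**Hubs.** Partner counts class superfamilies as small (< 4), medium
(4–7), large (≥ 8). The source material is internally inconsistent at
exactly 4 connections (one passage says "4–7", another "<4 / 5–7");
4 is placed in *medium* so the three classes tile the integers.

## Novelty ranking

The novelty score substitutes a leave-one-out k-NN density score for a
trained embedding-quality network, keeping the published range and
orientation (0–100, "close to 100" = novel): the raw statistic is the
Euclidean distance to the k-th nearest reference embedding (k default
**5**), calibrated through the right-continuous empirical CDF of the
references' own leave-one-out k-NN distances. The score therefore
depends only on pairwise distances (invariant to any common orthonormal
transform of the embedding space), and adding a reference identical to
the query can only lower it. Triage order is quality filter first, then
symmetry gate, then novelty scoring, mirroring the staged filter
arrangement of the workflow it implements; each representative lands in
exactly one bin.

## Redundancy analysis

Clusters of identical sequences are compared structurally: maximum
pairwise superposed RMSD (exact enumeration up to 50 members; beyond
that, RMSD to the medoid with an `exact = FALSE` flag — an O(n²)
control, not a statistical claim), medoid selection (minimum total RMSD
to the rest, ties to the lowest index), and a cluster-level consensus
chopping. "Consensus across structures" is realised as medoid + strict
per-residue majority vote (> n/2) with domains matched across members
by IoU against the member with most domains; averaging coordinates was
rejected because it fabricates non-physical geometry. RMSD is computed
over all residues; a plDDT mask is deliberately not applied by default
since divergence in low-confidence regions is part of the signal being
measured.

## What the generators emulate — and what they do not

The synthetic fixtures are *geometry-level*, not physics-level:
domains are compact self-avoiding random walks (3.8 Å steps, 3.6 Å
excluded volume, confined so Rg matches the collapsed-chain
expectation), linkers are straight low-confidence bridges, plDDT is
drawn high (90–98) in domains and low (30–50) in linkers, PAE matrices
are block-constant with truncated noise quantised to 0.01 Å, and
cyclic-repeat chains are exact rotational replicas. Every statistic
the package computes — IoU, RMSD, centre-of-mass directions, PAE block
means, shift periodicity, k-NN distances — is fully determined by this
level of realism. What the fixtures do **not** contain: secondary
structure, side chains, realistic PAE textures, homology structure in
the embedding space, or segmentation-method error modes beyond
boundary jitter, merges and drops. Passing tests therefore demonstrate
the correctness of the computations, not the biological performance of
the upstream predictors those inputs normally come from.

Self-avoidance in the random-walk null matters for the symmetry scan:
without excluded volume a densely confined walk revisits its own
neighbourhood constantly, producing spurious self-alignments.

All generators are pure functions of their arguments and a `seed`; the
caller's RNG state is saved and restored, so identical calls are
bit-identical anywhere in a session.

## Problem sizes and numerical choices

The test and acceptance workloads were sized to what the statistics
need, and run in well under a minute each: 200 random chopping triples
(≤ 300 residues, ≤ 4 true domains) against an exhaustive-matching +
vote oracle; CIO ensembles of up to 1000 instances; 100 random chains
plus C2/C6/C11 rings for the symmetry scan; 200 planted redundant
clusters checked against the exact binomial 99% interval of the 42%
planting rate; 20-chain end-to-end pipeline runs compared byte-for-byte.

Numerical conventions: IoU totals compared with a 1e-12 slack in the
branch-and-bound; Kabsch degenerate inputs (collinear, < 3 points)
rejected rather than regularised; rotation recovery asserted to 1e-6;
CIO rigid-motion invariance to 1e-6; chopping strings are 1-based
inclusive ranges and all interval arithmetic runs on explicit residue
sets, so numbering gaps are safe; TSV writers emit a fixed column
order so pipeline reruns are byte-identical.

## Known limitations

* The agreement rule (IoU + vote) and the PAE/contact thresholds are
  this package's own operationalisation of informally specified steps;
  they are exposed as configuration and documented, but other
  reasonable choices exist.
* The symmetry scan detects shift periodicity only; it does not
  determine point-group order, handle insertions between repeat units,
  or iterate alignment refinement.
* The novelty score ranks relative to the supplied reference
  embeddings; with few or unrepresentative references the ECDF
  calibration is coarse (steps of 100/n).
* CIO uses one vector per instance; for homotypic pairs a two-vector
  convention (one in each direction) would be equally defensible.
* Inter-chain (quaternary) interactions, all-atom RMSD and mmCIF are
  out of scope.
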
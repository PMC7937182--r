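---
title: "Inferring the order of trait emergence on a rooted phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the order of trait emergence on a rooted phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitorder)
```

## The model and its assumptions

`traitorder` treats each binary phenotypic trait as the product of a
single evolutionary gain followed by any number of irreversible losses —
the Dollo view of complex-trait evolution. The justification is
mechanistic: traits built from many co-regulated genes are gained rarely,
because every component must arrive and function together, while a single
disruption suffices for loss. Two consequences drive the whole pipeline:

* **The origin rule.** If a trait was gained once, the gain must have
  happened no later than the most recent common ancestor (MRCA) of all
  present-day bearers, and placing it exactly there is the most
  parsimonious choice. `assign_origin()` therefore maps each trait to the
  MRCA of its presence set. A looser phrasing of this rule — "the most
  recent node where the trait is present in any descendant" — is ambiguous
  if read literally (every ancestor of any single bearer qualifies); the
  MRCA-of-all-bearers reading is the only one consistent with a single
  gain plus losses, and it is the one implemented. This is deliberately
  conservative: a trait that in truth arose twice is assigned one deep
  origin instead, which is exactly the failure mode the homoplasy indices
  are there to flag.
* **Vertical inheritance.** The order inference assumes traits descend
  through the species tree rather than moving laterally. The package does
  not test this assumption directly; it quantifies its plausibility per
  trait through the retention index, and the synthetic generator can
  violate it on purpose (`lgt_prob`) to check that the indices respond.

Pairs of origin nodes are compared by ancestry (`compare_pair()`):
identical origins are *simultaneous* at the resolution of the sampled
taxa — denser sampling could still separate them; nested origins give a
strict order; origins in disjoint subtrees are *non-nested*, which under
the single-origin reading means the pair's order is simply not decidable
from presence/absence data. Non-nested pairs are reported as first-class
results rather than errors, because on noisy or simulated data they do
occur even when the generating process is strictly nested.

Within a block of simultaneous traits no internal order is claimed; blocks
are emitted with their member traits in input-column order, and block
sequence is by node depth (edges from the root), which is a linear
extension of the ancestry partial order whether or not non-nested pairs
exist.

## Homoplasy indices

For each trait the package reports the parsimony length $s$ on the fixed
species tree together with $m$ (0 for invariant traits, else 1) and $g$
(the parsimony length on a star tree: the smaller of the two state
counts), and from them $CI = m/s$ and $RI = (g-s)/(g-m)$. $s$ is computed
by `parsimony_steps()`, a Sankoff-style postorder dynamic program with
unit costs. This generalization of Fitch counting was chosen over the
classic two-state Fitch pass because it handles multifurcating nodes and
missing leaves without special cases: a missing leaf carries cost zero for
both states, so it never contributes steps and never pulls an origin
anywhere. Because the cost function is symmetric, the count is invariant
to root placement (re-rooting on every edge is part of the test suite), so
any rooting convention of an external parsimony program yields the same
number.

Degenerate cases are reported as undefined rather than patched: $CI$ is
undefined when $s = 0$ (invariant trait) and $RI$ when $g = m$ (e.g., a
trait present in exactly one species, or absent from exactly one).
Medians are taken over traits with defined values, and the excluded trait
names are part of the result object and the JSON summary, so a consumer
can always reconstruct an all-trait summary under their own convention.

## Gene-tree concordance

The species tree is one estimate; individual gene trees give a
distribution of estimates. For each trait pair the package asks: in what
fraction of rooted gene trees does the same MRCA rule, applied within the
gene tree's own taxon subset, reproduce the species-tree relation?

Choices worth stating explicitly:

* A gene tree only enters a pair's denominator if it contains **at least
  two bearers of each trait**; with fewer, the trait's origin in that tree
  is a single leaf and the comparison is vacuous. Pairs with an empty
  denominator have an undefined (NA) proportion, never a 0 or 1.
* Agreement is **exact relation equality** by default: simultaneous must
  match simultaneous, and a non-nested gene relation counts as
  disagreement. This is the strict reading of "the same order as in the
  species tree". A lenient mode (`lenient = TRUE`) instead removes
  non-nested gene relations from the denominator, on the view that such a
  tree abstains rather than votes; it is provided because gene trees with
  different resolution can turn a simultaneous pair into a nested one and
  vice versa, and the strict/lenient gap measures how much that matters.
* Missing trait states count as absences for evaluability, consistent
  with `presence_set()`.
* Rooting is upstream's job: `concordance()` consumes trees already
  rooted by `root_on_outgroup()` and never roots. The file-level driver
  `run_concordance()` does the rooting and reports how many trees were
  unrootable.
* The taxon-exclusion rerun (`exclude_taxa`) prunes the named species
  from every gene tree before evaluability is re-checked — the tool for
  asking whether a suspect clade (e.g., one prone to long-branch
  attraction) is responsible for disagreement.

## Root-support census

Outgroup rooting is only defined when the outgroup occupies one side of a
single branch, so the census discards trees whose outgroup leaves do not
form a single partition of the unrooted topology (reason
`outgroup_split`; trees with no outgroup leaf at all fall in the same
bin, since they cannot be rooted). Survivors are rooted, the outgroup is
stripped, and trees in which any named group has fewer than
`min_per_group` members (default 2) are discarded (`min_group_count`) —
with a single member, "on both sides of the root" is meaningless. The
outgroup filter runs first; the alternative order would only relabel the
overlap of the two discard sets, and the partition test is the cheaper
and more fundamental of the two.

Classification of the survivors follows from the root split: a group that
is the sole occupant of one side is **basal**; the unique group occurring
on both sides is **ancestral**; more than one spanning group is
**ambiguous**. Two further corner cases are resolved as ambiguous with an
explanatory note: both root children single-group (then "basal" is not
well defined — this requires that at most two groups survive filtering),
and a root polytomy in the ingroup subtree (sides are not defined). With
three groups present and no spanning group, exactly one side must be
single-group, so a basal verdict is guaranteed; this is asserted at run
time rather than assumed.

## The synthetic-data generator

`generate_dataset()` emulates the shape of the data the pipeline is aimed
at — a large bacterial phylum with a handful of outgroup genomes — with
every generating decision recorded as ground truth:

* **Species tree**: Yule (pure-birth) topology via `ape::rphylo`, the
  simplest process that produces realistic random rooted trees; death
  adds parameters without adding anything the pipeline could detect.
* **Traits**: origins are placed on the nodes of the longest root-to-tip
  backbone path, evenly spaced and root-first, so the true order is
  nested by construction; each edge strictly below an origin then loses
  the trait, in its whole subtree, with probability `loss_prob`. Traits
  that lose every bearer are redrawn (and the redraw is logged) so every
  trait remains observable. Optional lateral transfer is modeled as a
  **single extra gain** on one clade disjoint from the origin clade —
  deliberately minimal, because it creates exactly the homoplasy
  signature ($s \ge 2$) that CI/RI must detect, with a clean oracle.
* **Gene trees**: each keeps every species with probability `retention`
  (redrawn below 4 survivors), is perturbed by `n_nni` random
  nearest-neighbor interchanges — NNI rather than SPR because small
  composable moves map smoothly onto disagreement rates — and receives
  the outgroup as a sister clade so the rooting machinery is exercised
  end to end.
* **Groups**: derived from the realized tree — the smaller side of the
  root is the true basal group `G1`; the clade on the other side closest
  to `second_group_fraction` of the species is `G2`; the rest is `G3`.
* **Determinism**: one master seed; per-component substreams are derived
  from it so changing `n_gene_trees` does not alter the trait matrix, and
  a manifest with md5 checksums makes byte-identical reruns checkable.

Default sizes (199 species, 21 traits, 553 gene trees, 6 outgroup taxa,
three groups with the mid-size one near 16% of species) mirror the
cyanobacterial study system this pipeline was designed around. The noise
defaults are fixed once at moderate values: `loss_prob = 0.05` (a few
visible losses per trait on a 199-species tree), `retention = 0.8` (gene
families typically span most but not all genomes), `n_nni = 2` (mild
gene-tree discordance, consistent with mostly-concordant single-copy
genes), `lgt_prob = 0` (the vertical-inheritance assumption; transfers
are opt-in), `missing_prob = 0`.

What the generator does **not** emulate: phylogenetic error correlated
with alignment length or rate, long-branch attraction (perturbations are
uniform over edges, not biased toward long branches), trait correlation,
paralogy, or biased taxon sampling. A passing pipeline on synthetic data
therefore demonstrates correctness of the inference machinery under the
stated model — not robustness to systematic artifacts in real data, which
is precisely what the concordance and census analyses are for.

## Numerical and degenerate-input choices

* Branch lengths are parsed, preserved to 10 significant digits on
  round-trip, and never used in inference; when re-rooting splits an
  edge, its length is divided equally between the two halves — a pure
  serialization convention.
* Internal-node labels (bootstrap values in typical gene-tree files) are
  carried as opaque annotations and never interpreted as taxa.
* Polytomies are first-class everywhere (parsing, parsimony, MRCA);
  nothing is arbitrarily binarized.
* A single-species outgroup, or a single-species ingroup, is always a
  valid partition (its own pendant edge separates it).
* Duplicate leaf labels, unknown trait-state tokens, traits with no
  observation, and species-set mismatches between tree and matrix are
  hard errors at the boundary, not warnings downstream; `reconcile()`
  with `prune = TRUE` is the one sanctioned way to analyze partially
  overlapping inputs, and it reports everything it drops.

## Problem sizes used by the test suite

The suite verifies parsimony against brute-force enumeration on 200
random trees of up to 7 internal nodes (exhaustive over all internal
assignments), MRCA against a path-intersection oracle up to 64 leaves,
antisymmetry of the pair relation exhaustively on a 32-leaf tree, exact
noise-free recovery at 32 species / 8 traits / 50 gene trees, recovery
above 90% of pairs over 20 seeds at `loss_prob = 0.05`, and a strictly
decreasing mean concordance across `n_nni` in {0, 2, 4, 8} averaged over
20 seeds at 24 species / 6 traits / 16 gene trees — sizes chosen so each
Monte-Carlo comparison rests on a few thousand pair evaluations while the
whole suite stays fast enough to run on every change.

## Known limitations

* The origin rule cannot place a trait's gain more finely than the taxon
  sampling allows; "simultaneous" is a statement about resolution, not
  about time.
* A trait gained independently in two disjoint clades is silently mapped
  to their joint MRCA; only the indices (and a low concordance) reveal
  the misfit. There is no multiple-origin model.
* Parsimony is unweighted and the characters unordered; there is no
  likelihood or Bayesian ancestral-state machinery, no dating, and no
  support values computed on trees.
* The census verdicts depend on the group definition supplied by the
  user; the package checks consistency (every ingroup leaf mapped,
  groups disjoint from the outgroup) but cannot detect a scientifically
  wrong grouping.
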
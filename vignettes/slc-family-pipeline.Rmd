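---
title: "Classifying SLC-like transporters from HMM fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying SLC-like transporters from HMM fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcpipe)
```

## The problem

Solute carrier (SLC) proteins form the largest superfamily of membrane
transporters, but they are sequence-diverse enough that no single profile
HMM detects them all, and proteome downloads are polluted by fragments,
redundant predicted ORFs and multi-domain false positives. `slcpipe`
implements a complete discovery-and-classification pipeline for this
setting: candidate detection from profile-HMM similarity searches, collapse
of redundant sequences to one representative per gene, classification into
protein families by clustering *HMM fingerprints*, filtering of remote
structural homologs, and extraction of ortholog relations across a fixed
seven-species tree (human, mouse, rat, chicken, zebrafish, fly, worm).

Every stage can be exercised against synthetic inputs with planted ground
truth, which is how the package validates itself.

## HMM fingerprints and candidate selection

A protein's fingerprint is the vector of bit scores of its hits against a
panel of family-, subfamily- and domain-level HMMs. Bit scores are used
rather than E-values because they are independent of database size. Two
thresholds shape the matrix, both strict inequalities:

* **Search threshold, 50 bits.** A protein enters the candidate set only if
  some hit scores strictly above 50 bits (`select_candidates()`).
* **Fingerprint threshold, 25 bits.** An HMM contributes a column only if
  its best hit scores strictly above 25 bits (`build_fingerprints()`).

The 25-bit rule selects *columns*, not cells: once a model is retained, any
reported score to it is entered in the matrix, because the restriction is
on the number of HMMs considered informative, not on individual scores. The
stricter reading (zeroing cells at or below 25 bits) is available via
`threshold_config(cells_min_bits = TRUE)`.

Multi-domain HMMER rows are merged to one row per (protein, model) pair,
keeping the maximum full-sequence bit score and the union of domain
coordinate ranges (`merge_hits()`). The full-sequence score is used because
the thresholds act per protein–model pair, not per domain.

Four region-exclusion rules ship as defaults
(`region_exclusion_rules()`): hits that lie *entirely* inside known non-TM
stretches of four multi-domain models (TC# 2.A.19.3 positions 250–725,
TC# 9.B.64.1 above 200, OST3_OST6 below 200, RBP_receptor above 400) are
discarded before candidate selection; a hit with any domain segment outside
the window is retained.

## Fragment collapse

UniProt-style downloads contain fragments and genomic-screening artifacts,
so candidates are reduced to one representative per gene. Two records are
joined in the redundancy graph when they

* share an identical (namespace, value) gene annotation in one of the
  namespaces GN, HGNC, GeneID, UniGene, FlyBase, KEGG; or
* are linked by an HSP with strictly more than 95% sequence identity.

Connected components of this graph are gene clusters. Representatives
follow three rules: a single reviewed (Swiss-Prot-curated) member is taken;
with no reviewed member the longest sequence wins (ties broken by smallest
accession — the rule set is otherwise silent on ties, and a lexicographic
tie-break keeps runs reproducible across platforms); with two or more
reviewed members the cluster is routed to a manual-review report rather
than auto-split. Components whose members carry two or more distinct values
in the same annotation namespace are likewise flagged for review instead of
being resolved silently — automated resolution of conflicting annotations
is exactly the step that needs a human.

After collapse, representatives with fewer than 3 annotated transmembrane
helices are excluded (`sanitize_by_tmh()`); a configurable rescue list
exempts accessions whose functional unit is known to span 3+ TMs (in the
original curation this list held 8 proteins — it is config data, not code).
Records with no TM annotation at all go to review rather than being
silently excluded. The filter runs after collapse because representative
selection must see fragments (which naturally carry fewer annotated TMs).

## Family classification: cosine UPGMA with constrained cutting

The core classifier is hierarchical clustering of fingerprint rows:

* distance: cosine, `d(i,j) = 1 − x_i·x_j/(‖x_i‖‖x_j‖)`, which compares
  the *pattern* of model similarities rather than their magnitude, so a
  fragment-length score profile and a full-length one with the same shape
  are close. With nonnegative scores `d ∈ [0, 1]`.
* linkage: UPGMA (unweighted average). Merge heights are the **unhalved**
  average inter-cluster distance, so a cut "at 0.7 cosine distance" is
  directly comparable with pairwise distances. `upgma()` breaks ties by the
  lexicographically smallest pair of cluster labels, making the tree
  deterministic on any input; ties have measure zero on real data but the
  rule matters for reproducibility.
* cut: families are groups connected by merges with height strictly below
  the threshold (default 0.7); merges at exactly the threshold are not
  applied, consistent with the strict inequalities used everywhere else.

Join and split constraints adjust the cut locally:

* **join(p, q)**: if p and q are separate, the entire leaf set under their
  dendrogram LCA becomes one family — in a binary merge tree the LCA
  subtree *is* the smallest cluster containing both, so this realizes
  "cut just above the branch leading to that cluster".
* **split(p, q)**: if p and q are together, their family is re-cut strictly
  below the LCA's merge height. This separates the LCA's two child clades
  and also detaches any family members that joined above the LCA; the
  alternative (replacing the family by just the two child leaf sets) would
  orphan such members and break the partition invariant.

All splits are applied first, then all joins, then every constraint is
re-verified globally; any violated pair raises an error naming the
offenders. The fixed order plus verification makes constraint interaction
(e.g. one protein appearing in two split pairs, or a join whose raised cut
swallows a split family) a detected condition rather than a silent
order-dependent outcome. The shipped defaults carry eight join pairs and
five split pairs given as human gene symbols (`default_join_pairs()`,
`default_split_pairs()`); `run_pipeline()` applies only pairs whose
members are present in the data, logging skipped ones.

`threshold_scan()` reports family counts across cut heights (default
0.6/0.7/0.8); with no constraints the count is provably non-increasing in
the height. For polar dendrogram figures the radial coordinate is
transformed by `d' = 0.5 + arcsin(2d − 1)/π`, a strictly increasing
bijection of [0, 1] that magnifies detail near both ends; 0, 0.5 and 1 are
exact fixed points and `radial_inverse()` is its closed-form inverse.

## Structural homolog filtering

Remote-homology hits against PDB chains (entering as a normalized TSV; the
package does not parse native HH-suite reports) are accepted when **at
least 3 TM segments of the chain are fully contained in the aligned
region** and the E-value is strictly below 1e-4. Containment is read
literally — a clipped helix does not count — because a partial helix in the
aligned region is weak evidence that the alignment covers the membrane
domain; `allow_partial = TRUE` implements the overlap reading for
sensitivity analysis. Chains lacking a TM annotation reject with a warning
(the annotation table is a required input; no specific PDB annotation
source is bundled). `best_structural_homolog()` keeps the minimal-E
accepted hit per protein (ties: lexicographic chain id), and
`structural_orphans()` lists families in which no member has an accepted
hit.

## Orthology

Gene trees with `gene__species` leaf labels are reconciled against the
species tree by standard LCA mapping: each gene-tree node maps to the
lowest species-tree node containing its descendant species; a node is a
duplication when two of its children's mapped subtrees overlap (for binary
nodes: a child maps to the same node as the parent). Losses are inferred
per edge — one for each species node strictly between the parent and child
maps, plus one at the parent's node for a duplication whose child maps
strictly below it. Note that lineages outside the root's mapped subtree
never generate losses; LCA parsimony cannot see them.

Unrooted trees are rooted by duplication–loss parsimony: every edge is
evaluated as a root, minimizing duplications + losses, with ties broken by
fewest duplications and then the lexicographically smallest split. Support-
threshold-based topology rearrangement (as performed by reconciliation
tools such as NOTUNG) is deliberately **not** implemented: it alters the
input topology, and this package treats gene trees as data.

For a focal species (default human), `focal_matrix()` classifies each
focal gene against each other species by ortholog counts: with k orthologs
in the other species and m focal genes sharing at least one of them, the
categories are `none` (k = 0), `one_to_one` (1, 1), `one_to_many` (k > 1),
`many_to_one` (m > 1) and `many_to_many` (both) — the last category covers
duplications in both lineages, which the 1:1/1:many/many:1 scheme leaves
undefined; it is emitted and flagged rather than collapsed into a
neighboring category. Clusters with no surviving focal gene are reported as
`lost_in_focal` rows. Polytomous nodes are treated as duplications when any
two children overlap in their species maps.

## The synthetic-data generator

`simulate_bundle()` produces every pipeline input with known truth:

* **Hits** (`simulate_hits()`): each of K families owns a dedicated model
  subset; members hit all family models with bit scores ~ Normal(200, 15)
  truncated at 51 — far above the 50-bit threshold, as genuine family
  members are in practice — while noise hits to foreign models are drawn
  uniformly from 20–30 bits, deliberately straddling the 25-bit column
  threshold. The distributions themselves are free parameters with
  documented defaults; only their position relative to the thresholds
  matters for the recovery properties.
* **Fragments** (`simulate_fragments()`): 1–3 truncated copies (30–90%
  length) for a fraction of genes, sharing the parent's hits with scores
  scaled by the length fraction, an HSP of identity in (95, 100] to the
  parent, and labels dropped at a configurable rate; adversarial distractor
  HSPs in (80, 95] connect unrelated genes and must never merge them.
* **Structural hits** (`simulate_structural_hits()`): E-values log-uniform
  in [1e-12, 1e-2] and aligned regions covering a known number (0–6) of
  planted TM segments, so generated flags straddle both acceptance cutoffs.
* **Gene trees** (`simulate_gene_trees()`): birth–death evolution along the
  species tree — per branch, duplication with probability `dup_rate`, loss
  per copy with probability `loss_rate` — with true event labels recorded
  and trees emitted unrooted to exercise parsimony rooting. The species
  topology places fly and worm as successive outgroups to the vertebrates;
  the ordering among the two invertebrate outgroups is a configuration
  default, not a biological claim.

All generators are deterministic under the seed. What the generator does
*not* emulate: actual sequence evolution (sequences are random strings with
fragments as literal substrings), correlated noise between related
families, HMM construction, or realistic bit-score distributions. Passing
the planted-truth tests therefore demonstrates the correctness of the
*computation* — thresholds, graph operations, clustering, reconciliation —
not the biological performance of the thresholds on real proteomes, which
depends on database snapshots this package does not ship.

## Numerical choices and problem sizes

* Strict inequalities at every threshold (50, 25, 95%, 0.7, 1e-4), matching
  the stated selection rules exactly.
* UPGMA uses Lance–Williams updates; the test suite checks it against an
  exhaustive re-averaging implementation on random ≤8-leaf matrices
  (tolerance 1e-10) and against `hclust(method = "average")` cophenetic
  matrices.
* Cosine distances are clamped at 0 from below to absorb rounding in
  `tcrossprod`; the diagonal is exactly 0.
* Family ids are renumbered by smallest member accession, so output
  ordering never depends on merge order.
* The test and acceptance workloads use 20 planted families × 10 proteins
  × 3 models (the headline recovery case), 100 random matrices for the
  UPGMA cross-check, 200 random trees for orthology agreement, and 20
  loss-free birth–death trees for event recovery; these sizes give
  negligible sampling slack around the all-or-nothing recovery properties
  while keeping a full run in the minutes range on one CPU.

## Known limitations

* REVIEW clusters (multiple curated members, conflicting annotations) and
  proteins lacking TM annotations are reported, not resolved; downstream
  counts exclude them by design.
* LCA reconciliation is parsimony-based: duplication counts are lower
  bounds in the presence of losses, and losses outside the root map's
  subtree are invisible.
* The pipeline does not build HMMs, run hmmsearch/BLAST/hhblits, or
  construct alignments and trees; those are upstream tools whose outputs
  are this package's inputs.
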
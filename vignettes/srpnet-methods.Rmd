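---
title: "Reaction-network synthetic accessibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-network synthetic accessibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Generative molecule design produces structures faster than chemists can
judge whether they are makeable. A popular proxy, structural complexity,
conflates "looks complicated" with "is hard to make": a steroid is complex,
but one synthesis step away from cholesterol. `srpnet` instead estimates
synthetic accessibility (SA) from *reaction evidence*: a directed network is
built from recorded reactions, each substance's **shortest reaction path
(SRP)** from purchasable building blocks is computed, compounds are labeled
easy-to-synthesize (ES, SRP at or below a cut-off) or hard-to-synthesize
(HS), and classifiers are trained to predict the label from structure
alone, so it can be applied to molecules outside the network.

## From raw reaction records to a substance network

**Parsing and cleaning.** Input is reaction SMILES
(`reactants>agents>products`), one per line. Substance identity is the
OpenBabel canonical isomeric SMILES with atom maps stripped: stereochemistry
distinguishes substances, mapping numbers do not. Duplicate records are
detected on sorted key triples, so component order and atom maps are
irrelevant. The validity contract rejects records with no products, no
reactant-side species, a product equal to a reactant (a self-loop in the
network), products that share no atom map with any reactant, and — when
requested — records on which template extraction fails. The full
filter catalogue used by large curation pipelines (including dozens of
special functional-group rules) is deliberately not reproduced; the
contract above is the documented subset this package enforces.

**Templates and role designation.** Recorded reactant lists notoriously mix
true reactants with solvents, metals and counterions. The package separates
them with an inverse-template procedure:

1. all reactant-side species, agents included, are pooled as *original
   reactants* (ORs);
2. a radius-1 rewrite template is extracted from the atom-mapped record:
   the reaction center (atoms whose bonding, hydrogen count or formal
   charge changes) plus all atoms within one bond, plus multiply-bonded
   attachments (keeping carbonyls and nitro groups whole) and unmapped
   leaving-group fragments;
3. the inverse template applied to the product yields *predicted reactants*
   (PRs);
4. each PR consumes one OR: an exact canonical-key match if available,
   otherwise the unconsumed OR with the highest ECFP4/Tanimoto similarity;
   ORs left over are reagents.

Where several disjoint embeddings of the pattern exist, the PR set with the
most exact OR matches wins, ties broken by total similarity and then
lexicographically — the procedure is deterministic. PR sets keep
stoichiometric multiplicity: a record coupling two copies of the same
substance consumes two OR entries. Each OR is consumable once; a PR whose
best similarity falls below 0.2 is matched anyway but logged, since
reactant–reagent similarity is typically low and an argmax suffices. No R
toolkit exposes editable atom-mapped molecular graphs, so the package
carries a small internal SMILES parser/writer and subgraph matcher for this
machinery; OpenBabel remains the authority on substance identity,
descriptors and fingerprints. The internal graph treats `/`/`\` bond
stereo as plain single bonds; double-bond geometry survives in substance
keys but does not influence template matching.

**The network.** Every record with designated roles contributes one
directed edge from each true reactant to each product; reagents never
become nodes. Parallel edges from different reactions are kept, and each
(u, v) pair carries the number of distinct source documents as a weight.
Terminal nodes (no incoming edge) that match a purchasable building-block
list are the starting materials; SRP is the edge count of the shortest
directed path from any of them, computed by one breadth-first search from a
virtual super-source. SRP is a *single-lineage lower bound*: it follows one
reactant chain and ignores the cost of co-reactants joining along the
route. Label candidates are normal (product) nodes with molecular weight in
200–500 g/mol and calculated LogP in 0–5 (inclusive); filtering selects
candidates only — filtered-out substances still serve as path
intermediates. Unreachable candidates are excluded from labeling rather
than being assigned an arbitrary SRP.

## Curation and splits

Labeling at cut-off *c* is `ES iff SRP <= c` (the study uses c = 2, 3, 4).
The ES surplus is reduced by leader (sphere-exclusion) clustering on
ECFP4/Tanimoto — a documented substitute for the proprietary
clustering/fingerprint stack used at full scale — with per-cut-off
similarity thresholds 0.35, 0.615 and 0.655 kept as defaults; cluster
leaders are the diverse representatives, subsampled to the HS count.
Splits are 8:1:1 with the remainder to the test set, seeded, and stratified
by label (stratification is this package's addition: it keeps the small
validation and test sets balanced). The unbalanced test set is the balanced
test set plus every ES compound removed by down-sampling, with a hard error
on any overlap with training or validation.

## The three classifier families

* **RF-PCD** — a random forest on six physicochemical descriptors: MW,
  TPSA, rotatable bonds, H-bond donors, H-bond acceptors, LogP. One
  published descriptor list names five but counts six; LogP, used elsewhere
  in the pipeline, is adopted as the sixth.
* **DNN-ECFP** — a feed-forward network on 2048-bit ECFP4 (radius 2).
  OpenBabel's ECFP4 is emitted at 4096 bits and folded by OR to 2048.
  Architecture beyond optimizer and loss is unspecified upstream; the
  defaults here are two hidden layers (1024, 256), dropout 0.2, RMSprop,
  binary cross-entropy, learning rate halved when the validation AUC
  plateaus, best checkpoint kept. All of it is plain matrix algebra with
  hand-derived gradients — no deep-learning framework is involved.
* **Graph classifier** — a communicative message-passing network on the
  molecular graph: directed bond states and atom states are updated jointly
  for three interaction steps; incoming bond states are aggregated per atom
  by an elementwise sum-times-max booster; each bond state is refreshed
  from its source atom minus the reverse bond state (no echo), re-anchored
  on its initial embedding; readout is sum+max pooling into a dense head.
  Atom features are 133-dimensional: atomic number one-hot (100), degree
  (6), formal charge (5), H count (5), hybridization (5), chiral tag (4),
  aromaticity, ring membership, scaled mass, and 5 padding flags. Bond
  features are order one-hot (4) plus a ring flag. Molecules without bonds
  fall back to atom-only readout. Gradients are verified against finite
  differences in the test suite.

Scores are ES probabilities; ACC and MCC use a fixed 0.5 threshold, with
MCC defined as 0 whenever a denominator factor vanishes, and ROC-AUC is the
rank statistic with ties counted half (equivalent to the trapezoid sweep,
which the tests check explicitly). ES is the positive class.

## What the synthetic fixtures emulate — and what they do not

The commercial corpus behind the full-scale study cannot ship with a
package, so every stage is exercised on generated corpora with known
ground truth. The generator grows a layered synthesis network from ~10
building blocks using four coupling motifs (esterification, amide coupling,
Williamson etherification, N-alkylation), executed as actual bond rewiring
on molecular graphs — atom maps, roles and planted SRPs are therefore exact
by construction, and two bifunctional anchors guarantee products at every
depth. Corpus flaws are reproduced deliberately: solvents, metals and ions
injected into the reactant field, and exact duplicate records. Planted SRP
is defined by fixpoint relaxation over the emitted records, which is
precisely what the graph search should recover.

Fixture sizes and conditions used by the tests and the acceptance script
are the package's study conditions: 50 random layered DAGs of 60–500 nodes
for the shortest-path oracle; a depth-3 corpus of 1,000 reactions (grown
from 12 building blocks at branching 7) with 50% reagent injection and 10%
duplicates for role recovery; 2,000
molecules per planted-signal fixture with 20 permuted-label null runs
across the three families. Null-band checks use validation sets of ~200
molecules, for which chance-level AUC falls within [0.4, 0.6] with
comfortable margin.

These fixtures validate the *machinery*, not chemical breadth: real
corpora have thousands of reaction classes, imperfect atom maps,
stereochemistry-only transformations and genuinely ambiguous roles.
Passing fixtures therefore demonstrates correctness of parsing, template
logic, graph search, curation and training loops — not that the shipped
defaults reach the full-scale study's headline accuracies, which require
the commercial data.

## Numerical choices and degenerate inputs

* Canonicalization failures are `NA`, never silent placeholders; batch
  conversion isolates invalid entries and continues.
* Tanimoto of two empty fingerprints is 0.
* `evaluate_classifier` on one-class input returns `NA` AUC with a warning
  while ACC and MCC (0 by the zero-denominator rule) are still reported.
* Leader clustering scans in input order; determinism comes from the seeded
  subsample, and ties in similarity fall to the earlier leader.
* Split sizes use floors with the remainder assigned to test, so 101
  compounds split 80/10/11.
* The template matcher constrains element, aromaticity and charge
  everywhere, and hydrogen count plus heavy-atom degree at center atoms
  only, so environment atoms generalize across homologues.
* All randomness flows through explicit integer seeds; identical seeds give
  byte-identical corpora, splits and training histories (CPU arithmetic).

## Known limitations

* SRP underestimates true route length whenever a co-reactant is itself
  hard to make (single-lineage bound).
* The internal SMILES subset covers organic-subset and bracket atoms,
  aromatic rings and charges, but not isotope-labeled chemistry beyond
  parsing, wildcard atoms, or tetrahedral stereo *matching* (tags are
  carried but not used to constrain embeddings).
* Multi-product records drive templates from the largest product only;
  salts and byproducts do not shape the pattern.
* Stereo-duplicate reactions (same skeleton, different stereochemistry) are
  kept distinct, since stereochemistry matters for SA.
* The graph classifier is a desk-scale reimplementation of the
  communicative message-passing idea, not a port of any released model or
  weights; at full scale a GPU implementation would replace it.
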
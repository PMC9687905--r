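---
title: "Hydrogen-bond topology graphs and their classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen-bond topology graphs and their classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbgraph)
```

## The problem

Protein superfamilies that share a fold and a catalytic reaction often split
into subfamilies with different preferred ligands (alpha- vs beta-amylases,
trypsin vs chymotrypsin, seryl- vs threonyl-tRNA synthetases). Because
hydrogen bonds organize tertiary structure and govern much of recognition
specificity, the topology of a structure's feasible hydrogen bonds — taken
alone, with every other structural signal deliberately excluded — can carry
enough signal to assign a structure to its subfamily. When a classifier that
sees only hydrogen-bond topology succeeds, the classification itself
implicates hydrogen bonding in the specificity mechanism, which a holistic
structural comparison cannot do.

`hbgraph` implements that pipeline end to end: structure preparation,
geometric hydrogen-bond detection, molecular-graph construction, a
shared-weight graph convolutional network (GCN) embedding, and a logistic-
regression classification head, together with the repeated-split evaluation
protocol and synthetic fixture generators used to test all of it.

## Structure preparation

Preparation reduces a PDB entry to the standard amino-acid `ATOM` records of
one chain (model 1 of multi-model files), removing waters, ions, ligands and
all experimentally solved hydrogens, and collapsing alternate locations to
the highest-occupancy conformer (ties keep altloc `A`). Hydrogens are
removed even when present because crystal structures protonate
inconsistently; uniform protonation is then restored in software.

Hydrogens are placed by idealized covalent geometry rather than by an
external protonation tool. For each donor in the role table the placement
is:

* **sp2 donors** (backbone amide except proline, Arg guanidinium NE, His
  NE2, Trp NE1): one hydrogen in the plane of the two heavy neighbors, on
  the external bisector, at 1.00 Å.
* **sp2 amides with two hydrogens** (Asn ND2, Gln NE2, Arg NH1/NH2): both
  hydrogens in the amide/guanidinium plane at ±120° from the N→C direction.
* **sp3 donors** (Ser/Thr/Tyr hydroxyls at 0.96 Å, Lys ammonium and
  N-terminal amines at 1.00 Å): tetrahedral geometry with the azimuth chosen
  by a deterministic 5° scan that maximizes the minimal distance to the 1-3
  neighbors — the staggered rotamer. Hydroxyl orientations therefore differ
  from what an optimizing tool would produce, but they satisfy the same
  covalent constraints; the bond criteria are intentionally loose enough
  (2.5 Å H–A, angles > 90°) that feasibility is not sensitive to the exact
  rotamer in the common cases.

Protonation states assume pH 7: Asp/Glu deprotonated (acceptors only),
Lys/Arg protonated, His neutral with the NE2–H tautomer. A nitrogen with no
preceding carbonyl carbon within 1.8 Å is treated as an N-terminal amine,
which also protonates chain breaks and isolated residues sensibly. Residues
missing the frame atoms needed for a placement skip that hydrogen with a
warning; nonstandard residues are dropped with a warning rather than
remapped. Files protonated elsewhere can bypass placement
(`pre_protonated = TRUE`), with hydrogens attached to their nearest heavy
atom.

The chain and model conventions (first protein chain, model 1) are this
package's choices; nothing in the underlying method constrains them.

## Hydrogen-bond detection

A candidate bond involves four atoms: donor D, donor hydrogen H, acceptor A
and acceptor antecedent AA (the heavy atom covalently bonded to A, which
orients its lone pairs). The criteria are:

* d(D, A) ≤ 3.9 Å and d(H, A) ≤ 2.5 Å (inclusive bounds — "within");
* angles D–H–A, H–A–AA and D–A–AA each strictly greater than 90° (the
  middle atom is the vertex).

Distance bounds are inclusive and angle bounds strict because that is how
the criteria are stated ("within", "exceed"); the boundary tests pin both
conventions. Candidates with a zero-length angle arm (coincident atoms)
reject with a degenerate-geometry flag rather than propagating NaN.

The role table (which atoms donate, which accept, and through which
antecedents) is ordinary data returned by `default_role_table()` and can be
replaced without touching code. Hydroxyls are both donors and acceptors;
ring nitrogens and Met SD list two antecedents, and a bond is accepted if
the criteria hold for *any* hydrogen/antecedent combination. Each
donor-acceptor pair is reported at most once. Same-residue pairs are
excluded; sequence-adjacent backbone pairs are *not* excluded, because the
criteria are purely geometric and adjacent pairs that pass them are
legitimate edges under those criteria (in practice the D–H–A angle rejects
them).

The search loops over donors and radius-queries acceptors within 3.9 Å
using a cell-list lattice (`build_grid()`, cell size = the distance cutoff,
so a query touches at most 27 cells). `brute_force_hbond_search()` is the
exhaustive O(n²) reference with the identical output contract; the test
suite holds the two equal on 100 seeded random structures.

## Molecular graphs

Nodes are all donor/acceptor atoms — including singletons, which carry no
topological information individually but keep the node set a function of
the chemistry rather than of the bond search. Edges are feasible bonds. Two
modes share one data structure: coordinate-free graphs weight every edge
1.0; coordinate-based graphs weight each edge by the donor-acceptor
distance in Å, used as-is (no inversion or kernel — the weight *is* the
distance, so the two modes differ only in `A`'s nonzero values, never in
the edge set).

## The GCN classifier

Each graph contributes an input feature matrix `X(0) ∈ R^{N×3}`, the
one-hot encoding of node roles in the fixed column order (donor, acceptor,
both). Layers propagate

    X(l) = σ( Â X(l−1) W(l) ),     Â = D^{−1/2} (A + I) D^{−1/2},

feature aggregation by the self-looped, symmetrically normalized adjacency
followed by the linear transformation and nonlinearity. Self-loops make Â
well defined for degree-0 nodes; for binary adjacencies its spectrum lies
in [−1, 1]. The weight matrices are shared by every graph, which projects
graphs of different sizes into one feature space. The per-layer outputs are
concatenated column-wise (`X_all = [X(1), …, X(L)]`) so the classifier can
draw on every neighborhood radius at once; a last-layer-only mode exists
for the ablation. Mean pooling of `X_all`'s rows gives the graph embedding,
which is exactly invariant to node order and independent of node count.

Training minimizes node-level cross-entropy: every node inherits its
graph's class label, and Adam (standard moment decays) optimizes
`W(1..L)` together with a linear node classification matrix over shuffled
graph minibatches for exactly the requested number of epochs. Training on
node labels rather than pooled graph embeddings exploits all node-level
information and the substructure within each graph; the graph-level head is
then a *refit* logistic regression on the mean-pooled embeddings. The
node-level matrix could in principle be reused as the head, but refitting
is the reading consistent with a separate LR classification step, and it is
what this package does. The head is ridge-penalized (unit strength, i.e.
glmnet's `lambda = 1/n`), multinomial, with a deterministic solver; if every
training graph pools to the same embedding (a degenerate but constructible
case) the head falls back to class priors.

The activation (ReLU) and hidden width (64 per layer) are conventions of
this implementation — the propagation rule itself fixes neither — and both
are exposed as parameters. Defaults elsewhere follow the method's tuned
operating point: 3 layers, batch size 4, 50 epochs, learning rate 1e-3 when
tuning is disabled.

## Evaluation protocol

`stratified_split()` splits every class independently 4:1 (test counts
rounded to nearest, at least one test member per class).
`tune_hyperparams()` grid-searches learning rate {5e-4, 1e-4, 5e-3, 1e-3},
batch size {1, 2, 4, 8, 16} and 1–6 layers with stratified 5-fold CV on the
training partition only; selection keys on the single highest fold accuracy
(the literal protocol), with best-mean-across-folds available behind
`select = "mean"` since the literal rule is noisy on small folds. Ties
break to the higher mean, then grid order. `evaluate()` repeats the whole
split–(tune–)train–test cycle, 10 splits by default, and reports accuracy
(correct/total, recomputed from stored confusion counts), macro F1 and
one-vs-rest macro AUC-ROC as mean ± sd. Macro averaging is this package's
choice (robust to mild class imbalance); for two classes the AUC reduces to
the standard binary AUC. One master seed fans out to per-split, per-fold
and initialization seeds by fixed offsets, so any single split is
reproducible in isolation, and the split indices are stored on the result
so the no-leakage property is directly checkable.

## Synthetic fixtures

Three generators produce every input the tests need:

* `make_ideal_helix()` builds a poly-alanine backbone from textbook internal
  coordinates (N–CA 1.458, CA–C 1.525, C–N 1.329 Å; ω = 180°) at φ = −57°,
  ψ = −47°. That geometry puts every O(i)···N(i+4) pair at ≈ 3.07 Å with
  comfortable angles, so the fixture's bond set is known in advance — the
  helix is the positive control for the whole prep → protonate → detect
  pipeline.
* `make_random_structure()` scatters whole residues (mixed polar types) at
  random orientations in a box whose volume scales with residue count
  (≈ 30 Å³ per atom, enough for frequent contact at bonding range), with a
  1.5 Å minimum inter-residue separation by rejection. These are *not*
  protein decoys — residues are unbonded and rotamers fixed — they exist to
  exercise the geometric search on irregular input, where the lattice
  search must equal the exhaustive oracle exactly.
* `make_graph_family()` emulates labelled subfamily datasets: classes share
  one role distribution (checked by a chi-square on role counts at
  generation time) and differ only in edge-topology statistics, so
  classification must exploit topology. Edges respect donor/acceptor
  chemistry. The default study condition used by the acceptance checks is
  two classes at edge probabilities 0.05 vs 0.15, 60 graphs per class,
  30–60 nodes per graph — densities chosen well apart so that a sound
  pipeline should recover the classes at ≥ 90% accuracy, with a
  label-shuffled control expected at chance.

What passing these tests shows — and what it does not: the synthetic
families are i.i.d. random graphs, far easier than real subfamilies, whose
graphs are highly correlated within a class and whose differences are
localized. Success here validates the machinery (criteria, search,
invariances, protocol), not biological performance; the real-data
experiments require curated PDB datasets that are outside this package's
scope.

## Numerical choices and edge cases

* Dense matrices throughout (molecular graphs stay well under a few
  thousand nodes); sparsity would be an internal optimization, not a
  contract.
* Permutation-invariance tolerance: 1e-6 absolute in double precision
  (observed differences are at machine epsilon; the slack absorbs any
  BLAS reordering).
* Degenerate candidates (coincident atoms) reject with a flag; empty graphs
  cannot be pooled or trained on and error early; an all-constant embedding
  matrix falls back to a class-prior head instead of crashing the solver.
* Altloc ties keep conformer `A`; blank element columns fall back to the
  atom-name column; N-terminal detection is by distance, not record order.
* Problem sizes in the test suite (100 random structures of 30–80 residues
  for oracle equality; 120-graph families for classification; 10 repeated
  splits) were chosen as the smallest sizes at which the properties are
  meaningful and stable.

## Known limitations

* Hydrogen placement does not optimize rotatable hydrogens against the
  actual environment and never flips Asn/Gln/His; pKa effects, disulfides
  and crystallographic symmetry mates are out of scope.
* The role table covers the 20 standard amino acids only; modified residues
  are dropped.
* Coordinate-based weights use raw distances by design, so "heavier" edges
  are *longer* bonds; any re-weighting scheme would be a different method.
* The GCN has the expressive power of 1-dimensional Weisfeiler-Lehman
  refinement: families of regular graphs with identical local label
  statistics at every radius are indistinguishable regardless of depth (the
  test suite exploits exactly this boundary to construct a depth-selection
  oracle).

## A worked pipeline

```{r pipeline, eval = FALSE}
library(hbgraph)

helix <- make_ideal_helix(20)
s <- prepare_structure(helix, quiet = TRUE)
g <- build_molecular_graph(assign_roles(s), find_hbonds(s))
glance(g)
autoplot(g)

fam <- make_graph_family(
  classes = list(sparse = list(edge_prob = 0.05), dense = list(edge_prob = 0.15)),
  graphs_per_class = 60, seed = 11
)
ev <- evaluate(fam, hb_hyperparams(), n_splits = 10, seed = 1)
glance(ev)
autoplot(ev)
```
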
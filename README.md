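# hbgraph

Classify protein structures by the **topology of their hydrogen bonds** —
and nothing else.

Protein superfamilies that share a fold and a reaction often split into
subfamilies with different preferred ligands (alpha- vs beta-amylase,
trypsin vs chymotrypsin, seryl- vs threonyl-tRNA synthetase). `hbgraph`
represents each structure as a *molecular graph* whose nodes are
hydrogen-bond donor/acceptor atoms and whose edges are geometrically
feasible hydrogen bonds, then classifies collections of such graphs into
subfamilies with a graph convolutional network (GCN). Because the
representation contains only hydrogen-bond topology, an accurate
classification implicates hydrogen bonding itself in the specificity
mechanism — something no holistic structure comparison can claim.

The package is aimed at structural bioinformaticians who want to (a) extract
hydrogen-bond graphs from PDB files with explicit, reproducible geometric
criteria, and (b) run the full graph-classification protocol (repeated
stratified splits, cross-validated tuning, ablations) on labelled graph
collections, real or synthetic.

## The method in brief

1. **Preparation** — keep one chain's standard-amino-acid `ATOM` records
   (model 1), drop waters/ligands/ions/hydrogens, collapse altlocs, then
   place idealized polar hydrogens (sp2 in-plane, sp3 staggered; N–H 1.00 Å,
   O–H 0.96 Å) at biological-pH protonation states.
2. **Detection** — a bond is feasible between donor D (hydrogen H) and
   acceptor A (antecedent AA) iff

   d(D,A) ≤ 3.9 Å, d(H,A) ≤ 2.5 Å, and ∠D–H–A, ∠H–A–AA, ∠D–A–AA > 90°.

   The search is accelerated by a cell-list lattice and is exactly
   equivalent to the exhaustive O(n²) scan (tested).
3. **Graphs** — nodes = all donors/acceptors (singletons included); edge
   weights 1.0 (*coordinate-free*) or the D–A distance in Å
   (*coordinate-based*).
4. **Embedding** — L layers of `X(l) = σ(Â X(l−1) W(l))` with
   `Â = D^(−1/2)(A+I)D^(−1/2)`, weights shared across graphs, inputs the
   one-hot node roles; per-layer outputs concatenated and mean-pooled into a
   node-order-independent embedding.
5. **Classification** — node-level cross-entropy training with Adam
   (3 layers, batch 4, 50 epochs by default), then a ridge logistic
   regression refit on the pooled embeddings; metrics (accuracy, macro F1,
   macro AUC-ROC) reported as mean ± sd over 10 stratified 4:1 splits.

## Worked example

```r
library(hbgraph)

## A 20-residue ideal alpha-helix: its hydrogen bonds are known in advance.
helix <- make_ideal_helix(20)
s <- prepare_structure(helix, quiet = TRUE)
g <- build_molecular_graph(assign_roles(s), find_hbonds(s))
glance(g)
#> # A tibble: 1 × 6
#>   n_nodes n_edges n_singletons density mode            label
#>     <int>   <int>        <int>   <dbl> <chr>           <chr>
#> 1      40      16            8  0.0205 coordinate_free <NA>

tidy(g)[1:3, c("i", "j", "d_DA", "d_HA", "ang_DHA")]
#> # A tibble: 3 × 5
#>       i     j  d_DA  d_HA ang_DHA
#>   <int> <int> <dbl> <dbl>   <dbl>
#> 1     9     2  3.07  2.09    165.
#> 2    11     4  3.07  2.09    165.
#> 3    13     6  3.07  2.09    165.
```

The 40 nodes are the helix's 20 backbone carbonyl oxygens and 20 amide
nitrogens; the 16 edges are exactly the O(i)→N(i+4) ladder of an ideal
helix (each at a 3.07 Å donor-acceptor distance, well inside the criteria),
and the 8 singletons are the terminal donors/acceptors with no i±4 partner.

Classification on a synthetic two-class family whose classes differ only in
edge density (roles identically distributed, so only topology separates
them):

```r
fam <- make_graph_family(
  classes = list(sparse = list(edge_prob = 0.05), dense = list(edge_prob = 0.15)),
  graphs_per_class = 60, seed = 11
)
ev <- evaluate(fam, hb_hyperparams(), n_splits = 10, seed = 1)
ev
#> <hb_eval> 10 splits, layer concatenation
#>   accuracy 0.979 +/- 0.022
#>   auc      1.000 +/- 0.000
#>   f1       0.979 +/- 0.022
```

Each of the 10 rows in `tidy(ev)` is one stratified 4:1 split (96 training,
24 test graphs); the summary says the GCN recovers the topological classes
at ~98% test accuracy. `autoplot(ev)` draws the per-split metric
distributions, `autoplot(g)` the bond network.

A thin command-line front end (`inst/exec/hbgraph`) wraps the same
functions: `hbgraph prep`, `hbgraph build`, `hbgraph fixtures-helix`,
`hbgraph fixtures-graphs`, `hbgraph eval`.

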
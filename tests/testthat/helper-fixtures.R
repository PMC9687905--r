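## Shared fixtures, generated in code. Expensive ones are memoised per test
## run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

helix20 <- function() cached("helix20", make_ideal_helix(20))

helix20_prepped <- function() {
  cached("helix20_prepped", prepare_structure(helix20(), quiet = TRUE))
}

## Two-class topology family used by classifier tests: sparse vs dense edge
## probability, identical role distribution.
density_family <- function() {
  cached("density_family", make_graph_family(
    classes = list(sparse = list(edge_prob = 0.05), dense = list(edge_prob = 0.15)),
    graphs_per_class = 60, seed = 11
  ))
}

## Small fast family for mechanics-level tests.
small_family <- function() {
  cached("small_family", make_graph_family(
    classes = list(a = list(edge_prob = 0.05), b = list(edge_prob = 0.2)),
    graphs_per_class = 10, n_nodes = c(10L, 20L), seed = 3
  ))
}

## Full-protocol evaluations of the density family, shared across test files.
eval_density_concat <- function() {
  cached(
    "eval_density_concat",
    evaluate(density_family(), hb_hyperparams(), n_splits = 10, seed = 101)
  )
}

eval_density_lastlayer <- function() {
  cached(
    "eval_density_lastlayer",
    evaluate(density_family(), hb_hyperparams(),
      n_splits = 10, seed = 101,
      concat = FALSE
    )
  )
}

eval_density_shuffled <- function() {
  cached("eval_density_shuffled", {
    d <- density_family()
    shuffled <- withr::with_seed(
      202,
      graph_dataset(d$graphs, sample(as.character(d$labels)))
    )
    evaluate(shuffled, hb_hyperparams(), n_splits = 10, seed = 101)
  })
}

random_binary_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A + t(A)
}

random_mol_graph <- function(n = 20, p = 0.15) {
  roles <- sample(c("donor", "acceptor", "both"), n, replace = TRUE)
  A <- random_binary_graph(n, p)
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  new_mol_graph(
    tibble::tibble(role = roles),
    tibble::tibble(
      i = idx[, 1], j = idx[, 2], d_DA = rep(NA_real_, nrow(idx)),
      d_HA = rep(NA_real_, nrow(idx)), ang_DHA = rep(NA_real_, nrow(idx)),
      ang_HAAA = rep(NA_real_, nrow(idx)), ang_DAAA = rep(NA_real_, nrow(idx))
    )
  )
}

## Disjoint-path graphs whose classes share all 1-hop (role, neighbor-role,
## degree) statistics but differ at 2 hops: class A chains d-b-b-a, class B
## an equal mix of d-b-b-d and a-b-b-a chains. One GCN layer cannot separate
## them; three layers can.
path_motif_graph <- function(motifs) {
  roles <- unlist(motifs)
  off <- 0
  ii <- integer(0)
  jj <- integer(0)
  for (r in motifs) {
    m <- length(r)
    ii <- c(ii, off + seq_len(m - 1))
    jj <- c(jj, off + 2:m)
    off <- off + m
  }
  new_mol_graph(
    tibble::tibble(role = roles),
    tibble::tibble(
      i = as.integer(ii), j = as.integer(jj),
      d_DA = rep(NA_real_, length(ii)), d_HA = rep(NA_real_, length(ii)),
      ang_DHA = rep(NA_real_, length(ii)), ang_HAAA = rep(NA_real_, length(ii)),
      ang_DAAA = rep(NA_real_, length(ii))
    )
  )
}

depth_family <- function() {
  cached("depth_family", {
    mkA <- function(k) {
      path_motif_graph(rep(list(c("donor", "both", "both", "acceptor")), k))
    }
    mkB <- function(k) {
      path_motif_graph(c(
        rep(list(c("donor", "both", "both", "donor")), k / 2),
        rep(list(c("acceptor", "both", "both", "acceptor")), k / 2)
      ))
    }
    ks <- rep(c(2, 4, 6, 8), 3)
    graph_dataset(
      c(lapply(ks, mkA), lapply(ks, mkB)),
      rep(c("chains_mixed", "chains_pure"), each = length(ks))
    )
  })
}

bond_pair_key <- function(bonds) {
  sort(paste(bonds$donor_serial, bonds$acceptor_serial))
}

## Hand-written PDB exercising stripping: two chains, waters, a sulfate,
## experimental hydrogens, altlocs, and a second NMR model.
messy_pdb <- function() {
  ala <- function(serial, chain, resseq, x0, altloc = "", occ = 1.00, resn = "ALA") {
    at <- c("N", "CA", "C", "O", "CB")
    el <- c("N", "C", "C", "O", "C")
    dx <- c(0, 1.46, 2.0, 2.0, 1.9)
    dy <- c(0, 0, 1.2, 2.4, -1.0)
    sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial + seq_along(at) - 1, at, altloc, resn, chain, resseq,
      x0 + dx, dy, rep(0, 5), occ, 20.0, el
    )
  }
  c(
    "HEADER    TEST STRUCTURE",
    "MODEL        1",
    ala(1, "A", 1, 0),
    ## altloc pair for residue 2 CA: B has higher occupancy and must win
    sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      6, "N", "", "ALA", "A", 2, 4.0, 0.0, 0.0, 1.00, 20.0, "N"
    ),
    sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      7, "CA", "A", "ALA", "A", 2, 5.46, 0.0, 0.0, 0.40, 20.0, "C"
    ),
    sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      8, "CA", "B", "ALA", "A", 2, 5.50, 0.1, 0.0, 0.60, 20.0, "C"
    ),
    sprintf(
      "ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      9, "HB1", "", "ALA", "A", 2, 5.9, -1.5, 0.0, 1.00, 20.0, "H"
    ),
    ala(10, "B", 1, 20),
    "TER",
    sprintf(
      "HETATM%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      15:17, "O", "", "HOH", "A", 101:103, c(30, 32, 34), 5, 0, 1.00, 30.0, "O"
    ),
    sprintf(
      "HETATM%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      18, "S", "", "SO4", "A", 201, 40.0, 5.0, 0.0, 1.00, 30.0, "S"
    ),
    "ENDMDL",
    "MODEL        2",
    ala(1, "A", 1, 100),
    "ENDMDL",
    "END"
  )
}

## Small hand-built structure in which one hydroxyl donor reaches two
## backbone-carbonyl acceptors: OG at the origin donates via HG toward the
## midpoint of two C=O groups placed symmetrically in range.
twin_acceptor_pdb <- function() {
  rec <- function(serial, name, resn, resseq, x, y, z, el) {
    sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name, resn, resseq, x, y, z, 1.00, 20.0, el
    )
  }
  c(
    rec(1, "CB", "SER", 1, -1.420, 0, 0, "C"),
    rec(2, "OG", "SER", 1, 0, 0, 0, "O"),
    rec(3, "HG", "SER", 1, 0.960, 0, 0, "H"),
    rec(4, "C", "GLY", 2, 3.800, 1.2, 0, "C"),
    rec(5, "O", "GLY", 2, 2.800, 0.5, 0, "O"),
    rec(6, "C", "GLY", 3, 3.800, -1.2, 0, "C"),
    rec(7, "O", "GLY", 3, 2.800, -0.5, 0, "O"),
    "END"
  )
}

## Boundary quadruples with one angle at exactly 90 degrees: the two arms at
## the vertex are axis-aligned so their dot product is exactly zero in
## floating point, while the remaining criteria are comfortably satisfied.
exact90_candidates <- function() {
  list(
    dha = list(
      D = c(0, 0, 0), H = c(1, 0, 0), A = c(1, 1.9, 0), AA = c(1.6, 2.97, 0)
    ),
    haaa = list(
      D = c(1.3, -0.9, 0), H = c(1, 0, 0), A = c(1, 1.9, 0), AA = c(-0.23, 1.9, 0)
    ),
    daaa = list(
      D = c(0, 0, 0), H = c(0.55, 0.83, 0), A = c(0, 2.8, 0), AA = c(-1.23, 2.8, 0)
    )
  )
}

## Construct a hydrogen-bond candidate quadruple with prescribed geometry:
## D at the origin, H at (1,0,0), A at distance d_ha from H making angle
## ang_dha at H, AA at 1.23 A from A making `aa_angle` at A with respect to
## either H or D (`aa_ref`), on the side that opens the remaining angle.
make_candidate <- function(ang_dha, d_ha, aa_angle, aa_ref = c("H", "D")) {
  aa_ref <- match.arg(aa_ref)
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  th <- ang_dha * pi / 180
  ## exact perpendicular at the 90-degree boundary (cos(pi/2) != 0 in floats)
  cth <- if (ang_dha == 90) 0 else cos(th)
  A <- H + d_ha * c(-cth, sin(th), 0)
  u <- if (aa_ref == "H") (H - A) / sqrt(sum((H - A)^2)) else (D - A) / sqrt(sum((D - A)^2))
  p <- c(-u[2], u[1], 0)
  ph <- aa_angle * pi / 180
  cph <- if (aa_angle == 90) 0 else cos(ph)
  cand <- lapply(c(1, -1), function(sgn) A + 1.23 * (u * cph + sgn * p * sin(ph)))
  other_ref <- if (aa_ref == "H") D else H
  other_angle <- vapply(cand, function(aa) {
    v1 <- other_ref - A
    v2 <- aa - A
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }, numeric(1))
  AA <- cand[[which.max(other_angle)]]
  list(D = D, H = H, A = A, AA = AA)
}
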
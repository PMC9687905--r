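test_that("the ideal helix has textbook backbone geometry", {
  s <- read_pdb(helix20())
  a <- as_tibble(s)
  expect_equal(length(unique(a$residue_seq)), 20L)
  ca <- a[a$name == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(d - 3.8) < 0.05))
  ## O(i)..N(i+4) donor-acceptor distances sit inside the criteria envelope
  for (i in c(1, 8, 15)) {
    o <- a[a$name == "O" & a$residue_seq == i, ]
    n <- a[a$name == "N" & a$residue_seq == i + 4, ]
    don <- sqrt((o$x - n$x)^2 + (o$y - n$y)^2 + (o$z - n$z)^2)
    expect_true(don > 2.6 && don < 3.5)
  }
  expect_error(make_ideal_helix(4), class = "hb_param_error")
})

test_that("a 5-residue helix has exactly one i -> i+4 backbone pair in range", {
  s <- prepare_structure(make_ideal_helix(5), quiet = TRUE)
  bonds <- find_hbonds(s)
  bb <- bonds[bonds$donor_name == "N" & bonds$acceptor_name == "O", ]
  expect_equal(nrow(bb), 1L)
  expect_equal(bb$acceptor_residue_seq, 1L)
  expect_equal(bb$donor_residue_seq, 5L)
})

test_that("helix pipeline equals the exhaustive oracle end-to-end", {
  s <- helix20_prepped()
  expect_identical(
    bond_pair_key(find_hbonds(s)),
    bond_pair_key(brute_force_hbond_search(s))
  )
})

test_that("random structures are seed-deterministic and seed-sensitive", {
  expect_identical(
    make_random_structure(20, seed = 3),
    make_random_structure(20, seed = 3)
  )
  bondsets <- lapply(1:6, function(sd) {
    s <- suppressWarnings(
      prepare_structure(make_random_structure(30, seed = sd), quiet = TRUE)
    )
    bond_pair_key(find_hbonds(s))
  })
  expect_gt(length(unique(bondsets)), 1L)
  expect_error(make_random_structure(1, seed = 1), class = "hb_param_error")
})

test_that("random structures respect the minimum inter-residue separation", {
  s <- read_pdb(make_random_structure(30, seed = 9))
  a <- as_tibble(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))
  same_res <- outer(a$residue_seq, a$residue_seq, "==")
  expect_gt(min(d2[!same_res & upper.tri(d2)]), 1.5 - 1e-9)
})

test_that("graph families keep roles identically distributed across classes", {
  d <- density_family()
  expect_length(d$graphs, 120L)
  expect_equal(as.numeric(table(d$labels)), c(60, 60))
  expect_gt(attr(d, "role_chisq_p"), 0.01)
  for (g in d$graphs[c(1, 60, 61, 120)]) validate_mol_graph(g)
  ## edges respect donor/acceptor chemistry
  g <- d$graphs[[1]]
  for (k in seq_len(nrow(g$edges))) {
    ri <- g$nodes$role[g$edges$i[k]]
    rj <- g$nodes$role[g$edges$j[k]]
    expect_true(
      (ri %in% c("donor", "both") && rj %in% c("acceptor", "both")) ||
        (rj %in% c("donor", "both") && ri %in% c("acceptor", "both"))
    )
  }
})

test_that("the two density classes differ in topology, not composition", {
  d <- density_family()
  dens <- vapply(d$graphs, function(g) glance(g)$density, numeric(1))
  expect_gt(mean(dens[d$labels == "dense"]), 2 * mean(dens[d$labels == "sparse"]))
})

test_that("family generation is reproducible and flags degenerate specs", {
  d1 <- make_graph_family(
    classes = list(a = list(edge_prob = 0.1), b = list(edge_prob = 0.2)),
    graphs_per_class = 10, n_nodes = c(10L, 15L), seed = 21
  )
  d2 <- make_graph_family(
    classes = list(a = list(edge_prob = 0.1), b = list(edge_prob = 0.2)),
    graphs_per_class = 10, n_nodes = c(10L, 15L), seed = 21
  )
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_graph_dataset(d1, dir1)
  write_graph_dataset(d2, dir2)
  f1 <- list.files(dir1, full.names = TRUE)
  f2 <- list.files(dir2, full.names = TRUE)
  expect_identical(
    lapply(f1, readLines), lapply(f2, readLines)
  )
  ## manifest round trip
  back <- read_graph_dataset(file.path(dir1, "manifest.tsv"))
  expect_equal(as.character(back$labels), as.character(d1$labels))
  expect_equal(back$graphs[[3]]$A, d1$graphs[[3]]$A)

  expect_warning(
    dd <- make_graph_family(
      classes = list(a = list(edge_prob = 0.1), b = list(edge_prob = 0.1)),
      graphs_per_class = 10, n_nodes = c(10L, 12L), seed = 1
    ),
    "identical class definitions"
  )
  expect_true(attr(dd, "degenerate"))
})

test_that("generator parameter validation", {
  expect_error(
    make_graph_family(classes = list(a = list(edge_prob = 0.1)), graphs_per_class = 10),
    class = "hb_param_error"
  )
  expect_error(
    make_graph_family(
      classes = list(a = list(edge_prob = 0.1), b = list(edge_prob = 0.2)),
      graphs_per_class = 5
    ),
    class = "hb_param_error"
  )
})
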
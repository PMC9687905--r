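test_that("one-hot features follow the fixed (donor, acceptor, both) order", {
  g <- new_mol_graph(
    tibble::tibble(role = c("donor", "acceptor", "both")),
    tibble::tibble(
      i = integer(), j = integer(), d_DA = numeric(), d_HA = numeric(),
      ang_DHA = numeric(), ang_HAAA = numeric(), ang_DAAA = numeric()
    )
  )
  X <- one_hot_node_features(g)
  expect_equal(dim(X), c(3L, 3L))
  expect_equal(unname(X), diag(3))
  expect_true(all(rowSums(X) == 1))

  empty <- new_mol_graph(tibble::tibble(role = character()), g$edges)
  expect_equal(dim(one_hot_node_features(empty)), c(0L, 3L))
})

test_that("normalized adjacency matches closed forms", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(A2), matrix(1 / 2, 2, 2))
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(normalize_adjacency(K3), matrix(1 / 3, 3, 3))
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)),
    class = "hb_graph_error"
  )
})

test_that("normalized adjacency is symmetric with spectrum in [-1, 1]", {
  withr::local_seed(31)
  for (k in 1:50) {
    A <- random_binary_graph(sample(3:25, 1), stats::runif(1, 0.05, 0.5))
    Ah <- normalize_adjacency(A)
    expect_lt(max(abs(Ah - t(Ah))), 1e-12)
    ev <- eigen(Ah, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
  }
})

test_that("forward pass applies aggregation then transformation", {
  withr::local_seed(5)
  g <- random_mol_graph(10, 0.3)
  params <- init_gcn_params(n_layers = 2, hidden_dim = 8, seed = 2)
  X0 <- one_hot_node_features(g)
  Ah <- normalize_adjacency(g$A)
  out <- gcn_forward(Ah, X0, params)
  expect_equal(out[[1]], pmax(Ah %*% X0 %*% params$weights[[1]], 0))
  expect_equal(out[[2]], pmax(Ah %*% out[[1]] %*% params$weights[[2]], 0))

  ## all-zero weights give all-zero outputs
  zero <- params
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  expect_true(all(unlist(gcn_forward(Ah, X0, zero)) == 0))

  ## dimension mismatch names the offending layer
  err <- expect_error(
    gcn_forward(Ah, cbind(X0, X0), params),
    class = "hb_shape_error"
  )
  expect_match(conditionMessage(err), "layer 1")
})

test_that("forward pass commutes with node permutation at every layer", {
  withr::local_seed(6)
  g <- random_mol_graph(14, 0.25)
  params <- init_gcn_params(n_layers = 3, hidden_dim = 16, seed = 4)
  out <- gcn_forward(normalize_adjacency(g$A), one_hot_node_features(g), params)
  for (k in 1:5) {
    perm <- sample(14)
    gp <- permute_graph(g, perm)
    outp <- gcn_forward(
      normalize_adjacency(gp$A), one_hot_node_features(gp), params
    )
    for (l in 1:3) expect_equal(outp[[l]], out[[l]][perm, ], tolerance = 1e-12)
  }
})

test_that("on a k-regular graph with constant features one linear layer is exact", {
  ## every row of X0 equal and A k-regular binary: the constant vector is an
  ## eigenvector of Ahat with eigenvalue 1, so Ahat X0 = X0
  n <- 8
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, c(i %% n + 1, (i - 2) %% n + 1)] <- 1 # cycle, 2-regular
  X0 <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  Ah <- normalize_adjacency(A)
  expect_equal(Ah %*% X0, X0, tolerance = 1e-12)
  W <- matrix(stats::runif(3 * 5), 3, 5)
  params <- structure(
    list(weights = list(W), activation = "relu", dims = c(3, 5)),
    class = "gcn_params"
  )
  expect_equal(gcn_forward(Ah, X0, params)[[1]], pmax(X0 %*% W, 0), tolerance = 1e-12)
})

test_that("concatenation stacks layer widths; ablation keeps the last layer", {
  layers <- list(matrix(1, 4, 64), matrix(2, 4, 64), matrix(3, 4, 64))
  expect_equal(ncol(concat_layers(layers)), 192L)
  expect_equal(concat_layers(layers, concat = FALSE), layers[[3]])
  expect_equal(concat_layers(layers[1]), layers[[1]])
  expect_error(
    concat_layers(list(matrix(1, 4, 2), matrix(1, 5, 2))),
    class = "hb_shape_error"
  )
})

test_that("mean pooling is exact on constant and symmetric inputs and needs nodes", {
  u <- c(1, -2, 3)
  expect_equal(mean_pool(rbind(u, u, u)), u, ignore_attr = TRUE)
  expect_equal(mean_pool(rbind(u, -u)), c(0, 0, 0), ignore_attr = TRUE)
  expect_error(mean_pool(matrix(numeric(0), 0, 3)), class = "hb_graph_error")
})

test_that("embeddings are invariant to node order, both modes, to 1e-6", {
  withr::local_seed(17)
  params <- init_gcn_params(seed = 3)
  for (k in 1:10) {
    g <- random_mol_graph(sample(10:40, 1), stats::runif(1, 0.05, 0.3))
    if (k > 5) {
      ## coordinate-based variant: replace weights by plausible distances
      w <- g$A[upper.tri(g$A)]
      w[w != 0] <- stats::runif(sum(w != 0), 2.5, 3.9)
      A <- matrix(0, nrow(g$A), ncol(g$A))
      A[upper.tri(A)] <- w
      g$A <- A + t(A)
      g$mode <- "coordinate_based"
    }
    e0 <- embed_graph(g, params)
    for (p in 1:20) {
      gp <- permute_graph(g, sample(nrow(g$nodes)))
      expect_lt(max(abs(embed_graph(gp, params) - e0)), 1e-6)
    }
  }
})
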
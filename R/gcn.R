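## Graph convolutional core: one-hot node features, symmetric normalized
## adjacency, shared-weight multi-layer propagation, layer concatenation and
## mean pooling. All matrices are dense; molecular graphs stay well under a
## few thousand nodes.

ROLE_LEVELS <- c("donor", "acceptor", "both")

#' One-hot node features from donor/acceptor roles
#'
#' Initial node information is just the role label, so the input feature
#' matrix is the one-hot encoding over the fixed column order
#' (donor, acceptor, both).
#'
#' @param g A `mol_graph`.
#' @return An `N x 3` matrix with one-hot rows.
#' @export
one_hot_node_features <- function(g) {
  roles <- g$nodes$role
  if (length(roles) && !all(roles %in% ROLE_LEVELS)) {
    rlang::abort("every node needs a role in {donor, acceptor, both}",
      class = "hb_graph_error"
    )
  }
  X <- matrix(0, length(roles), 3,
    dimnames = list(NULL, ROLE_LEVELS)
  )
  if (length(roles)) X[cbind(seq_along(roles), match(roles, ROLE_LEVELS))] <- 1
  X
}

#' Symmetric normalized adjacency with self-loops
#'
#' Computes the propagation operator used by every GCN layer,
#' `D^(-1/2) (A + I) D^(-1/2)`, where `D` is the degree matrix of `A + I`.
#' Self-loops make the operator well defined for singleton (degree-0) nodes.
#' For binary adjacencies the eigenvalues lie in `[-1, 1]`.
#'
#' @param A Symmetric nonnegative weight matrix with zero diagonal.
#' @return The normalized operator, same shape as `A`.
#' @export
normalize_adjacency <- function(A) {
  if (is.data.frame(A)) A <- as.matrix(A)
  if (nrow(A) != ncol(A) || (nrow(A) && max(abs(A - t(A))) > 1e-9)) {
    rlang::abort("adjacency must be square and symmetric",
      class = "hb_graph_error"
    )
  }
  n <- nrow(A)
  if (n == 0L) {
    return(A)
  }
  At <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

#' GCN parameter initialization
#'
#' Glorot-uniform weights for `n_layers` layers of width `hidden_dim` on top
#' of the 3-column one-hot input, shared by every graph in a collection.
#'
#' @param n_layers Number of GCN layers.
#' @param hidden_dim Width of each layer.
#' @param input_dim Input feature count (3 for role one-hots).
#' @param seed Integer seed for the initialization.
#' @return List of class `gcn_params`: `weights` (list of matrices),
#'   `activation` (`"relu"`), `dims`.
#' @export
init_gcn_params <- function(n_layers = 3L, hidden_dim = 64L, input_dim = 3L,
                            seed = 1L) {
  dims <- c(input_dim, rep(hidden_dim, n_layers))
  weights <- with_local_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1]))
      matrix(
        stats::runif(dims[l] * dims[l + 1], -lim, lim),
        dims[l], dims[l + 1]
      )
    })
  })
  structure(
    list(weights = weights, activation = "relu", dims = dims),
    class = "gcn_params"
  )
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Multi-layer GCN forward pass
#'
#' Propagates node features through `X(l) = sigma(Ahat X(l-1) W(l))`:
#' neighborhood aggregation by the normalized adjacency, then linear
#' transformation and the nonlinearity, in that order.
#'
#' @param Ahat Normalized adjacency from [normalize_adjacency()].
#' @param X0 Input feature matrix (`N x 3` one-hots).
#' @param params A `gcn_params` object.
#' @param keep_preact Also return pre-activation matrices (for training).
#' @return List of per-layer output matrices `X(1)..X(L)` (with
#'   pre-activations in attribute `"preact"` when requested).
#' @export
gcn_forward <- function(Ahat, X0, params, keep_preact = FALSE) {
  X <- X0
  out <- vector("list", length(params$weights))
  pre <- if (keep_preact) vector("list", length(params$weights))
  for (l in seq_along(params$weights)) {
    W <- params$weights[[l]]
    if (ncol(X) != nrow(W)) {
      rlang::abort(
        sprintf(
          "layer %d: feature width %d does not match weight rows %d",
          l, ncol(X), nrow(W)
        ),
        class = "hb_shape_error"
      )
    }
    Z <- (Ahat %*% X) %*% W
    if (keep_preact) pre[[l]] <- Z
    X <- relu(Z)
    out[[l]] <- X
  }
  if (keep_preact) attr(out, "preact") <- pre
  out
}

#' Concatenate per-layer node features
#'
#' Column-binds the layer outputs `X(1)..X(L)` into the final per-node
#' representation; with `concat = FALSE` only the last layer is kept (the
#' no-concatenation ablation).
#'
#' @param layers List of `N x D(l)` matrices sharing a row count.
#' @param concat Concatenate all layers (`TRUE`) or keep the last only.
#' @return An `N x sum(D)` (or `N x D(L)`) matrix.
#' @export
concat_layers <- function(layers, concat = TRUE) {
  ns <- vapply(layers, nrow, integer(1))
  if (length(unique(ns)) > 1L) {
    rlang::abort("layer outputs disagree on node count", class = "hb_shape_error")
  }
  if (!concat) {
    return(layers[[length(layers)]])
  }
  do.call(cbind, layers)
}

#' Mean-pool node features into a graph embedding
#'
#' Averages the per-node rows, removing any dependence on node order and on
#' graph size.
#'
#' @param X_all Per-node feature matrix (`N >= 1` rows).
#' @return Numeric vector of length `ncol(X_all)`.
#' @export
mean_pool <- function(X_all) {
  if (nrow(X_all) == 0L) {
    rlang::abort("cannot pool an empty graph (no nodes)", class = "hb_graph_error")
  }
  colMeans(X_all)
}

#' Embed a molecular graph with fixed GCN parameters
#'
#' One-hot features, normalized adjacency, forward pass, concatenation (or
#' last layer), mean pooling.
#'
#' @param g A `mol_graph`.
#' @param params A `gcn_params`.
#' @param concat Use layer concatenation (default) or last layer only.
#' @return Numeric embedding vector.
#' @export
embed_graph <- function(g, params, concat = TRUE) {
  Ahat <- normalize_adjacency(g$A)
  layers <- gcn_forward(Ahat, one_hot_node_features(g), params)
  mean_pool(concat_layers(layers, concat = concat))
}
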
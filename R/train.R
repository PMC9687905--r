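#' Hyperparameter bundle
#'
#' Defaults follow the tuned operating point of the method: 3 GCN layers,
#' batch size 4, 50 epochs, Adam with learning rate 1e-3 when tuning is
#' disabled. The tuning grids are `lr` in {5e-4, 1e-4, 5e-3, 1e-3}, batch
#' size in {1, 2, 4, 8, 16} and 1-6 layers.
#'
#' @param lr Adam learning rate.
#' @param batch_size Graphs per optimization step.
#' @param n_layers Number of GCN layers.
#' @param epochs Training epochs.
#' @param hidden_dim Width of every GCN layer.
#' @param seed Seed for initialization and batch shuffling.
#' @return A list of class `hb_hyperparams`.
#' @export
hb_hyperparams <- function(lr = 1e-3, batch_size = 4L, n_layers = 3L,
                           epochs = 50L, hidden_dim = 64L, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, n_layers >= 1, epochs >= 0, hidden_dim >= 1)
  structure(
    list(
      lr = lr, batch_size = as.integer(batch_size),
      n_layers = as.integer(n_layers), epochs = as.integer(epochs),
      hidden_dim = as.integer(hidden_dim), seed = as.integer(seed)
    ),
    class = "hb_hyperparams"
  )
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

adam_new <- function(shapes) {
  list(
    m = lapply(shapes, function(s) matrix(0, s[1], s[2])),
    v = lapply(shapes, function(s) matrix(0, s[1], s[2])),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in seq_along(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

#' Train the shared-weight GCN classifier
#'
#' Optimizes the layer weights `W(1..L)` and a linear classification matrix
#' with node-level cross-entropy — every node inherits its graph's subfamily
#' label — using Adam over shuffled graph minibatches for exactly
#' `hyper$epochs` epochs. The same weight matrices are applied to every graph
#' so all graphs share one feature space. After GCN training, the final
#' graph-level head is a logistic-regression classifier (ridge-penalized,
#' deterministic) refit on the mean-pooled concatenated embeddings.
#'
#' @param graphs List of `mol_graph` objects (all with `>= 1` node).
#' @param labels Class labels, one per graph (factor or character); at least
#'   two classes.
#' @param hyper An [hb_hyperparams()] bundle.
#' @param concat Concatenate all layer outputs (default) or use the last
#'   layer only (the ablation mode).
#' @return An object of class `hb_gcn_model`: trained `gcn_params`, the
#'   glmnet head, class levels, per-epoch mean training loss.
#' @export
train_gcn <- function(graphs, labels, hyper = hb_hyperparams(), concat = TRUE) {
  if (length(graphs) == 0L) {
    rlang::abort("empty training set", class = "hb_train_error")
  }
  if (any(vapply(graphs, function(g) nrow(g$nodes), integer(1)) == 0L)) {
    rlang::abort("graph with zero nodes cannot be trained on",
      class = "hb_train_error"
    )
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    rlang::abort("need at least two classes", class = "hb_train_error")
  }
  M <- length(graphs)
  stopifnot(length(labels) == M)
  C <- nlevels(labels)
  y <- as.integer(labels)

  params <- init_gcn_params(
    n_layers = hyper$n_layers, hidden_dim = hyper$hidden_dim,
    seed = derive_seed(hyper$seed, 1L)
  )
  L <- hyper$n_layers
  dims <- params$dims
  emb_dim <- if (concat) sum(dims[-1]) else dims[L + 1L]
  theta <- with_local_seed(derive_seed(hyper$seed, 2L), {
    lim <- sqrt(6 / (emb_dim + C))
    matrix(stats::runif(emb_dim * C, -lim, lim), emb_dim, C)
  })

  pre <- lapply(graphs, function(g) {
    list(Ahat = normalize_adjacency(g$A), X0 = one_hot_node_features(g))
  })

  shapes <- c(
    lapply(params$weights, dim),
    list(dim(theta))
  )
  opt <- adam_new(shapes)
  epoch_loss <- numeric(hyper$epochs)

  if (hyper$epochs > 0L) {
    with_local_seed(derive_seed(hyper$seed, 3L), {
      for (ep in seq_len(hyper$epochs)) {
        ord <- sample.int(M)
        batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
        ep_loss <- 0
        ep_nodes <- 0
        for (b in batches) {
          gradW <- lapply(params$weights, function(w) matrix(0, nrow(w), ncol(w)))
          gradT <- matrix(0, emb_dim, C)
          nb <- sum(vapply(b, function(i) nrow(pre[[i]]$X0), integer(1)))
          bloss <- 0
          for (i in b) {
            Ahat <- pre[[i]]$Ahat
            X0 <- pre[[i]]$X0
            layers <- gcn_forward(Ahat, X0, params, keep_preact = TRUE)
            preact <- attr(layers, "preact")
            Xall <- concat_layers(layers, concat = concat)
            P <- softmax_rows(Xall %*% theta)
            yi <- y[i]
            bloss <- bloss - sum(log(pmax(P[, yi], 1e-300)))
            dZ <- P
            dZ[, yi] <- dZ[, yi] - 1
            dZ <- dZ / nb
            gradT <- gradT + crossprod(Xall, dZ)
            dXall <- dZ %*% t(theta)
            carry <- NULL
            col_hi <- emb_dim
            for (l in L:1) {
              if (concat) {
                dl <- dims[l + 1L]
                dX <- dXall[, (col_hi - dl + 1L):col_hi, drop = FALSE]
                col_hi <- col_hi - dl
              } else {
                dX <- if (l == L) dXall else matrix(0, nrow(X0), dims[l + 1L])
              }
              if (!is.null(carry)) dX <- dX + carry
              dpre <- dX * (preact[[l]] > 0)
              Xin <- if (l == 1L) X0 else layers[[l - 1L]]
              gradW[[l]] <- gradW[[l]] + crossprod(Ahat %*% Xin, dpre)
              if (l > 1L) {
                carry <- Ahat %*% (dpre %*% t(params$weights[[l]]))
              }
            }
          }
          st <- adam_step(
            opt, c(params$weights, list(theta)), c(gradW, list(gradT)),
            hyper$lr
          )
          opt <- st$state
          params$weights <- st$params[seq_len(L)]
          theta <- st$params[[L + 1L]]
          ep_loss <- ep_loss + bloss
          ep_nodes <- ep_nodes + nb
        }
        epoch_loss[ep] <- ep_loss / ep_nodes
      }
    })
  }

  emb <- t(vapply(
    graphs, function(g) embed_graph(g, params, concat = concat),
    numeric(emb_dim)
  ))
  head_fit <- fit_lr_head(emb, labels)

  structure(
    list(
      params = params, theta = theta, head = head_fit,
      classes = levels(labels), concat = concat, hyper = hyper,
      epoch_loss = epoch_loss, emb_dim = emb_dim
    ),
    class = "hb_gcn_model"
  )
}

## Ridge-penalized multinomial logistic regression on pooled embeddings
## (deterministic coordinate-descent solver; unit regularization strength
## scaled by sample size). Embeddings with no informative column — possible
## when every graph pools to the same point — fall back to class priors.
fit_lr_head <- function(emb, labels) {
  informative <- apply(emb, 2, function(col) diff(range(col)) > 1e-12)
  if (!any(informative)) {
    return(structure(
      list(priors = as.numeric(table(labels)) / length(labels)),
      class = "hb_prior_head"
    ))
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(
      x = emb[, informative, drop = FALSE], y = labels,
      family = "multinomial", alpha = 0,
      lambda = 1 / length(labels), standardize = FALSE
    ),
    ## glmnet flags very small classes; expected on tiny CV folds
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(fit = fit, informative = informative), class = "hb_lr_head")
}

head_probs <- function(model, emb) {
  head <- model$head
  if (inherits(head, "hb_prior_head")) {
    p <- matrix(head$priors, nrow(emb), length(model$classes),
      byrow = TRUE, dimnames = list(NULL, model$classes)
    )
    return(p)
  }
  p <- predict(head$fit,
    newx = emb[, head$informative, drop = FALSE],
    type = "response"
  )[, , 1, drop = FALSE]
  p <- matrix(p, nrow(emb), length(model$classes),
    dimnames = list(NULL, model$classes)
  )
  p / rowSums(p)
}

#' @export
print.hb_gcn_model <- function(x, ...) {
  cat(sprintf(
    "<hb_gcn_model> %d GCN layers (dim %d), %s, classes: %s\n",
    x$hyper$n_layers, x$hyper$hidden_dim,
    if (x$concat) "layer concatenation" else "last layer only",
    paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Predict subfamily labels for molecular graphs
#'
#' Embeds each graph with the trained GCN parameters and applies the
#' logistic-regression head. Probabilities sum to one; the predicted class
#' is the argmax.
#'
#' @param object A trained `hb_gcn_model`.
#' @param graphs A `mol_graph` or a list of them.
#' @param ... Unused.
#' @return A tibble with one row per graph: `.pred_class` plus one
#'   probability column per class (`.prob_<class>`).
#' @export
predict.hb_gcn_model <- function(object, graphs, ...) {
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  emb <- t(vapply(
    graphs, function(g) embed_graph(g, object$params, concat = object$concat),
    numeric(object$emb_dim)
  ))
  p <- head_probs(object, emb)
  out <- tibble::as_tibble(p, .name_repair = ~ paste0(".prob_", .x))
  out$.pred_class <- factor(
    object$classes[max.col(p, ties.method = "first")],
    levels = object$classes
  )
  out[, c(".pred_class", paste0(".prob_", object$classes))]
}
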
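#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a molecular graph
#'
#' `tidy()` returns the edge table (one row per hydrogen bond, with the
#' stored geometry); `glance()` returns a one-row summary.
#'
#' @param x A `mol_graph`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mol_graph <- function(x, ...) x$edges

#' @rdname tidy.mol_graph
#' @export
glance.mol_graph <- function(x, ...) {
  n <- nrow(x$nodes)
  m <- nrow(x$edges)
  tibble::tibble(
    n_nodes = n, n_edges = m,
    n_singletons = if (n) sum(rowSums(x$A != 0) == 0) else 0L,
    density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    mode = x$mode,
    label = x$label %||% NA_character_
  )
}

#' Tidy a trained classifier
#'
#' `tidy()` returns the per-epoch mean training loss; `glance()` a one-row
#' fit summary.
#'
#' @param x An `hb_gcn_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hb_gcn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$epoch_loss), loss = x$epoch_loss)
}

#' @rdname tidy.hb_gcn_model
#' @export
glance.hb_gcn_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$hyper$n_layers, hidden_dim = x$hyper$hidden_dim,
    epochs = x$hyper$epochs, lr = x$hyper$lr,
    batch_size = x$hyper$batch_size, concat = x$concat,
    embedding_dim = x$emb_dim, n_classes = length(x$classes),
    final_loss = if (length(x$epoch_loss)) {
      x$epoch_loss[length(x$epoch_loss)]
    } else {
      NA_real_
    }
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-split metric rows; `glance()` the mean and
#' standard deviation of each metric in one wide row.
#'
#' @param x An `hb_eval`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hb_eval <- function(x, ...) x$per_split

#' @rdname tidy.hb_eval
#' @export
glance.hb_eval <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(.rows = 1)
  for (i in seq_len(nrow(s))) {
    out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out$n_splits <- x$n_splits
  out
}
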
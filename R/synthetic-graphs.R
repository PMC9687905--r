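#' Generate labelled synthetic molecular-graph families
#'
#' Produces a [graph_dataset()] whose classes differ only in edge-topology
#' statistics: node roles are drawn i.i.d. from the same distribution for
#' every class, and edges are placed between donor-capable and
#' acceptor-capable nodes with a class-specific probability. A classifier
#' therefore has to exploit topology, not node composition — the synthetic
#' analogue of subfamilies sharing a fold but differing in bonding pattern.
#'
#' @param classes Named list of class definitions, each a list with
#'   `edge_prob` (attachment probability per eligible donor-acceptor pair).
#'   At least two classes.
#' @param graphs_per_class Graphs per class (at least 10).
#' @param n_nodes Length-2 integer range; node counts are uniform on it.
#' @param role_probs Probabilities for roles (donor, acceptor, both); shared
#'   by all classes.
#' @param mode Graph mode; `"coordinate_based"` draws edge weights uniformly
#'   from hydrogen-bond-plausible distances (2.5-3.9 A).
#' @param seed Integer seed; fixed seed, identical dataset.
#' @return A `graph_dataset`. Attribute `"role_chisq_p"` holds the p-value
#'   of a chi-square test of role-count homogeneity across classes;
#'   attribute `"degenerate"` flags identical class definitions.
#' @export
#' @examples
#' d <- make_graph_family(
#'   classes = list(sparse = list(edge_prob = 0.05), dense = list(edge_prob = 0.15)),
#'   graphs_per_class = 10, seed = 7
#' )
#' d
make_graph_family <- function(classes, graphs_per_class = 60L,
                              n_nodes = c(30L, 60L),
                              role_probs = c(donor = 0.4, acceptor = 0.4, both = 0.2),
                              mode = "coordinate_free", seed = 1L) {
  if (length(classes) < 2L) {
    rlang::abort("need at least 2 classes", class = "hb_param_error")
  }
  if (graphs_per_class < 10L) {
    rlang::abort("need at least 10 graphs per class", class = "hb_param_error")
  }
  mode <- match.arg(mode, c("coordinate_free", "coordinate_based"))
  degenerate <- length(unique(lapply(classes, function(cl) cl$edge_prob))) == 1L
  if (degenerate) {
    rlang::warn("identical class definitions: classes are indistinguishable by construction")
  }

  graphs <- list()
  labels <- character(0)
  role_counts <- matrix(0, length(classes), 3,
    dimnames = list(names(classes), ROLE_LEVELS)
  )
  with_local_seed(seed, {
    for (cl in names(classes)) {
      p <- classes[[cl]]$edge_prob
      for (gi in seq_len(graphs_per_class)) {
        n <- sample(n_nodes[1]:n_nodes[2], 1L)
        roles <- sample(ROLE_LEVELS, n, replace = TRUE, prob = role_probs)
        role_counts[cl, ] <- role_counts[cl, ] + table(factor(roles, ROLE_LEVELS))
        pairs <- which(
          upper.tri(matrix(TRUE, n, n)),
          arr.ind = TRUE
        )
        can_d <- roles %in% c("donor", "both")
        can_a <- roles %in% c("acceptor", "both")
        eligible <- (can_d[pairs[, 1]] & can_a[pairs[, 2]]) |
          (can_d[pairs[, 2]] & can_a[pairs[, 1]])
        pairs <- pairs[eligible, , drop = FALSE]
        on <- stats::runif(nrow(pairs)) < p
        pairs <- pairs[on, , drop = FALSE]
        m <- nrow(pairs)
        edges <- tibble::tibble(
          i = pairs[, 1], j = pairs[, 2],
          d_DA = if (mode == "coordinate_based") {
            stats::runif(m, 2.5, 3.9)
          } else {
            rep(NA_real_, m)
          },
          d_HA = rep(NA_real_, m), ang_DHA = rep(NA_real_, m),
          ang_HAAA = rep(NA_real_, m), ang_DAAA = rep(NA_real_, m)
        )
        graphs[[length(graphs) + 1L]] <- new_mol_graph(
          tibble::tibble(role = roles), edges,
          mode = mode, label = cl
        )
        labels <- c(labels, cl)
      }
    }
  })
  d <- graph_dataset(graphs, labels)
  chi_p <- tryCatch(
    suppressWarnings(stats::chisq.test(role_counts)$p.value),
    error = function(e) NA_real_
  )
  attr(d, "role_chisq_p") <- chi_p
  attr(d, "degenerate") <- degenerate
  d
}

## ---- dataset serialization -------------------------------------------------

#' Write / read a graph dataset as per-graph JSON plus a manifest
#'
#' `write_graph_dataset` stores one JSON file per graph and a tab-separated
#' manifest of (file, label) rows; `read_graph_dataset` loads a manifest
#' back into a [graph_dataset()].
#'
#' @param d A `graph_dataset`.
#' @param dir Output directory (created if needed).
#' @param manifest Path to a manifest TSV.
#' @return The manifest path (write) or a `graph_dataset` (read).
#' @export
write_graph_dataset <- function(d, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("graph_%04d.json", seq_along(d$graphs))
  for (i in seq_along(d$graphs)) {
    write_graph_json(d$graphs[[i]], file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(file = files, label = as.character(d$labels)),
    manifest,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(manifest)
}

#' @rdname write_graph_dataset
#' @export
read_graph_dataset <- function(manifest) {
  tab <- utils::read.table(manifest, sep = "\t", header = TRUE, colClasses = "character")
  dir <- dirname(manifest)
  graphs <- lapply(file.path(dir, tab$file), read_graph_json)
  graph_dataset(graphs, tab$label)
}
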
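#' Molecular graph of hydrogen-bond topology
#'
#' Nodes are donor/acceptor atoms (singletons included); edges are feasible
#' hydrogen bonds between a donor and an acceptor. In `coordinate_free` mode
#' every edge weight is 1; in `coordinate_based` mode the weight is the
#' donor-acceptor Euclidean distance in angstroms. The adjacency matrix is
#' symmetric with a zero diagonal.
#'
#' @param nodes Tibble with at least `role` (`donor`/`acceptor`/`both`);
#'   typically the output of [assign_roles()].
#' @param edges Tibble with columns `i`, `j` (node indices) and, for
#'   coordinate mode, `d_DA`; typically derived from [find_hbonds()].
#' @param mode `"coordinate_free"` or `"coordinate_based"`.
#' @param label Optional class label (character scalar).
#' @return An object of class `mol_graph` with elements `nodes`, `edges`,
#'   `A` (weight matrix), `mode`, `label`.
#' @export
new_mol_graph <- function(nodes, edges, mode = "coordinate_free", label = NULL) {
  mode <- match.arg(mode, c("coordinate_free", "coordinate_based"))
  n <- nrow(nodes)
  if (nrow(edges) && (any(edges$i < 1 | edges$i > n | edges$j < 1 | edges$j > n))) {
    rlang::abort("edge references a node outside the node table",
      class = "hb_graph_error"
    )
  }
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    w <- if (mode == "coordinate_free") rep(1, nrow(edges)) else edges$d_DA
    A[cbind(edges$i, edges$j)] <- w
    A[cbind(edges$j, edges$i)] <- w
  }
  structure(
    list(nodes = nodes, edges = edges, A = A, mode = mode, label = label),
    class = "mol_graph"
  )
}

#' Build the molecular graph of a structure's hydrogen bonds
#'
#' Combines a role table and a bond table into a [mol_graph][new_mol_graph]:
#' every role atom is a node (bonded or singleton, in role-table order), and
#' each bonded donor-acceptor pair contributes one undirected edge.
#'
#' @param roles Output of [assign_roles()].
#' @param bonds Output of [find_hbonds()].
#' @param mode `"coordinate_free"` (binary weights) or `"coordinate_based"`
#'   (donor-acceptor distance weights).
#' @param label Optional class label.
#' @return A `mol_graph`.
#' @export
#' @examples
#' s <- prepare_structure(make_ideal_helix(8), quiet = TRUE)
#' g <- build_molecular_graph(assign_roles(s), find_hbonds(s))
#' glance(g)
build_molecular_graph <- function(roles, bonds, mode = "coordinate_free",
                                  label = NULL) {
  i <- match(bonds$donor_row, roles$atom_row)
  j <- match(bonds$acceptor_row, roles$atom_row)
  if (nrow(bonds) && any(is.na(i) | is.na(j))) {
    rlang::abort("bond references an atom absent from the role table",
      class = "hb_graph_error"
    )
  }
  nodes <- roles[, c(
    "atom_row", "serial", "name", "residue_name", "chain",
    "residue_seq", "icode", "role"
  )]
  edges <- tibble::tibble(
    i = i, j = j,
    d_DA = bonds$d_DA %||% numeric(0), d_HA = bonds$d_HA %||% numeric(0),
    ang_DHA = bonds$ang_DHA %||% numeric(0),
    ang_HAAA = bonds$ang_HAAA %||% numeric(0),
    ang_DAAA = bonds$ang_DAAA %||% numeric(0)
  )
  new_mol_graph(nodes, edges, mode = mode, label = label)
}

#' Hydrogen-bond graph straight from PDB input
#'
#' Convenience pipeline: [prepare_structure()], [assign_roles()],
#' [find_hbonds()], [build_molecular_graph()].
#'
#' @inheritParams prepare_structure
#' @inheritParams build_molecular_graph
#' @param criteria See [hbond_criteria()].
#' @param role_table See [default_role_table()].
#' @return A `mol_graph`.
#' @export
structure_to_graph <- function(x, chain = NULL, mode = "coordinate_free",
                               criteria = hbond_criteria(),
                               role_table = default_role_table(),
                               pre_protonated = FALSE, label = NULL,
                               quiet = TRUE) {
  s <- prepare_structure(x,
    chain = chain, pre_protonated = pre_protonated,
    quiet = quiet
  )
  build_molecular_graph(
    assign_roles(s, role_table),
    find_hbonds(s, criteria, role_table),
    mode = mode, label = label
  )
}

#' Validate molecular-graph invariants
#'
#' Checks symmetry, zero diagonal, and the mode's weight contract (binary
#' weights for coordinate-free graphs; weights in `(0, d_da]` for
#' coordinate-based ones).
#'
#' @param g A `mol_graph`.
#' @param d_da Upper bound for coordinate-based weights.
#' @return `TRUE` invisibly, or an error.
#' @export
validate_mol_graph <- function(g, d_da = 3.9) {
  stopifnot(inherits(g, "mol_graph"))
  A <- g$A
  if (nrow(A) != nrow(g$nodes)) {
    rlang::abort("adjacency dimension does not match node count",
      class = "hb_graph_error"
    )
  }
  if (nrow(A) && (max(abs(A - t(A))) > 1e-12 || any(diag(A) != 0))) {
    rlang::abort("adjacency must be symmetric with zero diagonal",
      class = "hb_graph_error"
    )
  }
  w <- A[A != 0]
  if (g$mode == "coordinate_free" && length(w) && any(w != 1)) {
    rlang::abort("coordinate-free weights must all equal 1",
      class = "hb_graph_error"
    )
  }
  if (g$mode == "coordinate_based" && length(w) && any(w <= 0 | w > d_da)) {
    rlang::abort(sprintf("coordinate-based weights must lie in (0, %g]", d_da),
      class = "hb_graph_error"
    )
  }
  if (!all(g$nodes$role %in% c("donor", "acceptor", "both"))) {
    rlang::abort("node roles must be donor/acceptor/both",
      class = "hb_graph_error"
    )
  }
  invisible(TRUE)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf(
    "<mol_graph> %d nodes, %d edges, %s%s\n",
    nrow(x$nodes), nrow(x$edges), x$mode,
    if (is.null(x$label)) "" else paste0(", class ", x$label)
  ))
  invisible(x)
}

#' Reorder the nodes of a molecular graph
#'
#' Applies a permutation to the node order (and the adjacency accordingly).
#' Used to exercise the order-invariance of graph embeddings.
#'
#' @param g A `mol_graph`.
#' @param perm Integer permutation of `seq_len(nrow(g$nodes))`; node `k` of
#'   the result is node `perm[k]` of the input.
#' @return The permuted `mol_graph`.
#' @export
permute_graph <- function(g, perm) {
  stopifnot(length(perm) == nrow(g$nodes), !anyDuplicated(perm))
  inv <- order(perm)
  edges <- g$edges
  if (nrow(edges)) {
    edges$i <- inv[edges$i]
    edges$j <- inv[edges$j]
  }
  out <- g
  out$nodes <- g$nodes[perm, , drop = FALSE]
  out$edges <- edges
  out$A <- g$A[perm, perm, drop = FALSE]
  out
}

## ---- serialization ---------------------------------------------------------

#' Write / read a molecular graph as JSON
#'
#' The whole graph (node table, edge table with stored geometry, mode,
#' label) round-trips through a single JSON document.
#'
#' @param g A `mol_graph`.
#' @param path File path.
#' @return `write_graph_json` returns `path` invisibly; `read_graph_json`
#'   returns the `mol_graph`.
#' @export
write_graph_json <- function(g, path) {
  jsonlite::write_json(
    list(
      format = "hbgraph-graph/1", mode = g$mode,
      label = g$label %||% NA_character_,
      nodes = g$nodes, edges = g$edges
    ),
    path,
    dataframe = "columns", digits = NA, na = "null", auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- tibble::as_tibble(doc$nodes)
  edges <- tibble::as_tibble(doc$edges)
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(
      i = integer(), j = integer(), d_DA = numeric(), d_HA = numeric(),
      ang_DHA = numeric(), ang_HAAA = numeric(), ang_DAAA = numeric()
    )
  }
  label <- doc$label
  if (is.null(label) || (length(label) == 1 && is.na(label))) label <- NULL
  new_mol_graph(nodes, edges, mode = doc$mode, label = label)
}
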
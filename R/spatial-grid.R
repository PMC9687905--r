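#' Lattice spatial grid for radius queries
#'
#' Cell-list data structure: each atom is binned into the integer cell
#' `floor(position / cell_size)` per axis, so a radius query with
#' `r <= cell_size` only has to examine the 27 cells around the query point's
#' cell (proportionally wider shells for larger radii).
#'
#' @param positions An n x 3 coordinate matrix (angstroms), or a data frame
#'   with `x`, `y`, `z` columns.
#' @param cell_size Cell edge length in angstroms; must be positive. The
#'   hydrogen-bond search uses 3.9, the donor-acceptor distance cutoff.
#' @return An object of class `hb_grid`.
#' @export
build_grid <- function(positions, cell_size = 3.9) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    rlang::abort("cell_size must be a positive number", class = "hb_param_error")
  }
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  cells <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(positions)) {
    ijk <- floor(positions / cell_size)
    keys <- paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ":")
    groups <- split(seq_len(nrow(positions)), keys)
    for (k in names(groups)) assign(k, groups[[k]], envir = cells)
  }
  structure(
    list(cells = cells, cell_size = cell_size, positions = positions),
    class = "hb_grid"
  )
}

#' @export
print.hb_grid <- function(x, ...) {
  cat(sprintf(
    "<hb_grid> %d atoms in %d cells (cell %.2f A)\n",
    nrow(x$positions), length(ls(x$cells)), x$cell_size
  ))
  invisible(x)
}

#' Atoms within a radius of a point
#'
#' Returns the indices (into the grid's position matrix) of all atoms with
#' Euclidean distance `<= r` from `center` — a closed ball, so an atom
#' exactly at distance `r` is included.
#'
#' @param grid An `hb_grid` from [build_grid()].
#' @param center Length-3 numeric center.
#' @param r Query radius in angstroms.
#' @return Integer vector of atom indices (ascending).
#' @export
radius_query <- function(grid, center, r) {
  cs <- grid$cell_size
  lo <- floor((center - r) / cs)
  hi <- floor((center + r) / cs)
  cand <- integer(0)
  for (i in lo[1]:hi[1]) {
    for (j in lo[2]:hi[2]) {
      for (k in lo[3]:hi[3]) {
        hit <- get0(paste(i, j, k, sep = ":"), envir = grid$cells)
        if (!is.null(hit)) cand <- c(cand, hit)
      }
    }
  }
  if (length(cand) == 0L) {
    return(integer(0))
  }
  p <- grid$positions[cand, , drop = FALSE]
  d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2
  sort(cand[d2 <= r * r])
}
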
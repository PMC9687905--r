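#' Hydrogen-bond geometric criteria
#'
#' The detection thresholds: donor-acceptor distance within `d_da` (3.9 A),
#' hydrogen-acceptor distance within `d_ha` (2.5 A), and the three angles
#' D-H-A, H-A-AA and D-A-AA (middle atom at the vertex) each strictly
#' exceeding `min_angle` (90 degrees). Distance bounds are inclusive
#' ("within"); angle bounds strict ("exceed").
#'
#' @param d_da Donor-acceptor cutoff, angstroms.
#' @param d_ha Hydrogen-acceptor cutoff, angstroms.
#' @param min_angle Lower bound for the three angles, degrees (exclusive).
#' @return A named list of criteria.
#' @export
hbond_criteria <- function(d_da = 3.9, d_ha = 2.5, min_angle = 90) {
  if (d_da <= 0 || d_ha <= 0) {
    rlang::abort("distance cutoffs must be positive", class = "hb_param_error")
  }
  list(d_da = d_da, d_ha = d_ha, min_angle = min_angle)
}

## Vectorized geometry for candidate quadruples: D, H, A, AA are n x 3
## matrices. Returns all five measurements plus accept/degenerate flags.
hbond_geometry <- function(D, H, A, AA, criteria = hbond_criteria()) {
  d_da <- row_dist(D, A)
  d_ha <- row_dist(H, A)
  ang_dha <- row_angle(D, H, A)
  ang_haaa <- row_angle(H, A, AA)
  ang_daaa <- row_angle(D, A, AA)
  degenerate <- is.na(ang_dha) | is.na(ang_haaa) | is.na(ang_daaa)
  accept <- !degenerate &
    d_da <= criteria$d_da & d_ha <= criteria$d_ha &
    ang_dha > criteria$min_angle & ang_haaa > criteria$min_angle &
    ang_daaa > criteria$min_angle
  tibble::tibble(
    d_DA = d_da, d_HA = d_ha,
    ang_DHA = ang_dha, ang_HAAA = ang_haaa, ang_DAAA = ang_daaa,
    degenerate = degenerate, accept = accept
  )
}

#' Evaluate one hydrogen-bond candidate
#'
#' Tests the four critical atoms of a putative hydrogen bond — donor D,
#' donor hydrogen H, acceptor A, acceptor antecedent AA — against the
#' geometric criteria, returning all five measurements whatever the outcome.
#' Coincident atoms (a zero-length angle arm) reject with `degenerate = TRUE`.
#'
#' @param D,H,A,AA Length-3 coordinate vectors, angstroms.
#' @param criteria See [hbond_criteria()].
#' @return One-row tibble: `d_DA`, `d_HA`, `ang_DHA`, `ang_HAAA`, `ang_DAAA`,
#'   `degenerate`, `accept`.
#' @export
#' @examples
#' evaluate_candidate(
#'   D = c(0, 0, 0), H = c(1, 0, 0), A = c(2.9, 0.3, 0), AA = c(3.5, 1.4, 0)
#' )
evaluate_candidate <- function(D, H, A, AA, criteria = hbond_criteria()) {
  m <- function(v) matrix(as.numeric(v), 1, 3)
  hbond_geometry(m(D), m(H), m(A), m(AA), criteria)
}

empty_bonds <- function() {
  tibble::tibble(
    donor_row = integer(), hydrogen_row = integer(),
    acceptor_row = integer(), antecedent_row = integer(),
    donor_serial = integer(), acceptor_serial = integer(),
    donor_name = character(), acceptor_name = character(),
    donor_residue = character(), acceptor_residue = character(),
    donor_residue_seq = integer(), acceptor_residue_seq = integer(),
    d_DA = numeric(), d_HA = numeric(),
    ang_DHA = numeric(), ang_HAAA = numeric(), ang_DAAA = numeric()
  )
}

## Shared core: given donor/acceptor role rows and a candidate-pair list
## (donor role index, acceptor role index), test every hydrogen x antecedent
## combination and keep each donor-acceptor pair once (first passing combo in
## hydrogen-then-antecedent order). Same-residue pairs are excluded.
test_pairs <- function(s, donors, acceptors, pair_d, pair_a, criteria) {
  a <- s$atoms
  res_key <- paste(a$chain, a$residue_seq, a$icode)
  keep <- res_key[donors$atom_row[pair_d]] != res_key[acceptors$atom_row[pair_a]]
  pair_d <- pair_d[keep]
  pair_a <- pair_a[keep]
  if (length(pair_d) == 0L) {
    return(empty_bonds())
  }

  ## expand every (H, AA) combination per pair
  nh <- lengths(donors$hydrogens)[pair_d]
  na_ <- lengths(acceptors$antecedents)[pair_a]
  reps <- nh * na_
  pid <- rep(seq_along(pair_d), reps)
  h_rows <- unlist(lapply(seq_along(pair_d), function(k) {
    rep(donors$hydrogens[[pair_d[k]]], each = na_[k])
  }))
  aa_rows <- unlist(lapply(seq_along(pair_d), function(k) {
    rep(acceptors$antecedents[[pair_a[k]]], nh[k])
  }))
  xyz <- coords(a)
  g <- hbond_geometry(
    xyz[donors$atom_row[pair_d[pid]], , drop = FALSE],
    xyz[h_rows, , drop = FALSE],
    xyz[acceptors$atom_row[pair_a[pid]], , drop = FALSE],
    xyz[aa_rows, , drop = FALSE],
    criteria
  )
  ok <- which(g$accept)
  if (length(ok) == 0L) {
    return(empty_bonds())
  }
  first <- ok[!duplicated(pid[ok])]
  pd <- pair_d[pid[first]]
  pa <- pair_a[pid[first]]
  tibble::tibble(
    donor_row = donors$atom_row[pd],
    hydrogen_row = h_rows[first],
    acceptor_row = acceptors$atom_row[pa],
    antecedent_row = aa_rows[first],
    donor_serial = a$serial[donors$atom_row[pd]],
    acceptor_serial = a$serial[acceptors$atom_row[pa]],
    donor_name = a$name[donors$atom_row[pd]],
    acceptor_name = a$name[acceptors$atom_row[pa]],
    donor_residue = a$residue_name[donors$atom_row[pd]],
    acceptor_residue = a$residue_name[acceptors$atom_row[pa]],
    donor_residue_seq = a$residue_seq[donors$atom_row[pd]],
    acceptor_residue_seq = a$residue_seq[acceptors$atom_row[pa]],
    d_DA = g$d_DA[first], d_HA = g$d_HA[first],
    ang_DHA = g$ang_DHA[first], ang_HAAA = g$ang_HAAA[first],
    ang_DAAA = g$ang_DAAA[first]
  )
}

check_protonated <- function(s) {
  if (!isTRUE(s$protonated)) {
    rlang::abort("structure is not protonated; run place_hydrogens() first",
      class = "hb_prep_error"
    )
  }
}

#' Find all geometrically feasible hydrogen bonds
#'
#' For every donor, acceptors within the donor-acceptor cutoff are located
#' with a lattice radius query, then every donor-hydrogen x antecedent
#' combination is tested against the geometric criteria. Each donor-acceptor
#' pair is reported at most once (any passing combination suffices);
#' same-residue pairs are excluded.
#'
#' @param s A protonated `hb_structure`.
#' @param criteria See [hbond_criteria()].
#' @param role_table See [default_role_table()].
#' @return A tibble of bonds with atom references, both distances and all
#'   three angles.
#' @export
#' @examples
#' s <- prepare_structure(make_ideal_helix(8), quiet = TRUE)
#' find_hbonds(s)
find_hbonds <- function(s, criteria = hbond_criteria(),
                        role_table = default_role_table()) {
  check_protonated(s)
  roles <- assign_roles(s, role_table)
  donors <- roles[roles$role %in% c("donor", "both"), , drop = FALSE]
  acceptors <- roles[roles$role %in% c("acceptor", "both"), , drop = FALSE]
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) {
    return(empty_bonds())
  }
  grid <- build_grid(coords(s$atoms, acceptors$atom_row),
    cell_size = criteria$d_da
  )
  xyz <- coords(s$atoms)
  pair_d <- integer(0)
  pair_a <- integer(0)
  for (di in seq_len(nrow(donors))) {
    hits <- radius_query(grid, xyz[donors$atom_row[di], ], criteria$d_da)
    if (length(hits)) {
      pair_d <- c(pair_d, rep(di, length(hits)))
      pair_a <- c(pair_a, hits)
    }
  }
  test_pairs(s, donors, acceptors, pair_d, pair_a, criteria)
}

#' Exhaustive hydrogen-bond search (test oracle)
#'
#' Tests every donor x acceptor pair without any spatial acceleration; the
#' output contract is identical to [find_hbonds()]. Kept as an independent
#' O(n^2) reference for the lattice-accelerated search.
#'
#' @inheritParams find_hbonds
#' @return A tibble of bonds, as [find_hbonds()].
#' @export
brute_force_hbond_search <- function(s, criteria = hbond_criteria(),
                                     role_table = default_role_table()) {
  check_protonated(s)
  roles <- assign_roles(s, role_table)
  donors <- roles[roles$role %in% c("donor", "both"), , drop = FALSE]
  acceptors <- roles[roles$role %in% c("acceptor", "both"), , drop = FALSE]
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) {
    return(empty_bonds())
  }
  grid_idx <- expand.grid(
    a = seq_len(nrow(acceptors)), d = seq_len(nrow(donors))
  )
  test_pairs(s, donors, acceptors, grid_idx$d, grid_idx$a, criteria)
}
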
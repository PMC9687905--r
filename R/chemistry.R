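## Residue-level chemistry: which heavy atoms donate or accept hydrogen bonds
## at biological pH, and which covalent neighbors define acceptor orientation.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Donor/acceptor role table
#'
#' One row per polar heavy atom. `residue = "*"` matches any standard residue
#' (backbone atoms); a residue-specific row overrides the wildcard, so the
#' proline backbone nitrogen is excluded via a `role = "none"` row. Acceptor
#' antecedents (the covalent neighbors that orient the acceptor lone pairs)
#' are comma-separated atom names within the same residue; ring nitrogens and
#' thioethers list both neighbors, each of which is tested.
#'
#' Protonation states assume pH 7: Asp/Glu carboxylates deprotonated
#' (acceptors only), Lys/Arg protonated (donors), His neutral with the
#' NE2-H tautomer (ND1 accepts, NE2 donates). Hydroxyls (Ser/Thr/Tyr) both
#' donate and accept.
#'
#' @return A tibble with columns `residue`, `atom`, `role`, `antecedents`.
#' @export
default_role_table <- function() {
  tibble::tribble(
    ~residue, ~atom, ~role, ~antecedents,
    "*", "N", "donor", "",
    "PRO", "N", "none", "",
    "*", "O", "acceptor", "C",
    "*", "OXT", "acceptor", "C",
    "ARG", "NE", "donor", "",
    "ARG", "NH1", "donor", "",
    "ARG", "NH2", "donor", "",
    "LYS", "NZ", "donor", "",
    "HIS", "NE2", "donor", "",
    "HIS", "ND1", "acceptor", "CG,CE1",
    "TRP", "NE1", "donor", "",
    "ASN", "ND2", "donor", "",
    "ASN", "OD1", "acceptor", "CG",
    "GLN", "NE2", "donor", "",
    "GLN", "OE1", "acceptor", "CD",
    "SER", "OG", "both", "CB",
    "THR", "OG1", "both", "CB",
    "TYR", "OH", "both", "CZ",
    "ASP", "OD1", "acceptor", "CG",
    "ASP", "OD2", "acceptor", "CG",
    "GLU", "OE1", "acceptor", "CD",
    "GLU", "OE2", "acceptor", "CD",
    "MET", "SD", "acceptor", "CG,CE"
  )
}

## Idealized bond lengths for placed hydrogens (angstroms).
NH_BOND <- 1.00
OH_BOND <- 0.96

## Hydrogen placement recipes per donor. `geom` is one of:
##   amide    - single sp2 H in the plane of two heavy neighbors (bisector)
##   sp2_nh2  - two sp2 H in the plane defined by the antecedent's substituent
##   sp3_scan - sp3 H(s) staggered around the parent-antecedent axis, at the
##              azimuth maximizing distance from 1-3 neighbors
donor_placement_table <- function() {
  tibble::tribble(
    ~residue, ~atom, ~geom, ~n_h, ~length, ~frame, ~h_names,
    "ARG", "NE", "amide", 1L, NH_BOND, "CD,CZ", "HE",
    "ARG", "NH1", "sp2_nh2", 2L, NH_BOND, "CZ,NE", "HH11,HH12",
    "ARG", "NH2", "sp2_nh2", 2L, NH_BOND, "CZ,NE", "HH21,HH22",
    "LYS", "NZ", "sp3_scan", 3L, NH_BOND, "CE", "HZ1,HZ2,HZ3",
    "HIS", "NE2", "amide", 1L, NH_BOND, "CD2,CE1", "HE2",
    "TRP", "NE1", "amide", 1L, NH_BOND, "CD1,CE2", "HE1",
    "ASN", "ND2", "sp2_nh2", 2L, NH_BOND, "CG,OD1", "HD21,HD22",
    "GLN", "NE2", "sp2_nh2", 2L, NH_BOND, "CD,OE1", "HE21,HE22",
    "SER", "OG", "sp3_scan", 1L, OH_BOND, "CB", "HG",
    "THR", "OG1", "sp3_scan", 1L, OH_BOND, "CB", "HG1",
    "TYR", "OH", "sp3_scan", 1L, OH_BOND, "CZ", "HH"
  )
}
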
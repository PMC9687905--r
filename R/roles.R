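#' Assign donor/acceptor roles to the atoms of a protonated structure
#'
#' Every heavy atom matching the role table becomes a role atom: donors carry
#' their attached hydrogens (by the `parent` column when present, else by a
#' 1.3-A proximity attachment), acceptors carry their covalent antecedents.
#' A nominal donor left without any hydrogen (e.g., skipped placement) is
#' demoted to its acceptor role or dropped; an acceptor whose antecedent
#' atoms are missing is dropped likewise, so the returned table always
#' satisfies the role invariants.
#'
#' @param s A protonated `hb_structure`.
#' @param role_table Role definition table, default [default_role_table()].
#' @return A tibble with one row per role atom: atom identity columns,
#'   `role` (`donor`, `acceptor` or `both`), and list-columns `hydrogens` and
#'   `antecedents` holding row indices into `s$atoms`.
#' @export
assign_roles <- function(s, role_table = default_role_table()) {
  if (!isTRUE(s$protonated)) {
    rlang::abort("structure is not protonated; run place_hydrogens() first",
      class = "hb_prep_error"
    )
  }
  a <- s$atoms
  n <- nrow(a)
  res_key <- paste(a$chain, a$residue_seq, a$icode)

  ## attach hydrogens to parents
  h_idx <- which(a$element == "H")
  h_parent_row <- integer(0)
  if (length(h_idx)) {
    serial_row <- match(a$parent[h_idx], a$serial)
    h_parent_row <- serial_row
    missing <- which(is.na(serial_row))
    if (length(missing)) {
      heavy <- which(a$element != "H")
      hp <- coords(a)
      for (k in missing) {
        i <- h_idx[k]
        d <- sqrt(colSums((t(hp[heavy, , drop = FALSE]) - hp[i, ])^2))
        if (min(d) <= 1.3) h_parent_row[k] <- heavy[which.min(d)]
      }
    }
  }
  hydrogens_of <- vector("list", n)
  for (k in seq_along(h_idx)) {
    p <- h_parent_row[k]
    if (!is.na(p)) hydrogens_of[[p]] <- c(hydrogens_of[[p]], h_idx[k])
  }

  ## match atoms against the role table: specific residue rows override "*"
  rt_specific <- role_table[role_table$residue != "*", , drop = FALSE]
  rt_wild <- role_table[role_table$residue == "*", , drop = FALSE]
  key_s <- paste(rt_specific$residue, rt_specific$atom)
  m_s <- match(paste(a$residue_name, a$name), key_s)
  m_w <- match(a$name, rt_wild$atom)
  role <- ifelse(!is.na(m_s), rt_specific$role[m_s],
    ifelse(!is.na(m_w), rt_wild$role[m_w], NA_character_)
  )
  ants_spec <- ifelse(!is.na(m_s), rt_specific$antecedents[m_s],
    ifelse(!is.na(m_w), rt_wild$antecedents[m_w], "")
  )
  cand <- which(!is.na(role) & role != "none" & a$element != "H")

  rows <- list()
  for (i in cand) {
    r <- role[i]
    hyd <- hydrogens_of[[i]]
    ants <- integer(0)
    ant_names <- strsplit(ants_spec[i], ",")[[1]]
    if (length(ant_names)) {
      same_res <- which(res_key == res_key[i])
      ants <- same_res[a$name[same_res] %in% ant_names]
    }
    ## enforce invariants by demotion
    if (r %in% c("donor", "both") && length(hyd) == 0L) {
      r <- if (r == "both" && length(ants)) "acceptor" else NA_character_
    }
    if (!is.na(r) && r %in% c("acceptor", "both") && length(ants) == 0L) {
      r <- if (r == "both") "donor" else NA_character_
    }
    if (is.na(r)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      atom_row = i, serial = a$serial[i], name = a$name[i],
      residue_name = a$residue_name[i], chain = a$chain[i],
      residue_seq = a$residue_seq[i], icode = a$icode[i],
      role = r,
      hydrogens = list(hyd), antecedents = list(ants)
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      atom_row = integer(), serial = integer(), name = character(),
      residue_name = character(), chain = character(),
      residue_seq = integer(), icode = character(), role = character(),
      hydrogens = list(), antecedents = list()
    ))
  }
  dplyr::bind_rows(rows)
}
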
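#' Strip non-protein content from a parsed structure
#'
#' Restricts a structure to the standard amino-acid `ATOM` records of one
#' chain: waters, ions, ligands (all `HETATM` records), experimentally solved
#' hydrogens/deuteriums and nonstandard residues are removed, and alternate
#' locations are collapsed to the highest-occupancy conformer (ties keep
#' altloc `A`). Hydrogens are removed because crystal structures protonate
#' inconsistently; [place_hydrogens()] re-adds them uniformly.
#'
#' @param s An `hb_structure` from [read_pdb()].
#' @param chain Chain identifier; default is the first chain holding `ATOM`
#'   records.
#' @param quiet Suppress the removal-count message.
#' @return The stripped `hb_structure`.
#' @export
strip_nonprotein <- function(s, chain = NULL, quiet = FALSE) {
  a <- s$atoms
  protein_chains <- unique(a$chain[!a$is_hetero])
  if (is.null(chain)) chain <- protein_chains[1]
  if (!chain %in% protein_chains) {
    rlang::abort(
      sprintf(
        "chain '%s' not found; available chains: %s",
        chain, paste(protein_chains, collapse = ", ")
      ),
      class = "hb_chain_error"
    )
  }

  n_water <- sum(a$residue_name %in% c("HOH", "DOD", "WAT"))
  n_het <- sum(a$is_hetero & !a$residue_name %in% c("HOH", "DOD", "WAT"))
  n_h <- sum(a$element %in% c("H", "D") & !a$is_hetero & a$chain == chain)

  keep <- !a$is_hetero & a$chain == chain & !a$element %in% c("H", "D")
  nonstd <- keep & !a$residue_name %in% STANDARD_AA
  if (any(nonstd)) {
    rlang::warn(sprintf(
      "dropping %d atoms of nonstandard residues: %s",
      sum(nonstd), paste(unique(a$residue_name[nonstd]), collapse = ", ")
    ))
    keep <- keep & !nonstd
  }
  a <- a[keep, , drop = FALSE]

  ## collapse alternate locations: highest occupancy, ties -> altloc 'A'
  if (any(a$altloc != "")) {
    a <- a |>
      dplyr::group_by(.data$chain, .data$residue_seq, .data$icode, .data$name) |>
      dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(match(.data$serial, s$atoms$serial))
    a$altloc <- ""
  }

  if (!quiet) {
    rlang::inform(sprintf(
      "strip_nonprotein: removed %d water, %d ligand/ion, %d hydrogen atoms; %d atoms kept",
      n_water, n_het, n_h, nrow(a)
    ))
  }
  new_structure(a, chain_id = chain, model = s$model, protonated = FALSE)
}

## --- hydrogen placement geometry -------------------------------------------

## Single sp2 hydrogen on X with heavy neighbors n1, n2: along the external
## bisector, in the n1-X-n2 plane (e.g., backbone amide H trans to CA).
h_sp2_bisector <- function(x, n1, n2, len) {
  x + len * unit(unit(x - n1) + unit(x - n2))
}

## Two sp2 hydrogens on N (e.g., Asn ND2): both in the plane of (partner,
## antecedent, N), at 120 degrees from the N->antecedent direction.
h_sp2_nh2 <- function(n, antecedent, partner, len) {
  a <- unit(antecedent - n)
  nrm <- unit(vcross(partner - antecedent, n - antecedent))
  p <- unit(vcross(nrm, a))
  d1 <- a * cos(pi * 2 / 3) + p * sin(pi * 2 / 3)
  d2 <- a * cos(pi * 2 / 3) - p * sin(pi * 2 / 3)
  rbind(n + len * d1, n + len * d2)
}

## Staggered sp3 hydrogens on X bonded to antecedent Y: tetrahedral angle from
## the X->Y direction, azimuth scanned in 5-degree steps to maximize the
## minimal distance to Y's other heavy neighbors (1-3 neighbors of H).
h_sp3_scan <- function(x, y, avoid, n_h, len, angle = 109.5) {
  u <- unit(y - x)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- unit(vcross(u, ref))
  p2 <- vcross(u, p1)
  th <- angle * pi / 180
  pos_at <- function(phi) {
    d <- u * cos(th) + (p1 * cos(phi) + p2 * sin(phi)) * sin(th)
    x + len * d
  }
  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  if (is.null(avoid) || nrow(avoid) == 0L) {
    best <- 0
  } else {
    score <- vapply(phis, function(phi) {
      h <- pos_at(phi)
      min(sqrt(rowSums((avoid - matrix(h, nrow(avoid), 3, byrow = TRUE))^2)))
    }, numeric(1))
    best <- phis[which.max(score)]
  }
  offs <- seq(0, by = 2 * pi / 3, length.out = n_h)
  t(vapply(best + offs, pos_at, numeric(3)))
}

#' Place idealized polar hydrogens
#'
#' Adds one idealized hydrogen per donor valence for every hydrogen-bond
#' donor: backbone amide N (except proline; sp2, in the C(i-1)/N/CA plane
#' along the external bisector), N-terminal amine (sp3, three H), Arg
#' guanidinium, Lys ammonium, His NE2 (neutral tautomer), Trp indole,
#' Asn/Gln amides (sp2, in the amide plane) and Ser/Thr/Tyr hydroxyls (sp3,
#' staggered azimuth maximizing distance from 1-3 neighbors). N-H bonds are
#' 1.00 A and O-H bonds 0.96 A. A residue missing the heavy atoms needed to
#' frame a hydrogen gets that hydrogen skipped with a warning.
#'
#' A nitrogen more than 1.8 A from any preceding-residue carbonyl carbon is
#' treated as an N-terminal amine, so chain breaks and isolated residues are
#' protonated sensibly.
#'
#' @param s A stripped, hydrogen-free `hb_structure`.
#' @param quiet Suppress the added-hydrogen count message.
#' @return The structure with hydrogens appended after their residue's heavy
#'   atoms, serials renumbered, `protonated = TRUE`. Each hydrogen's `parent`
#'   column holds the serial of its donor heavy atom.
#' @export
place_hydrogens <- function(s, quiet = FALSE) {
  a <- s$atoms
  if (any(a$element %in% c("H", "D"))) {
    rlang::abort("structure already contains hydrogens; strip them first or use pre_protonated = TRUE downstream",
      class = "hb_prep_error"
    )
  }
  res_key <- paste(a$chain, a$residue_seq, a$icode)
  res_f <- factor(res_key, levels = unique(res_key))
  res_rows <- split(seq_len(nrow(a)), res_f)
  placements <- donor_placement_table()

  pos_of <- function(rows, nm) {
    i <- rows[a$name[rows] == nm]
    if (length(i) == 0L) {
      return(NULL)
    }
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }

  out_rows <- vector("list", length(res_rows))
  skipped <- 0L

  for (ri in seq_along(res_rows)) {
    rows <- res_rows[[ri]]
    resn <- a$residue_name[rows[1]]
    h_list <- list()

    add_h <- function(pos, names_, parent_name) {
      pos <- rbind(pos)
      for (k in seq_len(nrow(pos))) {
        h_list[[length(h_list) + 1L]] <<- list(
          name = names_[k], pos = pos[k, ], parent = parent_name
        )
      }
    }
    skip <- function(what) {
      rlang::warn(sprintf(
        "residue %s %s%s: missing frame atoms, skipped %s hydrogen",
        resn, a$residue_seq[rows[1]], a$icode[rows[1]], what
      ))
      skipped <<- skipped + 1L
    }

    ## backbone amide / N-terminal amine
    n_pos <- pos_of(rows, "N")
    ca_pos <- pos_of(rows, "CA")
    if (!is.null(n_pos) && !is.null(ca_pos) && resn != "PRO") {
      c_prev <- NULL
      if (ri > 1L) {
        cp <- pos_of(res_rows[[ri - 1L]], "C")
        if (!is.null(cp) && vnorm(n_pos - cp) < 1.8) c_prev <- cp
      }
      if (!is.null(c_prev)) {
        add_h(h_sp2_bisector(n_pos, c_prev, ca_pos, NH_BOND), "H", "N")
      } else {
        ## N-terminus: sp3 NH3+ staggered against CA's other substituents
        avoid_nm <- intersect(c("C", "CB"), a$name[rows])
        avoid <- do.call(rbind, lapply(avoid_nm, function(nm) pos_of(rows, nm)))
        add_h(
          h_sp3_scan(n_pos, ca_pos, avoid, 3L, NH_BOND),
          c("H1", "H2", "H3"), "N"
        )
      }
    }

    ## side-chain donors
    pl <- placements[placements$residue == resn, , drop = FALSE]
    if (nrow(pl)) {
      for (k in seq_len(nrow(pl))) {
        x <- pos_of(rows, pl$atom[k])
        if (is.null(x)) next
        frame_nm <- strsplit(pl$frame[k], ",")[[1]]
        fr <- lapply(frame_nm, function(nm) pos_of(rows, nm))
        if (any(vapply(fr, is.null, logical(1)))) {
          skip(pl$atom[k])
          next
        }
        hn <- strsplit(pl$h_names[k], ",")[[1]]
        pos <- switch(pl$geom[k],
          amide = h_sp2_bisector(x, fr[[1]], fr[[2]], pl$length[k]),
          sp2_nh2 = h_sp2_nh2(x, fr[[1]], fr[[2]], pl$length[k]),
          sp3_scan = {
            y <- fr[[1]]
            ## 1-3 neighbors: heavy atoms bonded to the antecedent (< 1.8 A)
            heavy <- coords(a, rows)
            d <- sqrt(rowSums((heavy - matrix(y, nrow(heavy), 3, byrow = TRUE))^2))
            avoid <- heavy[d > 0.1 & d < 1.8 &
              sqrt(rowSums((heavy - matrix(x, nrow(heavy), 3, byrow = TRUE))^2)) > 0.1, ,
            drop = FALSE
            ]
            h_sp3_scan(x, y, avoid, pl$n_h[k], pl$length[k])
          }
        )
        add_h(pos, hn, pl$atom[k])
      }
    }

    res_a <- a[rows, , drop = FALSE]
    if (length(h_list)) {
      htab <- tibble::tibble(
        serial = NA_integer_,
        name = vapply(h_list, `[[`, character(1), "name"),
        altloc = "",
        residue_name = resn,
        chain = res_a$chain[1],
        residue_seq = res_a$residue_seq[1],
        icode = res_a$icode[1],
        x = vapply(h_list, function(h) h$pos[1], numeric(1)),
        y = vapply(h_list, function(h) h$pos[2], numeric(1)),
        z = vapply(h_list, function(h) h$pos[3], numeric(1)),
        occupancy = 1, bfactor = 0, element = "H", is_hetero = FALSE,
        parent = NA_integer_
      )
      ## remember parent by name within residue; resolved after renumbering
      attr(htab, "parent_name") <- vapply(h_list, `[[`, character(1), "parent")
      res_a <- dplyr::bind_rows(res_a, htab)
      attr(res_a, "h_parent") <- c(
        rep(NA_character_, length(rows)),
        vapply(h_list, `[[`, character(1), "parent")
      )
    } else {
      attr(res_a, "h_parent") <- rep(NA_character_, length(rows))
    }
    out_rows[[ri]] <- res_a
  }

  parent_names <- unlist(lapply(out_rows, attr, "h_parent"))
  out <- dplyr::bind_rows(out_rows)
  out$serial <- seq_len(nrow(out))
  ## resolve hydrogen parents to serials within the same residue
  res_key2 <- paste(out$chain, out$residue_seq, out$icode)
  for (i in which(!is.na(parent_names))) {
    j <- which(res_key2 == res_key2[i] & out$name == parent_names[i])
    out$parent[i] <- out$serial[j[1]]
  }

  n_added <- sum(out$element == "H")
  if (!quiet) {
    rlang::inform(sprintf(
      "place_hydrogens: added %d hydrogens (%d skipped for missing frame atoms)",
      n_added, skipped
    ))
  }
  new_structure(out,
    chain_id = s$chain_id, model = s$model,
    protonated = TRUE
  )
}

#' One-call structure preparation
#'
#' [read_pdb()] then [strip_nonprotein()] then [place_hydrogens()], or — with
#' `pre_protonated = TRUE` — accept a file whose hydrogens were already
#' modelled (e.g., by an external protonation tool) and only mark it
#' protonated after attaching each hydrogen to its nearest heavy atom.
#'
#' @param x PDB path or text.
#' @param chain Chain selector (default first protein chain).
#' @param pre_protonated Input already carries modelled hydrogens.
#' @param quiet Suppress progress messages.
#' @return A protonated `hb_structure`.
#' @export
prepare_structure <- function(x, chain = NULL, pre_protonated = FALSE,
                              quiet = FALSE) {
  s <- read_pdb(x)
  if (pre_protonated) {
    a <- s$atoms
    protein_chains <- unique(a$chain[!a$is_hetero])
    if (is.null(chain)) chain <- protein_chains[1]
    keep <- !a$is_hetero & a$chain == chain & a$residue_name %in% STANDARD_AA
    a <- a[keep, , drop = FALSE]
    is_h <- a$element %in% c("H", "D")
    heavy <- which(!is_h)
    hp <- coords(a)
    for (i in which(is_h)) {
      d <- sqrt(colSums((t(hp[heavy, , drop = FALSE]) - hp[i, ])^2))
      j <- heavy[which.min(d)]
      if (d[which.min(d)] <= 1.3) a$parent[i] <- a$serial[j]
    }
    return(new_structure(a, chain_id = chain, model = s$model, protonated = TRUE))
  }
  s |>
    strip_nonprotein(chain = chain, quiet = quiet) |>
    place_hydrogens(quiet = quiet)
}
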
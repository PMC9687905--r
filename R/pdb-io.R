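#' Protein structure container
#'
#' An `hb_structure` bundles an atom table with chain/model bookkeeping. The
#' atom table is an ordinary tibble (one row per atom, PDB field per column)
#' so it can be filtered and summarised with dplyr verbs; [as_tibble()] on the
#' structure returns it.
#'
#' @param atoms Tibble of atom records (see [read_pdb()] for columns).
#' @param chain_id Chain identifier the structure was restricted to, or `NA`.
#' @param model Model number the atoms came from.
#' @param protonated Logical; `TRUE` after [place_hydrogens()].
#' @return An object of class `hb_structure`.
#' @keywords internal
new_structure <- function(atoms, chain_id = NA_character_, model = 1L,
                          protonated = FALSE) {
  structure(
    list(
      atoms = atoms, chain_id = chain_id, model = model,
      protonated = protonated
    ),
    class = "hb_structure"
  )
}

#' @export
as_tibble.hb_structure <- function(x, ...) x$atoms

#' @export
print.hb_structure <- function(x, ...) {
  cat(
    sprintf(
      "<hb_structure> %d atoms, %d residues, chain %s, %sprotonated\n",
      nrow(x$atoms),
      nrow(dplyr::distinct(x$atoms, .data$chain, .data$residue_seq, .data$icode)),
      if (is.na(x$chain_id)) "(all)" else x$chain_id,
      if (x$protonated) "" else "not "
    )
  )
  invisible(x)
}

pdb_field <- function(lines, from, to) {
  substr(lines, from, to)
}

## Element symbol from the PDB atom-name column when the element column is
## blank: drop leading digits, take the first letter. Two-letter metal/ion
## elements only occur in HETATM records, which structure preparation removes.
element_from_name <- function(name) {
  stripped <- sub("^[0-9' ]+", "", name)
  toupper(substr(stripped, 1, 1))
}

#' Parse PDB-format text
#'
#' Reads the `ATOM`/`HETATM` records of the first model of a PDB file into an
#' atom tibble. Fixed-column fields are decoded per PDB format v3; records are
#' kept in file order. Multi-model (e.g., NMR) files contribute model 1 only.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines.
#' @return An [hb_structure][new_structure] whose `atoms` tibble has columns
#'   `serial`, `name`, `altloc`, `residue_name`, `chain`, `residue_seq`,
#'   `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element`, `is_hetero`,
#'   `parent` (serial of the parent heavy atom for placed hydrogens, else
#'   `NA`).
#' @export
#' @examples
#' pdb <- make_ideal_helix(6)
#' s <- read_pdb(pdb)
#' dplyr::count(tibble::as_tibble(s), name)
read_pdb <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  rec <- pdb_field(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")

  ## restrict to the first MODEL block when present
  model_starts <- which(trimws(rec) == "MODEL")
  model_no <- 1L
  if (length(model_starts) >= 1L) {
    ends <- which(trimws(rec) %in% c("ENDMDL", "END"))
    end1 <- ends[ends > model_starts[1]][1]
    if (is.na(end1)) end1 <- length(lines)
    keep <- seq_along(lines) > model_starts[1] & seq_along(lines) < end1
    is_atom <- is_atom & keep
    model_no <- suppressWarnings(as.integer(pdb_field(lines[model_starts[1]], 11, 14)))
    if (is.na(model_no)) model_no <- 1L
  }

  idx <- which(is_atom)
  if (length(idx) == 0L) {
    rlang::abort("no atoms: input contains no ATOM/HETATM records",
      class = "hb_no_atoms"
    )
  }
  al <- lines[idx]

  num <- function(from, to, what) {
    raw <- pdb_field(al, from, to)
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(out) & trimws(raw) != "")
    blank <- which(trimws(raw) == "")
    if (what %in% c("x", "y", "z") && (length(bad) || length(blank))) {
      ln <- idx[c(bad, blank)[1]]
      rlang::abort(
        sprintf(
          "parse error at line %d: malformed %s coordinate field '%s'",
          ln, what, trimws(pdb_field(lines[ln], from, to))
        ),
        class = "hb_parse_error"
      )
    }
    out
  }

  atoms <- tibble::tibble(
    serial = suppressWarnings(as.integer(pdb_field(al, 7, 11))),
    name = trimws(pdb_field(al, 13, 16)),
    altloc = trimws(pdb_field(al, 17, 17)),
    residue_name = trimws(pdb_field(al, 18, 20)),
    chain = pdb_field(al, 22, 22),
    residue_seq = suppressWarnings(as.integer(pdb_field(al, 23, 26))),
    icode = trimws(pdb_field(al, 27, 27)),
    x = num(31, 38, "x"),
    y = num(39, 46, "y"),
    z = num(47, 54, "z"),
    occupancy = num(55, 60, "occupancy"),
    bfactor = num(61, 66, "bfactor"),
    element = toupper(trimws(pdb_field(al, 77, 78))),
    is_hetero = pdb_field(al, 1, 6) == "HETATM",
    parent = NA_integer_
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  blank_el <- atoms$element == ""
  atoms$element[blank_el] <- element_from_name(atoms$name[blank_el])
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("parse error: non-finite coordinates", class = "hb_parse_error")
  }
  new_structure(atoms, model = model_no)
}

#' Write a structure as PDB-format text
#'
#' @param s An `hb_structure`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`) the PDB lines.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  fmt_name <- function(name, element) {
    ## names of 1-3 chars for 1-letter elements start in column 14
    ifelse(nchar(name) >= 4 | nchar(element) > 1,
      formatC(name, width = -4),
      paste0(" ", formatC(name, width = -3))
    )
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$is_hetero, "HETATM", "ATOM"),
    a$serial, fmt_name(a$name, a$element), a$altloc, a$residue_name,
    a$chain, a$residue_seq, a$icode, a$x, a$y, a$z, a$occupancy, a$bfactor,
    a$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

coords <- function(atoms, rows = NULL) {
  if (!is.null(rows)) atoms <- atoms[rows, , drop = FALSE]
  as.matrix(atoms[, c("x", "y", "z")])
}
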
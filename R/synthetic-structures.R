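## Synthetic protein-like fixtures: an ideal alpha-helix with known
## O(i)...N(i+4) hydrogen-bond geometry, and seeded random residue clouds used
## as substrates for search-oracle tests.

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's global RNG state is untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Backbone internal-coordinate constants (angstroms / degrees).
BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, omega = 180
)

atoms_to_structure <- function(df, chain = "A") {
  df$serial <- seq_len(nrow(df))
  df$altloc <- ""
  df$chain <- chain
  df$icode <- ""
  df$occupancy <- 1
  df$bfactor <- 0
  df$is_hetero <- FALSE
  df$parent <- NA_integer_
  new_structure(
    tibble::as_tibble(df[, c(
      "serial", "name", "altloc", "residue_name", "chain", "residue_seq",
      "icode", "x", "y", "z", "occupancy", "bfactor", "element", "is_hetero",
      "parent"
    )]),
    chain_id = chain, protonated = FALSE
  )
}

#' Ideal poly-alanine alpha-helix in PDB format
#'
#' Builds backbone atoms (N, CA, C, O, CB) of a geometrically ideal
#' right-handed alpha-helix from standard internal coordinates, chaining
#' residues with the given backbone dihedrals (trans peptide, omega = 180).
#' The defaults (phi = -57, psi = -47) give every O(i)...N(i+4) pair a
#' donor-acceptor distance near 3 A, inside the hydrogen-bond criteria, which
#' makes the fixture's bond set known in advance.
#'
#' @param n_residues Number of residues (at least 5, so an i+4 pair exists).
#' @param phi,psi Backbone dihedrals in degrees.
#' @return PDB-format lines (character vector).
#' @export
#' @examples
#' helix <- make_ideal_helix(20)
#' s <- read_pdb(helix)
make_ideal_helix <- function(n_residues, phi = -57, psi = -47) {
  if (n_residues < 5) {
    rlang::abort("n_residues must be >= 5 (no i+4 pair exists otherwise)",
      class = "hb_param_error"
    )
  }
  res <- vector("list", n_residues)
  ## seed residue 1 in the xy-plane
  n <- c(0, 0, 0)
  ca <- c(BB$n_ca, 0, 0)
  th <- BB$ang_n_ca_c * pi / 180
  cc <- ca + BB$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_residues)) {
    o <- place_internal(n, ca, cc, BB$c_o, BB$ang_ca_c_o, psi + 180)
    cb <- place_internal(cc, n, ca, BB$ca_cb, BB$ang_n_ca_cb, 122.6)
    res[[i]] <- data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      residue_name = "ALA", residue_seq = i,
      x = c(n[1], ca[1], cc[1], o[1], cb[1]),
      y = c(n[2], ca[2], cc[2], o[2], cb[2]),
      z = c(n[3], ca[3], cc[3], o[3], cb[3]),
      element = c("N", "C", "C", "O", "C")
    )
    if (i < n_residues) {
      n1 <- place_internal(n, ca, cc, BB$c_n, BB$ang_ca_c_n, psi)
      ca1 <- place_internal(ca, cc, n1, BB$n_ca, BB$ang_c_n_ca, BB$omega)
      c1 <- place_internal(cc, n1, ca1, BB$ca_c, BB$ang_n_ca_c, phi)
      n <- n1
      ca <- ca1
      cc <- c1
    }
  }
  s <- atoms_to_structure(do.call(rbind, res))
  write_pdb(s)
}

## Template residues in local coordinates, built once from internal
## coordinates. Side-chain chi angles are fixed plausible rotamers; templates
## only need covalently correct geometry, not rotamer realism.
residue_template <- function(resn) {
  n <- c(0, 0, 0)
  ca <- c(BB$n_ca, 0, 0)
  th <- BB$ang_n_ca_c * pi / 180
  cc <- ca + BB$ca_c * c(-cos(th), sin(th), 0)
  o <- place_internal(n, ca, cc, BB$c_o, BB$ang_ca_c_o, 180)
  atoms <- list(
    N = list(n, "N"), CA = list(ca, "C"), C = list(cc, "C"), O = list(o, "O")
  )
  if (resn != "GLY") {
    atoms$CB <- list(place_internal(cc, n, ca, BB$ca_cb, BB$ang_n_ca_cb, 122.6), "C")
  }
  cb <- if (resn != "GLY") atoms$CB[[1]] else NULL
  if (resn == "SER") {
    atoms$OG <- list(place_internal(n, ca, cb, 1.417, 110.8, -60), "O")
  } else if (resn %in% c("ASN", "ASP")) {
    cg <- place_internal(n, ca, cb, 1.516, 113.0, -60)
    atoms$CG <- list(cg, "C")
    if (resn == "ASN") {
      atoms$OD1 <- list(place_internal(ca, cb, cg, 1.231, 120.8, -30), "O")
      atoms$ND2 <- list(place_internal(ca, cb, cg, 1.328, 116.4, 150), "N")
    } else {
      atoms$OD1 <- list(place_internal(ca, cb, cg, 1.249, 118.4, -30), "O")
      atoms$OD2 <- list(place_internal(ca, cb, cg, 1.249, 118.4, 150), "O")
    }
  } else if (resn == "LYS") {
    cg <- place_internal(n, ca, cb, 1.520, 113.0, -60)
    cd <- place_internal(ca, cb, cg, 1.520, 111.0, 180)
    ce <- place_internal(cb, cg, cd, 1.520, 111.0, 180)
    nz <- place_internal(cg, cd, ce, 1.489, 111.0, 180)
    atoms$CG <- list(cg, "C")
    atoms$CD <- list(cd, "C")
    atoms$CE <- list(ce, "C")
    atoms$NZ <- list(nz, "N")
  }
  data.frame(
    name = names(atoms),
    x = vapply(atoms, function(a) a[[1]][1], numeric(1)),
    y = vapply(atoms, function(a) a[[1]][2], numeric(1)),
    z = vapply(atoms, function(a) a[[1]][3], numeric(1)),
    element = vapply(atoms, function(a) a[[2]], character(1))
  )
}

random_rotation <- function() {
  ## uniform rotation from a random quaternion
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]
  x <- q[1]
  y <- q[2]
  z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Random residue-cloud structure in PDB format
#'
#' Scatters whole standard residues (mixed apolar and polar types: Ala, Gly,
#' Ser, Asn, Lys, Asp) at random positions and orientations in a cubic box,
#' rejecting placements that bring any two atoms of different residues closer
#' than 1.5 A. Residues are not chain-bonded, so every backbone nitrogen is
#' protonated as an N-terminal amine downstream. The box volume scales with
#' the residue count so that hydrogen-bond-range contacts are common, which
#' is what the search-oracle tests need.
#'
#' @param n_residues Number of residues (at least 2).
#' @param seed Integer seed; same seed, same file.
#' @return PDB-format lines.
#' @export
make_random_structure <- function(n_residues, seed) {
  if (n_residues < 2) {
    rlang::abort("n_residues must be >= 2", class = "hb_param_error")
  }
  with_local_seed(seed, {
    types <- sample(c("ALA", "GLY", "SER", "ASN", "LYS", "ASP"),
      n_residues,
      replace = TRUE,
      prob = c(0.2, 0.1, 0.2, 0.2, 0.15, 0.15)
    )
    side <- (240 * n_residues)^(1 / 3)
    placed <- NULL
    res <- vector("list", n_residues)
    for (i in seq_len(n_residues)) {
      tmpl <- residue_template(types[i])
      xyz0 <- as.matrix(tmpl[, c("x", "y", "z")])
      xyz0 <- sweep(xyz0, 2, colMeans(xyz0))
      ok <- FALSE
      for (try in 1:500) {
        xyz <- xyz0 %*% t(random_rotation())
        xyz <- sweep(xyz, 2, stats::runif(3, 0, side), "+")
        if (is.null(placed)) {
          ok <- TRUE
        } else {
          d2 <- outer(rowSums(xyz^2), rowSums(placed^2), "+") -
            2 * xyz %*% t(placed)
          dmin <- sqrt(max(0, min(d2)))
          ok <- dmin >= 1.5
        }
        if (ok) break
      }
      if (!ok) {
        rlang::abort("could not place residue without clashes after 500 tries",
          class = "hb_param_error"
        )
      }
      placed <- rbind(placed, xyz)
      df <- tmpl
      df$x <- xyz[, 1]
      df$y <- xyz[, 2]
      df$z <- xyz[, 3]
      df$residue_name <- types[i]
      df$residue_seq <- i
      res[[i]] <- df
    }
    write_pdb(atoms_to_structure(do.call(rbind, res)))
  })
}
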
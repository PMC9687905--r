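test_that("stripping removes waters, ligands, hydrogens and other chains", {
  s <- read_pdb(messy_pdb())
  clean <- strip_nonprotein(s, chain = "A", quiet = TRUE)
  a <- as_tibble(clean)
  expect_false(any(a$residue_name %in% c("HOH", "SO4")))
  expect_false(any(a$is_hetero))
  expect_false(any(a$element == "H"))
  expect_true(all(a$chain == "A"))
  ## altloc collapsed to the higher-occupancy conformer
  ca2 <- a[a$residue_seq == 2 & a$name == "CA", ]
  expect_equal(nrow(ca2), 1L)
  expect_equal(ca2$x, 5.50)
})

test_that("stripping is idempotent and an absent chain lists alternatives", {
  s <- read_pdb(messy_pdb())
  once <- strip_nonprotein(s, chain = "A", quiet = TRUE)
  twice <- strip_nonprotein(once, chain = "A", quiet = TRUE)
  expect_equal(as_tibble(twice), as_tibble(once))
  err <- expect_error(
    strip_nonprotein(s, chain = "Z", quiet = TRUE),
    class = "hb_chain_error"
  )
  expect_match(conditionMessage(err), "A, B")
})

test_that("amide hydrogens sit 1.0 A from N, in the C(i-1)/N/CA plane, on the bisector", {
  s <- helix20_prepped()
  a <- as_tibble(s)
  for (i in c(2, 7, 15)) {
    h <- a[a$residue_seq == i & a$name == "H", ]
    n <- a[a$residue_seq == i & a$name == "N", ]
    ca <- a[a$residue_seq == i & a$name == "CA", ]
    cp <- a[a$residue_seq == i - 1 & a$name == "C", ]
    expect_equal(nrow(h), 1L)
    p <- function(r) c(r$x, r$y, r$z)
    vh <- p(h) - p(n)
    v1 <- p(cp) - p(n)
    v2 <- p(ca) - p(n)
    expect_equal(sqrt(sum(vh^2)), 1.0, tolerance = 1e-9)
    ## coplanarity: triple product vanishes
    expect_lt(abs(det(cbind(vh, v1, v2))), 1e-9)
    ## external bisector: equal angles to both heavy neighbors
    ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    expect_equal(ang(vh, v1), ang(vh, v2), tolerance = 1e-9)
    ## parent bookkeeping
    expect_equal(h$parent, n$serial)
  }
})

test_that("proline gets no backbone amide hydrogen", {
  pdb <- helix20()
  pro <- gsub("ALA A   8", "PRO A   8", pdb)
  s <- read_pdb(pro) |>
    strip_nonprotein(quiet = TRUE) |>
    place_hydrogens(quiet = TRUE)
  a <- as_tibble(s)
  expect_equal(sum(a$residue_seq == 8 & a$element == "H"), 0L)
  expect_equal(sum(a$residue_seq == 9 & a$element == "H"), 1L)
})

test_that("every placed hydrogen lies within 0.9-1.1 A of its parent", {
  for (seed in 1:3) {
    s <- suppressWarnings(
      prepare_structure(make_random_structure(25, seed = seed), quiet = TRUE)
    )
    a <- as_tibble(s)
    h <- a[a$element == "H", ]
    expect_true(all(!is.na(h$parent)))
    pa <- a[match(h$parent, a$serial), ]
    d <- sqrt((h$x - pa$x)^2 + (h$y - pa$y)^2 + (h$z - pa$z)^2)
    expect_true(all(d >= 0.9 & d <= 1.1))
  }
})

test_that("hydrogen counts match the per-residue donor valences", {
  s <- helix20_prepped()
  a <- as_tibble(s)
  ## poly-Ala helix: 3 H on the N-terminal amine + 1 amide H per residue 2..20
  expect_equal(sum(a$element == "H"), 3L + 19L)
  expect_equal(nrow(a), 100L + 22L)

  ## serine hydroxyl: exactly one H on OG
  ser <- suppressWarnings(
    prepare_structure(make_random_structure(40, seed = 5), quiet = TRUE)
  )
  sa <- as_tibble(ser)
  og <- sa[sa$name == "OG", ]
  expect_gt(nrow(og), 0L)
  for (k in seq_len(nrow(og))) {
    expect_equal(sum(sa$parent == og$serial[k], na.rm = TRUE), 1L)
  }
  ## lysine ammonium: three H on NZ
  nz <- sa[sa$name == "NZ", ]
  for (k in seq_len(nrow(nz))) {
    expect_equal(sum(sa$parent == nz$serial[k], na.rm = TRUE), 3L)
  }
})

test_that("pre-protonated input skips placement but attaches hydrogens", {
  s1 <- helix20_prepped()
  pdb <- write_pdb(s1)
  s2 <- prepare_structure(pdb, pre_protonated = TRUE)
  expect_true(s2$protonated)
  a2 <- as_tibble(s2)
  expect_equal(sum(a2$element == "H"), 22L)
  expect_true(all(!is.na(a2$parent[a2$element == "H"])))
  expect_error(place_hydrogens(s2), class = "hb_prep_error")
})
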
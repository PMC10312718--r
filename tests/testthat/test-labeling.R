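geom <- function(dims = c(16, 16, 16), origin = c(0, 0, 0), voxel = 1)
  density_map(array(0, dims), origin = origin, voxel = voxel)

res_atoms <- function(chain, resno, resid, ca, n = NULL, c = NULL,
                      ss = "coil") {
  rows <- data.frame(chain = chain, resno = resno, resid = resid,
                     elety = "CA", x = ca[1], y = ca[2], z = ca[3], ss = ss)
  if (!is.null(n))
    rows <- rbind(rows, data.frame(chain = chain, resno = resno,
                                   resid = resid, elety = "N", x = n[1],
                                   y = n[2], z = n[3], ss = ss))
  if (!is.null(c))
    rows <- rbind(rows, data.frame(chain = chain, resno = resno,
                                   resid = resid, elety = "C", x = c[1],
                                   y = c[2], z = c[3], ss = ss))
  rows
}

test_that("coordinate-to-index follows nearest rounding per axis", {
  m <- geom()
  expect_equal(coord_to_index(c(10.4, 5.6, 3.2), m),
               data.frame(i = 3L, j = 6L, k = 10L))
  expect_equal(coord_to_index(c(0, 0, 0), m),
               data.frame(i = 0L, j = 0L, k = 0L))
  m2 <- geom(origin = c(-5, -5, -5))
  expect_equal(coord_to_index(c(-3.7, 0.0, 2.49), m2),
               data.frame(i = 7L, j = 5L, k = 1L))
  expect_error(coord_to_index(c(100, 0, 0), m),
               class = "voxtrace_out_of_bounds")
})

test_that("index-to-coordinate inverts the grid mapping", {
  m <- geom(origin = c(4, -3, 7))
  expect_equal(index_to_coord(c(0, 0, 0), m),
               data.frame(x = 4, y = -3, z = 7))
  m0 <- geom()
  expect_equal(index_to_coord(c(2, 3, 4), m0),
               data.frame(x = 4, y = 3, z = 2))
  expect_error(index_to_coord(c(99, 0, 0), m0),
               class = "voxtrace_out_of_bounds")
})

test_that("round trip deviates at most half a voxel per axis (property)", {
  set.seed(31)
  for (trial in 1:50) {
    origin <- stats::runif(3, -20, 20)
    voxel <- stats::runif(3, 0.3, 3)
    dims <- sample(4:10, 3, replace = TRUE)
    m <- density_map(array(0, dims), origin = origin, voxel = voxel)
    cc <- data.frame(
      x = origin[1] + stats::runif(20, 0, (dims[1] - 1) * voxel[1]),
      y = origin[2] + stats::runif(20, 0, (dims[2] - 1) * voxel[2]),
      z = origin[3] + stats::runif(20, 0, (dims[3] - 1) * voxel[3]))
    back <- index_to_coord(coord_to_index(cc, m), m)
    dev <- abs(as.matrix(back) - as.matrix(cc))
    expect_true(all(dev <= rep(0.5 * voxel, each = 20) + 1e-9))
  }
})

test_that("atom masks code Calpha/N/C as 1/2/3 at the rounded voxels", {
  m <- geom()
  s <- atomic_structure(res_atoms("A", 1, "ALA", ca = c(2, 3, 4),
                                  n = c(2, 3, 5.4), c = c(3.6, 3, 4)))
  lab <- make_atom_labels(s, m)
  vals <- lab$atom$values
  expect_equal(vals[2 + 1, 3 + 1, 4 + 1], 1)   # CA at (k=2, j=3, i=4)
  expect_equal(vals[2 + 1, 3 + 1, 5 + 1], 2)   # N  at (k=2, j=3, i=5)
  expect_equal(vals[4 + 1, 3 + 1, 4 + 1], 3)   # C  at (k=4, j=3, i=4)
  expect_equal(sum(vals != 0), 3)
  expect_equal(lab$collisions, 0L)
  # calpha mask equals (atom mask == 1) everywhere
  expect_equal(lab$calpha$values, (vals == 1) * 1L)
})

test_that("empty structures and collisions are handled per the mask rules", {
  m <- geom()
  empty <- atomic_structure(data.frame(chain = character(0),
                                       resno = integer(0),
                                       resid = character(0),
                                       elety = character(0), x = numeric(0),
                                       y = numeric(0), z = numeric(0)))
  lab <- make_atom_labels(empty, m)
  expect_true(all(lab$atom$values == 0))

  # two residues whose Calpha atoms round to the same voxel
  s <- atomic_structure(rbind(
    res_atoms("A", 1, "ALA", ca = c(2.1, 3, 4)),
    res_atoms("A", 2, "GLY", ca = c(1.9, 3, 4))))
  lab <- make_atom_labels(s, m)
  expect_equal(sum(lab$atom$values == 1), 1)
  expect_equal(lab$collisions, 1L)

  # all atoms out of bounds: empty mask with a warning
  far <- atomic_structure(res_atoms("A", 1, "ALA", ca = c(500, 500, 500)))
  expect_warning(lab <- make_atom_labels(far, m),
                 class = "voxtrace_empty_mask")
  expect_equal(lab$skipped, 1L)
})

test_that("amino masks use the alphabetical 1..20 code table", {
  m <- geom()
  s <- atomic_structure(res_atoms("A", 1, "ALA", ca = c(0, 0, 0)))
  lab <- make_amino_labels(s, m)
  expect_equal(lab$amino$values[1, 1, 1], 1)    # ALA = 1

  s2 <- atomic_structure(rbind(
    res_atoms("A", 1, "GLY", ca = c(2, 2, 2)),
    res_atoms("A", 2, "VAL", ca = c(6, 6, 6)),
    res_atoms("A", 3, "MSE", ca = c(10, 10, 10))))
  lab2 <- make_amino_labels(s2, m)
  expect_equal(lab2$amino$values[3, 3, 3], 8)   # GLY = 8
  expect_equal(lab2$amino$values[7, 7, 7], 20)  # VAL = 20
  expect_equal(lab2$amino$values[11, 11, 11], 0)  # non-standard: unknown
  expect_equal(lab2$unknown, 1L)
  # nonzero amino voxels never exceed the residue count
  expect_lte(sum(lab2$amino$values != 0), 3)
})

test_that("secondary-structure labels come from HELIX/SHEET annotations", {
  m <- geom()
  s <- atomic_structure(rbind(
    res_atoms("A", 1, "ALA", ca = c(0, 0, 0), ss = "helix"),
    res_atoms("A", 2, "GLY", ca = c(4, 0, 0), ss = "helix")))
  lab <- make_ss_labels(s, m)
  expect_equal(lab$ss$values[1, 1, 1], 2)
  expect_equal(lab$ss$values[5, 1, 1], 2)

  # toy PDB with HELIX and SHEET records; range membership decides the tag
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HELIX    1   1 ALA A    1  ALA A    1  1                                   1",
    "SHEET    1   A 1 VAL A   2  VAL A   2  0",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  VAL A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       8.000   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  sp <- read_structure(pdb)
  lab2 <- make_ss_labels(sp, m)
  expect_equal(lab2$ss$values[1, 1, 1], 2)   # helix record
  expect_equal(lab2$ss$values[5, 1, 1], 3)   # sheet record
  expect_equal(lab2$ss$values[9, 1, 1], 1)   # unannotated: coil default
})

test_that("sequence extraction emits one-letter codes with X for unknowns", {
  s <- atomic_structure(rbind(
    res_atoms("A", 1, "ALA", ca = c(0, 0, 0)),
    res_atoms("A", 2, "GLY", ca = c(4, 0, 0)),
    res_atoms("A", 3, "VAL", ca = c(8, 0, 0))))
  expect_equal(unname(extract_sequence(s)["A"]), "AGV")

  s2 <- atomic_structure(rbind(
    res_atoms("B", 1, "ALA", ca = c(0, 0, 0)),
    res_atoms("B", 2, "MSE", ca = c(4, 0, 0)),
    res_atoms("B", 3, "VAL", ca = c(8, 0, 0))))
  expect_equal(unname(extract_sequence(s2)["B"]), "AXV")

  empty <- atomic_structure(data.frame(chain = character(0),
                                       resno = integer(0),
                                       resid = character(0),
                                       elety = character(0), x = numeric(0),
                                       y = numeric(0), z = numeric(0)))
  expect_length(extract_sequence(empty), 0)

  # FASTA round trip
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(extract_sequence(s), f)
  expect_equal(unname(read_fasta(f)["A"]), "AGV")
})

test_that("verify_labels measures the round-trip match fraction", {
  m <- geom()
  s <- atomic_structure(rbind(
    res_atoms("A", 1, "ALA", ca = c(2.2, 3, 4)),
    res_atoms("A", 2, "GLY", ca = c(6, 3.4, 4)),
    res_atoms("A", 3, "VAL", ca = c(9.7, 3, 4.4)),
    res_atoms("A", 4, "LEU", ca = c(13.2, 3, 4))))
  lab <- make_atom_labels(s, m)
  v <- verify_labels(lab$calpha, s, m)
  expect_equal(v$fraction, 1.0)
  expect_equal(v$n_checked, 4L)

  # deleting one Calpha voxel drops the fraction to (n-1)/n
  mask <- lab$calpha
  idx <- coord_to_index(c(2.2, 3, 4), m)
  mask$values[idx$k + 1, idx$j + 1, idx$i + 1] <- 0
  v2 <- verify_labels(mask, s, m)
  expect_equal(v2$fraction, 3 / 4)
  expect_equal(nrow(v2$deviations), 1L)

  empty <- atomic_structure(data.frame(chain = character(0),
                                       resno = integer(0),
                                       resid = character(0),
                                       elety = character(0), x = numeric(0),
                                       y = numeric(0), z = numeric(0)))
  expect_equal(verify_labels(lab$calpha, empty, m)$fraction, 1.0)
})
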
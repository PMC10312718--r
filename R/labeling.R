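# Converting atomic structures to voxel label masks and back.
#
# Grid indices (i, j, k) are 0-based and follow the (section, row, column)
# convention: i indexes z, j indexes y, k indexes x. Internally the map
# arrays are indexed [x+1, y+1, z+1].

#' Build an atomic structure table
#'
#' The in-memory structure representation is a flat atom table: one row per
#' atom with its chain, residue number, 3-letter residue code, atom name
#' (`CA`, `N`, `C`, ...), coordinates in Angstrom and a per-residue
#' secondary-structure tag (`"coil"`, `"helix"` or `"strand"`).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` and optionally `ss` (defaults to `"coil"`).
#' @return data.frame of class `atomic_structure`.
#' @export
atomic_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    vx_stop(paste("atom table needs columns:", paste(need, collapse = ", ")),
            "voxtrace_value_error")
  if (is.null(atoms$ss)) atoms$ss <- rep("coil", nrow(atoms))
  atoms$ss[is.na(atoms$ss) | !(atoms$ss %in% c("coil", "helix", "strand"))] <-
    "coil"
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    vx_stop("atom coordinates must be finite", "voxtrace_value_error")
  class(atoms) <- c("atomic_structure", "data.frame")
  atoms
}

#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records with \pkg{bio3d} and tags each residue's
#' secondary structure from the file's HELIX and SHEET records; residues in
#' neither kind of record are tagged coil.
#'
#' @param path path to a PDB file.
#' @return An [atomic_structure()] table.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  s <- data.frame(chain = as.character(at$chain), resno = at$resno,
                  resid = as.character(at$resid),
                  elety = as.character(at$elety),
                  x = at$x, y = at$y, z = at$z,
                  ss = "coil", stringsAsFactors = FALSE)
  tag_range <- function(s, rec, tag) {
    if (is.null(rec) || length(rec$start) == 0L) return(s)
    for (r in seq_along(rec$start)) {
      sel <- s$chain == rec$chain[r] &
        s$resno >= as.integer(rec$start[r]) &
        s$resno <= as.integer(rec$end[r])
      s$ss[sel] <- tag
    }
    s
  }
  s <- tag_range(s, pdb$helix, "helix")
  s <- tag_range(s, pdb$sheet, "strand")
  atomic_structure(s)
}

round_half_away <- function(v) sign(v) * floor(abs(v) + 0.5)

#' Convert physical coordinates to grid indices
#'
#' Maps coordinates `(x, y, z)` in the map's physical frame to 0-based grid
#' indices `(i, j, k)` = (section, row, column), where `i` comes from `z`,
#' `j` from `y` and `k` from `x`: each index is the nearest integer of
#' `(coordinate - origin) / voxel` on its axis, rounding halves away from
#' zero. Nearest rounding is what guarantees the round-trip deviation bound
#' of half a voxel per axis.
#'
#' @param coords numeric matrix (or data.frame) with columns `x`, `y`, `z`,
#'   or a length-3 vector.
#' @param map a [density_map()] (or anything with `origin` and `voxel`)
#'   defining the grid.
#' @param check if `TRUE` (default) an index outside the grid raises a
#'   `voxtrace_out_of_bounds` error naming the offending axis; if `FALSE`
#'   out-of-bounds rows are returned as is (callers may skip them).
#' @return data.frame with 0-based integer columns `i`, `j`, `k`.
#' @examples
#' m <- density_map(array(0, c(16, 16, 16)))
#' coord_to_index(c(10.4, 5.6, 3.2), m)   # i = 3, j = 6, k = 10
#' @export
coord_to_index <- function(coords, map, check = TRUE) {
  xyz <- coords_as_matrix(coords)
  if (any(map$voxel <= 0))
    vx_stop("voxel sizes must be positive", "voxtrace_value_error")
  rel <- sweep(sweep(xyz, 2L, map$origin), 2L, map$voxel, "/")
  idx <- round_half_away(rel)              # columns: x, y, z
  d <- dim(map$values)
  if (check) {
    for (a in 1:3) {
      bad <- which(idx[, a] < 0 | idx[, a] >= d[a])
      if (length(bad) > 0L)
        vx_stop(sprintf("coordinate %d maps outside the grid on the %s axis",
                        bad[1L], c("x", "y", "z")[a]),
                "voxtrace_out_of_bounds")
    }
  }
  data.frame(i = as.integer(idx[, 3L]), j = as.integer(idx[, 2L]),
             k = as.integer(idx[, 1L]))
}

#' Convert grid indices back to physical coordinates
#'
#' The inverse mapping of [coord_to_index()] up to voxel quantization:
#' `x = k * voxel_x + origin_x`, `y = j * voxel_y + origin_y`,
#' `z = i * voxel_z + origin_z`. Composing the two maps moves a coordinate
#' by at most half a voxel per axis.
#'
#' @param index data.frame or matrix with 0-based columns `i`, `j`, `k`
#'   (section, row, column), or a length-3 vector `(i, j, k)`.
#' @inheritParams coord_to_index
#' @return data.frame with columns `x`, `y`, `z` in Angstrom.
#' @export
index_to_coord <- function(index, map) {
  if (is.null(dim(index))) index <- as.data.frame(as.list(
    stats::setNames(index, c("i", "j", "k"))))
  index <- as.data.frame(index)
  d <- dim(map$values)
  if (any(index$i < 0 | index$i >= d[3] | index$j < 0 | index$j >= d[2] |
          index$k < 0 | index$k >= d[1]))
    vx_stop("grid index outside the map bounds", "voxtrace_out_of_bounds")
  data.frame(x = index$k * map$voxel[1] + map$origin[1],
             y = index$j * map$voxel[2] + map$origin[2],
             z = index$i * map$voxel[3] + map$origin[3])
}

coords_as_matrix <- function(coords) {
  if (is.null(dim(coords))) {
    stopifnot(length(coords) == 3L)
    matrix(as.numeric(coords), nrow = 1L,
           dimnames = list(NULL, c("x", "y", "z")))
  } else {
    as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  }
}

# one row per residue holding its backbone atoms; NA coordinate = missing
residue_table <- function(s) {
  key <- paste(s$chain, s$resno, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = s$chain[first], resno = s$resno[first],
                    resid = s$resid[first], ss = s$ss[first],
                    stringsAsFactors = FALSE)
  for (nm in c("CA", "N", "C")) {
    sel <- s$elety == nm
    m <- match(paste(res$chain, res$resno, sep = "\r"), key[sel])
    for (ax in c("x", "y", "z"))
      res[[paste0(nm, "_", ax)]] <- s[[ax]][sel][m]
  }
  res[order(res$chain, res$resno), , drop = FALSE]
}

# write codes at the voxels of given coordinates; returns mask values,
# collision and out-of-bounds counters. Last-written atom wins a collision.
paint_voxels <- function(values, coords, codes, map) {
  n_skip <- 0L; n_coll <- 0L
  if (nrow(coords) > 0L) {
    idx <- coord_to_index(coords, map, check = FALSE)
    d <- dim(values)
    ok <- idx$k >= 0 & idx$k < d[1] & idx$j >= 0 & idx$j < d[2] &
      idx$i >= 0 & idx$i < d[3]
    n_skip <- sum(!ok)
    lin <- 1L + idx$k[ok] + d[1] * (idx$j[ok] + d[2] * idx$i[ok])
    codes <- codes[ok]
    for (n in seq_along(lin)) {
      if (values[lin[n]] != 0) n_coll <- n_coll + 1L
      values[lin[n]] <- codes[n]
    }
  }
  list(values = values, skipped = n_skip, collisions = n_coll)
}

backbone_coords <- function(res, atom) {
  cols <- paste0(atom, "_", c("x", "y", "z"))
  out <- res[, cols]
  names(out) <- c("x", "y", "z")
  out
}

#' Label backbone-atom voxels of a map
#'
#' Builds two masks on the geometry of `map`: the atom mask, where the voxel
#' holding each residue's Calpha is coded 1, its backbone nitrogen 2 and its
#' carbonyl backbone carbon 3; and the Calpha-only mask coded 0/1. Atoms
#' falling outside the grid are skipped and counted; when two atoms round to
#' the same voxel the last written wins and the collision is counted, with
#' Calpha atoms written last so they take precedence over N and C.
#'
#' @param s an [atomic_structure()].
#' @param map the reference [density_map()] supplying grid shape, origin and
#'   voxel size.
#' @return list with elements `atom` and `calpha` (both [label_volume()]s),
#'   `skipped` and `collisions` (integer counters). An all-out-of-bounds
#'   structure yields all-zero masks with a `voxtrace_empty_mask` warning.
#' @export
make_atom_labels <- function(s, map) {
  stopifnot(inherits(s, "atomic_structure"), inherits(map, "density_map"))
  res <- residue_table(s)
  zero <- array(0, dim = dim(map$values))
  vals <- zero; n_skip <- 0L; n_coll <- 0L
  # N and C are written first and Calpha last, so when backbone atoms of
  # nearby residues round to one voxel the Calpha label survives: it is the
  # signal every downstream stage (candidate states, threading) consumes
  for (atom in c("N", "C", "CA")) {
    cc <- backbone_coords(res, atom)
    cc <- cc[stats::complete.cases(cc), , drop = FALSE]
    code <- match(atom, c("CA", "N", "C"))
    p <- paint_voxels(vals, cc, rep(code, nrow(cc)), map)
    vals <- p$values; n_skip <- n_skip + p$skipped
    n_coll <- n_coll + p$collisions
  }
  n_atoms <- sum(stats::complete.cases(backbone_coords(res, "CA"))) +
    sum(stats::complete.cases(backbone_coords(res, "N"))) +
    sum(stats::complete.cases(backbone_coords(res, "C")))
  if (n_atoms > 0L && all(vals == 0))
    vx_warn("all atoms fall outside the grid; masks are empty",
            "voxtrace_empty_mask")
  list(atom = label_volume(vals, "atom", map$origin, map$voxel),
       calpha = label_volume((vals == 1) * 1L, "calpha", map$origin,
                             map$voxel),
       skipped = n_skip, collisions = n_coll)
}

#' Label amino-acid types at Calpha voxels
#'
#' The voxel holding each residue's Calpha is set to the residue's
#' amino-acid code, 1..20 in alphabetical order of the three-letter codes
#' (see [amino_codes()]); non-standard residues get code 0 (unknown) and
#' are counted.
#'
#' @inheritParams make_atom_labels
#' @return list with `amino` (a [label_volume()]), `skipped`, `collisions`
#'   and `unknown` counters.
#' @export
make_amino_labels <- function(s, map) {
  stopifnot(inherits(s, "atomic_structure"), inherits(map, "density_map"))
  res <- residue_table(s)
  cc <- backbone_coords(res, "CA")
  keep <- stats::complete.cases(cc)
  codes <- match(res$resid, AA3)
  n_unknown <- sum(is.na(codes[keep]))
  codes[is.na(codes)] <- 0L
  p <- paint_voxels(array(0, dim = dim(map$values)),
                    cc[keep, , drop = FALSE], codes[keep], map)
  list(amino = label_volume(p$values, "amino", map$origin, map$voxel),
       skipped = p$skipped, collisions = p$collisions, unknown = n_unknown)
}

#' Label secondary-structure types at Calpha voxels
#'
#' The voxel holding each residue's Calpha is set to 1 for coil, 2 for
#' alpha-helix, 3 for beta-strand, using the structure's per-residue tags
#' (from HELIX/SHEET records when read from PDB); untagged residues default
#' to coil.
#'
#' @inheritParams make_atom_labels
#' @return list with `ss` (a [label_volume()]), `skipped` and `collisions`.
#' @export
make_ss_labels <- function(s, map) {
  stopifnot(inherits(s, "atomic_structure"), inherits(map, "density_map"))
  res <- residue_table(s)
  cc <- backbone_coords(res, "CA")
  keep <- stats::complete.cases(cc)
  codes <- match(res$ss, c("coil", "helix", "strand"))
  codes[is.na(codes)] <- 1L
  p <- paint_voxels(array(0, dim = dim(map$values)),
                    cc[keep, , drop = FALSE], codes[keep], map)
  list(ss = label_volume(p$values, "ss", map$origin, map$voxel),
       skipped = p$skipped, collisions = p$collisions)
}

#' Extract per-chain one-letter sequences from a structure
#'
#' One sequence per chain, residues ordered by residue number; residues
#' whose 3-letter code is not one of the 20 standard amino acids are
#' emitted as `X`. Empty chains are omitted.
#'
#' @param s an [atomic_structure()].
#' @return named character vector of one-letter sequences, one per chain.
#' @export
extract_sequence <- function(s) {
  stopifnot(inherits(s, "atomic_structure"))
  res <- residue_table(s)
  res <- res[nzchar(res$resid), , drop = FALSE]
  if (nrow(res) == 0L) return(stats::setNames(character(0L), character(0L)))
  one <- AA1[match(res$resid, AA3)]
  one[is.na(one)] <- "X"
  out <- vapply(split(one, res$chain), paste, character(1L), collapse = "")
  out[nzchar(out)]
}

#' Write per-chain sequences to a FASTA file
#'
#' @param sequences named character vector as returned by
#'   [extract_sequence()]; names become FASTA record ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- sequences[nzchar(sequences)]
  seqinr::write.fasta(lapply(sequences, function(x) strsplit(x, "")[[1L]]),
                      names = names(sequences), file.out = path)
  invisible(path)
}

#' Read per-chain sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(unlist(recs)), names(recs))
}

#' Verify a Calpha mask by coordinate round trip
#'
#' For each Calpha atom of the structure that lies inside the grid, checks
#' that the mask voxel at its grid index is set and that converting that
#' index back to coordinates lands within half a voxel of the atom on every
#' axis. Returns the fraction of atoms passing and the deviating atoms.
#'
#' @param calpha_mask a [label_volume()] of kind `"calpha"`.
#' @param s the [atomic_structure()] the mask was built from.
#' @param map the reference [density_map()]; must have the mask's shape.
#' @return list with `fraction` (1.0 for a freshly built mask; vacuously 1.0
#'   for an empty structure), `n_checked`, and `deviations` (data.frame of
#'   failing atoms).
#' @export
verify_labels <- function(calpha_mask, s, map) {
  stopifnot(inherits(calpha_mask, "label_volume"),
            calpha_mask$kind == "calpha", inherits(s, "atomic_structure"))
  if (!identical(dim(calpha_mask$values), dim(map$values)))
    vx_stop("mask and map shapes differ", "voxtrace_value_error")
  res <- residue_table(s)
  cc <- backbone_coords(res, "CA")
  keep <- stats::complete.cases(cc)
  cc <- cc[keep, , drop = FALSE]
  res <- res[keep, , drop = FALSE]
  if (nrow(cc) == 0L)
    return(list(fraction = 1.0, n_checked = 0L,
                deviations = data.frame()))
  idx <- coord_to_index(cc, map, check = FALSE)
  d <- dim(map$values)
  inb <- idx$k >= 0 & idx$k < d[1] & idx$j >= 0 & idx$j < d[2] &
    idx$i >= 0 & idx$i < d[3]
  cc <- cc[inb, , drop = FALSE]; idx <- idx[inb, , drop = FALSE]
  res <- res[inb, , drop = FALSE]
  if (nrow(cc) == 0L)
    return(list(fraction = 1.0, n_checked = 0L, deviations = data.frame()))
  back <- index_to_coord(idx, map)
  dev <- abs(as.matrix(back) - as.matrix(cc))
  within <- dev[, 1] <= 0.5 * map$voxel[1] + 1e-9 &
    dev[, 2] <= 0.5 * map$voxel[2] + 1e-9 &
    dev[, 3] <= 0.5 * map$voxel[3] + 1e-9
  set <- calpha_mask$values[cbind(idx$k + 1L, idx$j + 1L, idx$i + 1L)] == 1
  ok <- within & set
  list(fraction = mean(ok), n_checked = nrow(cc),
       deviations = cbind(res[!ok, c("chain", "resno", "resid")],
                          cc[!ok, , drop = FALSE]))
}
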
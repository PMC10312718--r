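# Division of a map into fixed-size overlapping sub-grids and stitching of
# per-sub-grid predictions back into a full-map volume.
#
# With cube size c and border b, the core is c - 2b voxels per axis. Cubes
# are extracted at stride = core from the zero-padded volume, so adjacent
# cubes overlap by 2b voxels (b per face) and every original voxel lies in
# exactly one cube's core. The defaults (32, 6) give the standard 20^3 core.

#' Divide a map or mask into overlapping sub-grids
#'
#' The grid is zero-padded by `border` voxels on the low side of each axis
#' and up to the next core multiple plus `border` on the high side, then
#' cubes of `cube_size`^3 voxels are extracted at stride `core =
#' cube_size - 2 * border`. The number of cubes per axis is
#' `ceiling(dim / core)`.
#'
#' @param map a [density_map()] or [label_volume()].
#' @param cube_size sub-grid edge length in voxels (default 32).
#' @param border overlap border per face in voxels (default 6);
#'   `cube_size > 2 * border >= 0` is required.
#' @return An object of class `subgrid_set`: list with `cubes` (list of
#'   `cube_size`^3 arrays), `offsets` (0-based low-corner indices of each
#'   cube in padded space, matrix with columns x, y, z), `cube_size`,
#'   `border`, `core`, `orig_dim`, `padded_dim`, and the map's `origin` and
#'   `voxel`.
#' @export
divide_map <- function(map, cube_size = 32L, border = 6L) {
  stopifnot(inherits(map, "density_map"))
  cube_size <- as.integer(cube_size); border <- as.integer(border)
  if (border < 0L || cube_size <= 2L * border)
    vx_stop("need cube_size > 2 * border >= 0 (positive core)",
            "voxtrace_value_error")
  d <- dim(map$values)
  if (any(d <= 0L))
    vx_stop("map has a non-positive dimension", "voxtrace_value_error")
  core <- cube_size - 2L * border
  n_cubes <- as.integer(ceiling(d / core))
  padded <- n_cubes * core + 2L * border

  pad <- array(0, dim = padded)
  pad[border + seq_len(d[1]), border + seq_len(d[2]), border + seq_len(d[3])] <-
    map$values

  offs <- as.matrix(expand.grid(x = (seq_len(n_cubes[1]) - 1L) * core,
                                y = (seq_len(n_cubes[2]) - 1L) * core,
                                z = (seq_len(n_cubes[3]) - 1L) * core))
  cubes <- lapply(seq_len(nrow(offs)), function(n) {
    o <- offs[n, ]
    array(pad[o[1] + seq_len(cube_size), o[2] + seq_len(cube_size),
              o[3] + seq_len(cube_size)], dim = rep(cube_size, 3L))
  })
  structure(list(cubes = cubes, offsets = offs, cube_size = cube_size,
                 border = border, core = core, orig_dim = d,
                 padded_dim = padded, origin = map$origin,
                 voxel = map$voxel),
            class = "subgrid_set")
}

#' Stitch per-sub-grid values back into a full-map volume
#'
#' For each cube only the central core (`core`^3 voxels; 20^3 with the
#' defaults) is copied into the output at its position; the padding is
#' trimmed so the output has exactly the original grid shape. Cubes may
#' carry a trailing channel dimension (class probabilities); the output then
#' has that channel dimension too.
#'
#' @param subgrids a `subgrid_set` from [divide_map()], whose `cubes` may
#'   have been replaced by same-shaped prediction arrays (3D, or 4D with
#'   channels last).
#' @return numeric array of the original grid shape (plus a channel axis if
#'   the cubes had one).
#' @export
stitch_predictions <- function(subgrids) {
  stopifnot(inherits(subgrids, "subgrid_set"))
  cs <- subgrids$cube_size; b <- subgrids$border; core <- subgrids$core
  offs <- subgrids$offsets
  if (length(subgrids$cubes) != nrow(offs) ||
      any(vapply(subgrids$cubes, is.null, logical(1L))))
    vx_stop(sprintf("sub-grid set is incomplete: expected %d cubes",
                    nrow(offs)), "voxtrace_value_error")
  dims1 <- dim(subgrids$cubes[[1L]])
  n_chan <- if (length(dims1) == 4L) dims1[4L] else 0L
  for (n in seq_along(subgrids$cubes)) {
    dn <- dim(subgrids$cubes[[n]])
    okd <- if (n_chan > 0L) identical(dn, c(rep(cs, 3L), n_chan))
           else identical(dn, rep(cs, 3L))
    if (!okd)
      vx_stop(sprintf("cube at offset (%d, %d, %d) has the wrong shape",
                      offs[n, 1], offs[n, 2], offs[n, 3]),
              "voxtrace_value_error")
  }
  pd <- subgrids$padded_dim
  out <- if (n_chan > 0L) array(0, dim = c(pd, n_chan)) else array(0, dim = pd)
  core_idx <- b + seq_len(core)
  for (n in seq_along(subgrids$cubes)) {
    o <- offs[n, ]
    tx <- o[1] + core_idx; ty <- o[2] + core_idx; tz <- o[3] + core_idx
    if (n_chan > 0L) {
      out[tx, ty, tz, ] <-
        subgrids$cubes[[n]][core_idx, core_idx, core_idx, , drop = FALSE]
    } else {
      out[tx, ty, tz] <-
        subgrids$cubes[[n]][core_idx, core_idx, core_idx, drop = FALSE]
    }
  }
  d <- subgrids$orig_dim
  if (n_chan > 0L) {
    out[b + seq_len(d[1]), b + seq_len(d[2]), b + seq_len(d[3]), ,
        drop = FALSE]
  } else {
    out[b + seq_len(d[1]), b + seq_len(d[2]), b + seq_len(d[3]),
        drop = FALSE]
  }
}

#' Save a sub-grid archive
#'
#' Serializes a map's sub-grids together with any aligned label sub-grids as
#' one named, versioned container, mirroring the one-archive-per-map layout
#' used for training data.
#'
#' @param sets named list of `subgrid_set` objects (e.g. `map`, `atom`,
#'   `amino`) sharing one geometry.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_subgrid_archive <- function(sets, path) {
  stopifnot(is.list(sets), length(sets) > 0L,
            all(vapply(sets, inherits, logical(1L), "subgrid_set")))
  saveRDS(list(format = "voxtrace-subgrids", version = 1L, sets = sets),
          path)
  invisible(path)
}

#' Load a sub-grid archive
#'
#' @param path path written by [save_subgrid_archive()].
#' @return named list of `subgrid_set` objects.
#' @export
load_subgrid_archive <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "voxtrace-subgrids"))
    vx_stop("not a voxtrace sub-grid archive", "voxtrace_format_error")
  x$sets
}
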
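#' @keywords internal
"_PACKAGE"

vx_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "voxtrace_error", "error")))
}

vx_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "voxtrace_warning", "warning")))
}

#' Create a density map
#'
#' A density map couples a 3D grid of values with the spatial metadata needed
#' to place it in the physical frame of a cryo-EM experiment: the origin of
#' the grid in Angstrom and the voxel size per axis. Values are stored in an
#' R array of dimension `c(nx, ny, nz)` indexed `[x, y, z]`; because R arrays
#' are column-major this is byte-for-byte the canonical MRC layout in which
#' the x axis varies fastest (columns), then y (rows), then z (sections).
#'
#' @param values numeric 3D array, dimension `c(nx, ny, nz)`, indexed
#'   `[x, y, z]` (1-based).
#' @param origin numeric length-3 vector `(x, y, z)` in Angstrom.
#' @param voxel numeric length-3 vector of voxel sizes `(x, y, z)` in
#'   Angstrom, all positive. A scalar is recycled.
#' @return An object of class `density_map` with fields `values`, `origin`,
#'   `voxel`.
#' @examples
#' m <- density_map(array(0, c(4, 4, 4)), origin = c(0, 0, 0), voxel = 1)
#' dim(m$values)
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    vx_stop("'values' must be a 3D array", "voxtrace_value_error")
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  stopifnot(length(origin) == 3L, length(voxel) == 3L)
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    vx_stop("voxel sizes must be positive", "voxtrace_value_error")
  structure(list(values = values,
                 origin = as.numeric(origin),
                 voxel = as.numeric(voxel)),
            class = "density_map")
}

#' Create a label volume
#'
#' A label volume is an integer-coded mask on the same grid as a reference
#' density map. Four kinds are used: `"atom"` (0 = empty, 1 = Calpha, 2 = N,
#' 3 = C), `"calpha"` (0/1), `"amino"` (0 = absent/unknown, 1..20 = the
#' standard amino acids in alphabetical order of their three-letter codes)
#' and `"ss"` (0 = empty, 1 = coil, 2 = alpha-helix, 3 = beta-strand).
#'
#' @param values integer-valued 3D array, same convention as [density_map()].
#' @param kind one of `"atom"`, `"calpha"`, `"amino"`, `"ss"`.
#' @inheritParams density_map
#' @return An object of class `c("label_volume", "density_map")`.
#' @export
label_volume <- function(values, kind = c("atom", "calpha", "amino", "ss"),
                         origin = c(0, 0, 0), voxel = c(1, 1, 1)) {
  kind <- match.arg(kind)
  m <- density_map(values, origin, voxel)
  max_code <- c(atom = 3L, calpha = 1L, amino = 20L, ss = 3L)[[kind]]
  v <- m$values
  if (any(v != round(v)) || any(v < 0) || any(v > max_code))
    vx_stop(sprintf("'%s' labels must be integers in 0..%d", kind, max_code),
            "voxtrace_value_error")
  m$kind <- kind
  class(m) <- c("label_volume", "density_map")
  m
}

#' Create a prediction volume
#'
#' Per-voxel class probabilities over a named class set, standing in for the
#' voxel classifier output of a trained network. Atom-type volumes use the
#' classes `none, CA, N, C`; amino-type volumes use `UNK` plus the 20
#' standard amino-acid one-letter codes.
#'
#' @param probs numeric 4D array of dimension `c(nx, ny, nz, n_classes)`;
#'   every voxel's class probabilities must be in `[0, 1]` and sum to 1
#'   within `1e-6`.
#' @param classes character vector of class names, one per channel.
#' @inheritParams density_map
#' @return An object of class `prediction_volume`.
#' @export
prediction_volume <- function(probs, classes, origin = c(0, 0, 0),
                              voxel = c(1, 1, 1)) {
  if (!is.array(probs) || length(dim(probs)) != 4L)
    vx_stop("'probs' must be a 4D array (x, y, z, class)", "voxtrace_value_error")
  if (dim(probs)[4L] != length(classes))
    vx_stop("number of channels must match 'classes'", "voxtrace_value_error")
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    vx_stop("probabilities must lie in [0, 1]", "voxtrace_value_error")
  sums <- rowSums(probs, dims = 3L)
  if (any(abs(sums - 1) > 1e-6))
    vx_stop("per-voxel probabilities must sum to 1 (tolerance 1e-6)",
            "voxtrace_value_error")
  structure(list(probs = probs, classes = as.character(classes),
                 origin = as.numeric(origin), voxel = as.numeric(voxel)),
            class = "prediction_volume")
}

#' Extract one class channel of a prediction volume as a 3D array
#'
#' @param pred a [prediction_volume()].
#' @param class class name, e.g. `"CA"`.
#' @return numeric 3D array of that channel's probabilities.
#' @export
pred_channel <- function(pred, class) {
  stopifnot(inherits(pred, "prediction_volume"))
  i <- match(class, pred$classes)
  if (is.na(i))
    vx_stop(sprintf("no class '%s' in prediction volume", class),
            "voxtrace_value_error")
  ch <- pred$probs[, , , i, drop = FALSE]
  array(ch, dim = dim(pred$probs)[1:3])
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels\n",
              if (inherits(x, "label_volume")) paste0("label_volume:", x$kind)
              else "density_map",
              d[1], d[2], d[3]))
  cat(sprintf("  origin (%g, %g, %g) A, voxel (%g, %g, %g) A\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

# standard amino-acid tables; codes 1..20 are alphabetical by 3-letter code
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

#' Amino-acid integer codes
#'
#' The fixed mapping between the 20 standard residues and the integer labels
#' used in amino-type masks: alphabetical order of the three-letter codes,
#' `ALA = 1` through `VAL = 20`; 0 is reserved for absence or unknown type.
#'
#' @return data.frame with columns `code`, `aa3`, `aa1`.
#' @examples
#' amino_codes()[amino_codes()$aa3 %in% c("GLY", "VAL"), ]
#' @export
amino_codes <- function() {
  data.frame(code = seq_along(AA3), aa3 = AA3, aa1 = AA1,
             stringsAsFactors = FALSE)
}

# derive a per-component RNG seed from a user seed; stays below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * k) %% 2147483629)
}
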
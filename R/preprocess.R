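# Map standardization: resampling to a uniform voxel grid and percentile
# normalization of density values.

#' Resample a density map to a uniform voxel size
#'
#' Trilinear interpolation onto a new grid with the requested voxel size on
#' all axes (default 1 Angstrom, the standard training grid). The output
#' grid starts at the input origin and extends far enough to cover the full
#' physical extent of the input; sample points outside the input support are
#' filled with 0. Trilinear interpolation is exact on fields that are linear
#' in each coordinate, which gives an analytic oracle for testing.
#'
#' @param map a [density_map()].
#' @param target_voxel target voxel size in Angstrom (scalar, applied to all
#'   axes). Default 1.
#' @return A [density_map()] with voxel size `target_voxel` on every axis and
#'   the same origin as the input.
#' @export
resample_map <- function(map, target_voxel = 1) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(target_voxel) || target_voxel <= 0)
    vx_stop("target voxel size must be positive", "voxtrace_value_error")
  d <- dim(map$values)
  if (any(d < 2L))
    vx_stop("cannot resample an axis with fewer than 2 planes",
            "voxtrace_dimension_error")

  extent <- (d - 1L) * map$voxel                 # physical span per axis
  n_out <- pmax(2L, as.integer(ceiling(extent / target_voxel - 1e-9)) + 1L)

  # output sample positions in input-grid units (0-based fractional index)
  axes <- lapply(1:3, function(a) {
    (seq_len(n_out[a]) - 1) * target_voxel / map$voxel[a]
  })
  lo <- lapply(axes, function(t) pmin(pmax(floor(t), 0), 1e18))
  fr <- Map(function(t, l) t - l, axes, lo)

  out <- array(0, dim = n_out)
  V <- map$values
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- lo[[1]] + dx; iy <- lo[[2]] + dy; iz <- lo[[3]] + dz
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    # zero-fill outside the input support
    wx[ix < 0 | ix > d[1] - 1] <- 0
    wy[iy < 0 | iy > d[2] - 1] <- 0
    wz[iz < 0 | iz > d[3] - 1] <- 0
    ix <- pmin(pmax(ix, 0), d[1] - 1)
    iy <- pmin(pmax(iy, 0), d[2] - 1)
    iz <- pmin(pmax(iz, 0), d[3] - 1)
    w <- outer(outer(wx, wy), wz)
    if (all(w == 0)) next
    out <- out + w * V[ix + 1, iy + 1, iz + 1, drop = FALSE]
  }
  density_map(out, origin = map$origin, voxel = rep(target_voxel, 3L))
}

#' Normalize density values to [0, 1] by the positive-percentile rule
#'
#' Computes the given percentile (default the 95th) of the strictly positive
#' density values, divides every value in the map by it, then clips values
#' below 0 to 0 and above 1 to 1. This removes cross-map scale differences
#' caused by differing experimental conditions and reconstruction software
#' while leaving the relative ordering of in-range densities intact. The
#' percentile is the sort-based estimator with linear interpolation between
#' order statistics.
#'
#' @param map a [density_map()].
#' @param percentile percentile of the positive values used as the divisor,
#'   in (0, 100]. Default 95.
#' @return A [density_map()] with all values in `[0, 1]`. If the map has no
#'   strictly positive voxel an all-zero map is returned with a
#'   `voxtrace_no_positive_values` warning.
#' @examples
#' m <- density_map(array(c(-1, 0.2, 0.5, 1, 2, 0, 0, 0), c(2, 2, 2)))
#' range(normalize_map(m)$values)
#' @export
normalize_map <- function(map, percentile = 95) {
  stopifnot(inherits(map, "density_map"))
  if (!is.finite(percentile) || percentile <= 0 || percentile > 100)
    vx_stop("percentile must be in (0, 100]", "voxtrace_value_error")
  v <- map$values
  if (any(!is.finite(v)))
    vx_stop("grid contains non-finite values", "voxtrace_value_error")
  pos <- v[v > 0]
  if (length(pos) == 0L) {
    vx_warn("map has no strictly positive voxel; returning all-zero map",
            "voxtrace_no_positive_values")
    out <- map
    out$values[] <- 0
    return(out)
  }
  p <- stats::quantile(pos, percentile / 100, names = FALSE, type = 7L)
  out <- map
  out$values <- pmin(pmax(v / p, 0), 1)
  out
}
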
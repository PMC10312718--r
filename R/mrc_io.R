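# MRC2014 binary I/O.
#
# The 1024-byte header is fixed-layout little-endian; word offsets follow the
# MRC2014 standard. Data words: nx varies fastest (columns), then ny (rows),
# then nz (sections); mapc/mapr/maps say which crystallographic axis (1 = x,
# 2 = y, 3 = z) each of those corresponds to. On read the grid is always
# de-permuted to logical (x, y, z) axis order; on write the canonical
# 1,2,3 mapping is used.

MRC_HEADER_SIZE <- 1024L
MRC_MODES <- c(0L, 1L, 2L, 4L, 6L, 12L)          # valid per the standard
MRC_READ_MODES <- c(0L, 1L, 2L, 6L)              # modes this reader decodes
MRC_MODE_BYTES <- c(`0` = 1L, `1` = 2L, `2` = 4L, `4` = 8L, `6` = 2L, `12` = 2L)
MRC_MACHINE_STAMPS <- list(as.raw(c(0x44, 0x44, 0x00, 0x00)),
                           as.raw(c(0x44, 0x41, 0x00, 0x00)),
                           as.raw(c(0x11, 0x11, 0x00, 0x00)))

read_int32 <- function(raw, word) {
  readBin(raw[(4L * (word - 1L) + 1L):(4L * word)], integer(), n = 1L,
          size = 4L, endian = "little")
}

read_float32 <- function(raw, word) {
  readBin(raw[(4L * (word - 1L) + 1L):(4L * word)], numeric(), n = 1L,
          size = 4L, endian = "little")
}

parse_mrc_header <- function(hdr) {
  stopifnot(length(hdr) >= MRC_HEADER_SIZE)
  labels_raw <- hdr[225:1024]
  labels <- vapply(seq_len(10L), function(i) {
    bytes <- labels_raw[(80L * (i - 1L) + 1L):(80L * i)]
    rawToChar(bytes[bytes != as.raw(0)])
  }, character(1L))
  list(
    nx = read_int32(hdr, 1L), ny = read_int32(hdr, 2L), nz = read_int32(hdr, 3L),
    mode = read_int32(hdr, 4L),
    nxstart = read_int32(hdr, 5L), nystart = read_int32(hdr, 6L),
    nzstart = read_int32(hdr, 7L),
    mx = read_int32(hdr, 8L), my = read_int32(hdr, 9L), mz = read_int32(hdr, 10L),
    cella = c(read_float32(hdr, 11L), read_float32(hdr, 12L),
              read_float32(hdr, 13L)),
    cellb = c(read_float32(hdr, 14L), read_float32(hdr, 15L),
              read_float32(hdr, 16L)),
    mapc = read_int32(hdr, 17L), mapr = read_int32(hdr, 18L),
    maps = read_int32(hdr, 19L),
    dmin = read_float32(hdr, 20L), dmax = read_float32(hdr, 21L),
    dmean = read_float32(hdr, 22L),
    ispg = read_int32(hdr, 23L), nsymbt = read_int32(hdr, 24L),
    exttyp = rawToChar(hdr[105:108][hdr[105:108] != as.raw(0)]),
    nversion = read_int32(hdr, 28L),
    origin = c(read_float32(hdr, 50L), read_float32(hdr, 51L),
               read_float32(hdr, 52L)),
    map_id = rawToChar(hdr[209:212][hdr[209:212] != as.raw(0)]),
    map_id_raw = hdr[209:212],
    machst = hdr[213:216],
    rms = read_float32(hdr, 55L),
    nlabl = read_int32(hdr, 56L),
    labels = labels
  )
}

# quantize doubles to float32 so in-memory values equal on-disk values
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
          numeric(), n = length(v), size = 4L, endian = "little")
}

#' Read an MRC2014 density map
#'
#' Reads a volumetric MRC file and resolves the `mapc/mapr/maps` axis
#' permutation so that the returned grid is always in logical `(x, y, z)`
#' order, regardless of the on-disk storage order. Voxel sizes are derived as
#' cell dimension / sampling count per axis.
#'
#' @param path path to an `.mrc` file.
#' @return A [density_map()]; the raw parsed header is attached as attribute
#'   `"mrc_header"`.
#' @seealso [write_mrc()], [validate_mrc()]
#' @export
read_mrc <- function(path) {
  if (!file.exists(path))
    vx_stop(sprintf("file not found: %s", path), "voxtrace_io_error")
  n_bytes <- file.size(path)
  if (n_bytes < MRC_HEADER_SIZE)
    vx_stop(sprintf("file too small for an MRC header (%d bytes): %s",
                    n_bytes, path), "voxtrace_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, raw(), n = MRC_HEADER_SIZE)
  h <- parse_mrc_header(hdr_raw)

  if (!(h$mode %in% MRC_READ_MODES))
    vx_stop(sprintf("unsupported MRC mode %d (reader supports %s)",
                    h$mode, paste(MRC_READ_MODES, collapse = ", ")),
            "voxtrace_unsupported_mode")
  if (h$nx <= 0 || h$ny <= 0 || h$nz <= 0 ||
      h$mx <= 0 || h$my <= 0 || h$mz <= 0 || any(h$cella <= 0))
    vx_stop("non-positive map or cell dimensions", "voxtrace_format_error")
  perm <- c(h$mapc, h$mapr, h$maps)
  if (!identical(sort(perm), 1:3))
    vx_stop("mapc/mapr/maps is not a permutation of 1, 2, 3",
            "voxtrace_format_error")

  if (h$nsymbt > 0) readBin(con, raw(), n = h$nsymbt)
  n_vox <- as.double(h$nx) * h$ny * h$nz
  values <- switch(as.character(h$mode),
    `0` = as.numeric(readBin(con, integer(), n = n_vox, size = 1L,
                             signed = TRUE, endian = "little")),
    `1` = as.numeric(readBin(con, integer(), n = n_vox, size = 2L,
                             signed = TRUE, endian = "little")),
    `2` = readBin(con, numeric(), n = n_vox, size = 4L, endian = "little"),
    `6` = as.numeric(readBin(con, integer(), n = n_vox, size = 2L,
                             signed = FALSE, endian = "little")))
  if (length(values) < n_vox)
    vx_stop(sprintf("truncated data section: expected %d voxels, got %d",
                    n_vox, length(values)), "voxtrace_format_error")

  # file dims are (columns, rows, sections); de-permute to (x, y, z)
  arr <- array(values, dim = c(h$nx, h$ny, h$nz))
  arr <- aperm(arr, match(1:3, perm))
  m_counts <- c(h$mx, h$my, h$mz)        # sampling counts along x, y, z
  voxel <- h$cella / m_counts
  map <- density_map(arr, origin = h$origin, voxel = voxel)
  attr(map, "mrc_header") <- h
  map
}

#' Write a density map or mask as an MRC2014 file
#'
#' Writes the grid in canonical axis order (`mapc, mapr, maps = 1, 2, 3`),
#' recomputes the header data statistics (dmin, dmax, dmean, rms) from the
#' data, and stamps the file as MRC2014 (`nversion = 20140`, map id
#' `"MAP "`, little-endian machine stamp). The default mode 2 (32-bit real)
#' is used for maps and masks alike; integral label values are preserved
#' exactly.
#'
#' @param map a [density_map()] or [label_volume()].
#' @param path output path.
#' @param mode MRC data mode: one of 0 (int8), 1 (int16), 2 (float32,
#'   default), 6 (uint16).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path, mode = 2L) {
  stopifnot(inherits(map, "density_map"))
  mode <- as.integer(mode)
  if (!(mode %in% MRC_READ_MODES))
    vx_stop(sprintf("unsupported write mode %d", mode),
            "voxtrace_unsupported_mode")
  v <- map$values
  if (any(!is.finite(v)))
    vx_stop("grid contains non-finite values", "voxtrace_value_error")
  d <- dim(v)
  if (mode != 2L) {
    rng <- switch(as.character(mode), `0` = c(-128, 127),
                  `1` = c(-32768, 32767), `6` = c(0, 65535))
    if (any(v != round(v)) || any(v < rng[1]) || any(v > rng[2]))
      vx_stop(sprintf("values not representable in mode %d", mode),
              "voxtrace_value_error")
  } else {
    v <- as_float32(v)
  }
  stats <- c(min(v), max(v), mean(v))
  rms <- sqrt(mean((v - stats[3])^2))

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                                   # nx, ny, nz
  wi(mode)
  wi(c(0L, 0L, 0L))                       # n*start
  wi(d)                                   # mx, my, mz
  wf(d * map$voxel)                       # cella
  wf(c(90, 90, 90))                       # cellb
  wi(1:3)                                 # mapc, mapr, maps
  wf(stats)                               # dmin, dmax, dmean
  wi(1L)                                  # ispg: single volume
  wi(0L)                                  # nsymbt: no extended header
  writeBin(raw(8L), con)                  # extra words 25-26
  writeBin(raw(4L), con)                  # exttyp (unset: no ext header)
  wi(20140L)                              # nversion
  writeBin(raw(84L), con)                 # extra words 29-49
  wf(map$origin)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(MRC_MACHINE_STAMPS[[1L]], con) # little-endian stamp
  wf(rms)
  wi(1L)                                  # nlabl
  lab <- sprintf("%-80s", "voxtrace standardized volume")
  writeChar(substr(lab, 1L, 80L), con, nchars = 80L, eos = NULL)
  writeBin(raw(80L * 9L), con)            # unused labels stay blank
  switch(as.character(mode),
    `0` = writeBin(as.integer(v), con, size = 1L, endian = "little"),
    `1` = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    `2` = writeBin(as.numeric(v), con, size = 4L, endian = "little"),
    `6` = {
      iv <- as.integer(v)
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L   # reinterpret as int16
      writeBin(iv, con, size = 2L, endian = "little")
    })
  invisible(path)
}

mrc_check <- function(name, passed, message) {
  data.frame(check = name, passed = passed, message = message,
             stringsAsFactors = FALSE)
}

#' Validate an MRC file against the MRC2014 standard
#'
#' Runs the standard compliance battery and reports each check separately:
#' map ID string, machine stamp, data mode, map dimensions, cell dimensions,
#' axis mapping, volume-stack divisibility (spacegroups 401-630), header
#' label consistency, format version, extended-header type, data statistics
#' (or their undetermined markers), and on-disk file size versus the
#' header-derived expectation.
#'
#' @param path path to the file to validate.
#' @return A data.frame of class `mrc_validation` with columns `check`
#'   (12 rows), `passed` (logical) and `message`.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' write_mrc(density_map(array(stats::runif(64), c(4, 4, 4))), f)
#' rep <- validate_mrc(f)
#' all(rep$passed)
#' @export
validate_mrc <- function(path) {
  if (!file.exists(path) || file.access(path, mode = 4L) != 0L)
    vx_stop(sprintf("cannot read file: %s", path), "voxtrace_io_error")
  n_bytes <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, raw(), n = MRC_HEADER_SIZE)
  if (length(hdr_raw) < MRC_HEADER_SIZE) {
    out <- mrc_check("file_size", FALSE,
                     sprintf("file is %d bytes, smaller than the %d-byte header",
                             n_bytes, MRC_HEADER_SIZE))
    class(out) <- c("mrc_validation", "data.frame")
    return(out)
  }
  h <- parse_mrc_header(hdr_raw)
  checks <- list()

  checks$map_id <- mrc_check("map_id",
    identical(h$map_id_raw, charToRaw("MAP ")),
    sprintf("map field is '%s' (expect 'MAP ')", h$map_id))

  checks$machine_stamp <- mrc_check("machine_stamp",
    any(vapply(MRC_MACHINE_STAMPS, identical, logical(1L), h$machst)),
    sprintf("machine stamp %s", paste(format(h$machst), collapse = " ")))

  mode_ok <- h$mode %in% MRC_MODES
  checks$mode <- mrc_check("mode", mode_ok,
    sprintf("mode %d (supported: %s)", h$mode,
            paste(MRC_MODES, collapse = ", ")))

  checks$map_dimensions <- mrc_check("map_dimensions",
    all(c(h$nx, h$ny, h$nz, h$mx, h$my, h$mz) > 0),
    sprintf("nx,ny,nz = %d,%d,%d; mx,my,mz = %d,%d,%d",
            h$nx, h$ny, h$nz, h$mx, h$my, h$mz))

  checks$cell_dimensions <- mrc_check("cell_dimensions",
    all(h$cella > 0),
    sprintf("cella = %.4g, %.4g, %.4g", h$cella[1], h$cella[2], h$cella[3]))

  perm <- c(h$mapc, h$mapr, h$maps)
  checks$axis_mapping <- mrc_check("axis_mapping",
    identical(sort(perm), 1:3),
    sprintf("mapc,mapr,maps = %d,%d,%d", perm[1], perm[2], perm[3]))

  stack_ok <- !(h$ispg >= 401L && h$ispg <= 630L) ||
    (h$mz > 0L && h$nz %% h$mz == 0L)
  checks$volume_stack <- mrc_check("volume_stack", stack_ok,
    sprintf("ispg = %d; nz = %d, mz = %d", h$ispg, h$nz, h$mz))

  in_use <- nchar(trimws(h$labels)) > 0L
  lab_ok <- h$nlabl >= 0L && h$nlabl <= 10L &&
    all(in_use[seq_len(min(h$nlabl, 10L))]) &&
    !any(in_use[setdiff(seq_len(10L), seq_len(min(h$nlabl, 10L)))])
  checks$labels <- mrc_check("labels", lab_ok,
    sprintf("nlabl = %d, labels in use = %d", h$nlabl, sum(in_use)))

  checks$nversion <- mrc_check("nversion",
    h$nversion %in% c(20140L, 20141L),
    sprintf("nversion = %d", h$nversion))

  checks$exttyp <- mrc_check("exttyp",
    h$nsymbt == 0L || nchar(trimws(h$exttyp)) > 0L,
    sprintf("nsymbt = %d, exttyp = '%s'", h$nsymbt, h$exttyp))

  expected_size <- NA_real_
  stats_ok <- TRUE
  stats_msg <- "statistics marked undetermined"
  if (mode_ok) {
    n_vox <- as.double(h$nx) * h$ny * h$nz
    expected_size <- MRC_HEADER_SIZE + max(h$nsymbt, 0L) +
      n_vox * MRC_MODE_BYTES[[as.character(h$mode)]]
    determined <- h$dmax >= h$dmin
    if (determined && h$mode %in% MRC_READ_MODES &&
        n_bytes >= expected_size) {
      if (h$nsymbt > 0L) readBin(con, raw(), n = h$nsymbt)
      v <- switch(as.character(h$mode),
        `0` = as.numeric(readBin(con, integer(), n = n_vox, size = 1L,
                                 signed = TRUE, endian = "little")),
        `1` = as.numeric(readBin(con, integer(), n = n_vox, size = 2L,
                                 signed = TRUE, endian = "little")),
        `2` = readBin(con, numeric(), n = n_vox, size = 4L,
                      endian = "little"),
        `6` = as.numeric(readBin(con, integer(), n = n_vox, size = 2L,
                                 signed = FALSE, endian = "little")))
      tol <- 1e-4 * max(1, abs(h$dmax - h$dmin))
      stats_ok <- abs(min(v) - h$dmin) <= tol &&
        abs(max(v) - h$dmax) <= tol &&
        abs(mean(v) - h$dmean) <= tol &&
        (h$rms < 0 || abs(sqrt(mean((v - mean(v))^2)) - h$rms) <= tol)
      stats_msg <- sprintf(
        "header dmin/dmax/dmean = %.6g/%.6g/%.6g vs data %.6g/%.6g/%.6g",
        h$dmin, h$dmax, h$dmean, min(v), max(v), mean(v))
    } else if (determined && !(h$mode %in% MRC_READ_MODES)) {
      stats_msg <- sprintf("statistics not checked for mode %d", h$mode)
    }
  }
  checks$data_statistics <- mrc_check("data_statistics", stats_ok, stats_msg)

  size_ok <- !is.na(expected_size) && n_bytes == expected_size
  checks$file_size <- mrc_check("file_size", size_ok,
    sprintf("file is %.0f bytes, header implies %.0f", n_bytes,
            expected_size))

  out <- do.call(rbind, unname(checks))
  rownames(out) <- NULL
  class(out) <- c("mrc_validation", "data.frame")
  out
}

#' @export
print.mrc_validation <- function(x, ...) {
  status <- ifelse(x$passed, "PASS", "FAIL")
  cat(sprintf("%-18s %-4s %s\n", x$check, status, x$message), sep = "")
  cat(sprintf("%d/%d checks passed\n", sum(x$passed), nrow(x)))
  invisible(x)
}
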
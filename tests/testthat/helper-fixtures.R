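# Shared fixtures and independent oracles, built in code at test time.

AA1_TAB <- amino_codes()$aa1
AA3_TAB <- amino_codes()$aa3

random_map <- function(dims = c(6, 5, 4), origin = c(0, 0, 0), voxel = 1,
                       fill = stats::runif) {
  density_map(array(fill(prod(dims)), dim = dims), origin = origin,
              voxel = voxel)
}

# candidate-state table with a caller-supplied emission matrix, bypassing
# the prediction-volume path so the search can be tested in isolation
make_candidates <- function(coords, emission) {
  n <- nrow(coords)
  df <- data.frame(state = seq_len(n), i = seq_len(n) - 1L, j = 0L, k = 0L,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   calpha_prob = 1)
  class(df) <- c("ca_candidates", "data.frame")
  colnames(emission) <- AA1_TAB
  attr(df, "emission") <- emission
  df
}

# independent brute-force oracle for the constrained Viterbi: enumerates
# every injective assignment of residues to states and scores it from first
# principles (normal-density transitions, initial = normalized emission of
# the first residue)
brute_force_thread <- function(coords, emission, seq1, mu = 3.8047,
                               sigma = 0.036, lambda = 10,
                               cutoff = mu + 10 * sigma * lambda) {
  aa <- match(seq1, AA1_TAB)
  n <- nrow(coords)
  L <- length(aa)
  d <- as.matrix(stats::dist(coords))
  lt <- stats::dnorm(d, mu, sigma * lambda, log = TRUE)
  lt[d > cutoff] <- -Inf
  diag(lt) <- -Inf
  le <- log(emission)
  e1 <- emission[, aa[1]]
  linit <- log(e1 / sum(e1))
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), L)))
  if (L > 1L)
    paths <- paths[apply(paths, 1L, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
  best <- -Inf
  best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    sc <- linit[p[1]] + le[p[1], aa[1]]
    if (L > 1L) for (t in 2:L) {
      sc <- sc + lt[p[t - 1], p[t]] + le[p[t], aa[t]]
      if (!is.finite(sc)) break
    }
    if (sc > best) {
      best <- sc
      best_path <- p
    }
  }
  list(score = best, path = best_path)
}

# seeded random small HMM instance on a perturbed-chain geometry (keeps
# consecutive states mutually reachable)
random_hmm_instance <- function(seed, max_states = 7L, max_residues = 5L) {
  set.seed(seed)
  n <- sample(3:max_states, 1L)
  L <- sample(2:min(max_residues, n), 1L)
  base <- matrix(0, n, 3L)
  for (i in seq_len(n)[-1L]) {
    u <- stats::rnorm(3L)
    base[i, ] <- base[i - 1L, ] + 3.8 * u / sqrt(sum(u^2))
  }
  coords <- base + matrix(stats::rnorm(3L * n, 0, 0.4), n, 3L)
  em <- matrix(stats::rgamma(n * 20L, 1), n, 20L)
  em <- em / rowSums(em)
  seq1 <- sample(AA1_TAB, L, replace = TRUE)
  list(coords = coords, emission = em, seq = seq1)
}

# minimal raw MRC writer used as an independent oracle for axis-permuted
# files: writes an arbitrary header + float32 data without going through
# the package's writer
write_raw_mrc <- function(path, arr_file_order, perm, cella, origin,
                          mode = 2L, nversion = 20140L,
                          map_id = "MAP ", truncate_bytes = 0L) {
  d <- dim(arr_file_order)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wi(d); wi(mode); wi(c(0L, 0L, 0L))
  m_xyz <- integer(3L)
  m_xyz[perm] <- d                 # sampling counts along x, y, z
  wi(m_xyz)
  wf(cella)
  wf(c(90, 90, 90))
  wi(perm)
  v <- as.numeric(arr_file_order)
  wf(c(min(v), max(v), mean(v)))
  wi(1L); wi(0L)
  writeBin(raw(8L), con); writeBin(raw(4L), con)
  wi(nversion)
  writeBin(raw(84L), con)
  wf(origin)
  writeChar(map_id, con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sqrt(mean((v - mean(v))^2)))
  wi(0L)
  writeBin(raw(800L), con)
  wf(v)
  close(con)
  on.exit(NULL)
  if (truncate_bytes > 0L) {
    sz <- file.size(path)
    raw_all <- readBin(path, raw(), n = sz)
    writeBin(raw_all[seq_len(sz - truncate_bytes)], path)
  }
  invisible(path)
}

# patch one 4-byte little-endian integer word of a file in place
patch_mrc_word <- function(path, word, value) {
  raw_all <- readBin(path, raw(), n = file.size(path))
  raw_all[(4L * (word - 1L) + 1L):(4L * word)] <-
    writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  writeBin(raw_all, path)
  invisible(path)
}

patch_mrc_bytes <- function(path, offset, bytes) {
  raw_all <- readBin(path, raw(), n = file.size(path))
  raw_all[offset + seq_along(bytes)] <- bytes
  writeBin(raw_all, path)
  invisible(path)
}
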
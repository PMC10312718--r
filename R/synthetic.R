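# Synthetic fixtures: toy backbones, simulated density, ground-truth masks
# and corrupted "prediction" volumes with the statistical structure the
# pipeline assumes, so every stage can be exercised without downloads or
# trained networks.

#' Synthetic fixture configuration
#'
#' The defaults encode the geometry the threading model assumes:
#' consecutive Calpha-Calpha distances drawn from Normal(3.8047, 0.036)
#' Angstrom, a self-avoidance radius keeping non-consecutive residues at
#' least 3 Angstrom apart (so distinct residues always occupy distinct
#' 1 Angstrom voxels), Gaussian density blobs of 1 Angstrom width and a
#' small additive noise floor.
#'
#' @param n_residues residues per chain (default 30).
#' @param n_chains number of chains (default 1).
#' @param bond_mu mean consecutive Calpha-Calpha distance, Angstrom.
#' @param bond_sigma its standard deviation, Angstrom.
#' @param min_separation minimum distance between non-consecutive Calpha
#'   atoms, Angstrom (default 3).
#' @param blob_sigma width of the Gaussian density kernel per atom,
#'   Angstrom (default 1).
#' @param noise_sigma standard deviation of additive Gaussian map noise, in
#'   raw density units (default 0.02).
#' @param label_error_rate probability that a labeled voxel's predicted
#'   class is flipped to a random wrong class (default 0).
#' @param seed integer seed driving every stochastic draw; per-component
#'   sub-seeds are derived from it deterministically.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_residues = 30L, n_chains = 1L,
                             bond_mu = 3.8047, bond_sigma = 0.036,
                             min_separation = 3.0, blob_sigma = 1.0,
                             noise_sigma = 0.02, label_error_rate = 0,
                             seed = 7L) {
  if (n_residues < 2L || n_chains < 1L || bond_mu <= 0 || bond_sigma <= 0 ||
      min_separation <= 0 || blob_sigma <= 0 || noise_sigma < 0)
    vx_stop("synthetic_config parameters must be positive",
            "voxtrace_value_error")
  if (label_error_rate < 0 || label_error_rate >= 1)
    vx_stop("label_error_rate must be in [0, 1)", "voxtrace_value_error")
  structure(list(n_residues = as.integer(n_residues),
                 n_chains = as.integer(n_chains), bond_mu = bond_mu,
                 bond_sigma = bond_sigma, min_separation = min_separation,
                 blob_sigma = blob_sigma, noise_sigma = noise_sigma,
                 label_error_rate = label_error_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_unit_vector <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

#' Generate a random protein backbone
#'
#' A seeded self-avoiding random walk: consecutive Calpha distances are
#' drawn from Normal(bond_mu, bond_sigma) with uniformly random directions,
#' rejecting any step that brings a Calpha within `min_separation` of a
#' non-consecutive one (own chain or another chain). Backbone N and C atoms
#' are placed on the segment between consecutive Calpha atoms at fixed
#' fractions (0.35 from each end); residues get seeded uniform-random
#' amino-acid types. Identical seeds give identical structures.
#'
#' @param config a [synthetic_config()].
#' @return An [atomic_structure()] with chains `A`, `B`, ... and residues
#'   tagged coil.
#' @export
generate_backbone <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1L))
  all_ca <- list()
  rows <- list()
  for (ch in seq_len(config$n_chains)) {
    chain_id <- LETTERS[ch]
    ca <- matrix(NA_real_, nrow = config$n_residues, ncol = 3L)
    others <- if (length(all_ca) > 0L) do.call(rbind, all_ca) else
      matrix(numeric(0L), ncol = 3L)
    placed <- FALSE
    for (try_start in seq_len(200L)) {
      start <- if (ch == 1L) c(0, 0, 0) else
        others[sample(nrow(others), 1L), ] +
          random_unit_vector() * (config$min_separation + 5 +
                                    stats::runif(1L, 0, 10))
      if (nrow(others) == 0L ||
          min(sqrt(rowSums(sweep(others, 2L, start)^2))) >=
            config$min_separation) {
        ca[1L, ] <- start; placed <- TRUE; break
      }
    }
    if (!placed)
      vx_stop("could not place a chain start; increase the box or spacing",
              "voxtrace_generation_error")
    for (r in 2L:config$n_residues) {
      done <- FALSE
      for (attempt in seq_len(200L)) {
        step <- stats::rnorm(1L, config$bond_mu, config$bond_sigma) *
          random_unit_vector()
        cand <- ca[r - 1L, ] + as.numeric(step)
        prior <- rbind(others, ca[seq_len(r - 2L), , drop = FALSE])
        if (nrow(prior) == 0L ||
            min(sqrt(rowSums(sweep(prior, 2L, cand)^2))) >=
              config$min_separation) {
          ca[r, ] <- cand; done <- TRUE; break
        }
      }
      if (!done)
        vx_stop(sprintf(
          "self-avoiding walk stuck at residue %d; retry with another seed",
          r), "voxtrace_generation_error")
    }
    all_ca[[ch]] <- ca
    resid <- AA3[sample.int(20L, config$n_residues, replace = TRUE)]
    # N and C on the inter-Calpha segments at fixed fractions
    atoms <- list()
    for (r in seq_len(config$n_residues)) {
      atoms[[length(atoms) + 1L]] <- c("CA", ca[r, ])
      if (r > 1L) {
        npos <- ca[r, ] + 0.35 * (ca[r - 1L, ] - ca[r, ])
        atoms[[length(atoms) + 1L]] <- c("N", npos)
      }
      if (r < config$n_residues) {
        cpos <- ca[r, ] + 0.35 * (ca[r + 1L, ] - ca[r, ])
        atoms[[length(atoms) + 1L]] <- c("C", cpos)
      }
    }
    at <- do.call(rbind, atoms)
    # per-atom residue numbers and names, in the same append order as above
    resnos <- integer(0L); eletys <- character(0L)
    for (r in seq_len(config$n_residues)) {
      resnos <- c(resnos, r)
      eletys <- c(eletys, "CA")
      if (r > 1L) { resnos <- c(resnos, r); eletys <- c(eletys, "N") }
      if (r < config$n_residues) { resnos <- c(resnos, r); eletys <- c(eletys, "C") }
    }
    rows[[chain_id]] <- data.frame(
      chain = chain_id, resno = resnos, resid = resid[resnos],
      elety = eletys, x = as.numeric(at[, 2L]), y = as.numeric(at[, 3L]),
      z = as.numeric(at[, 4L]), ss = "coil", stringsAsFactors = FALSE)
  }
  atomic_structure(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Simulate a density map from a structure
#'
#' Sums an isotropic Gaussian blob of width `blob_sigma` at every atom on a
#' 1 Angstrom grid whose origin sits at the structure's bounding box minus a
#' 6 Angstrom margin, adds seeded Gaussian noise of scale `noise_sigma`,
#' and normalizes the result with [normalize_map()]. With zero noise the
#' voxel values equal the analytic kernel sum exactly, which is used as a
#' test oracle.
#'
#' @param s an [atomic_structure()].
#' @param config a [synthetic_config()].
#' @return A normalized [density_map()]; the pre-normalization raw map is
#'   attached as attribute `"raw_map"`.
#' @export
simulate_density <- function(s, config) {
  stopifnot(inherits(s, "atomic_structure"),
            inherits(config, "synthetic_config"))
  margin <- 6
  lo <- floor(c(min(s$x), min(s$y), min(s$z)) - margin)
  hi <- ceiling(c(max(s$x), max(s$y), max(s$z)) + margin)
  dims <- as.integer(hi - lo + 1)
  vals <- array(0, dim = dims)
  reach <- ceiling(4 * config$blob_sigma)
  ax <- lapply(1:3, function(a) lo[a] + seq_len(dims[a]) - 1)
  for (n in seq_len(nrow(s))) {
    p <- c(s$x[n], s$y[n], s$z[n])
    rng <- lapply(1:3, function(a) {
      which(ax[[a]] >= p[a] - reach & ax[[a]] <= p[a] + reach)
    })
    gx <- exp(-(ax[[1]][rng[[1]]] - p[1])^2 / (2 * config$blob_sigma^2))
    gy <- exp(-(ax[[2]][rng[[2]]] - p[2])^2 / (2 * config$blob_sigma^2))
    gz <- exp(-(ax[[3]][rng[[3]]] - p[3])^2 / (2 * config$blob_sigma^2))
    vals[rng[[1]], rng[[2]], rng[[3]]] <-
      vals[rng[[1]], rng[[2]], rng[[3]]] + outer(outer(gx, gy), gz)
  }
  if (config$noise_sigma > 0) {
    set.seed(derive_seed(config$seed, 2L))
    vals <- vals + stats::rnorm(length(vals), 0, config$noise_sigma)
  }
  raw <- density_map(vals, origin = lo, voxel = c(1, 1, 1))
  out <- normalize_map(raw)
  attr(out, "raw_map") <- raw
  out
}

# deterministic background probability row for unlabeled voxels
background_row <- function(k) c(0.99, rep(0.01 / (k - 1L), k - 1L))

corrupt_mask <- function(mask_values, n_classes, eps) {
  d <- dim(mask_values)
  probs <- array(0, dim = c(d, n_classes))
  flat <- as.integer(mask_values)          # true class codes, 0-based
  n_vox <- length(flat)
  winner <- flat
  labeled <- which(flat > 0L)
  if (eps > 0 && length(labeled) > 0L) {
    flip <- labeled[stats::runif(length(labeled)) < eps]
    if (length(flip) > 0L) {
      wrong <- vapply(flat[flip], function(true) {
        sample(setdiff(0:(n_classes - 1L), true), 1L)
      }, integer(1L))
      winner[flip] <- wrong
    }
  }
  bg <- background_row(n_classes)
  for (cl in 0:(n_classes - 1L)) {
    ch <- numeric(n_vox)
    sel_bg <- flat == 0L
    ch[sel_bg] <- bg[cl + 1L]
    sel_lab <- !sel_bg
    ch[sel_lab & winner == cl] <- if (eps > 0) 1 - eps else 1
    ch[sel_lab & winner != cl] <- if (eps > 0) eps / (n_classes - 1L) else 0
    probs[, , , cl + 1L] <- array(ch, dim = d)
  }
  probs
}

#' Corrupt ground-truth masks into simulated prediction volumes
#'
#' Emulates a voxel classifier of controllable quality: each labeled
#' voxel's winning class is its true class with probability `1 - eps` and a
#' uniformly random wrong class otherwise; the winner receives probability
#' `1 - eps` with `eps` spread evenly over the remaining classes (one-hot
#' when `eps = 0`). Unlabeled voxels deterministically favor the background
#' class with probability 0.99. Rows always sum to 1; identical seeds give
#' identical volumes.
#'
#' @param masks list with [label_volume()]s `atom` and `amino` (as produced
#'   by [make_atom_labels()] and [make_amino_labels()]).
#' @param eps flip probability in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `atom` and `amino` [prediction_volume()]s (classes
#'   `none, CA, N, C` and `UNK` plus the 20 one-letter codes).
#' @export
corrupt_to_predictions <- function(masks, eps = 0, seed = 7L) {
  stopifnot(inherits(masks$atom, "label_volume"),
            inherits(masks$amino, "label_volume"))
  if (eps < 0 || eps >= 1)
    vx_stop("eps must be in [0, 1)", "voxtrace_value_error")
  set.seed(derive_seed(seed, 3L))
  atom_probs <- corrupt_mask(masks$atom$values, 4L, eps)
  amino_probs <- corrupt_mask(masks$amino$values, 21L, eps)
  list(atom = prediction_volume(atom_probs, c("none", "CA", "N", "C"),
                                masks$atom$origin, masks$atom$voxel),
       amino = prediction_volume(amino_probs, c("UNK", AA1),
                                 masks$amino$origin, masks$amino$voxel))
}

#' Generate a complete synthetic fixture
#'
#' Chains together the full data-preparation pipeline on a synthetic
#' structure: backbone generation, density simulation and normalization,
#' the four label masks, sequence extraction, and corrupted prediction
#' volumes. When `dir` is given, all files are written in the standard
#' per-map directory layout (`emd_normalized_map.mrc`, the four mask files,
#' `model.pdb`, `sequence.fasta` and per-channel prediction maps
#' `pred_atom_<class>.mrc` / `pred_amino_<class>.mrc`), every MRC file
#' passing [validate_mrc()].
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; created if missing.
#' @return list of class `synthetic_fixture` with `structure`, `map`,
#'   `masks` (atom, calpha, amino, ss), `predictions` (atom, amino),
#'   `sequences` and `config`.
#' @export
make_fixture <- function(config = synthetic_config(), dir = NULL) {
  s <- generate_backbone(config)
  map <- simulate_density(s, config)
  atom <- make_atom_labels(s, map)
  amino <- make_amino_labels(s, map)
  ss <- make_ss_labels(s, map)
  masks <- list(atom = atom$atom, calpha = atom$calpha, amino = amino$amino,
                ss = ss$ss)
  preds <- corrupt_to_predictions(masks, config$label_error_rate,
                                  config$seed)
  sequences <- extract_sequence(s)
  fx <- structure(list(structure = s, map = map, masks = masks,
                       predictions = preds, sequences = sequences,
                       config = config),
                  class = "synthetic_fixture")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mrc(map, file.path(dir, "emd_normalized_map.mrc"))
    write_mrc(masks$atom, file.path(dir, "atom_emd_normalized_map.mrc"))
    write_mrc(masks$calpha,
              file.path(dir, "atom_ca_emd_normalized_map.mrc"))
    write_mrc(masks$amino, file.path(dir, "amino_emd_normalized_map.mrc"))
    write_mrc(masks$ss, file.path(dir, "sec_struc_emd_normalized_map.mrc"))
    write_structure_pdb(s, file.path(dir, "model.pdb"))
    write_fasta(sequences, file.path(dir, "sequence.fasta"))
    for (cl in preds$atom$classes)
      write_mrc(density_map(pred_channel(preds$atom, cl), map$origin,
                            map$voxel),
                file.path(dir, sprintf("pred_atom_%s.mrc", cl)))
    for (cl in preds$amino$classes)
      write_mrc(density_map(pred_channel(preds$amino, cl), map$origin,
                            map$voxel),
                file.path(dir, sprintf("pred_amino_%s.mrc", cl)))
  }
  fx
}

#' Write a full atomic structure as a PDB file
#'
#' ATOM records for every atom in the table, grouped by chain with TER
#' separators; readable back with [read_structure()].
#'
#' @param s an [atomic_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "atomic_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  element_of <- function(elety) substr(gsub("[0-9]", "", elety), 1L, 1L)
  serial <- 0L
  for (ch in unique(s$chain)) {
    rows <- s[s$chain == ch, , drop = FALSE]
    rows <- rows[order(rows$resno), , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      serial <- serial + 1L
      name4 <- if (nchar(rows$elety[r]) < 4L)
        sprintf(" %-3s", rows$elety[r]) else substr(rows$elety[r], 1L, 4L)
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, name4, rows$resid[r], substr(ch, 1L, 1L), rows$resno[r],
        rows$x[r], rows$y[r], rows$z[r], element_of(rows$elety[r])), con)
    }
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %-3s %1s%4d", serial,
                       rows$resid[nrow(rows)], substr(ch, 1L, 1L),
                       rows$resno[nrow(rows)]), con)
  }
  writeLines("END", con)
  invisible(path)
}
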
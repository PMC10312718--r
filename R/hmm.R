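# Hidden Markov model over predicted Calpha voxels and the constrained
# Viterbi search that threads a protein sequence through them.
#
# Hidden states are candidate Calpha voxels. Emissions over the 20 amino
# acids are the normalized geometric mean of the voxel classifier's
# amino-type probabilities and background frequencies. Transitions follow a
# Gaussian density on the Euclidean distance between two states, peaked at
# the consecutive Calpha-Calpha distance of an extended protein backbone.
# The search is a beam-pruned Viterbi in which every state may be used at
# most once across all chains; with an unbounded beam it is exhaustive and
# exact.

#' HMM threading parameters
#'
#' @param mu mean consecutive Calpha-Calpha distance in Angstrom
#'   (default 3.8047).
#' @param sigma its standard deviation in Angstrom (default 0.036).
#' @param lambda_scale dimensionless scale applied to `sigma` inside the
#'   transition density (default 10), so the effective spread is
#'   `sigma * lambda_scale`.
#' @param background length-20 amino-acid background frequency vector,
#'   summing to 1 (default uniform 1/20); order as in [amino_codes()].
#' @param neighbor_cutoff distance in Angstrom beyond which transition
#'   weight is exactly 0; default `mu + 10 * sigma * lambda_scale`
#'   (7.4047 A), which prunes the transition graph while retaining more
#'   than ten effective standard deviations of mass.
#' @param beam_width number of partial paths kept per Viterbi step
#'   (default 50); `Inf` disables pruning, making the search exhaustive and
#'   exact.
#' @param detection_threshold minimum Calpha-channel probability for a voxel
#'   to become a hidden state (default 0.5).
#' @param normalize_transitions if `TRUE`, each state's outgoing transition
#'   weights are renormalized to sum to 1 over its in-cutoff neighbors;
#'   default `FALSE` (unnormalized Gaussian densities), since the model
#'   specifies the Gaussian form and not a row normalization.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(mu = 3.8047, sigma = 0.036, lambda_scale = 10,
                       background = rep(1 / 20, 20),
                       neighbor_cutoff = mu + 10 * sigma * lambda_scale,
                       beam_width = 50, detection_threshold = 0.5,
                       normalize_transitions = FALSE) {
  if (mu <= 0 || sigma <= 0 || lambda_scale <= 0)
    vx_stop("mu, sigma and lambda_scale must be positive",
            "voxtrace_value_error")
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-6 ||
      any(background < 0))
    vx_stop("background must be 20 non-negative frequencies summing to 1",
            "voxtrace_value_error")
  if (neighbor_cutoff <= 0 || beam_width < 1)
    vx_stop("neighbor_cutoff and beam_width must be positive",
            "voxtrace_value_error")
  structure(list(mu = mu, sigma = sigma, lambda_scale = lambda_scale,
                 background = background / sum(background),
                 neighbor_cutoff = neighbor_cutoff, beam_width = beam_width,
                 detection_threshold = detection_threshold,
                 normalize_transitions = isTRUE(normalize_transitions)),
            class = "hmm_params")
}

#' Select candidate Calpha states from an atom-type prediction volume
#'
#' Every voxel whose Calpha-channel probability is at least `threshold`
#' becomes a hidden state; its representative coordinate is the voxel
#' center, obtained with [index_to_coord()].
#'
#' @param atom_pred a [prediction_volume()] with a `"CA"` class.
#' @param threshold detection threshold on the Calpha probability.
#' @return data.frame of class `ca_candidates` with columns `state`
#'   (1-based id), `i`, `j`, `k` (0-based grid index), `x`, `y`, `z`
#'   (Angstrom) and `calpha_prob`. Raises a `voxtrace_empty_model` error if
#'   no voxel qualifies.
#' @export
select_calpha_candidates <- function(atom_pred, threshold = 0.5) {
  probs <- pred_channel(atom_pred, "CA")
  sel <- which(probs >= threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    vx_stop(sprintf(
      "no voxel reaches the Calpha detection threshold %.3g", threshold),
      "voxtrace_empty_model")
  idx <- data.frame(i = sel[, 3L] - 1L, j = sel[, 2L] - 1L,
                    k = sel[, 1L] - 1L)
  geo <- list(values = probs, origin = atom_pred$origin,
              voxel = atom_pred$voxel)
  cc <- index_to_coord(idx, geo)
  out <- data.frame(state = seq_len(nrow(idx)), idx, cc,
                    calpha_prob = probs[sel])
  out <- out[order(out$i, out$j, out$k), , drop = FALSE]
  out$state <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ca_candidates", "data.frame")
  out
}

#' Attach amino-acid emission vectors to candidate states
#'
#' For each state and amino type `t` the raw emission is
#' `sqrt(a_t * b_t)` - the geometric mean of the predicted probability
#' `a_t` of that amino type at the state's voxel and its background
#' frequency `b_t` - and the emission vector is the raw vector normalized
#' to sum to 1. A state whose raw vector is all zero falls back to the
#' uniform emission with a warning.
#'
#' @param states a `ca_candidates` table from [select_calpha_candidates()].
#' @param amino_pred a [prediction_volume()] carrying the 20 amino-type
#'   channels (one-letter class names) on the same grid.
#' @param background length-20 background frequency vector summing to 1.
#' @return `states` with an `emission` attribute: an `n_states x 20` matrix
#'   whose rows sum to 1, columns ordered as [amino_codes()].
#' @export
build_emissions <- function(states, amino_pred,
                            background = rep(1 / 20, 20)) {
  stopifnot(inherits(states, "ca_candidates"))
  if (abs(sum(background) - 1) > 1e-6)
    vx_stop("background must sum to 1", "voxtrace_value_error")
  miss <- setdiff(AA1, amino_pred$classes)
  if (length(miss) > 0L)
    vx_stop(paste("amino prediction volume lacks classes:",
                  paste(miss, collapse = " ")), "voxtrace_value_error")
  d <- dim(amino_pred$probs)
  lin <- cbind(states$k + 1L, states$j + 1L, states$i + 1L)
  a <- vapply(AA1, function(cl) {
    ch <- match(cl, amino_pred$classes)
    amino_pred$probs[cbind(lin, ch)]
  }, numeric(nrow(states)))
  a <- matrix(a, nrow = nrow(states))    # guard against vapply dropping dims
  raw <- sqrt(sweep(a, 2L, background, "*"))
  tot <- rowSums(raw)
  zero <- tot == 0
  if (any(zero)) {
    vx_warn(sprintf(
      "%d state(s) have an all-zero emission vector; using uniform",
      sum(zero)), "voxtrace_zero_emission")
    raw[zero, ] <- 1 / 20
    tot[zero] <- 1
  }
  emission <- raw / tot
  colnames(emission) <- AA1
  attr(states, "emission") <- emission
  states
}

#' Transition weight between two candidate states
#'
#' The unnormalized transition weight is the normal density, with mean `mu`
#' and standard deviation `sigma * lambda_scale`, evaluated at the Euclidean
#' distance between the two states' coordinates; it is 0 beyond
#' `neighbor_cutoff` and 0 for a state to itself (self-transitions are
#' forbidden by the use-at-most-once constraint).
#'
#' @param s1,s2 single rows of a `ca_candidates` table (or any list with
#'   `x`, `y`, `z`).
#' @param params an [hmm_params()].
#' @return non-negative weight (density per Angstrom).
#' @examples
#' p <- hmm_params()
#' s <- list(x = 0, y = 0, z = 0)
#' transition_prob(s, list(x = p$mu, y = 0, z = 0), p)  # peak ~ 1.108
#' @export
transition_prob <- function(s1, s2, params = hmm_params()) {
  d <- sqrt((s1$x - s2$x)^2 + (s1$y - s2$y)^2 + (s1$z - s2$z)^2)
  w <- stats::dnorm(d, mean = params$mu,
                    sd = params$sigma * params$lambda_scale)
  w[d > params$neighbor_cutoff | d == 0] <- 0
  w
}

# n x n matrix of log transition weights; -Inf beyond cutoff and on the
# diagonal
transition_log_matrix <- function(states, params) {
  xyz <- as.matrix(states[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d <- sqrt(pmax(d2, 0))
  lw <- stats::dnorm(d, mean = params$mu,
                     sd = params$sigma * params$lambda_scale, log = TRUE)
  lw[d > params$neighbor_cutoff] <- -Inf
  diag(lw) <- -Inf
  if (isTRUE(params$normalize_transitions)) {
    row_tot <- apply(lw, 1L, function(r) {
      f <- r[is.finite(r)]
      if (length(f) == 0L) return(-Inf)
      m <- max(f)
      m + log(sum(exp(f - m)))
    })
    lw <- sweep(lw, 1L, row_tot)
    lw[!is.finite(lw)] <- -Inf
  }
  lw
}

#' Initial-state distribution for a chain
#'
#' The probability of a state being the initial state equals its emission
#' probability of the chain's first amino acid divided by the sum of that
#' emission over all states. If every state emits the first residue with
#' probability zero the distribution falls back to uniform with a warning.
#'
#' @param states a `ca_candidates` table with emissions attached by
#'   [build_emissions()].
#' @param first_residue one-letter amino-acid code of the chain's first
#'   residue.
#' @return numeric vector over states summing to 1.
#' @export
initial_probs <- function(states, first_residue) {
  emission <- attr(states, "emission")
  if (is.null(emission))
    vx_stop("states have no emissions; call build_emissions() first",
            "voxtrace_value_error")
  ai <- match(first_residue, AA1)
  if (is.na(ai))
    vx_stop(sprintf("unknown amino-acid code '%s'", first_residue),
            "voxtrace_value_error")
  e <- emission[, ai]
  if (sum(e) == 0) {
    vx_warn("no state emits the first residue; uniform initial distribution",
            "voxtrace_zero_emission")
    return(rep(1 / length(e), length(e)))
  }
  e / sum(e)
}

# beam search for one chain over the available states; exhaustive (exact)
# when beam_width = Inf. Hypotheses carry their own used-state path, so the
# at-most-once constraint holds within the chain; `available` restricts to
# states not consumed by earlier chains.
thread_one_chain <- function(aa_idx, emission_log, trans_log, init_log,
                             available, beam_width) {
  L <- length(aa_idx)
  hyp_path <- lapply(available, function(s) s)
  hyp_score <- init_log[available] + emission_log[available, aa_idx[1L]]
  keep <- is.finite(hyp_score)
  hyp_path <- hyp_path[keep]; hyp_score <- hyp_score[keep]
  best_prefix <- list(path = integer(0L), score = -Inf, length = 0L)
  prune <- function(paths, scores) {
    if (length(scores) == 0L) return(list(paths = paths, scores = scores))
    last <- vapply(paths, function(p) p[length(p)], integer(1L))
    o <- order(-scores, last)
    if (is.finite(beam_width) && length(o) > beam_width)
      o <- o[seq_len(beam_width)]
    list(paths = paths[o], scores = scores[o])
  }
  pr <- prune(hyp_path, hyp_score)
  hyp_path <- pr$paths; hyp_score <- pr$scores
  if (length(hyp_score) > 0L)
    best_prefix <- list(path = hyp_path[[1L]], score = hyp_score[[1L]],
                        length = 1L)
  t <- 1L
  while (t < L && length(hyp_score) > 0L) {
    t <- t + 1L
    new_path <- vector("list", 0L); new_score <- numeric(0L)
    for (hn in seq_along(hyp_path)) {
      p <- hyp_path[[hn]]
      last <- p[length(p)]
      cand <- available[is.finite(trans_log[last, available])]
      cand <- setdiff(cand, p)
      if (length(cand) == 0L) next
      sc <- hyp_score[hn] + trans_log[last, cand] +
        emission_log[cand, aa_idx[t]]
      ok <- is.finite(sc)
      if (!any(ok)) next
      cand <- cand[ok]; sc <- sc[ok]
      new_path <- c(new_path, lapply(cand, function(s) c(p, s)))
      new_score <- c(new_score, sc)
    }
    pr <- prune(new_path, new_score)
    hyp_path <- pr$paths; hyp_score <- pr$scores
    if (length(hyp_score) > 0L)
      best_prefix <- list(path = hyp_path[[1L]], score = hyp_score[[1L]],
                          length = t)
  }
  best_prefix
}

#' Thread protein sequences through candidate Calpha states
#'
#' Aligns each chain's amino-acid sequence to the candidate states by a
#' Viterbi search maximizing `log initial(s1) + log emission(s1, aa1) +
#' sum_t [log transition(s_(t-1), s_t) + log emission(s_t, aa_t)]`, with
#' every state used at most once within and across chains (states consumed
#' by earlier chains are removed before the next chain is threaded; chains
#' are threaded longest first). The search keeps `beam_width` partial paths
#' per step; with `beam_width = Inf` it enumerates every feasible injective
#' path and is exact. Transition weights are unnormalized Gaussian-distance
#' densities; all arithmetic is in log space and ties are broken by the
#' lowest state index.
#'
#' When a chain cannot be threaded to its full length (fewer reachable
#' states than residues, or a dead end), the longest achievable prefix is
#' returned for that chain together with a `voxtrace_partial_thread` warning
#' if `partial = TRUE` (the default), or a `voxtrace_partial_thread` error
#' if `partial = FALSE`.
#'
#' @param states a `ca_candidates` table with emissions attached.
#' @param sequences named character vector of one-letter sequences, one per
#'   chain.
#' @param params an [hmm_params()].
#' @param partial return partial threads with a warning instead of erroring.
#' @return A `backbone_model`: data.frame with columns `chain`, `resno`,
#'   `resid` (3-letter), `x`, `y`, `z` and `state`; per-chain log-scores in
#'   attribute `"scores"` and requested lengths in attribute `"lengths"`.
#' @export
viterbi_thread <- function(states, sequences, params = hmm_params(),
                           partial = TRUE) {
  stopifnot(inherits(states, "ca_candidates"))
  emission <- attr(states, "emission")
  if (is.null(emission))
    vx_stop("states have no emissions; call build_emissions() first",
            "voxtrace_value_error")
  if (length(sequences) == 0L || any(!nzchar(sequences)))
    vx_stop("sequences must be non-empty", "voxtrace_value_error")
  if (is.null(names(sequences)))
    names(sequences) <- LETTERS[seq_along(sequences)]
  n_states <- nrow(states)
  total_res <- sum(nchar(sequences))
  short <- n_states < total_res
  if (short && !partial)
    vx_stop(sprintf(
      "only %d candidate states for %d residues; cannot thread fully",
      n_states, total_res), "voxtrace_partial_thread")

  emission_log <- log(emission)
  trans_log <- transition_log_matrix(states, params)
  order_chains <- order(-nchar(sequences))
  available <- seq_len(n_states)
  rows <- list(); scores <- numeric(0L); partial_chains <- character(0L)

  for (cn in order_chains) {
    chain_id <- names(sequences)[cn]
    seq1 <- strsplit(sequences[[cn]], "")[[1L]]
    aa_idx <- match(seq1, AA1)
    if (any(is.na(aa_idx)))
      vx_stop(sprintf("chain %s has a non-standard residue letter", chain_id),
              "voxtrace_value_error")
    if (length(available) == 0L) {
      partial_chains <- c(partial_chains, chain_id)
      scores[chain_id] <- -Inf
      next
    }
    p0 <- initial_probs(states[available, , drop = FALSE],
                        seq1[1L])
    init_log <- rep(-Inf, n_states)
    init_log[available] <- log(p0)
    res <- thread_one_chain(aa_idx, emission_log, trans_log, init_log,
                            available, params$beam_width)
    if (res$length < length(aa_idx)) {
      partial_chains <- c(partial_chains, chain_id)
      if (!partial)
        vx_stop(sprintf(
          "chain %s: longest achievable prefix is %d of %d residues",
          chain_id, res$length, length(aa_idx)), "voxtrace_partial_thread")
    }
    if (res$length > 0L) {
      path <- res$path
      rows[[chain_id]] <- data.frame(
        chain = chain_id, resno = seq_len(res$length),
        resid = AA3[aa_idx[seq_len(res$length)]],
        x = states$x[path], y = states$y[path], z = states$z[path],
        state = path, stringsAsFactors = FALSE)
      available <- setdiff(available, path)
    }
    scores[chain_id] <- res$score
  }
  if (length(partial_chains) > 0L)
    vx_warn(sprintf("partial thread for chain(s): %s",
                    paste(partial_chains, collapse = ", ")),
            "voxtrace_partial_thread")
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = character(0L), resno = integer(0L),
                      resid = character(0L), x = numeric(0L),
                      y = numeric(0L), z = numeric(0L), state = integer(0L))
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  attr(out, "lengths") <- stats::setNames(nchar(sequences), names(sequences))
  class(out) <- c("backbone_model", "data.frame")
  out
}

#' Write a backbone model as a PDB file
#'
#' One ATOM record per residue (Calpha only), grouped by chain with TER
#' separators, parseable by standard PDB readers.
#'
#' @param model a `backbone_model` from [viterbi_thread()], or any
#'   data.frame with columns `chain`, `resno`, `resid`, `x`, `y`, `z`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(model, path) {
  if (nrow(model) == 0L)
    vx_stop("backbone model is empty", "voxtrace_value_error")
  if (nrow(model) > 99999L)
    vx_stop("more than 99999 atoms cannot be numbered in PDB format",
            "voxtrace_value_error")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(model$chain)) {
    rows <- model[model$chain == ch, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, rows$resid[r], substr(ch, 1L, 1L), rows$resno[r],
        rows$x[r], rows$y[r], rows$z[r]), con)
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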
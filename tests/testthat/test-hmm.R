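one_hot <- function(letters20) {
  em <- matrix(1e-12, length(letters20), 20)
  em[cbind(seq_along(letters20), match(letters20, AA1_TAB))] <- 1
  em / rowSums(em)
}

test_that("candidate selection thresholds the Calpha channel", {
  probs <- array(0, c(3, 3, 3, 4))
  probs[, , , 1] <- 1
  put <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 1))
  for (r in 1:3) {
    probs[put[r, 1], put[r, 2], put[r, 3], 2] <- 0.9
    probs[put[r, 1], put[r, 2], put[r, 3], 1] <- 0.1
  }
  pv <- prediction_volume(probs, c("none", "CA", "N", "C"),
                          origin = c(1, 2, 3))
  cand <- select_calpha_candidates(pv, 0.5)
  expect_equal(nrow(cand), 3L)
  # coordinates are voxel centers via the index-to-coordinate map
  expect_true(all(c(1, 2, 3) %in% round(cand$x - 0)))
  expect_equal(sort(cand$x), sort(put[, 1] - 1 + 1))  # origin_x = 1
  # threshold 0 selects every voxel; counts are monotone in the threshold
  expect_equal(nrow(select_calpha_candidates(pv, 0)), 27L)
  counts <- vapply(c(0, 0.05, 0.5, 0.89),
                   function(t) nrow(select_calpha_candidates(pv, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(select_calpha_candidates(pv, 0.99),
               class = "voxtrace_empty_model")
})

test_that("emissions are normalized geometric means of prediction and
           background", {
  probs <- array(0, c(2, 1, 1, 21))
  probs[1, 1, 1, ] <- c(0, rep(0.05, 20))            # uniform voxel
  probs[2, 1, 1, ] <- c(0, 0.8, 0.2, rep(0, 18))     # A = 0.8, R = 0.2
  pv <- prediction_volume(probs, c("UNK", AA1_TAB))
  cand <- data.frame(state = 1:2, i = 0L, j = 0L, k = 0:1,
                     x = c(0, 1), y = 0, z = 0, calpha_prob = 1)
  class(cand) <- c("ca_candidates", "data.frame")

  # uniform prediction x uniform background stays uniform
  cand_u <- build_emissions(cand, pv, rep(1 / 20, 20))
  em <- attr(cand_u, "emission")
  expect_equal(unname(em[1, ]), rep(0.05, 20), tolerance = 1e-12)

  # one-hot prediction annihilates every other type
  onehot <- em[2, ]
  b2 <- c(0.5, 0.5, rep(0, 18))
  cand_b <- build_emissions(cand, pv, b2)
  em_b <- attr(cand_b, "emission")
  # raw = (sqrt(0.4), sqrt(0.1)) -> normalized (2/3, 1/3)
  expect_equal(unname(em_b[2, 1:2]), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_equal(sum(em_b[2, ]), 1, tolerance = 1e-12)
  # first voxel under this background: raw = (sqrt(.025), sqrt(.025), 0...)
  expect_equal(unname(em_b[1, 1:2]), c(0.5, 0.5), tolerance = 1e-9)

  # a = (1, 0, ...) with uniform background gives a one-hot emission
  probs[1, 1, 1, ] <- c(0, 1, rep(0, 19))
  pv1 <- prediction_volume(probs, c("UNK", AA1_TAB))
  em1 <- attr(build_emissions(cand, pv1, rep(1 / 20, 20)), "emission")
  expect_equal(unname(em1[1, ]), c(1, rep(0, 19)))
})

test_that("transition weights follow the Gaussian-distance law", {
  p <- hmm_params()
  at <- function(x) transition_prob(list(x = 0, y = 0, z = 0),
                                    list(x = x, y = 0, z = 0), p)
  # peak at the mean: direct evaluation of the normal density with
  # sd = sigma * lambda = 0.36
  expect_equal(at(p$mu), 1 / (0.36 * sqrt(2 * pi)), tolerance = 1e-9)
  expect_equal(at(p$mu + 0.5), at(p$mu - 0.5), tolerance = 1e-12)
  expect_equal(at(50), 0)                       # beyond the cutoff
  expect_equal(at(0), 0)                        # self-transition forbidden
  expect_gt(at(p$mu + 1), 0)                    # within the default cutoff
})

test_that("initial-state distribution renormalizes first-residue emissions", {
  em <- matrix(1 / 20, 3, 20)
  em[, 1] <- c(0.5, 0.25, 0.25)
  em <- em / rowSums(em)
  cand <- make_candidates(matrix(rnorm(9), 3, 3), em)
  p <- initial_probs(cand, "A")
  expect_equal(p, em[, 1] / sum(em[, 1]), tolerance = 1e-12)

  # rows sum to 1 with the first-residue column exactly 0.2 / 0.3
  em2 <- matrix((1 - c(0.2, 0.3)) / 19, 2, 20)
  em2[, match("G", AA1_TAB)] <- c(0.2, 0.3)
  cand2 <- make_candidates(matrix(rnorm(6), 2, 3), em2)
  p2 <- initial_probs(cand2, "G")
  expect_equal(p2, c(0.4, 0.6), tolerance = 1e-9)

  # identical states give the uniform distribution
  cand3 <- make_candidates(matrix(rnorm(6), 2, 3), matrix(1 / 20, 2, 20))
  expect_equal(initial_probs(cand3, "W"), c(0.5, 0.5))
})

test_that("optional transition row normalization yields stochastic rows", {
  set.seed(52)
  coords <- matrix(0, 5, 3)
  for (i in 2:5) {
    u <- rnorm(3)
    coords[i, ] <- coords[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
  }
  cand <- make_candidates(coords, matrix(1 / 20, 5, 20))
  lw <- voxtrace:::transition_log_matrix(
    cand, hmm_params(normalize_transitions = TRUE))
  row_sums <- apply(lw, 1, function(r) sum(exp(r[is.finite(r)])))
  expect_equal(row_sums, rep(1, 5), tolerance = 1e-9)
  # normalization does not change the best path on a simple instance
  cand1 <- make_candidates(coords[1:3, ], one_hot(c("A", "G", "V")))
  bb_u <- viterbi_thread(cand1, c(A = "AGV"), hmm_params(beam_width = Inf))
  bb_n <- viterbi_thread(cand1, c(A = "AGV"),
                         hmm_params(beam_width = Inf,
                                    normalize_transitions = TRUE))
  expect_equal(bb_n$state, bb_u$state)
})

test_that("single-state threading returns that state and its emission score", {
  em <- matrix(1 / 20, 1, 20)
  cand <- make_candidates(matrix(c(1, 2, 3), 1, 3), em)
  bb <- viterbi_thread(cand, c(A = "V"))
  expect_equal(nrow(bb), 1L)
  expect_equal(bb$state, 1L)
  # initial prob is 1 for a lone state, so score = log emission
  expect_equal(unname(attr(bb, "scores")["A"]), log(1 / 20),
               tolerance = 1e-9)
})

test_that("threading recovers spatial order for near-one-hot emissions", {
  coords <- cbind(c(0, 3.8, 7.6), 0, 0)   # collinear, 3.8 A spacing
  cand <- make_candidates(coords, one_hot(c("A", "G", "V")))
  bb <- viterbi_thread(cand, c(A = "AGV"), hmm_params(beam_width = Inf))
  expect_equal(bb$state, c(1L, 2L, 3L))
  expect_equal(bb$resid, c("ALA", "GLY", "VAL"))
  # brute-force oracle over all 6 orderings agrees
  oracle <- brute_force_thread(coords, one_hot(c("A", "G", "V")),
                               c("A", "G", "V"))
  expect_equal(oracle$path, c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(unname(attr(bb, "scores")["A"]), oracle$score,
               tolerance = 1e-9)
})

test_that("unbounded beam equals the brute-force optimum on random
           instances", {
  for (seed in 1:25) {
    inst <- random_hmm_instance(seed)
    oracle <- brute_force_thread(inst$coords, inst$emission, inst$seq)
    cand <- make_candidates(inst$coords, inst$emission)
    if (is.finite(oracle$score)) {
      bb <- viterbi_thread(cand, c(A = paste(inst$seq, collapse = "")),
                           hmm_params(beam_width = Inf))
      expect_equal(unname(attr(bb, "scores")["A"]), oracle$score,
                   tolerance = 1e-9)
    } else {
      expect_warning(
        viterbi_thread(cand, c(A = paste(inst$seq, collapse = "")),
                       hmm_params(beam_width = Inf)),
        class = "voxtrace_partial_thread")
    }
  }
})

test_that("path score is monotone non-increasing as the beam narrows", {
  for (seed in 101:110) {
    inst <- random_hmm_instance(seed)
    cand <- make_candidates(inst$coords, inst$emission)
    seqs <- c(A = paste(inst$seq, collapse = ""))
    scores <- vapply(c(1, 4, Inf), function(bw) {
      bb <- suppressWarnings(
        viterbi_thread(cand, seqs, hmm_params(beam_width = bw)))
      if (nrow(bb) == length(inst$seq)) unname(attr(bb, "scores")["A"])
      else -Inf
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-9))
  }
})

test_that("no state is used twice within or across chains", {
  set.seed(51)
  n <- 14
  base <- matrix(0, n, 3)
  for (i in 2:n) {
    u <- rnorm(3)
    base[i, ] <- base[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
  }
  em <- matrix(rgamma(n * 20, 1), n, 20)
  em <- em / rowSums(em)
  cand <- make_candidates(base, em)
  seqs <- c(A = "AGVLK", B = "WYT")
  bb <- suppressWarnings(viterbi_thread(cand, seqs))
  expect_false(any(duplicated(bb$state)))
  # longest chain threaded first
  expect_equal(unique(bb$chain)[1], "A")
})

test_that("infeasible instances report the longest achievable prefix", {
  coords <- cbind(c(0, 3.8), 0, 0)
  cand <- make_candidates(coords, one_hot(c("A", "G")))
  expect_warning(bb <- viterbi_thread(cand, c(A = "AGVVV")),
                 class = "voxtrace_partial_thread")
  expect_equal(nrow(bb), 2L)
  expect_error(viterbi_thread(cand, c(A = "AGVVV"), partial = FALSE),
               class = "voxtrace_partial_thread")
})

test_that("backbone PDB output is standard and round trips", {
  bb <- data.frame(chain = c("A", "A", "A", "B", "B"), resno = c(1:3, 1:2),
                   resid = c("ALA", "GLY", "VAL", "TRP", "TYR"),
                   x = c(1, 4.8, 8.6, 20, 23.8), y = 0.25, z = -2,
                   state = 1:5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone(bb, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^ATOM", lines)), 5L)
  expect_equal(sum(grepl("^TER", lines)), 2L)    # one per chain
  expect_true(all(grepl(" CA ", lines[grepl("^ATOM", lines)])))
  back <- read_structure(f)
  expect_equal(back$x[back$chain == "A"], c(1, 4.8, 8.6))
  expect_equal(unname(extract_sequence(back)),
               c("AGV", "WY"))
  expect_error(write_backbone(bb[0, ], f), class = "voxtrace_value_error")
})

test_that("perfect emissions at true positions reproduce a 30-residue
           chain", {
  cfg <- synthetic_config(n_residues = 30, seed = 99, noise_sigma = 0)
  s <- generate_backbone(cfg)
  res <- s[s$elety == "CA", ]
  cand <- make_candidates(as.matrix(res[, c("x", "y", "z")]),
                          one_hot(AA1_TAB[match(res$resid, AA3_TAB)]))
  seqs <- extract_sequence(s)
  bb <- viterbi_thread(cand, seqs)
  expect_equal(nrow(bb), 30L)
  expect_equal(bb$state, seq_len(30L))
  expect_equal(bb$resid, res$resid)
})
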
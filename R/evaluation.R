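# Scoring voxel-wise Calpha predictions and comparing reconstructed
# backbones against reference structures.

#' Precision/recall/F1 sweep of voxel-wise Calpha predictions
#'
#' At each threshold, voxels whose Calpha probability is at least the
#' threshold are called positive; true/false positives and false negatives
#' are counted voxel-wise against the 0/1 truth mask and
#' `F1 = 2 P R / (P + R)`. When no voxel is called positive precision is
#' undefined and F1 is reported as 0 by convention, as is F1 when
#' `P + R = 0`.
#'
#' @param pred a [prediction_volume()] with a `"CA"` class, or a plain 3D
#'   probability array.
#' @param truth a [label_volume()] of kind `"calpha"` (or a 0/1 array) of
#'   the same shape.
#' @param thresholds numeric vector of probability thresholds.
#' @return data.frame with one row per threshold: `threshold`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
f1_sweep <- function(pred, truth, thresholds = seq(0.1, 0.9, by = 0.1)) {
  probs <- if (inherits(pred, "prediction_volume")) pred_channel(pred, "CA")
           else pred
  tv <- if (inherits(truth, "label_volume")) truth$values else truth
  if (!identical(dim(probs), dim(tv)))
    vx_stop("prediction and truth shapes differ", "voxtrace_value_error")
  pos <- tv == 1
  out <- lapply(thresholds, function(t) {
    called <- probs >= t
    tp <- sum(called & pos); fp <- sum(called & !pos)
    fn <- sum(!called & pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, out)
}

#' Compare a reconstructed backbone to a reference structure
#'
#' Matches model Calpha atoms to reference Calpha atoms one-to-one by
#' greedy nearest-neighbor pairing (closest pairs accepted first) under a
#' distance cutoff; both structures are taken in the shared map coordinate
#' frame, so no superposition is performed. Reports the percentage of
#' reference residues matched, the percentage of matched residues with the
#' same amino-acid type, and the RMSD over matched pairs.
#'
#' @param model a `backbone_model` (or data.frame with `resid`, `x`, `y`,
#'   `z`).
#' @param reference an [atomic_structure()] (its Calpha atoms are used) or a
#'   data.frame with `resid`, `x`, `y`, `z` per residue.
#' @param cutoff matching distance cutoff in Angstrom (default 3).
#' @return list of class `chain_compare_report`: `matched` (pair count),
#'   `n_reference`, `n_model`, `matching_pct`, `sequence_id_pct`, `rmsd`
#'   (Angstrom; `NA` when nothing matches) and `cutoff`.
#' @export
chain_compare <- function(model, reference, cutoff = 3.0) {
  if (inherits(reference, "atomic_structure")) {
    res <- residue_table(reference)
    cc <- backbone_coords(res, "CA")
    keep <- stats::complete.cases(cc)
    reference <- data.frame(resid = res$resid[keep], cc[keep, , drop = FALSE])
  }
  if (nrow(model) == 0L || nrow(reference) == 0L)
    vx_stop("model and reference must both be non-empty",
            "voxtrace_value_error")
  mm <- as.matrix(model[, c("x", "y", "z")])
  rr <- as.matrix(reference[, c("x", "y", "z")])
  d2 <- outer(rowSums(mm^2), rowSums(rr^2), "+") - 2 * tcrossprod(mm, rr)
  d <- sqrt(pmax(d2, 0))
  pairs <- which(d <= cutoff, arr.ind = TRUE)
  model_used <- logical(nrow(mm)); ref_used <- logical(nrow(rr))
  matched_m <- integer(0L); matched_r <- integer(0L); matched_d <- numeric(0L)
  if (nrow(pairs) > 0L) {
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      im <- pairs[p, 1L]; ir <- pairs[p, 2L]
      if (model_used[im] || ref_used[ir]) next
      model_used[im] <- TRUE; ref_used[ir] <- TRUE
      matched_m <- c(matched_m, im); matched_r <- c(matched_r, ir)
      matched_d <- c(matched_d, d[im, ir])
    }
  }
  m <- length(matched_m)
  same <- if (m > 0L)
    sum(model$resid[matched_m] == reference$resid[matched_r]) else 0L
  structure(list(
    matched = m, n_reference = nrow(rr), n_model = nrow(mm),
    matching_pct = 100 * m / nrow(rr),
    sequence_id_pct = if (m > 0L) 100 * same / m else 0,
    rmsd = if (m > 0L) sqrt(mean(matched_d^2)) else NA_real_,
    cutoff = cutoff), class = "chain_compare_report")
}

#' @export
print.chain_compare_report <- function(x, ...) {
  cat(sprintf("chain comparison (cutoff %.2f A)\n", x$cutoff))
  cat(sprintf("  matched %d of %d reference residues (%.1f%%)\n",
              x$matched, x$n_reference, x$matching_pct))
  cat(sprintf("  sequence identity over matches: %.1f%%\n",
              x$sequence_id_pct))
  cat(sprintf("  RMSD: %s\n",
              if (is.na(x$rmsd)) "undefined (no matches)"
              else sprintf("%.3f A", x$rmsd)))
  invisible(x)
}
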
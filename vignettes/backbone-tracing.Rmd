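---
title: "From density voxels to backbone traces: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From density voxels to backbone traces: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxtrace)
```

This vignette is the package's own account of the science it implements:
the models and conventions, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices made where the design
was genuinely open.

## Map standardization

Cryo-EM maps arrive with heterogeneous voxel sizes and arbitrary value
scales, both artifacts of reconstruction software and experimental
conditions rather than of the molecule. Two operations put maps on a
common footing.

**Resampling** (`resample_map`) interpolates the grid to a uniform voxel
size, 1 Å by default — fine enough that distinct backbone atoms of
well-separated residues land in distinct voxels, coarse enough to keep
volumes tractable. The kernel is trilinear: it is the standard default for
volume resampling, is exact on fields that are linear in each coordinate
(which supplies an analytic test oracle), and requires no tuning. Points
sampled outside the input support are filled with 0, consistent with 0
meaning background in normalized maps. The output grid keeps the input
origin and extends by `ceiling(extent / target)` voxels per axis so that
the physical extent is covered; resampling an already-uniform grid is the
identity.

**Normalization** (`normalize_map`) divides every value by the 95th
percentile of the *strictly positive* values, then clips to [0, 1].
Positive density marks probable protein; negative values and extreme
positive outliers are artifacts, which is why the divisor ignores
non-positive values and the clip bounds absorb the tails. The percentile
estimator is the sort-based one with linear interpolation between order
statistics (R's default, `type = 7`) — deterministic and the common
convention. A map with no positive voxel at all cannot be scaled; it is
returned as all zeros with a warning rather than an error, since such maps
do occur as degenerate corners of batch processing.

## Voxel labeling and its round trip

Atomic coordinates `(x, y, z)` map to 0-based grid indices
`(i, j, k)` = (section, row, column) by

    i = round((z - origin_z) / voxel_z),   and likewise j <- y, k <- x,

with halves rounded away from zero. Nearest rounding is the one choice
that guarantees the inverse map `x = k·voxel_x + origin_x` (etc.) returns
a point within half a voxel of the original on every axis, which is the
bound the round-trip verifier (`verify_labels`) checks.

Four masks are built per map: backbone atoms (Cα = 1, N = 2, C = 3),
Cα-only (0/1), amino-acid type (1–20 in alphabetical order of the
three-letter codes, ALA = 1 … VAL = 20; 0 = absent or non-standard), and
secondary structure (coil = 1, helix = 2, strand = 3, from the structure
file's HELIX/SHEET records; untagged residues default to coil). The
alphabetical amino-acid table is a convention choice — any fixed published
mapping would do — and is exposed via `amino_codes()`.

Two details deserve notice:

* **Out-of-grid atoms are skipped and counted**, not an error: deposited
  models routinely extend past the reconstructed box.
* **Voxel collisions.** Two atoms can round to one voxel; the mask keeps
  the last atom written and counts the collision. The atom mask is painted
  N, then C, then Cα, so a Cα label always survives a collision with a
  neighboring residue's N or C. This matters: a Cα voxel silently
  relabeled as nitrogen would delete a hidden state from the threading
  model downstream, a failure mode that is easy to miss because it only
  occurs when all three coordinate offsets between the two atoms are
  under one voxel.

## MRC2014 I/O

The reader, writer and validator are implemented directly against the
MRC2014 byte layout. The validator reports twelve separate checks — format
ID string, machine stamp, data mode, map dimensions, cell dimensions, axis
mapping, volume-stack divisibility, header-label consistency, format
version, extended-header type, data statistics, and file size — so a
failing file names the exact defect. Files with permuted `mapc/mapr/maps`
axis order are de-permuted on read to a fixed logical (x, y, z) layout and
written back in canonical 1,2,3 order; header statistics are always
recomputed from the data on write rather than marked undetermined, so the
statistics check is actually exercised. Everything is written in mode 2
(32-bit real) by default, including integer-valued masks, whose values are
preserved exactly in float32.

## Sub-grid division and stitching

Classifiers consume fixed-size cubes; maps are divided into 32³ sub-grids
with a 6-voxel border on each face, i.e. cubes placed at stride
`core = 32 − 2·6 = 20`. Adjacent cubes therefore share 12 voxels, and the
central 20³ core of each cube tiles the padded volume exactly: stitching
copies only cores, which discards the boundary-artifact-prone outer shell
of each prediction while reconstructing the full map voxel-for-voxel. The
divide→stitch identity holds for any `(cube, border)` with a positive core
and is property-tested as such. Padding is zero-valued, consistent with
the normalized-map background.

## The threading model

Candidate Cα voxels (probability ≥ a detection threshold, default 0.5)
become the hidden states of an HMM; the observation sequence is the known
protein sequence.

* **Emissions.** For state *s* and amino type *t*,
  `raw_t = sqrt(a_t · b_t)` — the geometric mean of the classifier's
  probability `a_t` at that voxel and the background frequency `b_t` —
  normalized to sum to 1. The geometric mean tempers overconfident
  classifier outputs with sequence statistics. The background defaults to
  the uniform 1/20 vector and can be replaced by any frequency table;
  corpus-derived frequencies belong to whoever trains the classifier.
* **Transitions.** The weight from one state to another is the normal
  density, mean µ = 3.8047 Å and standard deviation σ·Λ = 0.036 × 10 =
  0.36 Å, evaluated at their Euclidean distance. These constants are the
  empirical distribution of consecutive Cα–Cα distances in trans peptide
  bonds; the scale factor Λ widens the nominal σ to absorb voxel
  quantization (±0.87 Å worst case on a 1 Å grid). Weights are used as
  unnormalized densities in log space; per-state row normalization over
  in-cutoff neighbors is available behind a flag but off by default, since
  the model specifies the Gaussian form and not a normalization, and
  unnormalized weights keep scores comparable across states. Transitions
  beyond `neighbor_cutoff` (default µ + 10·σ·Λ ≈ 7.4 Å) are exactly zero,
  pruning the graph to near neighbors while retaining more than ten
  effective standard deviations of mass. Self-transitions are forbidden.
* **Initial state.** Any state may start a chain; its probability is its
  emission of the chain's first residue, renormalized over all states.

### The constrained Viterbi search

The decoder maximizes

    log init(s1) + log emis(s1, aa1) + Σ_t [ log trans(s_{t−1}, s_t) + log emis(s_t, aa_t) ]

subject to *each state appearing at most once in the whole model* — one
voxel holds one residue. This constraint breaks the Markov decomposition
that makes plain Viterbi polynomial; exact decoding would require carrying
the set of used states, which is exponential. The implementation is a
per-step beam search whose hypotheses carry their own used-state sets:
at each residue every surviving partial path is extended to all unused
in-cutoff neighbors, and the best `beam_width` (default 50) partial paths
are kept, ties broken by the lowest state index for determinism. With
`beam_width = Inf` no pruning occurs and the search is exhaustive over
injective paths — this exact mode is what the test suite compares against
independent brute-force enumeration on small instances. Path scores are
monotone non-increasing as the beam narrows.

Chains are threaded longest first (the most constrained problem gets the
freshest state pool); states consumed by earlier chains are removed before
later chains are threaded. When a chain cannot reach its full length —
fewer detected states than residues, or a geometric dead end — the longest
achievable prefix is returned with a `voxtrace_partial_thread` warning by
default (`partial = FALSE` upgrades it to an error). Returning the prefix
rather than failing is deliberate: degraded predictions are the normal
operating regime of this tool, and the evaluation module quantifies the
damage rather than hiding it behind an exception.

## Evaluation conventions

`f1_sweep` counts voxel-wise TP/FP/FN at each threshold with F1 reported 0
when precision + recall is 0 (including the no-positive-calls case where
precision is undefined). For uniform-random predictions against a
prevalence-*p* mask, precision converges to *p* and recall to 1 − t, so the
expected F1 at threshold *t* is `2p(1−t)/(p + (1−t))` — a closed form the
Monte-Carlo tests verify, and a floor any real classifier must beat.

`chain_compare` matches model and reference Cα atoms one-to-one by greedy
nearest-pair-first assignment under a cutoff (default 3 Å — the class of
criterion used by standard chain-comparison tools; configurable because
published tools do not all print theirs). Greedy matching is deterministic
and near-optimal at backbone densities, where inter-residue spacing
(≥ 3 Å) dwarfs within-pair displacement (≤ 0.87 Å); an optimal-assignment
mode could be added without changing the interface. No superposition is
applied: both structures live in the map's coordinate frame, so RMSD
measures placement error, not shape difference.

## The synthetic generator

`make_fixture` chains the full pipeline on generated data: a self-avoiding
random-walk backbone with Normal(3.8047, 0.036) bond lengths and a 3 Å
self-avoidance radius (so distinct residues always occupy distinct 1 Å
voxels); N and C atoms placed on the inter-Cα segments at fraction 0.35
from each end; density as a sum of isotropic Gaussian blobs (width 1 Å)
plus additive Gaussian noise (σ = 0.02 in raw units), normalized by the
package's own normalizer; masks computed by the labeling module; and
prediction volumes derived from the masks with a controllable corruption
rate ε — each labeled voxel's winning class is flipped to a random wrong
class with probability ε, winners receive probability 1 − ε with ε spread
over the rest, and background voxels deterministically favor the
background class at 0.99. All randomness flows from a single seed through
deterministically derived per-component sub-seeds. The bounding box adds a
6 Å margin so grid division always has at least one cube.

What this emulates is the *statistical contract* of the pipeline:
bond-length geometry, blob-like positive density, calibrated-but-wrong
classifier output. What it does not emulate is cryo-EM image formation —
CTF effects, projection artifacts, resolution anisotropy, missing density,
side-chain density. Passing the end-to-end tests therefore demonstrates
that the machinery is correct (at ε = 0 a 30-residue chain is recovered
with 100% matching, 100% sequence identity, and RMSD below the √3/2 ≈
0.87 Å quantization bound), not that any particular classifier will
perform well on experimental maps.

Problem sizes used throughout the tests — 30-residue single chains for
recovery, ≤ 7-state instances for brute-force comparison, 100-map fuzz
batches, 30³–40³ Monte-Carlo grids — were chosen as the smallest sizes at
which each property is non-trivially exercised.

## Known limitations

* Only PDB-format structures are parsed (no mmCIF); secondary structure
  comes from file annotations, not geometric assignment.
* The MRC reader decodes modes 0, 1, 2 and 6; modes 4 (complex) and 12
  (float16) are validated but not read.
* Beam search offers no optimality guarantee at finite beam width; the
  exact mode is exponential and practical only for small instances.
* Greedy chain matching can differ from optimal assignment in dense or
  pathological geometries.
* The threading model places Cα atoms only; full-atom building and
  refinement against density are out of scope.
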
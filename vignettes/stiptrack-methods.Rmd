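---
title: "Scale-selected spatio-temporal interest points for cell segmentation and tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stiptrack methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `stiptrack`, the tunable
parameters and their defaults, the numerical choices that matter, what the
synthetic generator does and does not emulate, and the places where the
design was genuinely open and a decision had to be made.

## The problem and the modelling idea

Time-lapse microscopy sequences vary in contrast and noise between
sequences, between frames, and even within a frame. A detector tuned at one
scale (one amount of smoothing, one threshold) therefore fails elsewhere.
The framework's central idea is to treat scale as a per-frame variable to be
*estimated*: build a nonlinear spatio-temporal scale space, watch how the
population of interest points changes across scales, and pick the scale at
which noise-driven features have decayed while cell-driven features persist.
Everything downstream — watershed segmentation, region classification,
boundary refinement, motion-compensated tracking — operates at that selected
scale.

## Spatio-temporal anisotropic diffusion

Each frame is diffused jointly with its two temporal neighbours
(τ ∈ {t−1, t, t+1}) under the edge-stopping equation
∂L/∂s = ∇·(g(|∇L|)∇L). Choices:

* **Conductance** g(x) = exp(−(x/k)²) (Perona–Malik exponential). The
  exponential form favours high-contrast edges over wide soft ramps, which
  suits non-spherical, sharply bounded cell regions. The edge-stopping
  parameter `k` defaults to the 90th percentile of the spatio-temporal
  gradient magnitude of the triplet, so "edge" is defined relative to each
  frame's own contrast; `conductance_k = Inf` reduces the scheme to linear
  (Gaussian) diffusion, which the tests exploit as an oracle.
* **Discretization.** Explicit 6-neighbour flux differencing with
  reflecting boundaries. The flux form conserves total intensity exactly
  and obeys the maximum principle for `step` ≤ 1/6; the default `step` is
  0.15. Reflecting boundaries mean a temporally constant triplet is a pure
  2D diffusion — convenient both physically and for testing.
* **Scale increments.** Consecutive scales are separated by
  `substeps` (default 4) explicit steps, so the default 8 scales span a
  diffusion time of 4.2 (Gaussian-equivalent σ ≈ 2.9 px). A single explicit
  step per scale would span σ ≈ 1.4 px over the whole scale space — too
  little smoothing for noise features ever to die, which would leave the
  count curve without an elbow. The spacing of the temporal axis equals the
  spatial spacing (no anisotropy factor); this is listed as an open choice
  below.

## Interest-point detectors

Derivatives are central finite differences taken directly on the diffused
maps — the diffusion itself is the regularization, so the differentiation
scale is tied to the scale index rather than to an extra Gaussian kernel.
Three detectors are provided:

* `moments` — 3D structure tensor with Harris strength
  S = det M − κ·tr³M. κ defaults to 0.005: because the trace is *cubed* in
  3D, the classical 2D κ = 0.04 would make the subtractive term dominate.
  The tensor entries are smoothed spatially with σᵢ = 2 px; the temporal
  window is the 3-frame triplet itself (τᵢ = 1 frame).
* `hessian_st` — |det| of the 3×3 spatio-temporal Hessian (blob detector).
* `hessian_temporal` (default) — |det| of the 2×2 spatial Hessian of the
  central temporal difference L_t. Static background structures have
  L_t ≈ 0, so this detector responds only to moving or appearing structure,
  matching the motion-centric task.

Interest points are regional maxima of the strength map. A flat plateau
contributes one locus (its centroid rounded to the nearest plateau pixel).
The strength threshold is *relative*: `min_strength_rel` (default 1e-3)
times the maximum of the **scale-0** response of the frame. Holding this
threshold fixed across the scales of one frame is essential for scale
selection: the count curve then measures how many scale-0-calibrated
features survive s increments of diffusion. (A threshold recomputed per
scale tracks the decaying response and makes the curve non-monotone; and a
much smaller relative value lets the heavy tail of the determinant response
at scale 0 prune proportionally more raw maxima than smoothed ones, which
can make counts *rise* over the first increment on pure noise.)

## Automatic scale selection

The counts are normalized by the scale-0 count (falling back to the maximum
when it is zero) and the selected scale is the smallest interior index
maximizing the discrete second difference of the normalized curve — the
elbow at which the rapid decay of noise features ends. Ties break toward the
smaller scale to preserve detail, and a fully degenerate profile (all counts
equal) returns scale 1 with a warning flag. The decision rule operates per
frame, so a sequence whose noise level drifts gets a drifting scale.

Two behavioural properties are enforced by tests: the mean selected scale is
non-decreasing in the injected noise level, and planted cells retain interest
points at the selected scale. On the retention check a caveat is worth
stating plainly: all three detectors are derivative-based and respond on the
*boundary ring* of a plateau-profile cell, not at its centre. For cells of
radius ≈ 5 px the nearest interest point to a cell centre therefore sits at
ring distance (every planted cell has a point within 5 px in our runs), and
a centre-proximity criterion with a 3 px radius is met only by small cells.
This is a geometric property of derivative detectors on plateau objects, not
a tuning artefact.

## Watershed segmentation

The relief that is flooded is the equal-weight sum of the min-max-normalized
gradient magnitude of the selected-scale map and the normalized *inverted*
Parzen density of the interest points (bandwidth = `bandwidth_rel` (0.5) ×
`expected_radius` (6 px)). Markers are the union of

1. regional-minima components of the **edge map** (the normalized gradient
   magnitude), extracted after quantization with tolerance `marker_tol`
   (0.02) so that the near-flat background — which is *enclosed by* the
   cell-boundary ridges — forms one large component and each cell interior
   its own; the mask is eroded by 1 px to sever one-pixel bridges through
   ridge gaps, and components that the erosion wipes out entirely (the
   interiors of small cells) are restored un-eroded, which cannot
   reintroduce a bridge; and
2. the interest points as single-pixel seeds, dropping seeds inside or
   adjacent to a minima component (they are absorbed by it).

Seeds are deliberately *not* dilated: a 3×3 seed placed on a boundary ridge
straddles both slopes and floods both sides, merging a cell interior with
the background basin. Using the edge map rather than the fused relief for
the minima is equally deliberate: the fused relief's minima sit in the
Parzen-density basins, which yields density-halo superpixels instead of
intensity-bounded ones. The priority-flood watershed itself is implemented
in C++ (a global min-heap on relief height with FIFO tie-breaking), so
boundaries fall on ridge lines and results are deterministic. Superpixels
below `min_superpixel_px` (5 px) merge into the neighbour behind the lowest
ridge.

## Detection: descriptors, balancing, network

Each superpixel is summarized by 9 features: mean and (population) variance
of diffused intensity, detector response, motion-displacement magnitude and
spatio-temporal gradient magnitude, plus the area. This enumeration — four
mean/variance pairs plus area — is the unique one matching a 9-node input
layer given the listed feature categories. Training labels come from
reference masks: a superpixel is a cell sample when at least half of its
pixels lie in a reference cell region.

Because background superpixels vastly outnumber cell superpixels, the
training set is re-balanced before fitting: DBSCAN (min_pts = 10, ε = the
15th percentile of pairwise distances on a ≤ 500-sample subsample, distances
Mahalanobis-whitened so cluster shape does not depend on feature scaling)
identifies the cluster prototypes, and the most populous cluster is
undersampled without replacement (seeded) to the size of the second most
populous. Only multiplicities change — no feature vector is altered. When
DBSCAN finds a single cluster the balancing is a documented no-op with a
warning. DBSCAN runs jointly on the full training set, not per class.

The classifier is a fully connected 9×12×6×2 network with ReLU activations
and softmax cross-entropy loss — 192 weights + 20 biases = 212 parameters —
trained by plain SGD with momentum 0.9, learning rate 1e-2, batch 64, 200
epochs, on z-scored features whose standardization constants are stored in
the model and re-applied at prediction time. Everything (He-style
initialization, batch shuffling) derives from one seed, and the RNG state of
the session is saved and restored around training, so identical seeds give
bitwise-identical models without side effects on user code. A 212-parameter
model needs no more machinery than this; the loss curve is retained in the
model object for inspection.

## Boundary refinement and cluster separation

The classified foreground evolves under a region-based level set with a
local two-phase clustering criterion: within a sliding window (default 7 px)
around every pixel the intensity is modelled by an inside mean m₁ and an
outside mean m₂ (box-filtered ratios), and the boundary moves to reduce
Σ H(I−m₁)² + (1−H)(I−m₂)² + ν·|∂H| with length weight ν (default 0.2 ×
intensity-range², i.e. 0.2 after normalization). Numerically the evolution
is narrow-band threshold dynamics: φ is kept an exact signed distance
(re-initialized every accepted step), and pixels within a ±2 px band flip to
the phase favoured by the local speed (band-normalized data misfit plus
ν-weighted curvature). A step that would increase the energy retries with a
±1 px band and evolution stops when no decrease is possible, so the recorded
energy trace is non-increasing by construction. Threshold dynamics was
chosen over an explicit time-stepped PDE after the latter proved fragile at
this scale: with a sub-pixel time step the front's progress is erased by
re-initialization, and without re-initialization φ distorts; flipping whole
band pixels per iteration sidesteps the step-size dilemma entirely.

Adherent clusters are then screened by solidity (area / convex-hull area,
hull rasterized on the pixel grid) and flagged regions are split along the
watershed lines of their internal distance map with h-maxima suppression.
Defaults: `solidity_threshold` 0.95 and `hmax` 0.5 px. Both are deliberately
tighter than the conventional 0.85/1.0: refined single cells in this regime
are nearly perfectly solid, so 0.95 flags touching pairs that a 0.85
threshold misses (side-by-side pairs can be 0.86–0.91 solid, end-to-end
pairs even higher), and for small cells (r ≈ 3 px) the two distance-map
maxima of a touching pair differ by less than 1 px, so `hmax` = 1 would
suppress the true second seed. For large, irregular real cells users should
relax both (`refinement.solidity_threshold`, `refinement.hmax` in the
configuration).

## Motion and tracking

Dense motion between consecutive frames is combined local–global optical
flow: the Lucas–Kanade structure tensor integrated over a ρ-neighbourhood
(ρ = 2 px) embedded in Horn–Schunck smoothness (weight α = (0.05 ×
intensity-range)²), solved by Jacobi fixed-point iteration with a per-pixel
2×2 solve (≤ 200 iterations, stop at mean update < 1e-4 px). A 2-level
coarse-to-fine pyramid extends the linearization range: the coarse estimate
warps the current frame back (bilinear) and the fine level solves only the
residual. One level is enough for sub-2 px cell steps; the second level is
what makes 4 px displacements recoverable, and `motion.pyramid_levels = 1`
restores the single-scale solver.

Bi-frame matching assigns each cell of the current frame the prior cell
maximizing the likelihood, concretized as the intersection-over-union of the
current region with the motion-warped prior region — the natural proximity
between indicator functions. A maximum below `reject_threshold` (0.1)
declares an appearance; when every IoU is zero but a prior centroid lies
within 2 × expected radius, a Gaussian centroid-distance fallback
(σ = expected radius) tolerates low temporal resolution. A prior cell
claimed by several current cells encodes division; claims beyond
`max_daughters` (2, binary fission) are demoted to appearances, keeping the
highest likelihoods. Reverse-chronological traversal of the linked
associations produces maximal chains; chains sharing an ancestor overlap on
a contiguous prefix, which is factored recursively into a mother track and
daughter tracks — a nested double division therefore yields the full
7-track family tree. The resulting lineage graph (migration edges within
tracks, division edges mother→daughter) is acyclic by construction and
verified. Cells reappearing after a full disappearance start new tracks;
there is no gap-closing.

## Evaluation measures

SEG averages, over reference cells, the Jaccard index with the unique result
region covering more than half of the cell (zero otherwise). DET and TRA
normalize the weighted cost of editing the computed graph into the reference
graph: node operations (split NS = 5, false negative FN = 10, false positive
FP = 1) for DET, plus edge operations (delete ED = 1, add EA = 1.5,
semantics EC = 1) for TRA, each normalized by the cost of building the
reference from scratch and clamped below at zero. The weights are the
published challenge weights — the measure definitions do not fix them — and
are exposed under `metrics.weights`. Node matching uses the same
half-coverage rule as SEG for internal consistency.

## The synthetic generator

`simulate_sequence()` emulates the phenomena the pipeline must survive:
elliptical cells with random orientation and an elongation factor of 1.4;
per-frame Brownian centroid steps (`motion_sd`, default 1 px/axis);
scheduled mitoses in which the mother is replaced by two half-area daughters
displaced along the elongation axis with a cleavage-furrow gap (offset
1.25 × daughter semi-major axis); rendering as background (0.1) + contrast
(0.5) × indicator, blurred with σ = 1 px; additive Gaussian noise
(`noise_sd` 0.03) plus signal-dependent noise (`noise_gain` 0.02 × √I ×
N(0,1)) so the contrast-to-noise ratio varies with local intensity; and
exact per-frame label masks, an "L B E P" lineage table and dense
ground-truth motion fields. Cells are solid bodies: after every Brownian
step an excluded-volume pass pushes interpenetrating pairs apart
symmetrically until their circle-equivalent boundaries are 2 px apart.
Without it, cells drift through one another — a physically impossible
configuration whose rendered image is a single convex blob carrying no
recoverable evidence of two objects; ground truth that cannot be recovered
from its own rendering cannot validate any method. With the 2 px floor,
contacts still occur (and exercise the solidity/distance-watershed
splitting) but always leave a shallow valley. The default two-sequence
fixture (128×128, 20 frames, 8 initial cells of radius 5 ± 1 px, 2 scheduled
divisions, distinct seeds) mirrors a train-on-01/test-on-02 protocol.

What the generator does **not** emulate: realistic point-spread functions,
vignetting or illumination gradients, cell deformation beyond rigid ellipse
motion, intensity heterogeneity inside cells, apoptosis, and cells entering
or leaving the field of view. Passing the fixture protocol therefore
demonstrates the mechanics of the whole chain — scale selection, marker
generation, classification, refinement, splitting, matching, lineage
assembly, scoring — under controlled contrast and noise, but not performance
on textured or deforming real cells; on real data the detector must be
retrained and the refinement thresholds revisited.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full protocol on the
two 128×128×20 fixture sequences (training on every second frame) and use
smaller frames (64–96 px) for property checks over many seeds — sizes at
which the complete suite exercises every module in a few minutes on one
core. All stochastic stages (simulation, DBSCAN subsampling, undersampling,
network training) are seeded; simulations, trained models and track files
are bitwise reproducible for a fixed seed.

## Known limitations

* Per-frame scale selection assumes the count curve has an elbow; a
  sequence with essentially no noise yields a flat curve and falls back to
  scale 1 with a warning.
* The solidity screen cannot flag merged pairs that form a convex union;
  such events surface as one-frame merges and cost tracking accuracy.
* Matching is greedy per cell over two frames; there is no global
  association optimization, no gap closing, and division timing can shift
  by a frame when daughters are momentarily unresolved.
* The 9-feature descriptor carries no texture or shape information beyond
  area; heterogeneous cell interiors may need richer descriptors.
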
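---
title: "Methods: arch standardization, Gaussian pair offsets and minimum-cost FDI numbering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arch standardization, Gaussian pair offsets and minimum-cost FDI numbering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalarch)
```

# The problem

A segmentation network applied to an intraoral scan (IOS) produces tooth
*instances* — vertex sets with centroids and 32-class logits — but its
per-tooth label distribution ignores anatomy: neighbouring teeth look
alike, and on partial-arch scans (a quadrant or sextant of the arch) the
network routinely shifts a whole run of labels by one position. This
package implements the deterministic machinery around such a network:
augmentation that manufactures realistic partial-arch training scans,
pose standardization so that spatial priors are expressed in one frame,
a postprocessor that re-labels instances by combining classifier
confidence with a spatial prior over tooth-pair centroid offsets, and
the evaluation metrics.

# Standard pose

All spatial reasoning happens in a canonical frame built from four
landmark teeth: the two first molars and the two central incisors. The
occlusal plane is the plane through the two first-molar centroids and
the mean central-incisor centroid. `standard_pose_from_landmarks()`
centres the scan on its vertex mean, aligns the molar-to-molar line with
the x-axis, sends the occlusal-plane normal (coronal side) to +z, and
leaves the anterior direction at −y; upper and lower arches end up
oriented identically. Two conventions were genuinely open and are fixed
here once:

* *Centre of the scan.* "Centred on the origin" could mean the landmark
  centroid or the vertex mean; we use the vertex mean because it is
  defined for every scan (also crops without landmarks) and matches the
  recentering the crop augmentation applies.
* *Coronal side of the plane.* The normal's sign is chosen to point from
  the gingiva toward the crowns, operationalized as pointing from the
  all-vertex mean toward the tooth-vertex mean. For a scan with no
  gingiva vertices the current +z hemisphere is kept.

`pca_rough_align()` provides the classical fallback: principal axes to
x/y/z in descending variance. PCA axes have sign ambiguity; signs are
fixed deterministically by requiring nonnegative coordinate skewness
along each axis, then flipping the last axis if needed for a proper
rotation. Determinism, not anatomical correctness, is the goal of this
convention — the landmark construction is the authoritative one.

The alignment losses are pure functions usable by any trainer. The
orientation loss is
$L_{orient} = 2 - \cos(f', \hat f) - \cos(u', \hat u) + |\cos(\hat f, \hat u)|$,
zero exactly when the predictions are parallel to the truth and mutually
orthogonal, and invariant to positive rescaling of the predictions. The
full loss adds smooth-L1 on the translation, and BCE plus soft-Dice on
an auxiliary binary tooth segmentation. Reductions and constants are not
universal conventions, so we document ours: smooth-L1 with $\beta = 1$,
mean over the 3 coordinates; BCE mean over vertices with scores clamped
at $10^{-7}$; Dice loss $1 - $ soft-Dice with additive smoothing
$10^{-6}$. `apply_standardization()` is the inference-side inverse:
reverse the translation, Gram-Schmidt the forward direction against the
up direction (up kept), complete a right-handed basis with
$r = f \times u$, rotate.

# Partial-arch crop augmentation

`maybe_crop()` applies the crop with probability 0.9. The tooth count is
drawn from a truncated geometric distribution on 2..12,
$P(n) \propto 0.75^{\,n-2}$ — the simplest monotone ("skewed toward
fewer teeth") choice; the ratio and the full distribution are
configurable. A count exceeding the teeth available is clipped. The crop
box is the principal-axes bounding box of the selected teeth's vertices
padded by 2 mm so the gingival collar survives; faces touching removed
vertices are dropped and only the largest connected surface component is
kept (ties go to the component nearest the selected teeth). Slivers of
neighbouring teeth caught by the padding are removed *before* the
component filter — a sliver must not act as a connectivity bridge — so a
crop's instances are exactly its selected teeth. The recentering vector
is recorded as the ground-truth translation target for alignment
training.

# The offset model and the minimum-cost FDI sequence

Teeth are first ordered along the arch: start at the most posterior
centroid (maximum y; ties by maximum x) and repeatedly append the
unvisited centroid whose origin-anchored xy-direction has maximal cosine
similarity to the last appended one. The phrase "minimum angle to the
last included tooth" admits two readings (origin-anchored directions vs
travel directions); we use origin-anchored directions, which on a
centred standardized arch is an angular sort about the arch centre — the
generator's monotone-polar-angle invariant validates exactly this.

Unary costs are $-\log$ softmax over the selected arch's 16 labels
(restriction before softmax keeps each row normalized; the arch itself
is chosen by total softmax mass over instances, ties to upper). The
costs are computed in log-space so that arbitrarily confident logits
stay finite.

Pairwise costs come from a multivariate Gaussian model of centroid
offsets per ordered FDI pair, fitted on annotated standardized scans:

* every co-occurring ordered pair $(i, j)$ contributes
  $c_j - c_i$;
* each offset is mirrored across the midline (pair labels mirrored,
  x negated), doubling the sample;
* per annotated tooth, disconnected surface patches contribute
  inter-component offsets, pooled per arch and assigned to every
  $(i, i)$ pair — this is what lets the relabeler assign the *same* FDI
  number to two instances that are fragments of one tooth.

Fitting uses the maximum-likelihood covariance plus a ridge
$\varepsilon I$ ($\varepsilon = 0.01\,\mathrm{mm}^2$); pairs with fewer
than 4 offsets shrink linearly toward the pooled within-arch covariance.
Pairs never observed in training are evaluated under the pooled-arch
Gaussian with the cost *floored* at 50: never-seen label pairs must stay
strongly discouraged, not merely "averagely plausible". (A cap instead
of a floor lets the optimizer escape into unobserved labels — e.g.
third molars absent from training — whenever an observed pair's cost
spikes under centroid noise; the floor is what makes the postprocessor
strictly dominate the argmax baseline in our tests.) Non-finite entries
are replaced by the same constant, so cost tables are always finite.

The optimal sequence over labels $l_1 .. l_T$ minimizing
$\sum_t u_t(l_t) + \sum_t p_t(l_t, l_{t+1})$ is found by a forward
dynamic program over the 16 label states with recorded predecessors;
repeated labels are allowed (same-FDI pairs are part of the model) and
ties break toward the lower label index. For $T \le 4$ the tests verify
exact agreement with exhaustive search over all $16^T$ sequences.

# Metrics

Detection uses a Hungarian assignment maximizing total IoU (a greedy
matching would depend on instance order), keeping pairs with IoU
$\ge 0.5$ — inclusive at the threshold. Tooth Dice averages point-wise
Dice over matched pairs; label macro-F1 is the unweighted per-class F1
over matched pairs; macro-IoU averages per-FDI-label point-wise IoU over
labels present on either side. For the challenge metrics, "tooth size"
(the TLA normalizer) is the diagonal of the annotated tooth's bounding
box, a missing prediction is penalized with normalized distance 5, and
"closely predicted" for TIR means normalized distance < 0.5 — all three
constants are arguments, since the metric definitions leave them open.
TLA is reported both as the raw mean normalized distance and as
$e^{-\mathrm{TLA}_{raw}}$ on the 0–1 higher-is-better scale used in the
combined score $(\mathrm{TLA} + \mathrm{TSA} + \mathrm{TIR}/100)/3$;
empty-vs-empty edge cases return the perfect value.

# What the synthetic generator does and does not emulate

`generate_arch()` places ellipsoid-like teeth along a parabolic arch
(intermolar width 50 mm, depth 40 mm) with class-dependent mesiodistal
widths (molars ≈ 10 mm > incisors/canines ≈ 7–8 mm > premolars ≈ 7 mm,
scaled to the arch length), joined by a triangulated gingiva ribbon
welded to each tooth so the surface is a single connected component.
Tooth positions get isotropic Gaussian jitter (SD 0.3 mm) emulating
anatomical variation; all draws flow from one integer seed, and emitted
scans are exact fixed points of the landmark standardization. The mock
predictor (`perturb_predictions()`) converts ground truth into
network-shaped output with controlled noise: instance drops, boundary
vertex flips, isotropic centroid noise, spurious gingiva instances, and
peak-logit confusion with an arch neighbour. Logits are one-hot with a
peak margin of 5 at temperature 1 (softmax confidence ≈ 0.83),
emulating a confident classifier head.

What this does *not* emulate: real crown morphology and contact areas,
scanner noise and stitching artifacts, pathology (residual roots,
prepared teeth, implants), crowding and rotations, or correlated
network errors. Passing tests therefore demonstrate the *algorithms'*
correctness and the mechanism by which pairwise priors repair label
confusions — not clinical-grade performance on patient data, which
requires a trained segmentation network and real scans.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise each property
at statistical resolution without waste: 800 random cost tables for
DP-vs-exhaustive equivalence; an offset model fitted on 50 arches and
evaluated on 100 noisy arches (0.5 mm centroid noise, 10% label
confusion) for end-to-end recovery; 500 draws per pair for Gaussian
parameter recovery; 100 random rigid motions for the standardization
round trip; 1000 crops for the crop invariants and 10⁴ draws for the
sampler rates. Gaussian densities are evaluated via Cholesky
factorization; the ridge guarantees positive definiteness. Point-cloud
connectivity (when no faces exist) uses an ε-radius graph with ε = 2 ×
the median nearest-neighbour distance.

# Known limitations

* The arch-ordering heuristic assumes a centred, standardized scan; on a
  badly misaligned scan the greedy walk can zigzag. Run the
  standardization first.
* The offset model is fitted on ground-truth centroids but applied to
  predicted centroids; heavy centroid noise inflates true-pair costs.
  The fallback floor keeps this from flipping labels in our conditions,
  but a principled treatment would convolve the pair Gaussians with the
  predictor's centroid-noise covariance.
* `select_arch()` assumes one arch per scan; scans containing both
  arches (occlusion scans) are out of scope.
* Only permanent-dentition FDI codes (11–48) are supported; primary
  teeth (51–85) are rejected at validation.
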
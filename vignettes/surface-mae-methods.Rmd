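---
title: "Methods: masked-autoencoder pretraining on protein surface point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-autoencoder pretraining on protein surface point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model in brief

surfmae represents a protein chain by its solvent-facing surface rather
than its atoms or sequence: a point cloud sampled on a smooth molecular
surface, where every point carries local geometry (multi-scale curvature)
and local chemistry (the types and distances of its nearest atoms). A
transformer is pretrained on unlabeled surfaces by masked reconstruction —
hide 60% of the surface patches, reconstruct their coordinates from the
rest — and the pretrained encoder is then fine-tuned for binding-site
segmentation, ligand-pocket classification, or protein–protein interaction
(PPI) descriptor matching.

This vignette records the package's own methodological choices: the exact
functional forms, the parameters that matter, what the synthetic data
emulate, and the numerical decisions taken where the design was open.

## Surface construction

**Smooth distance function (SDF).** The surface is the zero level set of a
soft-min over per-atom signed sphere distances,

$$\mathrm{SDF}(x) = -\sigma \log \sum_k \exp\!\big(-(\lVert x - a_k\rVert - r_k)/\sigma\big),$$

with van der Waals radii $r_k$ (C 1.70, H 1.10, O 1.52, N 1.55, S 1.80,
Se 1.90 Å) and smoothing width $\sigma = 0.5$ Å. For a single atom this
reduces exactly to $\lVert x-a\rVert - r$, which gives the geometry suite
its closed forms. The gradient is analytic (a softmax-weighted sum of
unit vectors from atoms to the query); normals are the normalized
gradient, pointing outward.

**Level-set sampling.** 20 candidates per atom are seeded uniformly in
the shell $[r_k,\, r_k + 1.5\sigma]$ and Newton-projected along the
gradient for at most 10 iterations ($x \leftarrow x - f\,g/\lVert
g\rVert^2$). Candidates with $|\mathrm{SDF}| > 0.05$ Å or vanishing
gradient are dropped, and the survivors are thinned to at most one point
per cell of a 1 Å cubic grid anchored at the origin (keeping the candidate
nearest its cell center, ties by candidate order). This realizes "sampled
at 1 Å resolution" deterministically for a fixed seed. Chains whose raw
surface exceeds 20 000 points are rejected; the rest are subsampled to
exactly `targetPoints` (2048 by default), with replacement only when the
raw surface is smaller than the target. Features are computed after
subsampling: both the chemical and curvature features are functions of
the full atom cloud and of the retained points, so the order changes cost,
not definitions.

**Curvature.** Mean and Gaussian curvature $(H_s, K_s)$ are estimated at
scales $s \in \{1,2,3,5,10\}$ Å by a weighted least-squares fit of
$z = \tfrac12(ax^2 + 2bxy + cy^2)$ in each point's tangent frame, over
neighbors within $3s$ with Gaussian weights $e^{-d^2/2s^2}$. The basis is
augmented with one radial quartic term $(x^2{+}y^2)^2$: the height
function of a curved surface has a fourth-order term that a pure quadric
fit absorbs into its quadratic coefficients, inflating $K$ by about 10%
on a sphere of radius 5 Å at scale 1; the quartic column absorbs that
bias (measured sphere errors drop to 0.5% in $H$ and 1% in $K$) while
curvatures are still read off the quadratic coefficients, and a plane
stays exactly at zero. Signs are calibrated so a sphere with outward
normals has $H = +1/R$, $K = +1/R^2$; scales with fewer than 6 usable
neighbors report zeros. The curvature vector is ordered
$(H_1, K_1, H_2, K_2, \ldots)$ by ascending scale.

**Raw chemical features.** Each surface point stores its 16 nearest atoms
(ascending distance, ties by atom index) as (one-hot element, distance)
rows — a $16\times7$ block; chains with fewer than 16 atoms are padded by
cycling the sorted neighbor list. Together with the 10 curvature channels
the per-point input feature has $16\cdot7 + 10 = 122$ dimensions.

## Network

**Tokenizer.** Patches are formed by farthest point sampling of $g$
centers (first center: farthest from the centroid, ties to the lowest
index — a deterministic start rule that makes tests exact) and $k'$-NN
membership; patches overlap. Defaults $g = 128$, $k' = 32$ for
2048-point clouds, so $g\,k' = 2N$. A message-passing point encoder turns
each point's $16\times7$ raw chemical block into a learned 6-vector: a
shared MLP (width 32) embeds each neighbor row, then three
message-passing blocks update a per-point local feature (initialized to
all ones) by mean-aggregating per-neighbor messages and adding the result
residually — mean aggregation makes the output invariant to neighbor
order. The 6 learned channels are concatenated with the 10 curvature
channels (chemical first), and each patch token is the channel-wise max
pool of a shared MLP over its members' 16-D fused features.

**Transformer.** Pre-norm blocks (multi-head self-attention + MLP of
ratio 4, GELU), 12 × 384 with 6 heads by default — the standard point-MAE
configuration this architecture mirrors. Positional information enters
additively through a learnable MLP (3 → 128 → d) of the patch center
coordinates, with separate weight sets for the encoder and decoder sides.
A learnable CLS token (with its own learnable position) is prepended for
classification tasks; it participates in pretraining forward passes but
is never passed to the decoder.

**Masked decoder.** During pretraining, `round(m·g)` patches (m = 0.6)
are hidden. The decoder input is the projected visible encodings plus one
shared learnable mask token per masked patch, each with decoder-side
positional encodings; four self-attention blocks and a linear head map
every masked slot to $k' \times 3$ coordinates *relative to the patch
center*, making the reconstruction loss translation-invariant per patch.
The loss is the chamfer distance summed over masked patches, each term
the mean-of-minimum squared Euclidean distance in both directions. At
fine-tuning and inference no patches are masked.

**Heads.** Binding site: per-point logits from inverse-distance
interpolation of the three nearest patch tokens (weights normalized to
sum to one; a point coinciding with a center takes that token alone),
concatenated with the point's fused 16-D feature and the global
max-pooled token, through a two-layer MLP. Pocket: CLS state
concatenated with the max pool of the other tokens, MLP to 7 logits.
PPI: the descriptor head is the identity on interpolated tokens
(optionally a linear projection when `descriptorDim` differs from `d`),
L2-normalized; the binding score of a point pair is a learnable affine
function of the descriptors' dot product, trained with binary
cross-entropy on a 1:1 balanced sample of contact and random pairs —
a concrete instantiation of a balanced metric loss whose general
formulation is open to choice.

## Training

AdamW (decoupled weight decay 0.01 on weight matrices) with initial
learning rate 1e-3, batch 16, 50 epochs as pretraining defaults; the
learning-rate schedule is constant with an optional cosine decay. The
best checkpoint is the epoch with minimal reconstruction loss (ties to
the earliest). The binding-site loss is a balanced binary cross-entropy:
the majority class is subsampled (seeded, without replacement) to the
minority count before the mean. Pocket fine-tuning uses the standard
softmax cross-entropy; binary decisions use a fixed 0.5 threshold on
sigmoid outputs. The whole stack — tokenizer, transformer, decoder,
heads — runs on the package's own reverse-mode autodiff engine over
dense matrices; every operation's adjoint is exercised by
finite-difference tests, including one through the complete pretraining
loss.

## Synthetic data and desk-scale experiments

The generator emulates three features of real chains: a self-avoiding
backbone walk with exact 3.8 Å steps (the Cα virtual bond), 1–4 pseudo
side-chain atoms within 2.5 Å of each backbone atom, and element
frequencies dominated by C/N/O with rare S and Se. It does **not**
emulate secondary structure, realistic packing density, rotamer
chemistry, or the size distribution of deposited structures — so passing
tests demonstrate that the pipeline's machinery (geometry, masking,
optimization, transfer) works, not that production-scale benchmark accuracy
would be reached on curated PDB splits, which require external data and
GPU-scale pretraining.

Experiment sizes were chosen so a laptop-class CPU core completes the
whole suite comfortably: 128-point surfaces, g = 32, k' = 16, d = 64,
two encoder and two decoder blocks. Pretraining uses 8 chains for 30
epochs with `batch = 1` (at dataset size 8 the default batch of 16 would
collapse each epoch into a single step). The single-sample overfit smoke
runs 200 steps at learning rate 1e-2 — a step size suited to that budget;
the 1e-3 default is the full-scale pretraining rate. Fine-tuning
experiments use learning rate 1e-3 for 12–20 epochs. The synthetic
binding-site task labels points by whether the scale-2 mean curvature
exceeds its per-surface median; the pocket task maps 7 classes to
sphere-shell radii 3–9 Å (jittered ±0.2 Å); PPI complexes pair a chain
with its mirror image interlocked deeply enough to give at least ~20
cross-surface contact pairs within 1 Å, at 256-point density (contact
pairs are vanishingly rare at 128 points).

## Numerical choices and degenerate inputs

- Ties are broken deterministically everywhere: lowest index in FPS and
  KNN, first maximum in max pooling, earliest epoch in checkpoint
  selection.
- `round(m·g)` uses half-up rounding (128 patches at m = 0.6 give 77
  masked / 51 visible).
- Rejections (disallowed element, oversized surface) are values, not
  errors, so bulk preprocessing can continue and log them.
- Queries at an atom center have no SDF gradient and raise an error;
  the sampler nudges such candidates.
- Chains smaller than the neighbor count pad chemical features
  cyclically; surfaces smaller than `targetPoints` subsample with
  replacement.
- All randomness flows from explicit integer seeds through a splitmix-
  style derivation, and the caller's RNG state is always restored;
  preprocessing outputs and loss curves are bit-reproducible.

## Known limitations

- The sphere-shell fixture needs a dense tiling (0.6 Å default): at ~1 Å
  spacing the soft-min surface of a shell of van der Waals spheres is
  corrugated and acquires a second, interior level set.
- Curvature at scales comparable to the object radius (e.g. 10 Å on a
  5 Å sphere) is unreliable — the 3s neighborhood wraps around the
  object; signs remain consistent but magnitudes do not.
- The cache format keeps the documented logical schema (surface/atoms
  groups with config, seed and schema-version attributes) in an RDS
  container.
- Training is CPU-bound and single-threaded beyond BLAS; the
  configuration scales to production sizes, but pretraining a
  full-scale model on hundreds of thousands of chains is out of scope
  for this implementation.
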
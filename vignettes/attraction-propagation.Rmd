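---
title: "Attraction propagation: model, numerics and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attraction propagation: model, numerics and the synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apseg)
```

## The model

Seeded graph segmentation treats the image as a weighted lattice graph: one
node per pixel, edges between 4- (or 8-) neighbors, weights
$w_{ij} = \exp(-\beta\,|g_i-g_j|) + \varepsilon_w$ on unit-scale intensities.
The random walker (RW) fixes seed nodes to their labels and solves, per label
$c \in \{f, b\}$, the sparse SPD system $L_U x^c = -B^\top m^c$, where $L_U$
is the unseeded block of the graph Laplacian, $B$ the seeded–unseeded
off-diagonal block and $m^c$ the seed indicator. The result is a per-pixel
transition probability; the label with the larger probability wins.

With a *single* foreground seed and a frame of background seeds — the
viewfinder initialization this package automates — RW suffers the small-cut
problem: the influence of one seed pixel dies out in noisy tissue, and the
much larger background frame wins almost everywhere.

Attraction propagation adds a shape-driven unary term
$\sum_{i \in \mathcal{A}} D(a_i, x_i^c, \tau_i^c)$ to the smoothness energy:

* the **attraction region** $\mathcal{A}$ is the support of a thresholded
  shape probability matrix, translated so that its canvas center (which
  coincides with the calibrated centroid by construction) sits on the
  foreground seed;
* the **range base** $\tau^f$ equals the shifted threshold matrix inside
  $\mathcal{A}$ and $\tau^b = 1-\tau^f$, so $\tau^f + \tau^b = 1$ on the
  region — this is what makes the L2 variant conservative (see below);
* the **attraction factor** $a_i = \exp(-|g_i-g_s|)$ discounts region pixels
  that look unlike the seed. On unit-range intensities this confines $a_i$
  to $[e^{-1}, 1]$ — a deliberately weak modulation; an optional sharpness
  multiplier is exposed for users who want a stronger discount, with
  default 1 (the published form).

Three distance forms give three variants (Pearson, inner product, squared
L2). Each leads to two sparse symmetric linear systems; the package
implements the *published operational systems verbatim*:

$$\mathrm{PEA}: (L_U + \tfrac12 A_U \operatorname{diag}(1/\tau^c))\,x = -B^\top m^c + a_U$$
$$\mathrm{INN}: L_U\,x = -B^\top m^c + A_U \tau^c$$
$$\mathrm{L2}: (L_U + A_U)\,x = -B^\top m^c + A_U \tau^c$$

For the L2 form these equations are exactly the stationarity condition of
the quadratic objective, so the solution is a true minimizer (the test suite
verifies it beats random perturbations). For PEA and INN the printed systems
do **not** match the gradients of the corresponding quadratic expansions
(the INN gradient would put $-\tfrac12 A\tau$ on the right-hand side; the
PEA expansion implies different constants). We follow the printed systems,
treating them as the operational algorithm, and do not "fix" the
discrepancy; it is observable — INN probabilities are not confined to
$[0,1]$ — and documented here rather than hidden.

## Conservation and range

For RW and L2-AP, summing the two per-label systems and using the Laplacian
row-sum identity $L_U \mathbf{1} + B^\top \mathbf{1} = 0$ together with
$\tau^f + \tau^b = 1$ on the region gives
$(L_U + A_U)(x^f + x^b) = (L_U + A_U)\mathbf{1}$, hence
$x^f_i + x^b_i = 1$ exactly, and each solve is a weighted average of
boundary values and targets in $[0,1]$, so $x \in [0,1]$ by the maximum
principle. PEA and INN provide no such guarantee and their probabilities are
reported unclamped.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `beta` | 310 | edge-weight contrast on unit intensities; 310/Γ = 0.8 is the published PEA/L2 operating point, 340/0.6 the INN one. Only sensible after [0,1] normalization — on a 0–255 scale every weight would underflow. |
| `gamma` (Γ) | 0.8 | shape-probability threshold; the region keeps cells covered by ≥ Γ·Ns training masks, so larger Γ gives a smaller, higher-confidence core (supports nest monotonically in Γ). |
| `epsilon_w` | 1e-6 | additive weight floor; keeps the lattice connected and $L_U$ SPD for any seed set. The graph stays solvable even where $\exp(-\beta\,\Delta)$ underflows. |
| `eps_tau` | 1e-6 | Pearson-only floor on τ inside the region: τ^b = 0 wherever the threshold matrix equals 1, which would make diag(1/τ) infinite. The floor is the minimal perturbation preserving ordering; L2/INN use exact τ. |
| `connectivity` | 4 | the RW convention; keeps systems sparsest. 8-connectivity available. |
| `margin_fraction`, `thickness` | 0.05, 1 | viewfinder geometry (never quantified in the source material; these are recorded as package decisions). |
| `sharpness` | 1 | multiplier inside $a_i$; the intensity scale of the published $a_i$ is unstated, so the published form is the default rather than a guess. |

Coordinates are 1-based `(row, col)` throughout (the R convention); node
linearization is row-major, `node = (row-1)*cols + col`.

## Shape prior learning

Masks are calibrated by integer translation of their rounded centroids
(halves round down) onto a common canvas — no scaling or interpolation, so
masks stay binary and SP entries stay exact multiples of 1/Ns. Masks of
different resolutions are placed on the common canvas without resampling.
The serialized prior stores the integer overlap counts and Ns rather than SP
floats, making the round-trip bit-exact. Training the prior on masks
disjoint from the evaluation images (the cross-database protocol) is
supported but is the user's responsibility to enforce.

## Numerical choices

* Sparse direct factorization (`Matrix::solve` on `dsCMatrix`) per label,
  followed by one step of iterative refinement whenever the residual exceeds
  `1e-12 (1 + ||b||∞)`; at β ≈ 300 the weights span many orders of magnitude
  and the refinement step is what keeps solutions at the 1e-10 level against
  a dense oracle.
* Fallback: Jacobi-preconditioned conjugate gradient (tolerance 1e-10,
  10·|V_U| iterations); plain CG stalls on these diagonals.
* Residual contract: `||Mx − b||∞ ≤ 1e-8 (1 + ||b||∞)`, else a solver error
  naming the likely cause (an unseeded component with `epsilon_w = 0`).
* Ties `x^f = x^b` go to foreground, favoring recall — consistent with
  retrieval-oriented evaluation (AAC/F2).
* The PEA system matrix depends on the label through diag(1/τ^c), so two
  label-specific matrices are assembled; the single-matrix notation of the
  source is resolved that way.

## The synthetic world

The phantom generator emulates the documented test conditions: a roughly
convex bright blob (the polyp) on a textured background with additive
Gaussian noise, radial vignetting (endoscope illumination), and an optional
weak-boundary arc where the edge is feathered below the noise level. The
stated world, chosen once:

* 96×96 canvas — a desk-scale stand-in for real 288×384 to 500×574 frames;
  object radii 16–24 px keep the seed-to-boundary distance, relative to a
  one-pixel seed, in the regime where single-seed RW is genuinely fragile.
* training corpus radii U(10, 24) — deliberately **broader** than the
  evaluation range U(16, 24), mirroring a training database with more size
  diversity than any one test subject. This keeps the Γ = 0.8 core a
  conservative subset of typical objects; if the core overhangs a small
  object, the attraction paints a foreground halo into the background —
  a real failure mode of the method worth knowing about.
* contrast +0.35 over background 0.35, sinusoidal texture amplitude 0.05,
  vignette 0.08, noise σ = 0.02 for the clean sets.
* weak boundary: over a contiguous arc (30% of the boundary in the standard
  sets) the contrast ramps across ±9 px, putting the per-pixel gradient
  (≈ 0.019) below the typical noise-induced neighbor difference (≈ 0.028),
  so the arc carries no reliable edge evidence.
* per-call integer seeds, no global RNG state; `generate_phantom_set()`
  freezes the evaluation protocol (shape mix, radii, ±3 px center jitter).

What the generator does **not** emulate: specular highlights, vessels,
bubbles, folds, depth-of-field blur, or spatially correlated sensor noise.
A green end-to-end test therefore establishes that the pipeline recovers
objects under noise, uneven illumination and locally absent boundaries with
a coarse prior — not clinical performance.

Two empirical properties of this world deserve explicit mention:

* **RW failure is bimodal.** On weak-boundary phantoms the random walker
  either recovers the object almost perfectly or collapses entirely,
  depending on whether the background frame's influence percolates through
  the feathered arc faster than the single seed's; the collapse probability
  is roughly 0.1 per phantom at the default settings. Mean-Dice margins
  over 20-phantom sets consequently vary noticeably with the set seed; the
  test suite uses the package-wide canonical seed. On real images, where
  boundary weakness is typical rather than arc-limited, the published RW
  baseline fails much more uniformly.
* **INN-AP floods on weak-edge graphs.** The printed INN system injects a
  positive source $A_U\tau^c$ without a compensating diagonal, so its effect
  scales with the inverse of the edge weights; when iid noise at β = 310
  makes all weights small, $x^f - x^b > 0$ almost everywhere and the whole
  frame interior is labeled foreground. This is faithful to the printed
  equations and consistent with the reported β-sensitivity of INN; it is
  why INN appears in the reduction and micro-example checks but not in the
  end-to-end recovery criteria.

## Known limitations

* One foreground seed only (by design); no multi-object or multi-label
  (K > 2) segmentation.
* 2-D lattices only; the formulation generalizes but is not implemented for
  3-D here.
* PEA/INN probabilities may leave $[0,1]$; only RW/L2 assert conservation.
* The prior is translation-only: no rotation or scale adaptation, so a
  Γ-core larger than the target object degrades precision (see above).
* PNG is the only raster format read or written (no TIFF reader is
  available in the supported dependency set).
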